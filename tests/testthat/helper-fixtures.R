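# Hand-built fixtures and the independent brute-force effect oracle.

# A tiny genome with one known CDS per strand. The plus-strand CDS is
# ATG CAT TGG TAA (M H W *) at chrP:4-15; the minus-strand contig carries
# the reverse complement of the same CDS at chrM:4-15.
tiny_cds_genome <- function() {
  plus_cds <- "ATGCATTGGTAA"
  minus_cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(plus_cds)))
  genome <- ref_genome(c(chrP = paste0("GGG", plus_cds, "GGGGG"),
                         chrM = paste0("GGG", minus_cds, "GGGGG")))
  cds <- cds_table(gene_id = c("gP", "gM"), contig = c("chrP", "chrM"),
                   start = c(4L, 4L), end = c(15L, 15L), strand = c("+", "-"))
  list(genome = genome, cds = cds)
}

# Independent effect oracle: rebuild the whole mutant contig by plain
# string editing, extract the (shifted) CDS span, reverse-complement if
# needed, translate with seqinr, and diff the proteins. Shares no code
# with annotate_effect().
oracle_translate <- function(seq) {
  aa <- seqinr::translate(strsplit(tolower(seq), "")[[1]])
  stop_at <- match("*", aa)
  if (is.na(stop_at)) list(protein = aa, stop = NA_integer_)
  else list(protein = aa[seq_len(stop_at - 1L)], stop = stop_at)
}

oracle_annotate <- function(cds, genome, variants) {
  contig <- genome$contigs[[cds$contig]]
  v <- variants[order(variants$pos, decreasing = TRUE), , drop = FALSE]
  mutant <- contig
  for (i in seq_len(nrow(v))) {
    p <- v$pos[i]; r <- v$ref[i]; a <- v$alt[i]
    stopifnot(substr(contig, p, p + nchar(r) - 1L) == r)
    mutant <- paste0(substr(mutant, 1L, p - 1L), a,
                     substr(mutant, p + nchar(r), nchar(mutant)))
  }
  net <- sum(nchar(v$alt) - nchar(v$ref))
  wt_seq <- substr(contig, cds$start, cds$end)
  mut_seq <- substr(mutant, cds$start, cds$end + net)
  if (cds$strand == "-") {
    rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    wt_seq <- rc(wt_seq); mut_seq <- rc(mut_seq)
  }
  tw <- oracle_translate(wt_seq); tm <- oracle_translate(mut_seq)
  pw <- tw$protein; pm <- tm$protein
  k <- min(length(pw), length(pm))
  d <- if (k) which(pw[seq_len(k)] != pm[seq_len(k)]) else integer(0)
  first_diff <- if (length(d)) d[1L] else k + 1L
  if (identical(pw, pm) && !is.na(tw$stop) && !is.na(tm$stop))
    return(list(effect = "synonymous", notation = "",
                n_altered_tail = NA_integer_, n_truncated = NA_integer_))
  if (net %% 3L != 0L) {
    n_alt <- length(pm) - (first_diff - 1L)
    n_tr <- if (is.na(tm$stop)) NA_integer_ else
      length(pw) - (first_diff - 1L) - n_alt
    return(list(effect = "frameshift", notation = paste0("fs@", first_diff),
                n_altered_tail = n_alt, n_truncated = n_tr))
  }
  has_indel <- any(nchar(v$ref) != nchar(v$alt))
  if (length(pm) < length(pw) && !has_indel) {
    s <- length(pm) + 1L
    return(list(effect = "nonsense", notation = paste0(pw[s], s, "*"),
                n_altered_tail = NA_integer_, n_truncated = length(pw) - length(pm)))
  }
  if (!has_indel && (is.na(tm$stop) || length(pm) > length(pw)) && !is.na(tw$stop))
    return(list(effect = "stop_lost",
                notation = paste0("*", length(pw) + 1L,
                                  if (length(pm) >= length(pw) + 1L)
                                    pm[length(pw) + 1L] else "*"),
                n_altered_tail = NA_integer_, n_truncated = NA_integer_))
  if (has_indel)
    return(list(effect = "inframe_indel", notation = paste0("inframe@", first_diff),
                n_altered_tail = NA_integer_, n_truncated = NA_integer_))
  list(effect = "missense",
       notation = paste0(pw[first_diff], first_diff, pm[first_diff]),
       n_altered_tail = NA_integer_, n_truncated = NA_integer_)
}

# Draw a random in-CDS variant set for the oracle-equivalence tests:
# 1-3 non-overlapping SNVs/insertions/deletions fully inside the CDS.
random_cds_variants <- function(cds, genome, n_max = 3L) {
  n <- sample.int(n_max, 1L)
  contig <- genome$contigs[[cds$contig]]
  taken <- matrix(integer(0), ncol = 2)
  out <- list()
  for (k in seq_len(n)) {
    for (try in 1:50) {
      p <- sample(cds$start:(cds$end - 5L), 1L)
      kind <- sample(c("snv", "ins", "del"), 1L, prob = c(0.6, 0.2, 0.2))
      len <- if (kind == "del") sample(1:4, 1L) else 0L
      lo <- p; hi <- p + len
      if (hi > cds$end) next
      if (!nrow(taken) || all(hi < taken[, 1] | lo > taken[, 2])) break
    }
    if (hi > cds$end || (nrow(taken) && any(hi >= taken[, 1] & lo <= taken[, 2])))
      next
    taken <- rbind(taken, c(lo, hi))
    base <- substr(contig, p, p)
    if (kind == "snv") {
      ref <- base
      alt <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
    } else if (kind == "ins") {
      ref <- base
      alt <- paste0(base, paste(sample(c("A", "C", "G", "T"),
                                       sample(1:4, 1L), replace = TRUE),
                                collapse = ""))
    } else {
      ref <- substr(contig, p, p + len)
      alt <- base
    }
    out[[length(out) + 1L]] <- data.frame(pos = p, ref = ref, alt = alt,
                                          stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# Build an annotated-effects fixture row block for cohort accounting tests.
fake_effects <- function(strain, n, category, aa = rep(FALSE, n),
                         gene = rep(NA_character_, n),
                         contig_class = rep("reference", n), offset = 0L) {
  data.frame(strain = strain, contig = "chr1", pos = offset + seq_len(n),
             ref = "A", parent_gt = "A/G",
             evolved_gt = if (category == "loh") "G/G" else "A/T",
             category = category, zygosity = if (category == "loh") "hom" else "het",
             is_reversion = if (category == "loh") FALSE else NA,
             novel_alleles = if (category == "loh") "" else "T",
             variant_kind = "snp", contig_class = contig_class,
             gene_id = gene, effect = ifelse(aa, "missense", "synonymous"),
             notation = ifelse(aa, "A1T", ""), aa_changing = aa,
             stringsAsFactors = FALSE)
}
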