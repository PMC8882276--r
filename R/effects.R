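# CDS effect annotation: apply anchored variants to a coding sequence,
# translate, and describe the protein-level consequence (substitution
# notation, premature stop, frameshift tail accounting).

#' Extract the strand-corrected coding sequence of a CDS feature
#' @param cds One-row [cds_table()] slice (or a list with the same fields).
#' @param genome A [ref_genome()].
#' @return Character scalar: the coding sequence 5'->3'.
#' @export
cds_sequence <- function(cds, genome) {
  s <- substr(genome$contigs[[cds$contig]], cds$start, cds$end)
  if (cds$strand == "-") revcomp(s) else s
}

#' Apply anchored variants to a CDS and return the mutant coding sequence
#'
#' Variants (VCF-style anchored `pos`/`ref`/`alt` in forward-strand genomic
#' coordinates) are applied jointly, right-to-left in genomic coordinates so
#' earlier edits do not shift later coordinates; for minus-strand features
#' the edited region is reverse-complemented afterwards. A variant
#' extending past the CDS boundary has its edit truncated to the CDS and
#' the result is flagged.
#'
#' @param cds One-row [cds_table()] slice.
#' @param genome A [ref_genome()].
#' @param variants data.frame with columns `pos`, `ref`, `alt`.
#' @return List: `wt` and `mut` coding sequences (5'->3'),
#'   `boundary_truncated` flag.
#' @export
apply_variants_to_cds <- function(cds, genome, variants) {
  region <- substr(genome$contigs[[cds$contig]], cds$start, cds$end)
  wt <- if (cds$strand == "-") revcomp(region) else region
  if (is.null(variants) || !nrow(variants))
    return(list(wt = wt, mut = wt, boundary_truncated = FALSE))
  v <- variants[order(variants$pos, decreasing = TRUE), , drop = FALSE]
  vend <- v$pos + nchar(v$ref) - 1L
  if (nrow(v) > 1L && any(v$pos[-nrow(v)] <= vend[-1L]))
    stop("overlapping variant intervals in ", cds$gene_id)
  truncated <- FALSE
  for (i in seq_len(nrow(v))) {
    p <- v$pos[i]; r <- v$ref[i]; a <- v$alt[i]
    if (p + nchar(r) - 1L < cds$start || p > cds$end) next
    obs <- substr(genome$contigs[[cds$contig]], p, p + nchar(r) - 1L)
    if (obs != r)
      stop("variant reference allele ", r, " does not match genome (", obs,
           ") at ", cds$contig, ":", p)
    if (p < cds$start || p + nchar(r) - 1L > cds$end) {
      # clip the edit to the CDS: delete only in-CDS reference bases; an
      # insertion anchored outside contributes nothing inside
      truncated <- TRUE
      lo <- max(p, cds$start); hi <- min(p + nchar(r) - 1L, cds$end)
      rel_lo <- lo - cds$start + 1L; rel_hi <- hi - cds$start + 1L
      repl <- if (p >= cds$start) substr(a, 1L, 1L) else ""
      region <- paste0(substr(region, 1L, rel_lo - 1L), repl,
                       substr(region, rel_hi + 1L, nchar(region)))
    } else {
      rel <- p - cds$start + 1L
      region <- paste0(substr(region, 1L, rel - 1L), a,
                       substr(region, rel + nchar(r), nchar(region)))
    }
  }
  mut <- if (cds$strand == "-") revcomp(region) else region
  list(wt = wt, mut = mut, boundary_truncated = truncated)
}

#' Translate a coding sequence with the standard nuclear genetic code
#'
#' Translation stops at the first stop codon; the protein, the codon index
#' of that stop and an incomplete-trailing-codon flag are returned.
#'
#' @param seq Coding nucleotide sequence (length >= 3).
#' @return List: `protein` (character scalar), `stop_codon` (codon index of
#'   the first stop, `NA` if none before the end), `incomplete` (logical).
#' @export
translate_cds <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) stop("sequence shorter than one codon")
  amb <- regexpr("[^ACGT]", seq)
  if (amb > 0L) stop("ambiguous base at position ", amb)
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stop_at <- match("*", aa)
  protein <- if (is.na(stop_at)) paste(aa, collapse = "") else
    paste(aa[seq_len(stop_at - 1L)], collapse = "")
  list(protein = protein, stop_codon = stop_at, incomplete = n %% 3L != 0L)
}

#' Classify an amino-acid substitution as conservative or not
#'
#' Conservative means a positive substitution score under the configured
#' similarity matrix (BLOSUM62 by default).
#'
#' @param aa_ref,aa_alt Single-letter amino acids.
#' @param matrix A substitution matrix; default BLOSUM62.
#' @return `"conservative"` or `"non_conservative"` (vectorized).
#' @export
classify_conservation <- function(aa_ref, aa_alt, matrix = NULL) {
  if (is.null(matrix)) matrix <- blosum62()
  if (any(aa_ref == "*" | aa_alt == "*"))
    stop("stop codon is not a substitution (handle as nonsense)")
  bad <- !(aa_ref %in% rownames(matrix)) | !(aa_alt %in% colnames(matrix))
  if (any(bad)) stop("non-standard amino acid: ",
                     paste(unique(c(aa_ref[bad], aa_alt[bad])), collapse = ", "))
  ifelse(matrix[cbind(aa_ref, aa_alt)] > 0, "conservative", "non_conservative")
}

blosum62_env <- new.env()
blosum62 <- function() {
  if (is.null(blosum62_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_env$m <- e$BLOSUM62
  }
  blosum62_env$m
}

#' Annotate the protein-level effect of a variant set on one CDS
#'
#' Compares the wild-type and mutant translations. A net in-CDS indel
#' length not divisible by 3 is a frameshift, reported with the position of
#' the first altered residue, the number of altered residues up to the new
#' stop, and the number of wild-type residues truncated; a premature stop
#' is nonsense (`aa_ref` + position + `"*"`); equal-length differing
#' proteins are missense, reported at the first differing residue; a
#' destroyed wild-type stop is `stop_lost`. Variants are applied jointly.
#'
#' @param cds One-row [cds_table()] slice.
#' @param genome A [ref_genome()].
#' @param variants data.frame with columns `pos`, `ref`, `alt` (anchored,
#'   genomic coordinates); may be empty.
#' @return One-row data.frame: `gene_id`, `effect`, `notation`,
#'   `protein_pos`, `aa_ref`, `aa_alt`, `conservation`,
#'   `n_altered_tail`, `n_truncated`, `stop_not_found`,
#'   `boundary_truncated`.
#' @export
annotate_effect <- function(cds, genome, variants) {
  in_cds <- if (is.null(variants) || !nrow(variants)) variants else
    variants[variants$pos + nchar(variants$ref) - 1L >= cds$start &
             variants$pos <= cds$end, , drop = FALSE]
  res <- list(gene_id = cds$gene_id, effect = "intergenic", notation = "",
              protein_pos = NA_integer_, aa_ref = NA_character_,
              aa_alt = NA_character_, conservation = "n/a",
              n_altered_tail = NA_integer_, n_truncated = NA_integer_,
              stop_not_found = FALSE, boundary_truncated = FALSE)
  if (is.null(in_cds) || !nrow(in_cds))
    return(as.data.frame(res, stringsAsFactors = FALSE))

  ap <- apply_variants_to_cds(cds, genome, in_cds)
  res$boundary_truncated <- ap$boundary_truncated
  tw <- translate_cds(ap$wt)
  tm <- translate_cds(ap$mut)
  pw <- strsplit(tw$protein, "")[[1L]]
  pm <- strsplit(tm$protein, "")[[1L]]
  net <- nchar(ap$mut) - nchar(ap$wt)
  has_indel <- any(nchar(in_cds$ref) != nchar(in_cds$alt))

  if (identical(pw, pm) && !is.na(tw$stop_codon) && !is.na(tm$stop_codon)) {
    res$effect <- "synonymous"
    return(as.data.frame(res, stringsAsFactors = FALSE))
  }
  k <- min(length(pw), length(pm))
  first_diff <- if (k == 0L) 1L else {
    d <- which(pw[seq_len(k)] != pm[seq_len(k)])
    if (length(d)) d[1L] else k + 1L
  }
  res$protein_pos <- first_diff
  res$aa_ref <- if (first_diff <= length(pw)) pw[first_diff] else "*"
  res$aa_alt <- if (first_diff <= length(pm)) pm[first_diff] else "*"

  if (net %% 3L != 0L) {
    res$effect <- "frameshift"
    res$notation <- paste0("fs@", first_diff)
    if (is.na(tm$stop_codon)) {
      res$stop_not_found <- TRUE
      res$n_altered_tail <- length(pm) - (first_diff - 1L)
      res$n_truncated <- NA_integer_
    } else {
      res$n_altered_tail <- length(pm) - (first_diff - 1L)
      res$n_truncated <- length(pw) - (first_diff - 1L) - res$n_altered_tail
    }
    return(as.data.frame(res, stringsAsFactors = FALSE))
  }
  if (length(pm) < length(pw) && !has_indel) {
    # premature stop by substitution
    s <- length(pm) + 1L
    res$effect <- "nonsense"
    res$protein_pos <- s
    res$aa_ref <- pw[s]; res$aa_alt <- "*"
    res$notation <- paste0(pw[s], s, "*")
    res$n_truncated <- length(pw) - length(pm)
    return(as.data.frame(res, stringsAsFactors = FALSE))
  }
  if (!has_indel && (is.na(tm$stop_codon) || length(pm) > length(pw)) &&
      !is.na(tw$stop_codon)) {
    res$effect <- "stop_lost"
    res$protein_pos <- length(pw) + 1L
    res$aa_ref <- "*"
    res$aa_alt <- if (length(pm) >= length(pw) + 1L) pm[length(pw) + 1L] else "*"
    res$notation <- paste0("*", length(pw) + 1L, res$aa_alt)
    res$stop_not_found <- is.na(tm$stop_codon)
    return(as.data.frame(res, stringsAsFactors = FALSE))
  }
  if (has_indel) {
    res$effect <- "inframe_indel"
    res$notation <- paste0("inframe@", first_diff)
    res$stop_not_found <- is.na(tm$stop_codon)
    return(as.data.frame(res, stringsAsFactors = FALSE))
  }
  # equal length, substitutions only: missense at the first differing residue
  if (length(pm) < length(pw)) s <- NULL  # unreachable; guarded above
  res$effect <- "missense"
  if (res$aa_alt == "*") {  # paranoid: should have been caught as nonsense
    res$effect <- "nonsense"
    res$notation <- paste0(res$aa_ref, first_diff, "*")
  } else {
    res$notation <- paste0(res$aa_ref, first_diff, res$aa_alt)
    res$conservation <- classify_conservation(res$aa_ref, res$aa_alt)
  }
  as.data.frame(res, stringsAsFactors = FALSE)
}

AA_CHANGING <- c("missense", "nonsense", "stop_lost", "frameshift", "inframe_indel")

call_alt_allele <- function(calls) {
  # the allele to annotate against the reference: the (first) novel allele
  # for a new variant, the retained allele for an LOH event
  retained <- sub("/.*$", "", calls$evolved_gt)
  ifelse(calls$category == "new_variant",
         sub(",.*$", "", calls$novel_alleles), retained)
}

#' Annotate all mutation calls of a strain against the gene models
#'
#' Each call is located in the CDS features; calls outside any CDS are
#' `intergenic`. In `"per_variant"` mode (default, used for the per-call
#' amino-acid-change flag of cohort tables) each call is annotated alone;
#' in `"joint"` mode all of a strain's calls within one CDS are applied
#' together and every member call receives the gene-level annotation.
#' LOH reversions carry the reference allele and therefore produce no
#' protein change; they are annotated `synonymous` with empty notation.
#'
#' @param calls A `mutation_calls` data.frame (one strain).
#' @param genome A [ref_genome()].
#' @param cds A [cds_table()].
#' @param mode `"per_variant"` or `"joint"`.
#' @return `calls` with annotation columns appended (`gene_id`, `effect`,
#'   `notation`, `aa_changing`, ...).
#' @export
annotate_calls <- function(calls, genome, cds, mode = c("per_variant", "joint")) {
  mode <- match.arg(mode)
  n <- nrow(calls)
  ann <- data.frame(gene_id = rep(NA_character_, n), effect = "intergenic",
                    notation = "", protein_pos = NA_integer_,
                    aa_ref = NA_character_, aa_alt = NA_character_,
                    conservation = "n/a", n_altered_tail = NA_integer_,
                    n_truncated = NA_integer_, stop_not_found = FALSE,
                    boundary_truncated = FALSE, stringsAsFactors = FALSE)
  if (n && nrow(cds)) {
    call_gr <- GenomicRanges::GRanges(calls$contig,
      IRanges::IRanges(calls$pos, width = nchar(calls$ref)))
    cds_gr <- GenomicRanges::GRanges(cds$contig,
      IRanges::IRanges(cds$start, cds$end))
    hits <- GenomicRanges::findOverlaps(call_gr, cds_gr, select = "first")
    alt <- call_alt_allele(calls)
    groups <- split(seq_len(n)[!is.na(hits)], hits[!is.na(hits)])
    for (g in names(groups)) {
      feat <- cds[as.integer(g), ]
      idx <- groups[[g]]
      changed <- idx[alt[idx] != calls$ref[idx]]
      unchanged <- setdiff(idx, changed)
      if (length(unchanged)) {  # reversions: no edit relative to the reference
        ann$gene_id[unchanged] <- feat$gene_id
        ann$effect[unchanged] <- "synonymous"
      }
      if (!length(changed)) next
      if (mode == "joint") {
        v <- data.frame(pos = calls$pos[changed], ref = calls$ref[changed],
                        alt = alt[changed], stringsAsFactors = FALSE)
        a <- annotate_effect(feat, genome, v)
        for (cn in names(ann)) ann[changed, cn] <- a[[cn]]
      } else {
        for (i in changed) {
          v <- data.frame(pos = calls$pos[i], ref = calls$ref[i],
                          alt = alt[i], stringsAsFactors = FALSE)
          a <- annotate_effect(feat, genome, v)
          for (cn in names(ann)) ann[i, cn] <- a[[cn]]
        }
      }
    }
  }
  out <- cbind(as.data.frame(calls), ann)
  out$aa_changing <- out$effect %in% AA_CHANGING
  class(out) <- c("mutation_effects", "data.frame")
  out
}

#' Write / read an annotated effects table as TSV
#' @param effects A `mutation_effects` data.frame.
#' @param path TSV path.
#' @return `path` (writer) or the table (reader).
#' @export
write_effects <- function(effects, path) {
  write.table(as.data.frame(effects), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_effects
#' @export
read_effects <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = "NA")
  for (cn in c("novel_alleles", "notation"))
    df[[cn]][is.na(df[[cn]])] <- ""
  class(df) <- c("mutation_effects", "data.frame")
  df
}
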