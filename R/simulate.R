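# Synthetic diploid-evolution generator: heterozygous parent, evolved
# lineages dominated by LOH tracts, scattered de novo events, CNVs with
# Poisson depth, and a machine-readable truth set.

STOP_CODONS <- c("TAA", "TAG", "TGA")

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulation configuration for a synthetic diploid-evolution cohort
#'
#' Defaults emulate an industrial-yeast adaptive-evolution setting: a
#' heterozygous diploid parent at ~1 het site per 300 bp, evolved lineages
#' in which LOH tracts dwarf de novo mutation (about 200 LOH sites against
#' a mean of 18 de novo events per lineage, i.e. ~8% new variants), roughly
#' half of LOH tracts retaining the reference allele, and mean sequencing
#' depth 50x.
#'
#' @param contig_lengths Named integer vector of contig lengths in bp.
#' @param gc_fraction Genome GC content (yeast-like 0.38).
#' @param n_cds_per_contig CDS features planted per contig.
#' @param cds_length_range Min/max CDS length in bp (rounded to codons).
#' @param het_density Parent heterozygous sites per bp.
#' @param n_loh_tracts LOH tracts per evolved lineage.
#' @param tract_mean_length Mean of the geometric tract-length distribution (bp).
#' @param p_terminal_tract Probability a tract is anchored at a contig end.
#' @param p_retain_reference Probability a tract homozygoses to the
#'   reference allele (a reversion tract).
#' @param n_de_novo Poisson mean of de novo events per lineage.
#' @param snv_fraction Fraction of de novo events that are SNVs (rest indels).
#' @param p_de_novo_hom Probability a de novo event is homozygous.
#' @param cnv_events `NULL`, or a data.frame with columns `contig`, `start`,
#'   `end` (`NA` for whole-contig) and `copy_delta` in {-1, +1, +2}, applied
#'   to every lineage (per-lineage events can be passed to
#'   [evolve_lineage()] directly).
#' @param mean_depth Mean per-base sequencing depth at copy number 2.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(contig_lengths = c(chrI = 100000L, chrII = 100000L, chrIII = 100000L),
                       gc_fraction = 0.38,
                       n_cds_per_contig = 30L,
                       cds_length_range = c(300L, 1500L),
                       het_density = 1 / 300,
                       n_loh_tracts = 4L,
                       tract_mean_length = 15000,
                       p_terminal_tract = 0.2,
                       p_retain_reference = 0.5,
                       n_de_novo = 18,
                       snv_fraction = 0.9,
                       p_de_novo_hom = 0.1,
                       cnv_events = NULL,
                       mean_depth = 50) {
  stopifnot(all(contig_lengths > 0), length(contig_lengths) >= 1)
  if (is.null(names(contig_lengths)))
    names(contig_lengths) <- sprintf("chr%02d", seq_along(contig_lengths))
  probs <- c(gc_fraction, het_density, p_terminal_tract,
             p_retain_reference, snv_fraction, p_de_novo_hom)
  if (any(probs < 0 | probs > 1)) stop("probabilities/densities must lie in [0, 1]")
  stopifnot(tract_mean_length > 0, n_de_novo >= 0, mean_depth > 0,
            n_loh_tracts >= 0, cds_length_range[1] >= 9,
            cds_length_range[1] <= cds_length_range[2])
  if (!is.null(cnv_events)) {
    stopifnot(is.data.frame(cnv_events),
              all(c("contig", "start", "end", "copy_delta") %in% names(cnv_events)),
              all(cnv_events$copy_delta %in% c(-1L, 1L, 2L)))
  }
  structure(list(contig_lengths = contig_lengths, gc_fraction = gc_fraction,
                 n_cds_per_contig = as.integer(n_cds_per_contig),
                 cds_length_range = as.integer(cds_length_range),
                 het_density = het_density,
                 n_loh_tracts = as.integer(n_loh_tracts),
                 tract_mean_length = tract_mean_length,
                 p_terminal_tract = p_terminal_tract,
                 p_retain_reference = p_retain_reference,
                 n_de_novo = n_de_novo, snv_fraction = snv_fraction,
                 p_de_novo_hom = p_de_novo_hom, cnv_events = cnv_events,
                 mean_depth = mean_depth),
            class = "sim_config")
}

random_codons <- function(n) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  paste(sample(sense, n, replace = TRUE), collapse = "")
}

#' Generate a random reference genome with planted CDS features
#'
#' Sequences are i.i.d. draws at the configured GC fraction. CDS features
#' are non-overlapping, placed on both strands, and constructed as
#' ATG + sense codons + stop, so every feature translates to a protein with
#' no internal stop. Output is deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer RNG seed.
#' @return List with elements `genome` ([ref_genome()]) and `cds`
#'   ([cds_table()]).
#' @export
make_reference <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  gc <- config$gc_fraction
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  contigs <- character(0)
  feats <- list()
  for (ct in names(config$contig_lengths)) {
    len <- config$contig_lengths[[ct]]
    seq_chars <- sample(names(base_prob), len, replace = TRUE, prob = base_prob)
    placed <- matrix(numeric(0), ncol = 2)  # start, end
    for (k in seq_len(config$n_cds_per_contig)) {
      len_choices <- seq(config$cds_length_range[1], config$cds_length_range[2], by = 3L)
      cds_len <- len_choices[sample.int(length(len_choices), 1L)]
      ok <- FALSE
      for (try in 1:200) {
        st <- sample.int(len - cds_len + 1L, 1L)
        en <- st + cds_len - 1L
        if (!nrow(placed) || all(en + 2L < placed[, 1] | st - 2L > placed[, 2])) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place ", config$n_cds_per_contig,
                    " CDS features on contig ", ct, " without overlap")
      strand <- sample(c("+", "-"), 1L)
      cds_seq <- paste0("ATG", random_codons(cds_len / 3L - 2L),
                        sample(STOP_CODONS, 1L))
      genomic <- if (strand == "+") cds_seq else revcomp(cds_seq)
      seq_chars[st:en] <- strsplit(genomic, "")[[1L]]
      placed <- rbind(placed, c(st, en))
      feats[[length(feats) + 1L]] <- data.frame(
        gene_id = sprintf("%s_g%02d", ct, k), contig = ct,
        start = st, end = en, strand = strand, stringsAsFactors = FALSE)
    }
    contigs[[ct]] <- paste(seq_chars, collapse = "")
  }
  fd <- do.call(rbind, feats)
  list(genome = ref_genome(contigs),
       cds = cds_table(fd$gene_id, fd$contig, fd$start, fd$end, fd$strand))
}

#' Generate the heterozygous diploid parent
#'
#' Heterozygous SNV sites are drawn uniformly over the genome; the site
#' count is Binomial(genome size, `het_density`) and every site carries a
#' ref/alt genotype with a uniformly chosen non-reference base.
#'
#' @param reference A [ref_genome()].
#' @param het_density Heterozygous sites per bp.
#' @param seed Integer RNG seed.
#' @param strain_id Strain id for the table (default "parent").
#' @return A [genotype_table()] in which every site is heterozygous.
#' @export
make_parent <- function(reference, het_density, seed, strain_id = "parent") {
  stopifnot(inherits(reference, "ref_genome"), het_density >= 0)
  set.seed(seed)
  lens <- contig_lengths(reference)
  total <- sum(lens)
  n <- rbinom(1L, total, het_density)
  if (n == 0L) return(genotype_table(strain_id = strain_id))
  flat <- sort(sample.int(total, n))
  offsets <- cumsum(c(0, as.numeric(lens)))
  idx <- findInterval(flat, offsets + 1)
  contig <- names(lens)[idx]
  pos <- as.integer(flat - offsets[idx])
  refb <- substring(reference$contigs[contig], pos, pos)
  alt <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  genotype_table(contig, pos, refb, refb, alt, strain_id = strain_id)
}

draw_tracts <- function(config, lens, retry_cap = 100L) {
  n <- config$n_loh_tracts
  tracts <- data.frame(contig = character(), start = integer(), end = integer(),
                       terminal = logical(), stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(retry_cap)) {
      ct <- sample(names(lens), 1L, prob = lens / sum(lens))
      L <- lens[[ct]]
      tlen <- min(L, rgeom(1L, 1 / config$tract_mean_length) + 1L)
      if (runif(1) < config$p_terminal_tract) {
        if (runif(1) < 0.5) { st <- 1L; en <- tlen }
        else { st <- L - tlen + 1L; en <- L }
        term <- TRUE
      } else {
        st <- sample.int(L - tlen + 1L, 1L); en <- st + tlen - 1L
        term <- st == 1L || en == L
      }
      same <- tracts[tracts$contig == ct, , drop = FALSE]
      if (!nrow(same) || all(en < same$start | st > same$end)) { ok <- TRUE; break }
    }
    if (!ok) stop("could not draw ", n, " non-overlapping LOH tracts (retry cap hit)")
    tracts <- rbind(tracts, data.frame(contig = ct, start = st, end = en,
                                       terminal = term, stringsAsFactors = FALSE))
  }
  tracts
}

#' Evolve one lineage from the parent
#'
#' Plants LOH tracts (each tract homozygoses every parent-het site it
#' covers to a single homolog: the reference homolog with probability
#' `p_retain_reference`, in which case the sites become hom-ref, drop out
#' of the evolved genotype table, and are recorded as reversions in the
#' truth set), de novo SNVs/indels at fresh positions, and copy-number
#' events recorded only in the true copy profile (genotypes stay diploid).
#'
#' @param parent Parent [genotype_table()].
#' @param reference A [ref_genome()].
#' @param config A [sim_config()].
#' @param seed Integer RNG seed.
#' @param strain_id Evolved strain id.
#' @param cnv_events Optional per-lineage CNV data.frame overriding
#'   `config$cnv_events`.
#' @return List of class `lineage` with elements `evolved`
#'   ([genotype_table()]) and `truth` (a `truth_set`: `sites` data.frame
#'   with per-site labels, `tracts`, `de_novo`, and `copy` — the true
#'   per-position copy-number profile).
#' @export
evolve_lineage <- function(parent, reference, config, seed,
                           strain_id = "evolved", cnv_events = NULL) {
  stopifnot(inherits(parent, "genotype_table"), inherits(config, "sim_config"))
  set.seed(seed)
  lens <- contig_lengths(reference)
  tracts <- draw_tracts(config, lens)
  if (nrow(tracts))
    tracts$retain_reference <- runif(nrow(tracts)) < config$p_retain_reference

  evolved <- as.data.frame(parent)
  truth_sites <- list()
  drop_idx <- integer(0)

  for (i in seq_len(nrow(tracts))) {
    tr <- tracts[i, ]
    in_tract <- which(evolved$contig == tr$contig &
                      evolved$pos >= tr$start & evolved$pos <= tr$end)
    if (!length(in_tract)) next
    het <- in_tract[evolved$a1[in_tract] != evolved$a2[in_tract]]
    if (!length(het)) next
    alt <- ifelse(evolved$a1[het] == evolved$ref[het], evolved$a2[het], evolved$a1[het])
    if (tr$retain_reference) {
      retained <- evolved$ref[het]
      drop_idx <- c(drop_idx, het)
    } else {
      retained <- alt
      evolved$a1[het] <- retained
      evolved$a2[het] <- retained
    }
    truth_sites[[length(truth_sites) + 1L]] <- data.frame(
      contig = evolved$contig[het], pos = evolved$pos[het],
      ref = evolved$ref[het], category = "loh", zygosity = "hom",
      is_reversion = tr$retain_reference, allele = retained,
      tract = i, stringsAsFactors = FALSE)
  }
  if (length(drop_idx)) evolved <- evolved[-drop_idx, , drop = FALSE]

  # de novo events at fresh positions
  n_dn <- rpois(1L, config$n_de_novo)
  used <- paste(parent$contig, parent$pos)
  de_novo <- list()
  for (k in seq_len(n_dn)) {
    for (try in 1:200) {
      ct <- sample(names(lens), 1L, prob = lens / sum(lens))
      p <- sample.int(lens[[ct]] - 5L, 1L)
      # keep a 5-bp clearance so anchored deletions cannot swallow a
      # neighbouring variable site
      if (!any(paste(ct, p:(p + 4L)) %in% used)) break
    }
    used <- c(used, paste(ct, p:(p + 4L)))
    refb <- substring(reference$contigs[[ct]], p, p)
    if (runif(1) < config$snv_fraction) {
      ref_al <- refb
      alt_al <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
      kind <- "snp"
    } else if (runif(1) < 0.5) {  # insertion after anchor
      ins <- paste(sample(c("A", "C", "G", "T"), sample(1:4, 1L), replace = TRUE),
                   collapse = "")
      ref_al <- refb
      alt_al <- paste0(refb, ins)
      kind <- "indel"
    } else {                      # deletion anchored at p
      dlen <- sample(1:4, 1L)
      ref_al <- substring(reference$contigs[[ct]], p, p + dlen)
      alt_al <- refb
      kind <- "indel"
    }
    hom <- runif(1) < config$p_de_novo_hom
    a1 <- if (hom) alt_al else ref_al
    a2 <- alt_al
    evolved <- rbind(evolved, data.frame(contig = ct, pos = p, ref = ref_al,
                                         a1 = a1, a2 = a2, stringsAsFactors = FALSE))
    de_novo[[k]] <- data.frame(contig = ct, pos = p, ref = ref_al,
                               category = "new_variant",
                               zygosity = if (hom) "hom" else "het",
                               is_reversion = NA, allele = alt_al,
                               kind = kind, stringsAsFactors = FALSE)
    truth_sites[[length(truth_sites) + 1L]] <-
      cbind(de_novo[[k]][, c("contig", "pos", "ref", "category", "zygosity",
                             "is_reversion", "allele")], tract = NA_integer_)
  }

  # true copy-number profile
  ev <- if (!is.null(cnv_events)) cnv_events else config$cnv_events
  copy <- lapply(lens, function(L) rep(2, L))
  if (!is.null(ev)) for (i in seq_len(nrow(ev))) {
    ct <- ev$contig[i]
    if (!ct %in% names(copy)) stop("CNV event on unknown contig ", ct)
    span <- if (is.na(ev$start[i]) || is.na(ev$end[i]))
      seq_len(lens[[ct]]) else ev$start[i]:ev$end[i]
    copy[[ct]][span] <- pmax(0, copy[[ct]][span] + ev$copy_delta[i])
  }

  sites <- if (length(truth_sites)) do.call(rbind, truth_sites) else
    data.frame(contig = character(), pos = integer(), ref = character(),
               category = character(), zygosity = character(),
               is_reversion = logical(), allele = character(),
               tract = integer(), stringsAsFactors = FALSE)
  sites <- sites[order(sites$contig, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  truth <- structure(list(sites = sites, tracts = tracts,
                          de_novo = if (length(de_novo)) do.call(rbind, de_novo) else NULL,
                          copy = copy),
                     class = "truth_set")
  ev_gt <- genotype_table(evolved$contig, evolved$pos, evolved$ref,
                          evolved$a1, evolved$a2, strain_id = strain_id)
  structure(list(evolved = ev_gt, truth = truth), class = "lineage")
}

#' Simulate a per-base depth track from a true copy profile
#'
#' Depth at position i is an independent Poisson draw with mean
#' `mean_depth * copy_i / 2`, so copy-2 regions average `mean_depth`.
#'
#' @param copy_profile Named list of per-position copy numbers.
#' @param mean_depth Mean depth at copy number 2 (> 0).
#' @param seed Integer RNG seed.
#' @return A [depth_track()].
#' @export
simulate_depth <- function(copy_profile, mean_depth, seed) {
  stopifnot(mean_depth > 0)
  if (any(vapply(copy_profile, function(v) any(v < 0), TRUE)))
    stop("negative copy number in profile")
  set.seed(seed)
  depth_track(lapply(copy_profile, function(cp)
    rpois(length(cp), mean_depth * cp / 2)))
}

#' Generate a complete synthetic cohort on disk
#'
#' Writes the reference FASTA, GFF3 gene models, contig-class manifest,
#' parent VCF, and per-lineage VCFs, depth TSVs, depth WIG tracks and truth
#' JSON, plus a strain-group manifest and an md5 checksum manifest that
#' makes the fixture reproducible.
#'
#' @param config A [sim_config()].
#' @param n_lineages Number of evolved lineages (>= 1).
#' @param out_dir Output directory; must be empty unless `force = TRUE`.
#' @param seed Integer master seed; all per-lineage seeds derive from it.
#' @param groups Optional named list `group -> character vector of strain
#'   ids` (ids are `EV1..EVn`); default splits lineages into two media
#'   groups `YE_SSL` and `MM_SSL`.
#' @param cnv_events Optional list of per-lineage CNV data.frames, named by
#'   strain id.
#' @param force Overwrite a non-empty `out_dir`.
#' @return Invisibly, a list with the file manifest and in-memory objects
#'   (`genome`, `cds`, `parent`, `lineages`).
#' @export
generate_cohort <- function(config, n_lineages, out_dir, seed,
                            groups = NULL, cnv_events = NULL, force = FALSE) {
  stopifnot(inherits(config, "sim_config"), n_lineages >= 1)
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stop("output directory ", out_dir, " is non-empty (use force = TRUE)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_lineages + 2L)
  ref <- make_reference(config, seeds[1L])
  parent <- make_parent(ref$genome, config$het_density, seeds[2L])

  ids <- sprintf("EV%d", seq_len(n_lineages))
  if (is.null(groups)) {
    half <- ceiling(n_lineages / 2)
    groups <- list(YE_SSL = ids[seq_len(half)],
                   MM_SSL = ids[setdiff(seq_len(n_lineages), seq_len(half))])
  }
  gdf <- data.frame(strain = unlist(groups, use.names = FALSE),
                    group = rep(names(groups), lengths(groups)))

  paths <- list(
    fasta = file.path(out_dir, "reference.fa"),
    gff = file.path(out_dir, "genes.gff3"),
    classes = file.path(out_dir, "classes.tsv"),
    parent_vcf = file.path(out_dir, "parent.vcf"),
    groups = file.path(out_dir, "groups.tsv"))
  write_genome(ref$genome, paths$fasta)
  write_cds(ref$cds, paths$gff)
  write_class_manifest(ref$genome$class, paths$classes)
  write_diploid_vcf(parent, paths$parent_vcf, ref$genome)
  write_groups(gdf, paths$groups)

  lineages <- list()
  for (i in seq_len(n_lineages)) {
    id <- ids[i]
    lin <- evolve_lineage(parent, ref$genome, config, seeds[i + 2L],
                          strain_id = id, cnv_events = cnv_events[[id]])
    depth <- simulate_depth(lin$truth$copy, config$mean_depth, seeds[i + 2L])
    vcf <- file.path(out_dir, paste0(id, ".vcf"))
    dts <- file.path(out_dir, paste0(id, ".depth.tsv"))
    wig <- file.path(out_dir, paste0(id, ".depth.wig"))
    tj <- file.path(out_dir, paste0(id, ".truth.json"))
    write_diploid_vcf(lin$evolved, vcf, ref$genome)
    write_depth(depth, dts)
    write_wig(lapply(depth, as.numeric), wig)
    jsonlite::write_json(truth_to_json(lin$truth), tj, auto_unbox = TRUE, digits = NA)
    lineages[[id]] <- lin
    paths[[paste0("vcf_", id)]] <- vcf
    paths[[paste0("depth_", id)]] <- dts
  }

  files <- list.files(out_dir, full.names = TRUE)
  sums <- tools::md5sum(files)
  write.table(data.frame(md5 = unname(sums), file = basename(names(sums))),
              file.path(out_dir, "checksums.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(paths = paths, genome = ref$genome, cds = ref$cds,
                 parent = parent, lineages = lineages, groups = gdf))
}

truth_to_json <- function(truth) {
  list(sites = truth$sites, tracts = truth$tracts, de_novo = truth$de_novo,
       copy_rle = lapply(truth$copy, function(v) {
         r <- rle(v); list(lengths = r$lengths, values = r$values)
       }))
}

#' Read a truth-set JSON written by [generate_cohort()]
#' @param path Truth JSON file.
#' @return A `truth_set` list (`sites`, `tracts`, `de_novo`, `copy`).
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  copy <- lapply(x$copy_rle, function(r)
    inverse.rle(structure(list(lengths = r$lengths, values = r$values),
                          class = "rle")))
  structure(list(sites = x$sites, tracts = x$tracts,
                 de_novo = x$de_novo, copy = copy),
            class = "truth_set")
}
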