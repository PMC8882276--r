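# End-to-end driver: classify -> annotate -> LOH segments -> CNV ->
# cohort summary for every strain of a cohort directory.

#' Pipeline options
#'
#' @param max_gap,min_sites,min_reciprocal_overlap LOH segmentation
#'   parameters (see [segment_loh()], [shared_segments()]).
#' @param smooth_window Copy-number smoothing window in bp (`NULL` = none).
#' @param ploidy Baseline ploidy for CNV calls.
#' @param annotate_mode `"per_variant"` or `"joint"` (see [annotate_calls()]).
#' @return Validated options list.
#' @export
pipeline_options <- function(max_gap = 25000, min_sites = 3L,
                             min_reciprocal_overlap = 0.5,
                             smooth_window = NULL, ploidy = 2L,
                             annotate_mode = "per_variant") {
  stopifnot(max_gap > 0, min_sites >= 1,
            min_reciprocal_overlap > 0, min_reciprocal_overlap <= 1,
            ploidy >= 1, annotate_mode %in% c("per_variant", "joint"))
  list(max_gap = max_gap, min_sites = min_sites,
       min_reciprocal_overlap = min_reciprocal_overlap,
       smooth_window = smooth_window, ploidy = ploidy,
       annotate_mode = annotate_mode)
}

#' Run the full parent-vs-evolved analysis over a cohort directory
#'
#' Expects the layout written by [generate_cohort()] (or equivalent):
#' `reference.fa`, `genes.gff3`, `classes.tsv`, `parent.vcf`, `groups.tsv`,
#' and per strain `<id>.vcf` plus optional `<id>.depth.tsv`. For each
#' strain the pipeline classifies parent-vs-evolved differences, annotates
#' CDS effects, segments LOH calls, and (when depth is present) estimates
#' copy number; it then writes per-strain TSVs, shared-segment and cohort
#' summary tables, and a run manifest with file checksums. Deterministic:
#' rerunning on the same inputs reproduces identical outputs.
#'
#' @param cohort_dir Input directory.
#' @param out_dir Output directory (created if needed).
#' @param options A [pipeline_options()] list.
#' @return Invisibly, a list with all in-memory results (`effects`,
#'   `segments`, `shared`, `cnv_genes`, `cnv_events`, `table`,
#'   `per_strain`).
#' @export
run_pipeline <- function(cohort_dir, out_dir, options = pipeline_options()) {
  need <- c("reference.fa", "genes.gff3", "parent.vcf", "groups.tsv")
  for (f in need)
    if (!file.exists(file.path(cohort_dir, f)))
      stop("missing required input: ", file.path(cohort_dir, f))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  classes <- file.path(cohort_dir, "classes.tsv")
  genome <- read_genome(file.path(cohort_dir, "reference.fa"),
                        if (file.exists(classes)) classes else NULL)
  cds <- read_cds(file.path(cohort_dir, "genes.gff3"), genome)
  parent <- read_diploid_vcf(file.path(cohort_dir, "parent.vcf"))
  groups <- read_groups(file.path(cohort_dir, "groups.tsv"))

  vcfs <- list.files(cohort_dir, pattern = "\\.vcf$", full.names = TRUE)
  vcfs <- vcfs[basename(vcfs) != "parent.vcf"]
  if (!length(vcfs)) stop("no evolved-strain VCFs in ", cohort_dir)

  all_effects <- list(); all_segments <- list()
  cnv_genes <- list(); cnv_events <- list()
  lens <- contig_lengths(genome)

  for (vcf in vcfs) {
    id <- sub("\\.vcf$", "", basename(vcf))
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e)
        stop("stage '", what, "' failed for strain ", id, ": ",
             conditionMessage(e), call. = FALSE))
    }
    evolved <- stage("read", read_diploid_vcf(vcf, strain_id = id))
    calls <- stage("classify", classify_strain(parent, evolved, genome))
    eff <- stage("annotate",
                 annotate_calls(calls, genome, cds, mode = options$annotate_mode))
    seg <- stage("loh", segment_loh(calls, max_gap = options$max_gap,
                                    min_sites = options$min_sites,
                                    contig_len = lens))
    eff <- flag_in_segment(eff, seg)
    message(sprintf("[%s] %d calls (%d new, %d LOH), %d LOH segment(s)",
                    id, nrow(calls), sum(calls$category == "new_variant"),
                    sum(calls$category == "loh"), nrow(seg)))
    write_effects(eff, file.path(out_dir, paste0(id, ".effects.tsv")))
    write.table(seg, file.path(out_dir, paste0(id, ".segments.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    all_effects[[id]] <- eff
    all_segments[[id]] <- seg

    depth_path <- file.path(cohort_dir, paste0(id, ".depth.tsv"))
    if (file.exists(depth_path)) {
      depth <- stage("cnv", read_depth(depth_path))
      prof <- stage("cnv", normalize_coverage(depth, window = options$smooth_window))
      gcn <- stage("cnv", gene_copy_number(prof, cds, ploidy = options$ploidy))
      ev <- stage("cnv", call_chromosome_events(gcn, ploidy = options$ploidy))
      write_copy_wig(prof, file.path(out_dir, paste0(id, ".copynumber.wig")))
      write.table(gcn, file.path(out_dir, paste0(id, ".genes.cnv.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(ev, file.path(out_dir, paste0(id, ".cnv.events.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      cnv_genes[[id]] <- gcn; cnv_events[[id]] <- ev
    }
  }

  effects <- do.call(rbind, all_effects)
  rownames(effects) <- NULL
  segments <- do.call(rbind, all_segments)
  rownames(segments) <- NULL
  shared <- shared_segments(segments, options$min_reciprocal_overlap)
  tab <- tabulate_cohort(effects, groups)
  per_strain <- per_strain_counts(effects)

  write.table(shared, file.path(out_dir, "shared.segments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_cohort_table(tab, file.path(out_dir, "cohort.summary.tsv"))
  write.table(per_strain, file.path(out_dir, "per.strain.counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("alemut")),
    options = options[!vapply(options, is.null, TRUE)],
    inputs = as.list(tools::md5sum(sort(c(file.path(cohort_dir, need), vcfs)))))
  jsonlite::write_json(manifest, file.path(out_dir, "run.manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(effects = effects, segments = segments, shared = shared,
                 cnv_genes = cnv_genes, cnv_events = cnv_events,
                 table = tab, per_strain = per_strain))
}
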