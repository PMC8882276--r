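# Depth-based copy-number estimation: per-base depth is converted to an
# approximate copy number by dividing by the sample's genome-wide median
# depth and multiplying by two, then aggregated per gene and per contig.

#' Convert a depth track to an adjusted copy-number profile
#'
#' The adjusted copy number at position i is `2 * depth_i / m`, with `m`
#' the median depth over all positions of all contigs, so the genome-wide
#' median of the profile is exactly 2 by construction. Optional smoothing
#' replaces each non-overlapping window by its median, applied after
#' normalization.
#'
#' @param depth A [depth_track()].
#' @param window `NULL` for no smoothing, or a window size in bp
#'   (non-overlapping window medians; default 1000 when smoothing is
#'   requested via `smooth = TRUE`).
#' @param smooth Logical; smooth with the default 1000-bp window.
#' @param per_contig Use each contig's own median instead of the
#'   genome-wide one (off by default).
#' @return Object of class `copy_profile`: named list of per-position
#'   numeric copy numbers, with the median depth in attribute
#'   `"median_depth"`.
#' @export
normalize_coverage <- function(depth, window = NULL, smooth = FALSE,
                               per_contig = FALSE) {
  stopifnot(inherits(depth, "depth_track"))
  if (smooth && is.null(window)) window <- 1000L
  all_d <- unlist(depth, use.names = FALSE)
  if (!length(all_d)) stop("empty depth track")
  m <- median(all_d)
  if (m == 0) stop("degenerate depth: genome-wide median is 0")
  prof <- lapply(names(depth), function(ct) {
    mm <- if (per_contig) median(depth[[ct]]) else m
    if (mm == 0) stop("degenerate depth: median is 0 on contig ", ct)
    v <- 2 * depth[[ct]] / mm
    if (!is.null(window) && window > 1L) {
      idx <- ceiling(seq_along(v) / window)
      v <- unname(unlist(lapply(split(v, idx), function(w) rep(median(w), length(w)))))
    }
    v
  })
  names(prof) <- names(depth)
  structure(prof, median_depth = m, class = "copy_profile")
}

round_half_up <- function(x) floor(x + 0.5)

#' Per-gene copy-number estimates and gain/loss calls
#'
#' Each gene's copy number is the median of the adjusted profile over its
#' span, rounded half-up to an integer; the call is `loss` below the
#' baseline ploidy, `gain` above it.
#'
#' @param profile A `copy_profile` from [normalize_coverage()].
#' @param features A [cds_table()].
#' @param ploidy Baseline ploidy (default 2).
#' @return data.frame: `gene_id`, `contig`, `start`, `end`, `copy_median`,
#'   `copy` (integer), `call`.
#' @export
gene_copy_number <- function(profile, features, ploidy = 2L) {
  stopifnot(inherits(profile, "copy_profile"))
  missing_ct <- setdiff(unique(features$contig), names(profile))
  if (length(missing_ct))
    stop("gene(s) on contig absent from profile: ",
         paste(missing_ct, collapse = ", "))
  med <- vapply(seq_len(nrow(features)), function(i)
    median(profile[[features$contig[i]]][features$start[i]:features$end[i]]), 1)
  copy <- as.integer(round_half_up(med))
  data.frame(gene_id = features$gene_id, contig = features$contig,
             start = features$start, end = features$end,
             copy_median = med, copy = copy,
             call = ifelse(copy < ploidy, "loss",
                           ifelse(copy > ploidy, "gain", "neutral")),
             stringsAsFactors = FALSE)
}

#' Call chromosome-scale copy-number events from per-gene calls
#'
#' A whole-contig event is called when at least `whole_fraction` of a
#' contig's genes (contigs with fewer than `min_genes` genes are skipped)
#' share the same non-neutral call; otherwise maximal runs of at least
#' `min_run` consecutive same-call genes are reported as partial events.
#'
#' @param genes Output of [gene_copy_number()].
#' @param whole_fraction Fraction of genes required for a whole-contig
#'   call (default 0.8).
#' @param min_run Minimum consecutive genes for a partial event (default 3).
#' @param min_genes Minimum genes per contig to attempt calling (default 5).
#' @param ploidy Baseline ploidy.
#' @return data.frame: `contig`, `scope` (`whole`/`partial`), `start`,
#'   `end`, `copy_delta`, `n_genes`.
#' @export
call_chromosome_events <- function(genes, whole_fraction = 0.8, min_run = 3L,
                                   min_genes = 5L, ploidy = 2L) {
  out <- list()
  for (ct in unique(genes$contig)) {
    g <- genes[genes$contig == ct, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) < min_genes) next
    tab <- table(g$call[g$call != "neutral"])
    if (length(tab) && max(tab) / nrow(g) >= whole_fraction) {
      dominant <- names(tab)[which.max(tab)]
      delta_mode <- as.integer(names(sort(table(g$copy[g$call == dominant]),
                                          decreasing = TRUE))[1]) - ploidy
      out[[length(out) + 1L]] <- data.frame(
        contig = ct, scope = "whole", start = min(g$start), end = max(g$end),
        copy_delta = delta_mode, n_genes = nrow(g), stringsAsFactors = FALSE)
      next
    }
    r <- rle(g$call)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (r$values[j] == "neutral" || r$lengths[j] < min_run) next
      idx <- starts[j]:ends[j]
      delta_mode <- as.integer(names(sort(table(g$copy[idx]),
                                          decreasing = TRUE))[1]) - ploidy
      out[[length(out) + 1L]] <- data.frame(
        contig = ct, scope = "partial", start = min(g$start[idx]),
        end = max(g$end[idx]), copy_delta = delta_mode,
        n_genes = length(idx), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(contig = character(), scope = character(),
                      start = integer(), end = integer(),
                      copy_delta = integer(), n_genes = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Export an adjusted copy-number profile as fixedStep WIG
#' @param profile A `copy_profile`.
#' @param path Output WIG file.
#' @return `path`, invisibly.
#' @export
write_copy_wig <- function(profile, path) {
  write_wig(unclass(profile), path)
}
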