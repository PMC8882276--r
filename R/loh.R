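# LOH segmentation: cluster a strain's LOH calls along each chromosome into
# segments, and find segments shared between independently evolved strains.

#' Cluster LOH calls into chromosomal segments
#'
#' A single linear scan per contig joins consecutive LOH calls whose
#' inter-site distance is at most `max_gap`; clusters with at least
#' `min_sites` supporting calls become segments. Reversion calls (which
#' have no record in the evolved VCF but are recovered by the parent-aware
#' classifier) count as supporting sites. Segment bounds are the outermost
#' supporting calls.
#'
#' @param calls A `mutation_calls` data.frame for one strain.
#' @param max_gap Maximum distance between consecutive supporting sites
#'   (default 25000 bp; at a het density of 1/300 this comfortably bridges
#'   the sampling gaps inside a real tract).
#' @param min_sites Minimum supporting sites per segment (default 3).
#' @param contig_len Optional named vector of contig lengths, used for the
#'   terminal flag.
#' @param terminal_margin A segment reaching within this many bp of a
#'   contig end is flagged terminal (default 10000).
#' @return data.frame of class `loh_segments`: `strain`, `contig`, `start`,
#'   `end`, `n_sites`, `reversion_fraction`, `terminal`.
#' @export
segment_loh <- function(calls, max_gap = 25000, min_sites = 3L,
                        contig_len = NULL, terminal_margin = 10000) {
  stopifnot(max_gap > 0, min_sites >= 1)
  loh <- calls[calls$category == "loh", , drop = FALSE]
  loh <- loh[order(loh$contig, loh$pos), , drop = FALSE]
  out <- list()
  for (ct in unique(loh$contig)) {
    s <- loh[loh$contig == ct, , drop = FALSE]
    cl <- cumsum(c(1L, diff(s$pos) > max_gap))
    for (k in unique(cl)) {
      sub <- s[cl == k, , drop = FALSE]
      if (nrow(sub) < min_sites) next
      st <- min(sub$pos); en <- max(sub$pos)
      term <- NA
      if (!is.null(contig_len) && ct %in% names(contig_len))
        term <- st <= terminal_margin ||
          en >= contig_len[[ct]] - terminal_margin
      out[[length(out) + 1L]] <- data.frame(
        strain = sub$strain[1L], contig = ct, start = st, end = en,
        n_sites = nrow(sub), reversion_fraction = mean(sub$is_reversion),
        terminal = term, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(strain = character(), contig = character(), start = integer(),
               end = integer(), n_sites = integer(),
               reversion_fraction = numeric(), terminal = logical(),
               stringsAsFactors = FALSE)
  class(res) <- c("loh_segments", "data.frame")
  res
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmin(e1, e2) - pmax(s1, s2) + 1
  ifelse(ov <= 0, 0, pmin(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1)))
}

#' Find LOH segments shared between strains
#'
#' Segments from different strains on the same contig are linked when
#' their reciprocal overlap is at least `min_reciprocal_overlap`; connected
#' components with two or more strains are reported with the intersection
#' interval of their member segments.
#'
#' @param segments An `loh_segments` data.frame (all strains together).
#' @param min_reciprocal_overlap Fraction in (0, 1] (default 0.5).
#' @return data.frame: `contig`, `start`, `end` (intersection), `n_strains`,
#'   `strains` (comma-joined ids).
#' @export
shared_segments <- function(segments, min_reciprocal_overlap = 0.5) {
  stopifnot(min_reciprocal_overlap > 0, min_reciprocal_overlap <= 1)
  n <- nrow(segments)
  empty <- data.frame(contig = character(), start = integer(), end = integer(),
                      n_strains = integer(), strains = character(),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  # union-find over pairwise links
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (segments$contig[i] != segments$contig[j]) next
    ro <- reciprocal_overlap(segments$start[i], segments$end[i],
                             segments$start[j], segments$end[j])
    if (ro >= min_reciprocal_overlap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  out <- list()
  for (k in unique(comp)) {
    idx <- which(comp == k)
    strains <- unique(segments$strain[idx])
    if (length(strains) < 2L) next
    out[[length(out) + 1L]] <- data.frame(
      contig = segments$contig[idx[1L]],
      start = max(segments$start[idx]), end = min(segments$end[idx]),
      n_strains = length(strains),
      strains = paste(sort(strains), collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$contig, res$start), , drop = FALSE]
}

#' Flag new variants falling inside a strain's LOH segments
#'
#' Inside a selected LOH tract most mutations are passengers inherited with
#' the rearrangement; this positional flag lets downstream reports separate
#' isolated new variants from candidates co-inherited with a segment.
#'
#' @param calls A `mutation_calls` data.frame for one strain.
#' @param segments `loh_segments` for the same strain.
#' @return `calls` with a logical `in_loh_segment` column.
#' @export
flag_in_segment <- function(calls, segments) {
  seg <- segments[segments$strain %in% unique(calls$strain), , drop = FALSE]
  flag <- rep(FALSE, nrow(calls))
  for (i in seq_len(nrow(seg)))
    flag <- flag | (calls$contig == seg$contig[i] &
                    calls$pos >= seg$start[i] & calls$pos <= seg$end[i])
  calls$in_loh_segment <- flag
  calls
}

#' Write segments as BED (0-based half-open)
#' @param segments `loh_segments`.
#' @param path BED output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  df <- data.frame(segments$contig, segments$start - 1L, segments$end,
                   paste0(segments$strain, "_loh"), segments$n_sites)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
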