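# Cohort-level mutation accounting: per-strain tallies, media-group union
# counts with a shared row, per-contig-class blocks with amino-acid-change
# columns, Venn overlaps, and recurrently mutated genes.

#' Cross-strain identity key of a mutation call
#'
#' Two calls are "the same mutation" when they hit the same site and
#' produce the same evolved genotype; gene-level sharing instead uses
#' `gene_id` only.
#'
#' @param calls A `mutation_calls`/`mutation_effects` data.frame.
#' @return Character vector of keys.
#' @export
mutation_key <- function(calls) {
  paste(calls$contig, calls$pos, calls$ref, calls$evolved_gt, sep = "|")
}

count_block <- function(eff) {
  # eff: effects rows de-duplicated by key; returns c(all, aa, genes)
  aa <- eff$aa_changing
  c(all = nrow(eff), aa_changing = sum(aa),
    genes_aa = length(unique(eff$gene_id[aa & !is.na(eff$gene_id)])))
}

dedup_by_key <- function(eff) eff[!duplicated(mutation_key(eff)), , drop = FALSE]

#' Build the cohort accounting table
#'
#' Rows are {all mutations, new variants, LOH events} crossed with scope
#' {overall, one row per group, shared between all groups}; group rows
#' count the union of member strains' mutation keys and the shared row
#' counts keys present in at least one strain of every group, so the
#' inclusion-exclusion identity `overall = sum(groups) - shared` holds for
#' two groups. Within each row, one `total` column plus an
#' (all, AA-changing, genes-with-AA-changes) triplet per contig class.
#'
#' @param effects Annotated calls for all strains combined (rbind of
#'   [annotate_calls()] outputs).
#' @param groups data.frame with columns `strain`, `group`.
#' @return data.frame of class `cohort_table`.
#' @export
tabulate_cohort <- function(effects, groups) {
  strains <- unique(effects$strain)
  missing <- setdiff(strains, groups$strain)
  if (length(missing))
    stop("strain(s) missing from group manifest: ", paste(missing, collapse = ", "))
  classes <- c("reference", "inserted_pathway", "strain_specific")
  gnames <- unique(groups$group)

  scope_rows <- function(eff_subset, scope) {
    lapply(c(all = "all", new_variants = "new_variant", loh = "loh"),
           function(cat) {
      e <- if (cat == "all") eff_subset else
        eff_subset[eff_subset$category == cat, , drop = FALSE]
      row <- list(category = if (cat == "all") "all" else cat, scope = scope,
                  total = nrow(e))
      for (cl in classes) {
        b <- count_block(e[e$contig_class == cl, , drop = FALSE])
        row[[paste0(cl, "_all")]] <- unname(b["all"])
        row[[paste0(cl, "_aa")]] <- unname(b["aa_changing"])
        row[[paste0(cl, "_genes")]] <- unname(b["genes_aa"])
      }
      as.data.frame(row, stringsAsFactors = FALSE)
    })
  }

  overall <- dedup_by_key(effects)
  rows <- scope_rows(overall, "overall")
  group_keys <- list()
  for (g in gnames) {
    members <- groups$strain[groups$group == g]
    eg <- dedup_by_key(effects[effects$strain %in% members, , drop = FALSE])
    group_keys[[g]] <- mutation_key(eg)
    rows <- c(rows, scope_rows(eg, g))
  }
  shared_keys <- Reduce(intersect, group_keys)
  es <- overall[mutation_key(overall) %in% shared_keys, , drop = FALSE]
  rows <- c(rows, scope_rows(es, "shared"))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Per-strain mutation tallies (new variants vs LOH)
#' @param effects Annotated calls for all strains combined.
#' @return data.frame: `strain`, `n_total`, `n_new_variant`, `n_loh`,
#'   `n_reversion`.
#' @export
per_strain_counts <- function(effects) {
  do.call(rbind, lapply(split(effects, effects$strain), function(e)
    data.frame(strain = e$strain[1L], n_total = nrow(e),
               n_new_variant = sum(e$category == "new_variant"),
               n_loh = sum(e$category == "loh"),
               n_reversion = sum(e$category == "loh" & e$is_reversion),
               stringsAsFactors = FALSE)))
}

#' Venn partition of two strains' mutations
#' @param calls_a,calls_b `mutation_calls` for two strains.
#' @return Named integer vector `c(only_a, shared, only_b)`.
#' @export
venn_calls <- function(calls_a, calls_b) {
  ka <- unique(mutation_key(calls_a)); kb <- unique(mutation_key(calls_b))
  c(only_a = length(setdiff(ka, kb)), shared = length(intersect(ka, kb)),
    only_b = length(setdiff(kb, ka)))
}

#' Genes mutated in multiple independent strains
#'
#' Reports genes whose filtered mutation set is non-empty in at least
#' `min_strains` strains, with per-strain notations, and separately the
#' largest number of strains sharing one identical mutation key in the
#' gene (the "same heterozygous SNP in seven strains" style of report).
#'
#' @param effects Annotated calls for all strains combined.
#' @param category Optional filter: `"new_variant"` or `"loh"`.
#' @param aa_changing Keep only amino-acid-changing calls (default TRUE).
#' @param min_strains Minimum number of strains (>= 2).
#' @return data.frame: `gene_id`, `n_strains`, `strains`, `notations`,
#'   `max_identical`.
#' @export
shared_mutated_genes <- function(effects, category = NULL, aa_changing = TRUE,
                                 min_strains = 2L) {
  stopifnot(min_strains >= 2L)
  e <- effects[!is.na(effects$gene_id), , drop = FALSE]
  if (!is.null(category)) e <- e[e$category == category, , drop = FALSE]
  if (aa_changing) e <- e[e$aa_changing, , drop = FALSE]
  if (!nrow(e))
    return(data.frame(gene_id = character(), n_strains = integer(),
                      strains = character(), notations = character(),
                      max_identical = integer(), stringsAsFactors = FALSE))
  out <- lapply(split(e, e$gene_id), function(g) {
    ns <- length(unique(g$strain))
    if (ns < min_strains) return(NULL)
    ident <- max(vapply(split(g$strain, mutation_key(g)),
                        function(s) length(unique(s)), 1L))
    data.frame(gene_id = g$gene_id[1L], n_strains = ns,
               strains = paste(sort(unique(g$strain)), collapse = ","),
               notations = paste(unique(paste0(g$strain, ":", g$notation)),
                                 collapse = ";"),
               max_identical = ident, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) out <- data.frame(gene_id = character(), n_strains = integer(),
                                      strains = character(), notations = character(),
                                      max_identical = integer(), stringsAsFactors = FALSE)
  out <- out[order(-out$n_strains, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Format a percentage the way results text prints it
#'
#' `100 * numerator / denominator`, rounded half-away-from-zero to
#' `decimals` places, with a percent sign.
#'
#' @param numerator,denominator Counts; `denominator` must be > 0.
#' @param decimals Decimal places (default 1).
#' @return Character scalar like `"8.3%"`.
#' @export
percent_printed <- function(numerator, denominator, decimals = 1L) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  x <- 100 * numerator / denominator
  f <- 10^decimals
  r <- sign(x) * floor(abs(x) * f + 0.5) / f
  paste0(formatC(r, format = "f", digits = decimals), "%")
}

#' Write / read a cohort table as TSV
#' @param tab A `cohort_table`.
#' @param path TSV path.
#' @return `path` (writer) or the table (reader).
#' @export
write_cohort_table <- function(tab, path) {
  write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  class(df) <- c("cohort_table", "data.frame")
  df
}
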