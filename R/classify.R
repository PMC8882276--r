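# Parent-vs-evolved comparison and mutation classification.
#
# The comparison is parent-aware by necessity: an LOH tract that retains the
# reference allele (a reversion) leaves no record in the evolved strain's
# genotype table — the evolved strain is simply hom-ref there — so the
# parent's variable sites define the site universe and absent sites are
# imputed hom-ref.

#' Compare two genotype tables site by site
#'
#' The site universe is the union of sites in either table; a site absent
#' from one table is imputed homozygous-reference there. Sites with
#' identical genotypes (allele multisets) in both strains are dropped; a
#' message reports how many.
#'
#' @param parent,evolved [genotype_table()]s on the same reference.
#' @return A data.frame of differing sites with columns `contig`, `pos`,
#'   `ref`, `p1`, `p2` (parent alleles) and `e1`, `e2` (evolved alleles).
#' @export
diff_sites <- function(parent, evolved) {
  stopifnot(inherits(parent, "genotype_table"), inherits(evolved, "genotype_table"))
  p <- as.data.frame(parent); e <- as.data.frame(evolved)
  names(p)[3:5] <- c("ref_p", "p1", "p2")
  names(e)[3:5] <- c("ref_e", "e1", "e2")
  m <- merge(p, e, by = c("contig", "pos"), all = TRUE)
  both <- !is.na(m$ref_p) & !is.na(m$ref_e)
  if (any(both & m$ref_p != m$ref_e))
    stop("conflicting reference allele at ",
         paste(m$contig[both & m$ref_p != m$ref_e],
               m$pos[both & m$ref_p != m$ref_e], sep = ":", collapse = ", "))
  m$ref <- ifelse(is.na(m$ref_p), m$ref_e, m$ref_p)
  # impute hom-ref where a table lacks the site
  miss_p <- is.na(m$p1)
  m$p1[miss_p] <- m$ref[miss_p]; m$p2[miss_p] <- m$ref[miss_p]
  miss_e <- is.na(m$e1)
  m$e1[miss_e] <- m$ref[miss_e]; m$e2[miss_e] <- m$ref[miss_e]
  same <- m$p1 == m$e1 & m$p2 == m$e2  # alleles stored sorted => multiset equality
  if (any(same))
    message(sum(same), " site(s) with identical genotypes dropped")
  out <- m[!same, c("contig", "pos", "ref", "p1", "p2", "e1", "e2")]
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify one compared site as a new variant or an LOH event
#'
#' Rules, applied in order: (1) if the evolved genotype contains any allele
#' absent from the parent genotype the site is a `new_variant` (zygosity
#' from the evolved genotype itself); (2) otherwise the evolved alleles are
#' a subset of a heterozygous parent's and the site is `loh`, a reversion
#' when the retained allele equals the reference. LOH requires a
#' heterozygous parent: a hom-parent site changing to a different
#' homozygous allele is a homozygous new variant even if it matches the
#' reference.
#'
#' @param ref,p1,p2,e1,e2 Reference allele, parent alleles, evolved alleles
#'   (vectors of equal length are accepted).
#' @return data.frame with columns `category`, `zygosity`, `is_reversion`,
#'   `novel_alleles` (comma-joined, `""` for loh), `variant_kind`.
#' @export
classify_site <- function(ref, p1, p2, e1, e2) {
  n <- length(ref)
  stopifnot(length(p1) == n, length(p2) == n, length(e1) == n, length(e2) == n)
  category <- character(n); zyg <- character(n)
  rev <- rep(NA, n); novel <- character(n)
  for (i in seq_len(n)) {
    par <- c(p1[i], p2[i]); ev <- c(e1[i], e2[i])
    nov <- setdiff(unique(ev), par)
    if (length(nov)) {
      category[i] <- "new_variant"
      zyg[i] <- if (ev[1] == ev[2]) "hom" else "het"
      novel[i] <- paste(sort(nov), collapse = ",")
      rev[i] <- NA
    } else {
      if (par[1] == par[2] || ev[1] != ev[2])
        stop("unclassifiable site (identical genotypes should be filtered upstream)")
      category[i] <- "loh"
      zyg[i] <- "hom"
      rev[i] <- ev[1] == ref[i]
      novel[i] <- ""
    }
  }
  kind <- ifelse(nchar(ref) != 1L | nchar(p1) != 1L | nchar(p2) != 1L |
                 nchar(e1) != 1L | nchar(e2) != 1L, "indel", "snp")
  data.frame(category = category, zygosity = zyg, is_reversion = rev,
             novel_alleles = novel, variant_kind = kind,
             stringsAsFactors = FALSE)
}

#' Classify all differences between a parent and an evolved strain
#'
#' Runs [diff_sites()] then [classify_site()] per site, tags each call with
#' its contig class, and returns a sorted, TSV-serializable call table.
#' One site counts as one mutation.
#'
#' @param parent,evolved [genotype_table()]s.
#' @param genome Optional [ref_genome()] supplying contig classes; calls on
#'   contigs without a class default to `"reference"`.
#' @return data.frame of class `mutation_calls`: columns `strain`, `contig`,
#'   `pos`, `ref`, `parent_gt`, `evolved_gt`, `category`, `zygosity`,
#'   `is_reversion`, `novel_alleles`, `variant_kind`, `contig_class`.
#' @export
classify_strain <- function(parent, evolved, genome = NULL) {
  d <- diff_sites(parent, evolved)
  sid <- strain_id(evolved)
  if (!nrow(d)) return(empty_calls(sid))
  cl <- classify_site(d$ref, d$p1, d$p2, d$e1, d$e2)
  cls <- rep("reference", nrow(d))
  if (!is.null(genome)) {
    known <- d$contig %in% names(genome$class)
    cls[known] <- unname(genome$class[d$contig[known]])
  }
  calls <- data.frame(strain = sid, contig = d$contig, pos = d$pos,
                      ref = d$ref,
                      parent_gt = paste(d$p1, d$p2, sep = "/"),
                      evolved_gt = paste(d$e1, d$e2, sep = "/"),
                      cl, contig_class = cls, stringsAsFactors = FALSE)
  calls <- calls[order(calls$contig, calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("mutation_calls", "data.frame")
  calls
}

empty_calls <- function(sid = NA_character_) {
  df <- data.frame(strain = character(), contig = character(), pos = integer(),
                   ref = character(), parent_gt = character(),
                   evolved_gt = character(), category = character(),
                   zygosity = character(), is_reversion = logical(),
                   novel_alleles = character(), variant_kind = character(),
                   contig_class = character(), stringsAsFactors = FALSE)
  class(df) <- c("mutation_calls", "data.frame")
  df
}

#' Write / read a mutation-call table as TSV
#' @param calls A `mutation_calls` data.frame.
#' @param path TSV path.
#' @return `path` (writer) or the call table (reader).
#' @export
write_calls <- function(calls, path) {
  write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c(pos = "integer"), na.strings = "NA")
  df$novel_alleles[is.na(df$novel_alleles)] <- ""
  class(df) <- c("mutation_calls", "data.frame")
  df
}
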