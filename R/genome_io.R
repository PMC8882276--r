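#' @importFrom stats median rbinom rgeom rpois runif setNames
#' @importFrom utils read.table write.table head tail
NULL

# ---- reference genome ------------------------------------------------------

#' Construct a reference genome object
#'
#' A reference genome is an ordered set of named contig sequences plus a
#' class label per contig distinguishing the host reference chromosomes from
#' engineered pathway insertions and strain-specific contigs (the three
#' contig groups reported separately in cohort tables).
#'
#' @param contigs Named character vector of nucleotide sequences (A/C/G/T/N).
#' @param contig_class Named character vector mapping contig ids to one of
#'   `"reference"`, `"inserted_pathway"`, `"strain_specific"`. Contigs not
#'   named default to `"reference"`.
#' @return An object of class `ref_genome` with elements `contigs` and
#'   `class`.
#' @export
ref_genome <- function(contigs, contig_class = NULL) {
  if (length(contigs) == 0) stop("genome must contain at least one contig")
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    stop("all contigs must be named")
  if (anyDuplicated(names(contigs)))
    stop("duplicate contig ids: ",
         paste(unique(names(contigs)[duplicated(names(contigs))]), collapse = ", "))
  contigs <- toupper(contigs)
  if (any(!nzchar(contigs))) stop("empty contig sequence")
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad))
    stop("non-ACGTN characters in contig(s): ",
         paste(names(contigs)[bad], collapse = ", "))
  cls <- setNames(rep("reference", length(contigs)), names(contigs))
  if (!is.null(contig_class)) {
    unknown <- setdiff(names(contig_class), names(contigs))
    if (length(unknown))
      stop("contig class manifest names unknown contig(s): ",
           paste(unknown, collapse = ", "))
    ok <- c("reference", "inserted_pathway", "strain_specific")
    if (any(!contig_class %in% ok))
      stop("contig class must be one of: ", paste(ok, collapse = ", "))
    cls[names(contig_class)] <- contig_class
  }
  structure(list(contigs = contigs, class = cls), class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("ref_genome with", length(x$contigs), "contig(s):\n")
  for (id in names(x$contigs))
    cat(sprintf("  %s  %d bp  [%s]\n", id, nchar(x$contigs[[id]]), x$class[[id]]))
  invisible(x)
}

#' Contig lengths of a reference genome
#' @param genome A `ref_genome`.
#' @return Named integer vector of contig lengths in bp.
#' @export
contig_lengths <- function(genome) {
  stopifnot(inherits(genome, "ref_genome"))
  setNames(nchar(genome$contigs), names(genome$contigs))
}

#' Read a reference genome from FASTA
#'
#' Sequences are upper-cased and record order preserved. Contig classes
#' default to `"reference"` unless a class manifest (two-column TSV,
#' contig id and class, no header) overrides them.
#'
#' @param path FASTA file.
#' @param class_manifest Optional path to a contig-class TSV.
#' @return A [ref_genome()].
#' @export
read_genome <- function(path, class_manifest = NULL) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- setNames(as.character(ss), ids)
  cls <- if (!is.null(class_manifest)) read_class_manifest(class_manifest) else NULL
  ref_genome(seqs, cls)
}

#' Write a reference genome to FASTA (60-column wrapping)
#' @param genome A `ref_genome`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  stopifnot(inherits(genome, "ref_genome"))
  ss <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read a contig-class manifest
#' @param path Two-column TSV (contig id, class), no header.
#' @return Named character vector of classes.
#' @export
read_class_manifest <- function(path) {
  if (!file.exists(path)) stop("class manifest not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("contig", "class"))
  setNames(df$class, df$contig)
}

#' Write a contig-class manifest
#' @param contig_class Named character vector.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_class_manifest <- function(contig_class, path) {
  write.table(data.frame(names(contig_class), unname(contig_class)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- CDS features ----------------------------------------------------------

#' Construct a CDS feature table
#'
#' @param gene_id,contig Character vectors.
#' @param start,end 1-based inclusive genomic coordinates (always
#'   forward-strand coordinates, also for minus-strand genes).
#' @param strand `"+"` or `"-"`.
#' @param flagged Logical; `TRUE` marks features whose length is not a
#'   multiple of 3 (kept but flagged).
#' @return A data.frame of class `cds_table`.
#' @export
cds_table <- function(gene_id, contig, start, end, strand,
                      flagged = rep(FALSE, length(gene_id))) {
  stopifnot(all(start <= end), all(strand %in% c("+", "-")))
  df <- data.frame(gene_id = as.character(gene_id),
                   contig = as.character(contig),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   phase = rep(0L, length(gene_id)),
                   flagged = as.logical(flagged),
                   stringsAsFactors = FALSE)
  df <- df[order(df$contig, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("cds_table", "data.frame")
  df
}

#' Read CDS features from a GFF3 file
#'
#' Only rows of type `CDS` are returned. Coordinates are validated against
#' the genome's contig lengths; a CDS whose length is not divisible by 3 is
#' kept but flagged with a warning, and overlapping features on a contig
#' raise a warning only (the simulator guarantees non-overlap; external
#' annotations may not).
#'
#' @param path GFF3 file; CDS rows must carry an `ID` (or `gene_id`)
#'   attribute.
#' @param genome A [ref_genome()] used for bounds checking.
#' @return A [cds_table()].
#' @export
read_cds <- function(path, genome) {
  if (!file.exists(path)) stop("GFF3 not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[tolower(as.character(gr$type)) == "cds"]
  if (length(gr) == 0) return(cds_table(character(), character(), integer(), integer(), character()))
  ids <- gr$ID
  if (is.null(ids) && !is.null(gr$gene_id)) ids <- gr$gene_id
  if (is.null(ids) || any(is.na(ids))) stop("CDS rows lack an ID/gene_id attribute")
  contig <- as.character(GenomicRanges::seqnames(gr))
  len <- contig_lengths(genome)
  if (any(!contig %in% names(len)))
    stop("CDS on contig absent from genome: ",
         paste(unique(setdiff(contig, names(len))), collapse = ", "))
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  out_of_bounds <- st < 1L | en > len[contig]
  if (any(out_of_bounds))
    stop("CDS outside contig bounds: ", paste(ids[out_of_bounds], collapse = ", "))
  flag <- (en - st + 1L) %% 3L != 0L
  if (any(flag))
    warning("CDS length not divisible by 3 (flagged): ",
            paste(ids[flag], collapse = ", "))
  ft <- cds_table(ids, contig, st, en, as.character(GenomicRanges::strand(gr)), flag)
  # overlap check per contig
  for (ct in unique(ft$contig)) {
    sub <- ft[ft$contig == ct, ]
    if (nrow(sub) > 1 && any(sub$start[-1] <= sub$end[-nrow(sub)]))
      warning("overlapping CDS features on contig ", ct)
  }
  ft
}

#' Write CDS features to GFF3
#' @param features A [cds_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cds <- function(features, path) {
  gr <- GenomicRanges::GRanges(features$contig,
                               IRanges::IRanges(features$start, features$end),
                               strand = features$strand)
  gr$type <- "CDS"
  gr$ID <- features$gene_id
  gr$phase <- 0L
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# ---- genotype tables -------------------------------------------------------

#' Construct a per-strain diploid genotype table
#'
#' Each row is one variable site with an unphased diploid genotype: a VCF
#' style anchored representation (`ref` is the reference allele text starting
#' at `pos`; indel alleles carry the shared anchor base). The two allele
#' columns are stored sorted so the pair is an unordered multiset.
#'
#' @param contig,pos,ref Site coordinates and reference allele.
#' @param a1,a2 The two allele sequences (unphased).
#' @param strain_id Strain identifier, stored as an attribute.
#' @return A data.frame of class `genotype_table`, sorted by (contig, pos).
#' @export
genotype_table <- function(contig = character(), pos = integer(),
                           ref = character(), a1 = character(),
                           a2 = character(), strain_id = NA_character_) {
  df <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                   ref = toupper(as.character(ref)),
                   a1 = toupper(as.character(a1)), a2 = toupper(as.character(a2)),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    swap <- df$a1 > df$a2
    tmp <- df$a1[swap]; df$a1[swap] <- df$a2[swap]; df$a2[swap] <- tmp
    df <- df[order(df$contig, df$pos), , drop = FALSE]
    key <- paste(df$contig, df$pos)
    if (anyDuplicated(key))
      stop("multiple records at site(s): ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
    if (any(!nzchar(df$ref)) || any(!nzchar(df$a1)) || any(!nzchar(df$a2)))
      stop("empty allele text")
  }
  rownames(df) <- NULL
  attr(df, "strain_id") <- strain_id
  class(df) <- c("genotype_table", "data.frame")
  df
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table for strain", attr(x, "strain_id"),
      "with", nrow(x), "site(s)\n")
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}

#' Strain id of a genotype table
#' @param gt A `genotype_table`.
#' @return Character scalar.
#' @export
strain_id <- function(gt) attr(gt, "strain_id")

is_het <- function(gt) gt$a1 != gt$a2

# Left-normalize one anchored variant: trim the common suffix, then the
# common prefix (keeping at least one base), advancing pos.
normalize_alleles <- function(pos, alleles) {
  while (all(nchar(alleles) > 1L)) {
    last <- substr(alleles, nchar(alleles), nchar(alleles))
    if (length(unique(last)) != 1L) break
    alleles <- substr(alleles, 1L, nchar(alleles) - 1L)
  }
  while (all(nchar(alleles) > 1L)) {
    first <- substr(alleles, 1L, 1L)
    if (length(unique(first)) != 1L) break
    alleles <- substr(alleles, 2L, nchar(alleles))
    pos <- pos + 1L
  }
  list(pos = pos, alleles = alleles)
}

#' Read a single-sample diploid VCF into a genotype table
#'
#' Accepts VCF 4.2 with a GT field; phased separators (`|`) are treated as
#' unphased, records with missing genotype (`./.`) are skipped (a message
#' reports the count), and multi-allelic records are collapsed to the two
#' called alleles. Indel records are left-normalized so that parent and
#' evolved representations of the same event are comparable.
#'
#' @param path VCF file (plain text).
#' @param strain_id Optional strain id; defaults to the VCF sample name.
#' @return A [genotype_table()].
#' @export
read_diploid_vcf <- function(path, strain_id = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  gt_mat <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt_mat)) stop("VCF has no GT field: ", path)
  if (ncol(gt_mat) != 1L) stop("expected a single-sample VCF, got ", ncol(gt_mat), " samples")
  if (is.null(strain_id)) strain_id <- colnames(gt_mat)
  gt_str <- gsub("\\|", "/", as.character(gt_mat[, 1L]))
  rr <- SummarizedExperiment::rowRanges(vcf)
  contig <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)
  alts <- lapply(seq_along(alts), function(i) as.character(alts[[i]]))

  missing <- gt_str %in% c("./.", ".")
  if (any(missing))
    message(sum(missing), " record(s) with missing GT skipped in ", basename(path))
  keep <- which(!missing)

  parts <- strsplit(gt_str[keep], "/", fixed = TRUE)
  ploidy_ok <- lengths(parts) == 2L
  if (any(!ploidy_ok))
    stop("non-diploid GT at ", contig[keep][!ploidy_ok][1L], ":",
         pos[keep][!ploidy_ok][1L])
  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    idx <- as.integer(parts[[j]])
    pool <- c(refs[i], alts[[i]])
    if (any(is.na(idx)) || any(idx < 0L) || any(idx + 1L > length(pool)))
      stop("invalid GT index at ", contig[i], ":", pos[i])
    al <- pool[idx + 1L]
    norm <- normalize_alleles(pos[i], c(refs[i], al))
    out[[j]] <- list(contig = contig[i], pos = norm$pos,
                     ref = norm$alleles[1L],
                     a1 = norm$alleles[2L], a2 = norm$alleles[3L])
  }
  if (!length(out))
    return(genotype_table(strain_id = strain_id))
  genotype_table(contig = vapply(out, `[[`, "", "contig"),
                 pos = vapply(out, function(x) x$pos, 1),
                 ref = vapply(out, `[[`, "", "ref"),
                 a1 = vapply(out, `[[`, "", "a1"),
                 a2 = vapply(out, `[[`, "", "a2"),
                 strain_id = strain_id)
}

#' Write a genotype table as a single-sample VCF 4.2
#'
#' Emits one record per site with the site's non-reference alleles as ALT
#' and an unphased GT. Homozygous-reference rows (possible only for
#' imputed tables) are skipped.
#'
#' @param gt A [genotype_table()].
#' @param path Output file.
#' @param genome Optional [ref_genome()]; adds `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_diploid_vcf <- function(gt, path, genome = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  sample <- strain_id(gt)
  if (is.na(sample)) sample <- "sample"
  hdr <- c("##fileformat=VCFv4.2",
           "##source=alemut",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(genome))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(genome$contigs), contig_lengths(genome)))
  hdr <- c(hdr, paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  body <- character(0)
  if (nrow(gt)) {
    rows <- vapply(seq_len(nrow(gt)), function(i) {
      alts <- setdiff(unique(c(gt$a1[i], gt$a2[i])), gt$ref[i])
      if (!length(alts)) return(NA_character_)
      pool <- c(gt$ref[i], alts)
      g <- paste(match(c(gt$a1[i], gt$a2[i]), pool) - 1L, collapse = "/")
      paste(gt$contig[i], gt$pos[i], ".", gt$ref[i],
            paste(alts, collapse = ","), ".", ".", ".", "GT", g, sep = "\t")
    }, "")
    body <- rows[!is.na(rows)]
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- depth tracks and WIG --------------------------------------------------

#' Construct a per-base depth track
#' @param depths Named list of non-negative integer vectors, one per contig,
#'   dense from position 1.
#' @return Object of class `depth_track`.
#' @export
depth_track <- function(depths) {
  stopifnot(is.list(depths), !is.null(names(depths)))
  depths <- lapply(depths, function(v) {
    v <- as.integer(v)
    if (any(is.na(v)) || any(v < 0L)) stop("depths must be non-negative integers")
    v
  })
  structure(depths, class = "depth_track")
}

#' Read a per-base depth TSV (contig, pos, depth; no header)
#' @param path Input TSV.
#' @return A [depth_track()].
#' @export
read_depth <- function(path) {
  if (!file.exists(path)) stop("depth TSV not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("contig", "pos", "depth"),
                   colClasses = c("character", "integer", "integer"))
  out <- lapply(split(df, df$contig), function(d) {
    d <- d[order(d$pos), ]
    if (!identical(d$pos, seq_len(nrow(d))))
      stop("depth track not dense from position 1 on contig ", d$contig[1])
    d$depth
  })
  depth_track(out)
}

#' Write a per-base depth TSV
#' @param track A [depth_track()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_depth <- function(track, path) {
  stopifnot(inherits(track, "depth_track"))
  con <- file(path, "w")
  on.exit(close(con))
  for (ct in names(track)) {
    v <- track[[ct]]
    write.table(data.frame(ct, seq_along(v), v), con, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write a dense numeric track as fixedStep WIG
#'
#' One `fixedStep chrom=<contig> start=1 step=1 span=1` block per contig;
#' values are written with up to 4 decimal places (integers stay integral),
#' which bounds the round-trip error of [read_wig()] at 1e-4.
#'
#' @param track Named list of numeric vectors (per-contig, dense from pos 1).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_wig <- function(track, path) {
  stopifnot(is.list(track))
  if (length(track) == 0 || any(lengths(track) == 0))
    stop("empty track")
  stopifnot(!is.null(names(track)))
  if (any(vapply(track, function(v) any(is.na(v)), TRUE)))
    stop("NaN/NA values in track")
  con <- file(path, "w")
  on.exit(close(con))
  for (ct in names(track)) {
    writeLines(sprintf("fixedStep chrom=%s start=1 step=1 span=1", ct), con)
    writeLines(sprintf("%.15g", round(track[[ct]], 4)), con)
  }
  invisible(path)
}

#' Read a fixedStep WIG file into per-contig numeric vectors
#' @param path WIG file.
#' @return Named list of numeric vectors.
#' @export
read_wig <- function(path) {
  if (!file.exists(path)) stop("WIG not found: ", path)
  gr <- rtracklayer::import(path, format = "wig")
  if (length(gr) == 0) stop("empty WIG: ", path)
  out <- list()
  for (ct in as.character(unique(GenomicRanges::seqnames(gr)))) {
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == ct]
    pos <- GenomicRanges::start(sub)
    v <- numeric(max(GenomicRanges::end(sub)))
    # expand spans (writer emits span=1; be liberal on read)
    for (i in seq_along(sub))
      v[GenomicRanges::start(sub)[i]:GenomicRanges::end(sub)[i]] <- sub$score[i]
    out[[ct]] <- v
  }
  out
}

# ---- strain-group manifest -------------------------------------------------

#' Read a strain-group manifest (strain, group TSV with header)
#' @param path TSV with columns `strain` and `group`.
#' @return data.frame with columns strain, group.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) stop("group manifest not found: ", path)
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("strain", "group") %in% names(df)))
    stop("group manifest must have columns 'strain' and 'group'")
  if (anyDuplicated(df$strain)) stop("strain assigned to more than one group")
  df[, c("strain", "group")]
}

#' Write a strain-group manifest
#' @param groups data.frame with columns strain, group.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_groups <- function(groups, path) {
  write.table(groups[, c("strain", "group")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
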