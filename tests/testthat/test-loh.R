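mk_loh_calls <- function(pos, contig = "chrA", strain = "EV1",
                         is_reversion = rep(FALSE, length(pos)),
                         category = rep("loh", length(pos))) {
  data.frame(strain = strain, contig = contig, pos = as.integer(pos),
             ref = "A", parent_gt = "A/G",
             evolved_gt = ifelse(category == "loh" & is_reversion, "A/A", "G/G"),
             category = category, zygosity = "hom",
             is_reversion = ifelse(category == "loh", is_reversion, NA),
             novel_alleles = ifelse(category == "loh", "", "T"),
             variant_kind = "snp", contig_class = "reference",
             stringsAsFactors = FALSE)
}

test_that("linear-scan clustering joins sites within max_gap", {
  calls <- mk_loh_calls(c(10000, 12000, 15000))
  seg <- segment_loh(calls, max_gap = 25000, min_sites = 3)
  expect_equal(nrow(seg), 1L)
  expect_equal(c(seg$start, seg$end), c(10000L, 15000L))
  expect_equal(seg$n_sites, 3L)

  # two distant sites: two clusters, both below min_sites
  seg2 <- segment_loh(mk_loh_calls(c(10000, 100000)), max_gap = 25000, min_sites = 3)
  expect_equal(nrow(seg2), 0L)

  # reversion calls support segments and set the reversion fraction
  calls3 <- mk_loh_calls(c(1000, 2000, 3000, 4000),
                         is_reversion = c(TRUE, TRUE, FALSE, FALSE))
  seg3 <- segment_loh(calls3, max_gap = 5000, min_sites = 3)
  expect_equal(seg3$reversion_fraction, 0.5)

  # new variants never support LOH segments
  mixed <- rbind(mk_loh_calls(c(1000, 2000)),
                 mk_loh_calls(3000, category = "new_variant"))
  expect_equal(nrow(segment_loh(mixed, max_gap = 5000, min_sites = 3)), 0L)
})

test_that("segments within a strain are disjoint and separated by > max_gap", {
  set.seed(301)
  pos <- sort(sample.int(5e5, 400))
  seg <- segment_loh(mk_loh_calls(pos), max_gap = 2000, min_sites = 2)
  if (nrow(seg) > 1) {
    gaps <- seg$start[-1] - seg$end[-nrow(seg)]
    expect_true(all(gaps > 2000))
  }
  # every call lies in at most one segment
  hits <- vapply(pos, function(p)
    sum(p >= seg$start & p <= seg$end), 1L)
  expect_true(all(hits <= 1))
})

test_that("a planted tract is recovered as one segment with het-site bounds", {
  cfg <- sim_config(contig_lengths = c(c1 = 100000L), n_cds_per_contig = 0L,
                    n_loh_tracts = 1L, tract_mean_length = 20000,
                    p_terminal_tract = 0, n_de_novo = 0)
  ref <- make_reference(cfg, 311)
  parent <- make_parent(ref$genome, 1 / 300, 312)
  lens <- contig_lengths(ref$genome)
  for (seed in 313:317) {
    lin <- evolve_lineage(parent, ref$genome, cfg, seed, strain_id = "EV")
    tr <- lin$truth$tracts
    het_in <- parent$pos[parent$contig == tr$contig &
                         parent$pos >= tr$start & parent$pos <= tr$end]
    if (length(het_in) < 3) next
    calls <- suppressMessages(classify_strain(parent, lin$evolved, ref$genome))
    seg <- segment_loh(calls, contig_len = lens)
    expect_equal(nrow(seg), 1L)
    expect_equal(seg$start, min(het_in))
    expect_equal(seg$end, max(het_in))
    expect_equal(seg$n_sites, length(het_in))
  }
})

test_that("shared segments link strains by reciprocal overlap", {
  segs <- do.call(rbind, lapply(c("s1", "s2", "s3"), function(id)
    data.frame(strain = id, contig = "chrA", start = 10000L, end = 50000L,
               n_sites = 10L, reversion_fraction = 0.5, terminal = FALSE,
               stringsAsFactors = FALSE)))
  sh <- shared_segments(segs)
  expect_equal(nrow(sh), 1L)
  expect_equal(sh$n_strains, 3L)
  expect_equal(sh$strains, "s1,s2,s3")
  expect_equal(c(sh$start, sh$end), c(10000L, 50000L))

  disjoint <- segs
  disjoint$start <- c(1L, 60000L, 120000L)
  disjoint$end <- c(50000L, 110000L, 170000L)
  expect_equal(nrow(shared_segments(disjoint)), 0L)

  # two segments of the same strain never form a shared record
  same <- segs[1:2, ]; same$strain <- "s1"
  expect_equal(nrow(shared_segments(same)), 0L)
})

test_that("a common planted tract is shared; a private one is not", {
  cfg <- sim_config(contig_lengths = c(c1 = 100000L, c2 = 100000L),
                    n_cds_per_contig = 0L, n_loh_tracts = 0L, n_de_novo = 0)
  ref <- make_reference(cfg, 321)
  parent <- make_parent(ref$genome, 1 / 300, 322)
  lens <- contig_lengths(ref$genome)

  homozygose <- function(parent, contig, lo, hi, strain) {
    df <- as.data.frame(parent)
    idx <- df$contig == contig & df$pos >= lo & df$pos <= hi
    alt <- ifelse(df$a1[idx] == df$ref[idx], df$a2[idx], df$a1[idx])
    df$a1[idx] <- alt; df$a2[idx] <- alt
    genotype_table(df$contig, df$pos, df$ref, df$a1, df$a2, strain_id = strain)
  }
  evA <- homozygose(parent, "c1", 20000, 60000, "A")
  evB <- homozygose(homozygose(parent, "c1", 20000, 60000, "B"),
                    "c2", 10000, 40000, "B")
  segs <- rbind(
    segment_loh(suppressMessages(classify_strain(parent, evA, ref$genome)),
                contig_len = lens),
    segment_loh(suppressMessages(classify_strain(parent, evB, ref$genome)),
                contig_len = lens))
  sh <- shared_segments(segs)
  expect_equal(nrow(sh), 1L)
  expect_equal(sh$contig, "c1")
  expect_equal(sh$n_strains, 2L)
})

test_that("new variants inside a strain's LOH segments are flagged", {
  calls <- rbind(mk_loh_calls(c(10000, 12000, 15000)),
                 mk_loh_calls(c(13000, 90000), category = "new_variant"))
  seg <- segment_loh(calls, max_gap = 25000, min_sites = 3)
  flagged <- flag_in_segment(calls, seg)
  nv <- flagged[flagged$category == "new_variant", ]
  expect_equal(nv$in_loh_segment, c(TRUE, FALSE))
})

test_that("BED export is 0-based half-open", {
  seg <- data.frame(strain = "s1", contig = "chrA", start = 100L, end = 200L,
                    n_sites = 5L, reversion_fraction = 0, terminal = FALSE)
  f <- withr::local_tempfile(fileext = ".bed")
  write_segments_bed(seg, f)
  expect_equal(strsplit(readLines(f), "\t")[[1]][1:3], c("chrA", "99", "200"))
})
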