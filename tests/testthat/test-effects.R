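test_that("variants are applied jointly, right-to-left, strand-aware", {
  fx <- tiny_cds_genome()
  gP <- fx$cds[fx$cds$gene_id == "gP", ]
  gM <- fx$cds[fx$cds$gene_id == "gM", ]

  # SNP at CDS base 6 (genomic 9 on chrP): CAT -> CAA
  ap <- apply_variants_to_cds(gP, fx$genome,
                              data.frame(pos = 9L, ref = "T", alt = "A"))
  expect_equal(ap$wt, "ATGCATTGGTAA")
  expect_equal(ap$mut, "ATGCAATGGTAA")

  # same edit in genome space on the minus-strand mirror: CDS base 6 is
  # genomic position end - 5 = 10, base complemented
  ap_m <- apply_variants_to_cds(gM, fx$genome,
                                data.frame(pos = 10L, ref = "A", alt = "T"))
  expect_equal(ap_m$wt, "ATGCATTGGTAA")
  expect_equal(ap_m$mut, "ATGCAATGGTAA")

  # two SNPs editing one codon jointly
  ap2 <- apply_variants_to_cds(gP, fx$genome,
                               data.frame(pos = c(8L, 9L), ref = c("A", "T"),
                                          alt = c("G", "C")))
  expect_equal(ap2$mut, "ATGCGCTGGTAA")

  expect_error(apply_variants_to_cds(gP, fx$genome,
                                     data.frame(pos = 9L, ref = "G", alt = "A")),
               "does not match")
  expect_error(apply_variants_to_cds(gP, fx$genome,
                                     data.frame(pos = c(8L, 9L), ref = c("AT", "T"),
                                                alt = c("A", "C"))),
               "overlapping")
})

test_that("translation follows the standard code and reports stops", {
  tr <- translate_cds("ATGCATTGGTAA")
  expect_equal(tr$protein, "MHW")
  expect_equal(tr$stop_codon, 4L)
  expect_false(tr$incomplete)
  expect_equal(translate_cds("ATGTAA")$protein, "M")
  t3 <- translate_cds("ATGGG")
  expect_equal(t3$protein, "M")  # complete codons only
  expect_true(t3$incomplete)
  expect_error(translate_cds("ATGNAT"), "position 4")
})

test_that("effect annotation reproduces canonical substitution calls", {
  fx <- tiny_cds_genome()
  gP <- fx$cds[fx$cds$gene_id == "gP", ]

  # CAT -> CAA: H2Q missense (non-conservative under BLOSUM62)
  a <- annotate_effect(gP, fx$genome, data.frame(pos = 9L, ref = "T", alt = "A"))
  expect_equal(a$effect, "missense")
  expect_equal(a$notation, "H2Q")
  expect_equal(a$conservation, "non_conservative")

  # TGG -> TGA: W3* nonsense, truncation at residue 3
  a <- annotate_effect(gP, fx$genome, data.frame(pos = 12L, ref = "G", alt = "A"))
  expect_equal(a$effect, "nonsense")
  expect_equal(a$notation, "W3*")
  expect_equal(a$protein_pos, 3L)

  # wobble position of CAU (-> CAC, still H): synonymous
  a <- annotate_effect(gP, fx$genome, data.frame(pos = 9L, ref = "T", alt = "C"))
  expect_equal(a$effect, "synonymous")

  # stop codon TAA -> CAA: stop lost
  a <- annotate_effect(gP, fx$genome, data.frame(pos = 13L, ref = "T", alt = "C"))
  expect_equal(a$effect, "stop_lost")
  expect_true(a$stop_not_found)

  # variant outside the CDS: intergenic, not an error
  a <- annotate_effect(gP, fx$genome, data.frame(pos = 1L, ref = "G", alt = "A"))
  expect_equal(a$effect, "intergenic")
})

test_that("frameshift accounting matches a brute-force rebuild on a long CDS", {
  # 60-codon synthetic CDS with a 4-bp deletion starting at CDS base 4
  set.seed(91)
  cfg <- sim_config(contig_lengths = c(c1 = 3000L), n_cds_per_contig = 1L,
                    cds_length_range = c(180L, 180L))
  ref <- make_reference(cfg, 91)
  cds <- ref$cds[1, ]
  if (cds$strand == "-") {
    # place the deletion at CDS base 4 from the 3' genomic end
    pos <- cds$end - 7L
  } else {
    pos <- cds$start + 3L
  }
  v <- data.frame(pos = pos,
                  ref = substr(ref$genome$contigs[[1]], pos, pos + 4L),
                  alt = substr(ref$genome$contigs[[1]], pos, pos))
  a <- annotate_effect(cds, ref$genome, v)
  o <- oracle_annotate(cds, ref$genome, v)
  expect_equal(a$effect, "frameshift")
  expect_equal(a$effect, o$effect)
  expect_equal(a$notation, o$notation)
  expect_equal(a$n_altered_tail, o$n_altered_tail)
  expect_equal(a$n_truncated, o$n_truncated)
  # tail accounting is consistent with the wild-type length whenever the
  # shifted frame reaches a stop
  if (!is.na(a$n_truncated))
    expect_equal((a$protein_pos - 1L) + a$n_altered_tail + a$n_truncated,
                 nchar(translate_cds(cds_sequence(cds, ref$genome))$protein))
})

test_that("random variant sets agree with the brute-force oracle", {
  cfg <- sim_config(contig_lengths = c(c1 = 20000L), n_cds_per_contig = 10L,
                    cds_length_range = c(150L, 600L))
  ref <- make_reference(cfg, 93)
  set.seed(94)
  n_checked <- 0
  for (k in 1:80) {
    cds <- ref$cds[sample.int(nrow(ref$cds), 1L), ]
    v <- random_cds_variants(cds, ref$genome)
    if (is.null(v)) next
    a <- annotate_effect(cds, ref$genome, v)
    o <- oracle_annotate(cds, ref$genome, v)
    expect_equal(a$effect, o$effect, label = paste("case", k, "effect"))
    expect_equal(a$notation, o$notation, label = paste("case", k, "notation"))
    if (a$effect == "frameshift") {
      expect_equal(a$n_altered_tail, o$n_altered_tail)
      expect_equal(a$n_truncated, o$n_truncated)
    }
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 60)
})

test_that("strand mirroring leaves protein-level annotation unchanged", {
  # same coding sequence planted on + and -: the corresponding genomic
  # edits must give identical annotations
  plus_cds <- "ATGCATTGGCCTACTATTGTTTAA"  # M H W P T I V *
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(plus_cds)))
  genome <- ref_genome(c(p = paste0("AAAA", plus_cds, "AAAA"),
                         m = paste0("AAAA", rc, "AAAA")))
  cds_p <- list(gene_id = "gp", contig = "p", start = 5L,
                end = 4L + nchar(plus_cds), strand = "+")
  cds_m <- list(gene_id = "gm", contig = "m", start = 5L,
                end = 4L + nchar(plus_cds), strand = "-")
  # edit CDS base 10 (codon 4, P -> T): plus genomic 14 C->A; on the minus
  # contig the same CDS base sits at end - 9 with the complement edit
  a_p <- annotate_effect(cds_p, genome, data.frame(pos = 14L, ref = "C", alt = "A"))
  a_m <- annotate_effect(cds_m, genome,
                         data.frame(pos = cds_m$end - 9L, ref = "G", alt = "T"))
  expect_equal(a_p$notation, "P4T")
  expect_equal(a_m$notation, a_p$notation)
  expect_equal(a_m$effect, a_p$effect)
  expect_equal(a_p$conservation, "non_conservative")
})

test_that("conservation classification uses the matrix sign", {
  expect_equal(classify_conservation("H", "Q"), "non_conservative")  # score 0
  expect_equal(classify_conservation("P", "T"), "non_conservative")  # score -1
  expect_equal(classify_conservation("I", "V"), "conservative")      # score 3
  expect_error(classify_conservation("W", "*"), "nonsense")
  expect_error(classify_conservation("O", "A"), "non-standard")
})

test_that("per-call annotation assigns genes, reversions and the AA flag", {
  fx <- tiny_cds_genome()
  calls <- data.frame(
    strain = "EV1",
    contig = c("chrP", "chrP", "chrM"),
    pos = c(9L, 1L, 10L),
    ref = c("A", "G", "A"),
    parent_gt = c("A/T", "G/T", "A/T"),
    evolved_gt = c("A/A", "T/T", "T/T"),
    category = c("loh", "loh", "loh"),
    zygosity = "hom", is_reversion = c(TRUE, FALSE, FALSE),
    novel_alleles = "", variant_kind = "snp", contig_class = "reference",
    stringsAsFactors = FALSE)
  # note chrP:9 truly carries T in the genome; for the reversion row the
  # retained allele equals ref so no edit is attempted against the genome
  calls$ref[1] <- "T"; calls$parent_gt[1] <- "G/T"; calls$evolved_gt[1] <- "T/T"
  eff <- annotate_calls(calls, fx$genome, fx$cds)
  expect_equal(eff$gene_id, c("gP", NA, "gM"))
  expect_equal(eff$effect[1], "synonymous")   # reversion: no change vs reference
  expect_equal(eff$effect[2], "intergenic")
  expect_equal(eff$aa_changing, c(FALSE, FALSE, TRUE))
})
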