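test_that("FASTA reading normalizes case, preserves order, and round-trips", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrA", "acgt", ">chrB", "GGCC"), f)
  g <- read_genome(f)
  expect_equal(unname(g$contigs), c("ACGT", "GGCC"))
  expect_equal(names(g$contigs), c("chrA", "chrB"))
  expect_equal(unname(g$class), c("reference", "reference"))

  f2 <- withr::local_tempfile(fileext = ".fa")
  write_genome(g, f2)
  expect_identical(readLines(f2), c(">chrA", "ACGT", ">chrB", "GGCC"))

  # a 130-bp contig wraps at 60 columns and round-trips byte-identically
  long <- paste(rep("ACGTA", 26), collapse = "")
  f3 <- withr::local_tempfile(fileext = ".fa")
  write_genome(ref_genome(c(big = long)), f3)
  expect_equal(nchar(readLines(f3)[2]), 60L)
  f4 <- withr::local_tempfile(fileext = ".fa")
  write_genome(read_genome(f3), f4)
  expect_identical(readLines(f3), readLines(f4))
})

test_that("malformed genomes are rejected", {
  expect_error(ref_genome(setNames(c("ACGT", "GG"), c("a", "a"))), "duplicate")
  expect_error(ref_genome(setNames("", "a")), "empty")
  expect_error(ref_genome(setNames("ACXT", "a")), "non-ACGTN")
  expect_error(ref_genome(setNames("ACGT", "a"),
                          contig_class = c(b = "reference")), "unknown contig")
})

test_that("class manifest overrides contig classes", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrA", "ACGT", ">pXYL", "GGCC"), f)
  m <- withr::local_tempfile(fileext = ".tsv")
  writeLines("pXYL\tinserted_pathway", m)
  g <- read_genome(f, m)
  expect_equal(unname(g$class), c("reference", "inserted_pathway"))
})

test_that("GFF3 CDS reading validates coordinates and flags bad lengths", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrA", strrep("ACGTG", 4)), fa)  # 20 bp
  g <- read_genome(fa)

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrA\t.\tCDS\t4\t12\t.\t+\t0\tID=g1",
               "chrA\t.\tCDS\t14\t19\t.\t-\t0\tID=g2"), gff)
  ft <- read_cds(gff, g)
  expect_equal(ft$gene_id, c("g1", "g2"))
  expect_equal(ft$start, c(4L, 14L))
  expect_equal(ft$end, c(12L, 19L))
  expect_equal(ft$strand, c("+", "-"))  # forward-strand coordinates always
  expect_false(any(ft$flagged))

  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chrA\t.\tCDS\t10\t25\t.\t+\t0\tID=g1"), bad)
  expect_error(read_cds(bad, g), "outside contig bounds")

  odd <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chrA\t.\tCDS\t4\t11\t.\t+\t0\tID=g1"), odd)
  expect_warning(ft2 <- read_cds(odd, g), "divisible by 3")
  expect_true(ft2$flagged)
})

test_that("diploid VCF reading handles GT conventions", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
               "chrA\t7\t.\tA\tG\t.\t.\t.\tGT\t0/1",
               "chrA\t9\t.\tCA\tC\t.\t.\t.\tGT\t1/1",
               "chrA\t12\t.\tA\tG,T\t.\t.\t.\tGT\t1/2",
               "chrA\t15\t.\tA\tG\t.\t.\t.\tGT\t./.",
               "chrA\t20\t.\tT\tC\t.\t.\t.\tGT\t1|0"), vcf)
  expect_message(gt <- read_diploid_vcf(vcf), "1 record\\(s\\) with missing GT")
  expect_equal(strain_id(gt), "s1")
  expect_equal(nrow(gt), 4L)             # ./. skipped
  expect_equal(gt$pos, c(7L, 9L, 12L, 20L))
  expect_equal(c(gt$a1[1], gt$a2[1]), c("A", "G"))
  expect_equal(c(gt$a1[2], gt$a2[2]), c("C", "C"))   # 1-bp deletion, anchored
  expect_equal(gt$ref[2], "CA")
  expect_equal(c(gt$a1[3], gt$a2[3]), c("G", "T"))   # multi-allelic 1/2
  expect_equal(c(gt$a1[4], gt$a2[4]), c("C", "T"))   # phased treated unphased
})

test_that("non-diploid GT is an error naming the record", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
               "chrA\t7\t.\tA\tG\t.\t.\t.\tGT\t0/1/1"), vcf)
  expect_error(read_diploid_vcf(vcf), "non-diploid GT at chrA:7")
})

test_that("indel representations are left-normalized on read", {
  # CAA>CA (shared suffix A) is the same 1-bp deletion as CA>C
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
               "chrA\t9\t.\tCAA\tCA\t.\t.\t.\tGT\t1/1"), vcf)
  gt <- read_diploid_vcf(vcf)
  expect_equal(gt$ref, "CA")
  expect_equal(gt$a1, "C")
})

test_that("genotype tables round-trip through VCF", {
  gt <- genotype_table(contig = c("chrA", "chrA", "chrB"),
                       pos = c(5L, 11L, 3L),
                       ref = c("A", "CA", "G"),
                       a1 = c("A", "C", "T"), a2 = c("G", "CA", "T"),
                       strain_id = "EV1")
  f <- withr::local_tempfile(fileext = ".vcf")
  write_diploid_vcf(gt, f)
  back <- read_diploid_vcf(f)
  expect_equal(as.data.frame(back), as.data.frame(gt))
  expect_equal(strain_id(back), "EV1")
})

test_that("genotype table invariants hold", {
  expect_error(genotype_table("c", c(1L, 1L), c("A", "A"), c("A", "A"),
                              c("G", "T")), "multiple records")
  gt <- genotype_table("c", c(9L, 2L), c("A", "T"), c("G", "T"), c("A", "C"))
  expect_equal(gt$pos, c(2L, 9L))              # sorted
  expect_true(all(gt$a1 <= gt$a2))             # unordered pair canonicalized
})

test_that("WIG fixedStep export matches the dialect and round-trips", {
  f <- withr::local_tempfile(fileext = ".wig")
  write_wig(list(chrA = c(2, 2, 3)), f)
  lines <- readLines(f)
  expect_equal(lines[1], "fixedStep chrom=chrA start=1 step=1 span=1")
  expect_equal(lines[2:4], c("2", "2", "3"))

  set.seed(11)
  track <- list(chrA = runif(100, 0, 4), chrB = runif(50, 0, 4))
  f2 <- withr::local_tempfile(fileext = ".wig")
  write_wig(track, f2)
  back <- read_wig(f2)
  expect_equal(back$chrA, track$chrA, tolerance = 1e-4)
  expect_equal(back$chrB, track$chrB, tolerance = 1e-4)

  expect_error(write_wig(list(), f), "empty track")
  expect_error(write_wig(list(chrA = numeric(0)), f), "empty track")
  expect_error(write_wig(list(chrA = c(1, NaN)), f), "NaN")
})

test_that("depth TSV round-trips and rejects sparse tracks", {
  tr <- depth_track(list(chrA = c(5L, 7L, 0L, 3L), chrB = c(2L, 2L)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_depth(tr, f)
  back <- read_depth(f)
  expect_equal(unclass(back), unclass(tr))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrA\t1\t5", "chrA\t3\t7"), f2)
  expect_error(read_depth(f2), "not dense")
  expect_error(depth_track(list(chrA = -1L)), "non-negative")
})

test_that("group manifest is validated", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_groups(data.frame(strain = c("a", "b"), group = c("G1", "G2")), f)
  g <- read_groups(f)
  expect_equal(g$group, c("G1", "G2"))
  writeLines(c("strain\tgroup", "a\tG1", "a\tG2"), f)
  expect_error(read_groups(f), "more than one group")
})
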