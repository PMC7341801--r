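test_that("VCF genotypes map to dosages, phase-insensitively, with missing states", {
  path <- withr::local_tempfile(fileext = ".vcf")
  rows <- list(
    c("chr1", "100", "v1", "N", "<DEL>", ".", "PASS", "SVTYPE=DEL;SVLEN=-200;END=300"),
    c("chr1", "500", "v2", "N", "<INS>", ".", "PASS", "SVTYPE=INS;SVLEN=120;END=500"),
    c("chr2", "900", "v3", "N", "<INV>", ".", "PASS", "SVTYPE=INV;SVLEN=400;END=1300"))
  gts <- rbind(c("0/0", "0/1", "1/1"),
               c("1/0", "0|1", "./."),
               c("./1", ".|.", "0/0"))
  write_vcf_fixture(path, rows, c("s1", "s2", "s3"), gts)
  res <- read_sv_vcf(path)
  expect_equal(nrow(res$records), 3L)
  expect_equal(unname(res$genotypes["v1", ]), c(0L, 1L, 2L))
  # "1/0" and "0|1" both mean one alt copy; half-calls and "./." are missing
  expect_equal(unname(res$genotypes["v2", ]), c(1L, 1L, NA_integer_))
  expect_equal(unname(res$genotypes["v3", ]), c(NA_integer_, NA_integer_, 0L))
  expect_equal(res$records$svlen, c(200L, 120L, 400L))
  expect_equal(res$records$end, c(300L, 500L, 1300L))
  expect_equal(sum(res$skipped), 0L)
})

test_that("records outside the SV closed set and multi-allelics are skipped with counts", {
  path <- withr::local_tempfile(fileext = ".vcf")
  rows <- list(
    c("chr1", "100", "v1", "N", "<DEL>", ".", "PASS", "SVTYPE=DEL;SVLEN=-50;END=150"),
    c("chr1", "200", "v2", "N", "N[chr2:3[", ".", "PASS", "SVTYPE=BND"),
    c("chr1", "300", "v3", "N", "<DEL>,<INS>", ".", "PASS", "SVTYPE=DEL;SVLEN=-60;END=360"))
  gts <- rbind(c("0/1"), c("0/1"), c("0/1"))
  write_vcf_fixture(path, rows, "s1", gts)
  res <- read_sv_vcf(path)
  expect_equal(res$records$id, "v1")
  expect_equal(unname(res$skipped["non_sv_type"]), 1L)
  expect_equal(unname(res$skipped["multiallelic"]), 1L)
  # skipped + parsed == input
  expect_equal(nrow(res$records) + sum(res$skipped), 3L)
})

test_that("a VCF without genotype columns is refused", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
                     collapse = "\t"),
               paste(c("chr1", "100", "v1", "N", "<DEL>", ".", "PASS",
                       "SVTYPE=DEL;SVLEN=-50;END=150"), collapse = "\t")),
             path)
  expect_error(read_sv_vcf(path), "genotype")
})

test_that("write_sv_vcf / read_sv_vcf round-trips records and dosages exactly", {
  p <- sim_params(m_variants = 100L, missing_rate = 0.1, seed = 11L)
  co <- simulate_cohort(p)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(co$records, co$genotypes, path, chrom_table = p$chrom_table)
  back <- read_sv_vcf(path)
  expect_identical(unclass(back$genotypes), unclass(co$genotypes))
  expect_equal(back$records$pos, co$records$pos)
  expect_equal(back$records$svlen, co$records$svlen)
  expect_equal(back$records$svtype, co$records$svtype)
  # a second write of the re-read data is a fixed point
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(back$records, back$genotypes, path2, chrom_table = p$chrom_table)
  back2 <- read_sv_vcf(path2)
  expect_identical(unclass(back2$genotypes), unclass(back$genotypes))
  expect_equal(back2$records, back$records)
})

test_that("an empty record set writes a header-only VCF and ids must align", {
  path <- withr::local_tempfile(fileext = ".vcf")
  empty <- sv_records(character(), integer(), character(), character(), integer())
  write_sv_vcf(empty, NULL, path)
  expect_true(all(grepl("^#", readLines(path))))
  g <- genotype_matrix(matrix(0L, 1, 1, dimnames = list("vX", "s1")))
  r <- sv_records("chr1", 1L, "vY", "DEL", 10L)
  expect_error(write_sv_vcf(r, g, path), "ids")
})

test_that("RepeatMasker .out parsing derives overlap from the query interval", {
  path <- withr::local_tempfile(fileext = ".out")
  rows <- c(
    " 1200 10.0 0.5 0.5 sv1   10  109  (50) + ERVK-LTR1 LTR/ERVK    1 100 (0) 1",
    "  800 12.0 0.5 0.5 sv1   20   79  (80) C CR1-E1    LINE/CR1    1  60 (0) 2",
    "  500  8.0 0.1 0.1 sv2    1   50 (100) + (AT)n     Simple_repeat 1 50 (0) 3",
    "  450  8.0 0.1 0.1 sv2    5   44 (100) + Low_cplx  Low_complexity 1 40 (0) 4",
    "  300  9.0 0.1 0.1 sv2   10   29 (100) + ERVL-LTR3 LTR/ERVL    1 20 (0) 5")
  write_rm_fixture(path, rows)
  m <- read_repeat_table(path)
  expect_equal(nrow(m), 5L)
  expect_equal(m$overlap_bp[1], 100L)          # [10, 109] spans 100 bp
  expect_equal(sort(unique(m$variant_id)), c("sv1", "sv2"))
  expect_equal(m$repeat_class, c("LTR", "LINE/CR1", "tandem", "tandem", "LTR"))
  # empty table
  empty <- withr::local_tempfile(fileext = ".out")
  write_rm_fixture(empty, character())
  expect_equal(nrow(read_repeat_table(empty)), 0L)
  # negative coordinates rejected with a warning
  bad <- withr::local_tempfile(fileext = ".out")
  write_rm_fixture(bad, c(rows[1], " 100 1.0 0 0 sv3 -5 10 (0) + X Simple_repeat 1 5 (0) 6"))
  expect_warning(mb <- read_repeat_table(bad), "rejected")
  expect_equal(nrow(mb), 1L)
})

test_that("clade maps read from YAML and TSV with sizes, tolerances and errors", {
  inds <- c(sprintf("J%02d", 1:8), sprintf("C%02d", 1:24))
  cm <- clade_map(inds, population = rep(c("jack", "crow"), c(8, 24)),
                  clade = rep(c("A", "B"), c(8, 24)))
  expect_equal(length(clade_individuals(cm, "A")), 8L)
  expect_equal(length(clade_individuals(cm, "B")), 24L)
  # defaults: larger clade tolerates 4 errors as outgroup, smaller 2
  expect_equal(clade_tolerance(cm, "B"), 4L)
  expect_equal(clade_tolerance(cm, "A"), 2L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_clade_map(cm, path)
  back <- read_clade_map(path)
  expect_equal(back$individual, cm$individual)
  expect_equal(attr(back, "tolerances"), attr(cm, "tolerances"))
  expect_error(clade_map(c("a", "a"), c("p", "p"), c("A", "B")), "duplicate")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("individual\tpopulation", "a\tp"), tsv)
  expect_error(read_clade_map(tsv), "clade")
})

test_that("BED round-trips through the 1-based internal convention", {
  path <- withr::local_tempfile(fileext = ".bed")
  iv <- data.frame(chrom = c("chr1", "chr2"), start = c(101L, 1L), end = c(200L, 50L))
  write_bed(iv, path)
  on_disk <- utils::read.delim(path, header = FALSE)
  expect_equal(on_disk$V2, c(100L, 0L))        # 0-based half-open on disk
  expect_equal(read_bed(path), iv)
})
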