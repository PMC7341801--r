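make_map <- function(nA = 8L, nB = 24L, tol = c(A = 2L, B = 4L)) {
  clade_map(c(sprintf("A%02d", seq_len(nA)), sprintf("B%02d", seq_len(nB))),
            population = rep(c("pA", "pB"), c(nA, nB)),
            clade = rep(c("A", "B"), c(nA, nB)), tolerances = tol)
}

test_that("homref-outgroup classification counts non-reference outgroup genotypes", {
  cm <- make_map()
  row <- stats::setNames(c(rep(1L, 4), rep(0L, 4), rep(0L, 24)), cm$individual)
  v <- classify_variant(row, cm, focal_clade = "A", mode = "homref_outgroup")
  expect_true(v$retained)
  expect_equal(v$error_count, 0L)
  # 5 non-hom-ref outgroup individuals exceed the tolerance of 4
  row[paste0("B", sprintf("%02d", 1:5))] <- c(1L, 2L, 1L, 1L, 2L)
  v5 <- classify_variant(row, cm, focal_clade = "A", mode = "homref_outgroup")
  expect_false(v5$retained)
  expect_equal(v5$error_count, 5L)
  row[paste0("B", sprintf("%02d", 5))] <- 0L
  expect_true(classify_variant(row, cm, "A", "homref_outgroup")$retained)
})

test_that("fixed-outgroup classification uses the majority homozygous state", {
  cm <- make_map()
  # outgroup A: seven hom-alt, one het -> majority state 2, one discordant
  row <- stats::setNames(c(rep(2L, 7), 1L, rep(1L, 24)), cm$individual)
  v <- classify_variant(row, cm, focal_clade = "B", mode = "fixed_outgroup")
  expect_equal(v$outgroup_state, 2L)
  expect_equal(v$error_count, 1L)
  expect_true(v$retained)
  # tie between hom states resolves to reference
  row[1:8] <- c(rep(0L, 4), rep(2L, 4))
  vt <- classify_variant(row, cm, "B", "fixed_outgroup")
  expect_equal(vt$outgroup_state, 0L)
  expect_equal(vt$error_count, 4L)
  expect_false(vt$retained)
  # missing outgroup calls are not errors by default, but can be
  row[1:8] <- c(rep(0L, 6), NA, NA)
  expect_equal(classify_variant(row, cm, "B", "fixed_outgroup")$error_count, 0L)
  expect_equal(classify_variant(row, cm, "B", "fixed_outgroup",
                                missing_as_error = TRUE)$error_count, 2L)
})

test_that("a clean cohort is retained in full and injected FPs are excluded", {
  p <- sim_params(m_variants = 2000L, genotyping_error_rate = 0,
                  fp_cross_clade_rate = 0.05, missing_rate = 0, seed = 41L)
  co <- simulate_cohort(p)
  pf <- apply_phylo_filter(co$genotypes, co$clades)
  fp <- co$truth$origin == "cross_clade_FP"
  expect_true(all(!pf$verdicts$retained[fp]))
  expect_true(all(pf$verdicts$retained[!fp]))
  expect_setequal(pf$retained_union, co$truth$variant_id[!fp])
  # partition: each variant gets exactly one verdict
  expect_equal(nrow(pf$verdicts), nrow(co$records))
  expect_equal(unname(pf$counts["retained"] + pf$counts["excluded"]),
               unname(pf$counts["input"]))
})

test_that("verdicts are invariant under individual permutation and monotone in tolerance", {
  p <- sim_params(m_variants = 500L, genotyping_error_rate = 0.05,
                  fp_cross_clade_rate = 0.1, missing_rate = 0.05, seed = 42L)
  co <- simulate_cohort(p)
  pf <- apply_phylo_filter(co$genotypes, co$clades)
  perm <- sample(colnames(co$genotypes))
  pf_perm <- apply_phylo_filter(co$genotypes[, perm], co$clades)
  expect_equal(pf$verdicts, pf_perm$verdicts)
  # raising tolerances never shrinks the retained set
  for (tol in list(c(A = 0L, B = 0L), c(A = 1L, B = 2L))) {
    attr_map <- co$clades; attr(attr_map, "tolerances") <- tol
    r_lo <- apply_phylo_filter(co$genotypes, attr_map)$retained_union
    expect_true(all(r_lo %in% pf$retained_union))
  }
  tol_hi <- co$clades; attr(tol_hi, "tolerances") <- c(A = 8L, B = 12L)
  r_hi <- apply_phylo_filter(co$genotypes, tol_hi)$retained_union
  expect_true(all(pf$retained_union %in% r_hi))
})

test_that("with error tolerance some cross-clade variants survive, as on noisy data", {
  p <- sim_params(m_variants = 3000L, genotyping_error_rate = 0.05,
                  fp_cross_clade_rate = 0, missing_rate = 0, seed = 43L)
  co <- simulate_cohort(p)
  pf <- apply_phylo_filter(co$genotypes, co$clades)
  A <- clade_individuals(co$clades, "A"); B <- clade_individuals(co$clades, "B")
  segA <- rowSums(co$genotypes[, A] > 0, na.rm = TRUE) > 0
  segB <- rowSums(co$genotypes[, B] > 0, na.rm = TRUE) > 0
  both <- segA & segB & pf$verdicts$retained
  expect_gt(sum(both), 0)
})

test_that("an unmapped individual is an error", {
  g <- genotype_matrix(matrix(0L, 2, 2, dimnames = list(c("v1", "v2"), c("A01", "Zz"))))
  expect_error(apply_phylo_filter(g, make_map()), "Zz")
})

test_that("distance to chromosome end matches a direct two-end minimum", {
  ct <- chrom_table("chr1", 1e6)
  r <- sv_records("chr1", 100L, "d1", "DEL", 400L)
  expect_equal(distance_to_chrom_end(r, ct), 100)
  set.seed(7)
  pos <- sample.int(900000L, 50L)
  rr <- sv_records("chr1", pos, paste0("d", 1:50), "DEL",
                   sample(50:1000, 50, TRUE))
  d <- distance_to_chrom_end(rr, ct)
  expect_equal(d, pmin(rr$pos, 1e6 - rr$end))
  expect_true(all(d >= 0))
  bad <- sv_records("chr1", 999999L, "x", "DEL", 100L)
  expect_error(distance_to_chrom_end(bad, ct), "exceeds")
})

test_that("retention summaries tabulate by type and distance bin", {
  ct <- chrom_table("chr1", 1e6)
  r <- sv_records("chr1", c(1000L, 2000L, 500000L), c("v1", "v2", "v3"),
                  c("DEL", "DEL", "INS"), c(100L, 100L, 100L))
  verd <- data.frame(variant_id = c("v1", "v2", "v3"),
                     retained = c(FALSE, FALSE, TRUE))
  tab <- retention_summary(verd, r, ct, n_bins = 2L)
  expect_equal(sum(tab$retained), 1L)
  expect_equal(sum(tab$excluded), 2L)
  expect_equal(tab$excluded[tab$svtype == "DEL" & tab$dist_bin == 1], 2L)
  expect_equal(tab$retained[tab$svtype == "INS" & tab$dist_bin == 2], 1L)
  # all retained -> excluded column all zero
  verd$retained <- TRUE
  expect_true(all(retention_summary(verd, r, ct, 2L)$excluded == 0))
})

test_that("end-biased false positives give excluded fractions that fall with distance", {
  p <- sim_params(m_variants = 4000L, genotyping_error_rate = 0,
                  fp_cross_clade_rate = 0.3, missing_rate = 0,
                  fp_end_bias = 1, seed = 44L)
  co <- simulate_cohort(p)
  pf <- apply_phylo_filter(co$genotypes, co$clades)
  tab <- retention_summary(pf$verdicts, co$records, p$chrom_table, n_bins = 4L)
  frac <- vapply(1:4, function(b) {
    s <- tab[tab$dist_bin == b, ]
    sum(s$excluded) / max(1, sum(s$excluded) + sum(s$retained))
  }, numeric(1))
  expect_gt(frac[1], frac[4])
})
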