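dip_matrix <- function(rows, inds = NULL) {
  m <- do.call(rbind, rows)
  rownames(m) <- paste0("v", seq_len(nrow(m)))
  colnames(m) <- inds %||% paste0("i", seq_len(ncol(m)))
  svclades::genotype_matrix(m)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the folded spectrum folds on the minor allele and drops monomorphic sites", {
  # 24 diploids: alt count 3 -> bin 3; alt count 45 -> 2N - 45 = 3
  g3 <- c(rep(1L, 3), rep(0L, 21))
  g45 <- c(rep(2L, 21), rep(1L, 3))
  g0 <- rep(0L, 24)
  afs <- folded_afs(dip_matrix(list(g3, g45, g0)))
  expect_equal(afs$n_variants[afs$minor_count == 3], 2L)
  expect_equal(sum(afs$n_variants), 2L)  # monomorphic row contributes nowhere
  expect_equal(attr(afs, "N"), 24L)
})

test_that("spectrum mass equals the segregating-variant count per class", {
  co <- simulate_cohort(sim_params(m_variants = 1000L, missing_rate = 0.05, seed = 51L))
  B <- clade_individuals(co$clades, "B")
  gB <- co$genotypes[, B]
  cls <- stats::setNames(co$truth$class, co$truth$variant_id)
  afs <- folded_afs(gB, classes = cls)
  k <- rowSums(gB, na.rm = TRUE)
  nn <- rowSums(!is.na(gB))
  seg <- pmin(k, 2 * nn - k) >= 1
  for (cl in unique(co$truth$class)) {
    expect_equal(sum(afs$n_variants[afs$class == cl]),
                 sum(seg & cls[rownames(gB)] == cl),
                 info = cl)
  }
})

test_that("Weir-Cockerham components match frozen hand values and limiting cases", {
  # pop1 {0,1}, pop2 {2,2}: a, b, c worked through the variance-component
  # algebra by hand (independently reproduced by the ANOVA oracle)
  d <- stats::setNames(c(0L, 1L, 2L, 2L), paste0("i", 1:4))
  pops <- stats::setNames(c("p1", "p1", "p2", "p2"), names(d))
  f <- weir_cockerham_fst(d, pops)
  expect_equal(f$a, 0.25, tolerance = 1e-10)
  expect_equal(f$b, 0.0, tolerance = 1e-10)
  expect_equal(f$c, 0.125, tolerance = 1e-10)
  expect_equal(f$theta, 2 / 3, tolerance = 1e-10)
  # fixed difference: theta exactly 1
  dd <- stats::setNames(c(0L, 0L, 0L, 2L, 2L, 2L), paste0("i", 1:6))
  pp <- stats::setNames(rep(c("p1", "p2"), each = 3), names(dd))
  expect_equal(weir_cockerham_fst(dd, pp)$theta, 1, tolerance = 1e-12)
  # identical configurations in both populations: no among-population variance
  ee <- stats::setNames(c(0L, 1L, 2L, 0L, 1L, 2L), paste0("i", 1:6))
  expect_lte(weir_cockerham_fst(ee, pp)$theta, 0)
  # monomorphic: flagged undefined
  mm <- stats::setNames(rep(0L, 6), paste0("i", 1:6))
  expect_false(weir_cockerham_fst(mm, pp)$defined)
})

test_that("Weir-Cockerham agrees with the nested-ANOVA oracle on random configurations", {
  set.seed(77)
  for (rep in seq_len(400)) {
    n1 <- sample(2:3, 1); n2 <- sample(2:3, 1)
    d <- stats::setNames(c(sample(0:2, n1, TRUE), sample(0:2, n2, TRUE)),
                         paste0("i", seq_len(n1 + n2)))
    pops <- stats::setNames(rep(c("p1", "p2"), c(n1, n2)), names(d))
    f <- weir_cockerham_fst(d, pops)
    if (!f$defined) next
    o <- anova_fst_oracle(d, pops[names(d)])
    expect_equal(f$a, o$a, tolerance = 1e-10)
    expect_equal(f$b, o$b, tolerance = 1e-10)
    expect_equal(f$c, o$c, tolerance = 1e-10)
    expect_equal(f$theta, o$theta, tolerance = 1e-10)
  }
})

test_that("missing individuals are dropped variant-wise in the scan", {
  g <- dip_matrix(list(c(0L, NA, 2L, 2L), c(0L, 0L, 2L, 2L)))
  pops <- stats::setNames(c("p1", "p1", "p2", "p2"), colnames(g))
  sc <- fst_scan(g, pops)
  expect_equal(nrow(sc), 2L)
  expect_equal(sc$theta[1],
               weir_cockerham_fst(g[1, c(1, 3, 4)], pops[c(1, 3, 4)])$theta)
})

test_that("outlier scans use the interpolated percentile with a strict cut", {
  theta <- stats::setNames(seq_len(100) / 100, paste0("v", 1:100))
  out <- fst_outliers(theta, percentile = 99)
  expect_equal(out$outliers, "v100")
  # all equal values: nothing strictly exceeds the threshold
  flat <- stats::setNames(rep(0.5, 50), paste0("v", 1:50))
  expect_length(fst_outliers(flat)$outliers, 0L)
  # an added value below the threshold does not change the outlier set
  theta2 <- c(theta, vlow = 0.001)
  expect_equal(fst_outliers(theta2)$outliers, "v100")
  expect_error(fst_outliers(stats::setNames(NA_real_, "x")), "defined")
})

test_that("chromosomal enrichment is the outlier share over the length share", {
  ct <- chrom_table(c("c1", "c2"), c(9e6, 1e6))
  r <- sv_records(rep(c("c1", "c2"), c(9, 1)), seq(1e5, 1e6, 1e5),
                  paste0("v", 1:10), "DEL", rep(100L, 10))
  # all outliers on the 10%-of-genome chromosome -> enrichment 10
  e <- chrom_enrichment("v10", r, ct, "c2")
  expect_equal(e$enrichment, 10)
  # outliers spread proportionally to length -> enrichment 1 on both
  e1 <- chrom_enrichment(paste0("v", 1:10), r, ct, "c1")
  expect_equal(e1$enrichment, 1)
  expect_true(is.na(chrom_enrichment(character(), r, ct, "c1")$enrichment))
  expect_error(chrom_enrichment("v1", r, ct, "nope"), "not in table")
})

test_that("window densities count cluster starts and agree with a direct scan", {
  ct <- chrom_table(c("c1", "c2"), c(3e6, 1e6))
  r <- sv_records("c1", c(100L, 150L, 400L), paste0("v", 1:3), "DEL",
                  c(100L, 100L, 50L))
  wd <- window_density(r, ct, window = 1e6, collapse_overlapping = TRUE)
  expect_equal(wd$count[wd$chrom == "c1" & wd$window_start == 0], 2L)
  wd_raw <- window_density(r, ct, window = 1e6, collapse_overlapping = FALSE)
  expect_equal(wd_raw$count[wd_raw$chrom == "c1" & wd_raw$window_start == 0], 3L)
  # empty chromosome still emits all-zero windows tiling its length
  expect_equal(sum(wd$chrom == "c2"), 1L)
  expect_equal(wd$count[wd$chrom == "c2"], 0L)
  set.seed(23)
  pos <- sort(sample.int(2.9e6, 200L))
  rr <- sv_records("c1", pos, paste0("r", 1:200), "INS", rep(1L, 200))
  wd2 <- window_density(rr, ct, window = 1e6, collapse_overlapping = FALSE)
  ref <- vapply(c(0, 1e6, 2e6), function(s) sum(pos > s & pos <= s + 1e6), 0)
  expect_equal(wd2$count[wd2$chrom == "c1"], as.integer(ref))
})

test_that("genotype PCA separates simulated clades and behaves spectrally", {
  co <- simulate_cohort(sim_params(m_variants = 800L, seed = 61L))
  pca <- genotype_pca(co$genotypes, n_components = 3L)
  A <- pca$scores[clade_individuals(co$clades, "A"), 1]
  B <- pca$scores[clade_individuals(co$clades, "B"), 1]
  expect_true(max(A) < min(B) || max(B) < min(A))
  expect_true(all(diff(pca$explained) <= 1e-9))  # decreasing eigenvalues
  expect_lte(sum(pca$explained_fraction), 1 + 1e-9)
  # a duplicated individual lands on identical coordinates
  g2 <- cbind(unclass(co$genotypes), dup = co$genotypes[, 1])
  colnames(g2)[ncol(g2)] <- "dup"
  pca2 <- genotype_pca(genotype_matrix(g2))
  expect_equal(unname(pca2$scores["dup", ]), unname(pca2$scores[1, ]),
               tolerance = 1e-8)
  expect_error(genotype_pca(genotype_matrix(
    matrix(1L, 2, 2, dimnames = list(c("a", "b"), c("x", "y"))))), "variance")
})
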