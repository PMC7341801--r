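# Population-genetic summaries on SV genotype matrices: folded allele
# frequency spectra, per-variant Weir-Cockerham F_ST with percentile outlier
# scans and chromosomal enrichment, 1-Mb window densities, and genotype PCA.

#' Folded allele frequency spectrum, optionally per variant class
#'
#' For each variant the minor-allele count is `min(k, 2N' - k)` where `k` is
#' the alt-allele count and `N'` the number of non-missing diploid
#' individuals. Monomorphic variants (minor count 0) contribute to no bin.
#'
#' @param genotypes a [genotype_matrix] (subset to the clade/population of
#'   interest beforehand).
#' @param classes optional named character vector mapping variant ids to class
#'   labels; unnamed variants fall into class `"all"`.
#' @return data.frame with columns `class`, `minor_count`, `n_variants`;
#'   attribute `N` holds the diploid sample size. Bins run 1..N.
#' @export
folded_afs <- function(genotypes, classes = NULL) {
  N <- ncol(genotypes)
  k <- rowSums(genotypes, na.rm = TRUE)
  nprime <- rowSums(!is.na(genotypes))
  minor <- pmin(k, 2L * nprime - k)
  cls <- if (is.null(classes)) rep("all", nrow(genotypes)) else {
    out <- unname(classes[rownames(genotypes)])
    out[is.na(out)] <- "all"
    out
  }
  keep <- minor >= 1L & nprime > 0L
  bins <- seq_len(max(1L, N))
  res <- lapply(sort(unique(cls)), function(cl) {
    sel <- keep & cls == cl
    tab <- tabulate(minor[sel], nbins = max(bins))
    data.frame(class = cl, minor_count = bins, n_variants = tab[bins],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  attr(res, "N") <- N
  res
}

#' Per-variant Weir-Cockerham F_ST variance components
#'
#' Computes the among-population (`a`), among-individuals-within-population
#' (`b`) and within-individual (`c`) variance components of the
#' Weir-Cockerham estimator for a biallelic variant from diploid dosages,
#' accommodating unequal sample sizes and observed heterozygosity, and returns
#' `theta = a / (a + b + c)`. Theta may legitimately be negative; when
#' `a + b + c == 0` (monomorphic) theta is undefined and flagged. Missing
#' individuals are dropped variant-wise.
#'
#' @param dosage_row named dosage vector (0/1/2/NA).
#' @param populations named character vector assigning each individual to a
#'   population; at least two populations with >= 1 non-missing diploid each.
#' @return list with `a`, `b`, `c`, `theta`, `defined`, `n` (per-population
#'   non-missing counts).
#' @export
weir_cockerham_fst <- function(dosage_row, populations) {
  pops <- populations[names(dosage_row)]
  ok <- !is.na(dosage_row) & !is.na(pops)
  d <- dosage_row[ok]; p <- pops[ok]
  n_i <- tapply(rep(1L, length(d)), p, sum)
  n_i <- n_i[!is.na(n_i)]
  r <- length(n_i)
  if (r < 2L) stop("need >= 2 populations with non-missing genotypes", call. = FALSE)
  p_i <- tapply(d, p, mean) / 2          # alt allele frequency per population
  h_i <- tapply(d == 1L, p, mean)        # observed heterozygote proportion
  n_i <- as.numeric(n_i[names(p_i)])
  n_bar <- mean(n_i)
  n_tot <- sum(n_i)
  p_bar <- sum(n_i * p_i) / n_tot
  h_bar <- sum(n_i * h_i) / n_tot
  s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  n_c <- (n_tot - sum(n_i^2) / n_tot) / (r - 1)
  if (n_bar <= 1) {
    return(list(a = NA_real_, b = NA_real_, c = NA_real_, theta = NA_real_,
                defined = FALSE, n = stats::setNames(n_i, names(p_i))))
  }
  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) * (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  tot <- a + b + cc
  defined <- abs(tot) > .Machine$double.eps
  list(a = a, b = b, c = cc,
       theta = if (defined) a / tot else NA_real_,
       defined = defined, n = stats::setNames(n_i, names(p_i)))
}

#' Weir-Cockerham F_ST for every variant in a genotype matrix
#'
#' @param genotypes a [genotype_matrix].
#' @param populations named population assignment covering the matrix columns.
#' @return data.frame with columns `variant_id`, `a`, `b`, `c`, `theta`,
#'   `defined`.
#' @export
fst_scan <- function(genotypes, populations) {
  rows <- lapply(seq_len(nrow(genotypes)), function(i) {
    f <- weir_cockerham_fst(genotypes[i, ], populations)
    data.frame(variant_id = rownames(genotypes)[i], a = f$a, b = f$b, c = f$c,
               theta = f$theta, defined = f$defined, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Flag F_ST outliers above a percentile threshold
#'
#' The threshold is the linear-interpolation quantile (type 7) of the defined
#' theta values; outliers strictly exceed it. Undefined (monomorphic) variants
#' never enter the scan.
#'
#' @param fst data.frame from [fst_scan()], or a numeric theta vector with
#'   names as variant ids.
#' @param percentile percentile on the 0-100 scale (default 99).
#' @return list with `outliers` (variant ids), `threshold`, `n_defined`.
#' @export
fst_outliers <- function(fst, percentile = 99) {
  if (is.data.frame(fst)) {
    theta <- fst$theta[fst$defined]
    ids <- fst$variant_id[fst$defined]
  } else {
    ids <- names(fst)
    keep <- !is.na(fst)
    theta <- fst[keep]; ids <- ids[keep]
  }
  if (length(theta) < 2L) stop("need >= 2 defined theta values", call. = FALSE)
  thr <- stats::quantile(theta, probs = percentile / 100, type = 7, names = FALSE)
  list(outliers = ids[theta > thr], threshold = thr, n_defined = length(theta))
}

#' Fold enrichment of outliers on one chromosome
#'
#' `(outliers on chrom / total outliers) / (chrom length / assembly length)` —
#' the factor by which the chromosome carries more outliers than its share of
#' the assembly predicts.
#'
#' @param outlier_ids outlier variant ids.
#' @param records [sv_records] covering the outliers.
#' @param chrom_table a [chrom_table()] (the assembly).
#' @param chrom chromosome of interest.
#' @return list with `enrichment` (NA when there are no outliers),
#'   `n_on_chrom`, `n_outliers`, `length_fraction`.
#' @export
chrom_enrichment <- function(outlier_ids, records, chrom_table, chrom) {
  if (!chrom %in% chrom_table$chrom) stop("chromosome not in table: ", chrom, call. = FALSE)
  lf <- chrom_table$length[chrom_table$chrom == chrom] / sum(chrom_table$length)
  n_out <- length(outlier_ids)
  on_chrom <- sum(records$chrom[match(outlier_ids, records$id)] == chrom, na.rm = TRUE)
  list(enrichment = if (n_out == 0) NA_real_ else (on_chrom / n_out) / lf,
       n_on_chrom = on_chrom, n_outliers = n_out, length_fraction = lf)
}

#' SV density in fixed-width genomic windows
#'
#' Windows tile each chromosome without overlap (0-based half-open starts);
#' a record is assigned to the window containing its start. With
#' `collapse_overlapping`, overlapping same-type records are merged into one
#' counted cluster first (so tandem stacks of redundant calls count once).
#'
#' @param records an [sv_records] table.
#' @param chrom_table a [chrom_table()].
#' @param window window width in bp (default 1 Mb).
#' @param collapse_overlapping merge overlapping same-type records before
#'   counting (default TRUE).
#' @return data.frame with columns `chrom`, `window_start` (0-based), `count`.
#' @export
window_density <- function(records, chrom_table, window = 1000000L,
                           collapse_overlapping = TRUE) {
  res <- lapply(seq_len(nrow(chrom_table)), function(ci) {
    ch <- chrom_table$chrom[ci]; L <- chrom_table$length[ci]
    starts <- seq(0, L - 1, by = window)
    r <- records[records$chrom == ch, , drop = FALSE]
    pos <- r$pos
    if (collapse_overlapping && nrow(r)) {
      pos <- unlist(lapply(unique(r$svtype), function(tp) {
        rt <- r[r$svtype == tp, , drop = FALSE]
        IRanges::start(IRanges::reduce(IRanges::IRanges(rt$pos, rt$end)))
      }))
    }
    idx <- pmin(length(starts), (pos - 1) %/% window + 1)
    cnt <- tabulate(idx, nbins = length(starts))
    data.frame(chrom = ch, window_start = starts, count = cnt,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Principal component analysis of a genotype dosage matrix
#'
#' Variants with missing calls are mean-imputed per variant; each variant
#' column is then centered and the individual-by-individual covariance matrix
#' eigendecomposed. Components are ordered by decreasing eigenvalue; each
#' score vector's sign is fixed so its largest-magnitude entry is positive.
#'
#' @param genotypes a [genotype_matrix].
#' @param n_components number of components to return.
#' @return list with `scores` (individuals x components), `explained`
#'   (variance per component) and `explained_fraction`.
#' @export
genotype_pca <- function(genotypes, n_components = 2L) {
  if (ncol(genotypes) < 2L) stop("need >= 2 individuals", call. = FALSE)
  X <- t(unclass(genotypes))          # individuals x variants
  storage.mode(X) <- "double"
  for (j in seq_len(ncol(X))) {
    mj <- mean(X[, j], na.rm = TRUE)
    if (is.nan(mj)) mj <- 0
    X[is.na(X[, j]), j] <- mj
    X[, j] <- X[, j] - mj
  }
  if (all(abs(X) < 1e-12)) stop("genotype matrix has zero variance", call. = FALSE)
  C <- tcrossprod(X) / max(1L, ncol(X) - 1L)
  eig <- eigen(C, symmetric = TRUE)
  k <- min(n_components, ncol(eig$vectors))
  scores <- eig$vectors[, seq_len(k), drop = FALSE]
  lam <- pmax(eig$values, 0)
  scores <- sweep(scores, 2, sqrt(lam[seq_len(k)] * max(1L, nrow(X) - 1L)), `*`)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(scores[, j]))
    if (scores[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- colnames(genotypes)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, explained = lam[seq_len(k)],
       explained_fraction = lam[seq_len(k)] / sum(lam))
}
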