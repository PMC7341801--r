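# Dating an LTR retrotransposon insertion from the divergence between its two
# terminal repeats. The two LTRs are identical at insertion time; each copy
# then accumulates neutral substitutions independently, so the difference
# count k over an LTR of length L after t million years has expectation
# 2 * mu * L * t, giving t = k / (2 * mu * L). Because some observed
# differences may still be segregating rather than fixed, the estimate is an
# upper bound on the age.

#' Count differences between the two aligned LTR copies
#'
#' Differences are mismatched non-gap alignment columns plus isolated 1-bp
#' indel events. Gap runs of 2 bp or more are excluded from both the
#' difference count and the effective LTR length (their origin as single
#' mutational events of unknown age makes them uninformative under a per-site
#' clock).
#'
#' @param left,right aligned sequences of equal length (character strings,
#'   `-` for gaps).
#' @return list with `k` (difference count) and `L` (effective compared
#'   length in bp).
#' @export
count_ltr_differences <- function(left, right) {
  l <- strsplit(toupper(left), "")[[1]]
  r <- strsplit(toupper(right), "")[[1]]
  if (!length(l) || !length(r)) stop("empty alignment", call. = FALSE)
  if (length(l) != length(r)) stop("aligned sequences must have equal length", call. = FALSE)
  gap <- l == "-" | r == "-"
  runs <- rle(gap)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  long_gap <- logical(length(l))
  k_indel <- 0L
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    if (runs$lengths[i] == 1L) k_indel <- k_indel + 1L
    else long_gap[starts[i]:ends[i]] <- TRUE
  }
  cmp <- !gap & !long_gap
  k_sub <- sum(l[cmp] != r[cmp])
  L <- sum(!long_gap)
  list(k = as.integer(k_sub + k_indel), L = as.integer(L))
}

#' Estimate the insertion age of an LTR retrotransposon
#'
#' `age = k / (L * 2 * mu)` in million years, where `k` is the number of
#' differences (substitutions + 1-bp indels) between the two LTRs, `L` the
#' LTR length in bp and `mu` the neutral substitution rate per site per
#' million years. Reported in both Myr and years; the value is an upper bound
#' when not all differences are fixed.
#'
#' @param k difference count (>= 0).
#' @param L LTR length in bp (>= 1).
#' @param mu neutral substitution rate per site per million years (default
#'   0.0158, a corvid genome-wide estimate).
#' @return list with `age_myr` and `age_years`.
#' @export
#' @examples
#' estimate_insertion_age(k = 5, L = 296, mu = 0.0158)
estimate_insertion_age <- function(k, L, mu = 0.0158) {
  if (L < 1) stop("L must be >= 1", call. = FALSE)
  if (mu <= 0) stop("mu must be positive", call. = FALSE)
  if (k < 0 || k > L) stop("k must lie in [0, L]", call. = FALSE)
  age <- k / (L * 2 * mu)
  list(age_myr = age, age_years = age * 1e6)
}
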