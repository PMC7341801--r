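# Synthetic two-clade diploid SV cohorts with ground-truth labels.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: clade-private variants under the infinite sites model with a
# neutral 1/i folded frequency spectrum for interspersed and unannotated
# classes, hypermutable tandem-repeat loci at intermediate frequencies,
# injected cross-clade false positives segregating in both clades, per-call
# genotyping error and dropout, and repeat-family length mixtures with peaks
# near 0.9 / 2.4 / 6.5 kb for the LTR class.

#' Default chromosome-length table used by the simulator
#'
#' Ten chromosomes totalling 120 Mb, with sizes spanning two orders of
#' magnitude as in avian karyotypes (macro- and microchromosomes).
#'
#' @return a [chrom_table()].
#' @export
default_chrom_table <- function() {
  chrom_table(paste0("chr", 1:10),
              c(40e6, 25e6, 18e6, 12e6, 9e6, 7e6, 4e6, 2.5e6, 1.5e6, 1e6))
}

#' Simulation parameters for a two-clade SV cohort
#'
#' Defaults mirror the sampling design the package targets: 8 individuals in
#' clade A (the smaller, jackdaw-like clade) and 24 in clade B (the crow-like
#' clade), a repeat-class mix close to the empirical composition of long-read
#' avian SV sets (about half the variants without a repeat match, roughly
#' equal tandem and interspersed shares), a 5% cross-clade false-positive
#' injection rate, and small per-call error (1%) and dropout (2%) rates.
#'
#' @param n_clade_A,n_clade_B diploid individual counts per clade.
#' @param m_variants number of variants to simulate.
#' @param class_mix named proportions over
#'   `c("tandem","LTR","LINE/CR1","no_match")`; must sum to 1.
#' @param fp_cross_clade_rate fraction of variants injected as segregating in
#'   both clades (genotyping artifacts / hypermutable sites).
#' @param genotyping_error_rate per-genotype-call flip probability; a flipped
#'   call moves to one of the other two dosage states uniformly.
#' @param missing_rate per-call dropout probability (to `NA`).
#' @param fp_end_bias fraction of false positives placed within 5% of a
#'   chromosome end, emulating the enrichment of artifacts in repeat-dense
#'   chromosome ends.
#' @param chrom_table chromosome-length table variants are placed on.
#' @param seed integer seed; all randomness is fanned out to named substreams
#'   so each stage's draws are stable when other stages change.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(n_clade_A = 8L, n_clade_B = 24L, m_variants = 1000L,
                       class_mix = c(tandem = 0.215, LTR = 0.235,
                                     "LINE/CR1" = 0.028, no_match = 0.522),
                       fp_cross_clade_rate = 0.05,
                       genotyping_error_rate = 0.01,
                       missing_rate = 0.02,
                       fp_end_bias = 0.5,
                       chrom_table = default_chrom_table(),
                       seed = 1L) {
  stopifnot(n_clade_A >= 1, n_clade_B >= 1)
  if (m_variants < 1) stop("m_variants must be >= 1", call. = FALSE)
  probs <- c(fp_cross_clade_rate, genotyping_error_rate, missing_rate, fp_end_bias)
  if (any(probs < 0 | probs > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1", call. = FALSE)
  if (any(class_mix < 0)) stop("class_mix proportions must be non-negative", call. = FALSE)
  structure(list(n_clade_A = as.integer(n_clade_A), n_clade_B = as.integer(n_clade_B),
                 m_variants = as.integer(m_variants), class_mix = class_mix,
                 fp_cross_clade_rate = fp_cross_clade_rate,
                 genotyping_error_rate = genotyping_error_rate,
                 missing_rate = missing_rate, fp_end_bias = fp_end_bias,
                 chrom_table = chrom_table, seed = as.integer(seed)),
            class = "sim_params")
}

# Minor-allele count drawn with P(i) proportional to 1/i (neutral folded SFS),
# i = 1 .. floor(2N/2).
rsfs_count <- function(n, n_dip) {
  imax <- n_dip  # floor(2N/2)
  p <- (1 / seq_len(imax)) / sum(1 / seq_len(imax))
  sample.int(imax, n, replace = TRUE, prob = p)
}

# Intermediate-frequency minor-allele count for hypermutable tandem loci:
# frequency from a symmetric Beta centred at 0.5, folded to the minor allele.
rtandem_count <- function(n, n_dip) {
  p <- stats::rbeta(n, 3, 3)
  cnt <- pmin(pmax(round(p * 2 * n_dip), 1L), 2L * n_dip - 1L)
  pmin(cnt, 2L * n_dip - cnt)
}

# Place `count` alt alleles on 2N haplotypes and collapse to diploid dosages.
dosages_from_count <- function(count, n_dip) {
  hap <- integer(2L * n_dip)
  hap[sample.int(2L * n_dip, count)] <- 1L
  hap[seq(1L, 2L * n_dip, by = 2L)] + hap[seq(2L, 2L * n_dip, by = 2L)]
}

# Class-conditional SV length model (bp, clipped to [51, 99999]). The LTR
# class is a three-component Gaussian mixture with peaks at 0.9/2.4/6.5 kb
# over a small log-normal background; other classes are log-normal.
rsvlen <- function(n, class) {
  out <- numeric(n)
  ltr <- class == "LTR"
  if (any(ltr)) {
    k <- sum(ltr)
    comp <- sample.int(4L, k, replace = TRUE, prob = c(0.40, 0.30, 0.18, 0.12))
    x <- stats::rlnorm(k, log(600), 0.9)             # background component
    peak <- comp < 4L
    x[peak] <- stats::rnorm(sum(peak), c(900, 2400, 6500)[comp[peak]],
                            c(60, 160, 420)[comp[peak]])
    out[ltr] <- x
  }
  rest <- !ltr
  if (any(rest)) {
    meanlog <- c(tandem = log(150), "LINE/CR1" = log(500), no_match = log(200))
    sdlog <- c(tandem = 0.9, "LINE/CR1" = 0.8, no_match = 1.0)
    cl <- class[rest]
    out[rest] <- stats::rlnorm(sum(rest), meanlog[cl], sdlog[cl])
  }
  as.integer(pmin(pmax(round(out), 51), 99999))
}

#' Simulate a two-clade diploid SV cohort with ground truth
#'
#' Clade-private variants are drawn with minor-allele counts proportional to
#' `1/i` (tandem loci instead from a symmetric Beta centred at 0.5) in their
#' clade of origin and are homozygous reference in the other clade before
#' error injection. Cross-clade false positives segregate at intermediate
#' frequency (per-clade minor-allele count uniform over 35-65% of 2N) in both
#' clades. Genotyping errors then flip each call independently to one of the
#' other two dosage states; dropout sets calls to missing. The truth table
#' records the pre-error state of every variant.
#'
#' @param params a [sim_params()] object.
#' @return a list with `records` ([sv_records]), `genotypes`
#'   ([genotype_matrix]), `truth` (data.frame: `variant_id`, `origin` in
#'   `{A, B, cross_clade_FP}`, `class`, `true_length`, `true_minor_count`),
#'   `true_dosage` (pre-error matrix), `repeats` (repeat-match table),
#'   `clades` (a [clade_map]) and `params`.
#' @export
simulate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  m <- params$m_variants
  nA <- params$n_clade_A; nB <- params$n_clade_B
  ids <- sprintf("sv%05d", seq_len(m))
  individuals <- c(sprintf("A_%02d", seq_len(nA)), sprintf("B_%02d", seq_len(nB)))
  clades <- clade_map(individuals,
                      population = c(rep("popA1", nA), rep("popB1", nB %/% 2), rep("popB2", nB - nB %/% 2)),
                      clade = c(rep("A", nA), rep("B", nB)),
                      tolerances = c(A = 2L, B = 4L))

  set.seed(substream_seed(params$seed, "classes"))
  class <- sample(names(params$class_mix), m, replace = TRUE, prob = params$class_mix)
  is_fp <- stats::runif(m) < params$fp_cross_clade_rate
  # private variants arise in a clade with probability proportional to its size
  origin <- ifelse(is_fp, "cross_clade_FP",
                   ifelse(stats::runif(m) < nA / (nA + nB), "A", "B"))

  set.seed(substream_seed(params$seed, "lengths"))
  svlen <- rsvlen(m, class)
  svtype <- sample(c("INS", "DEL", "INV"), m, replace = TRUE, prob = c(0.55, 0.43, 0.02))

  set.seed(substream_seed(params$seed, "positions"))
  ct <- params$chrom_table
  chrom_i <- sample.int(nrow(ct), m, replace = TRUE, prob = ct$length / sum(ct$length))
  pos <- integer(m)
  span <- ifelse(svtype == "INS", 1L, svlen)
  for (i in seq_len(m)) {
    L <- ct$length[chrom_i[i]]
    if (origin[i] == "cross_clade_FP" && stats::runif(1) < params$fp_end_bias) {
      edge <- max(1, round(0.05 * L))
      p <- sample.int(edge, 1L)
      if (stats::runif(1) < 0.5) p <- as.integer(L - span[i] - p + 1L)
      pos[i] <- max(1L, p)
    } else {
      pos[i] <- sample.int(max(1, L - span[i]), 1L)
    }
  }

  set.seed(substream_seed(params$seed, "genotypes"))
  true_dosage <- matrix(0L, nrow = m, ncol = nA + nB,
                        dimnames = list(ids, individuals))
  colA <- seq_len(nA); colB <- nA + seq_len(nB)
  fp_count_range <- function(n_dip) {
    lo <- round(0.35 * 2 * n_dip); hi <- round(0.65 * 2 * n_dip)
    c(lo, hi)
  }
  minor_count <- integer(m)
  for (i in seq_len(m)) {
    if (origin[i] == "cross_clade_FP") {
      rA <- fp_count_range(nA); rB <- fp_count_range(nB)
      cA <- sample(seq(rA[1], rA[2]), 1L)
      cB <- sample(seq(rB[1], rB[2]), 1L)
      true_dosage[i, colA] <- dosages_from_count(cA, nA)
      true_dosage[i, colB] <- dosages_from_count(cB, nB)
      minor_count[i] <- min(cA + cB, 2L * (nA + nB) - cA - cB)
    } else {
      focal <- if (origin[i] == "A") colA else colB
      n_dip <- length(focal)
      cnt <- if (class[i] == "tandem") rtandem_count(1L, n_dip) else rsfs_count(1L, n_dip)
      true_dosage[i, focal] <- dosages_from_count(cnt, n_dip)
      minor_count[i] <- cnt
    }
  }

  set.seed(substream_seed(params$seed, "errors"))
  dosage <- true_dosage
  if (params$genotyping_error_rate > 0) {
    flip <- matrix(stats::runif(length(dosage)) < params$genotyping_error_rate,
                   nrow = m)
    idx <- which(flip)
    if (length(idx)) {
      cur <- dosage[idx]
      # move to one of the two other dosage states uniformly
      shift <- sample.int(2L, length(idx), replace = TRUE)
      dosage[idx] <- (cur + shift) %% 3L
    }
  }
  set.seed(substream_seed(params$seed, "missing"))
  if (params$missing_rate > 0) {
    drop <- matrix(stats::runif(length(dosage)) < params$missing_rate, nrow = m)
    dosage[drop] <- NA_integer_
  }

  set.seed(substream_seed(params$seed, "repeats"))
  repeats <- simulate_repeat_matches(ids, class, svlen)

  records <- sv_records(chrom = ct$chrom[chrom_i], pos = pos, id = ids,
                        svtype = svtype, svlen = svlen,
                        end = ifelse(svtype == "INS", pos, pos + svlen),
                        support = pmin(60L, pmax(5L, stats::rpois(m, 15))))
  truth <- data.frame(variant_id = ids, origin = origin, class = class,
                      true_length = svlen, true_minor_count = minor_count,
                      stringsAsFactors = FALSE)
  list(records = records, genotypes = genotype_matrix(dosage), truth = truth,
       true_dosage = true_dosage, repeats = repeats, clades = clades,
       params = params)
}

# Repeat-match rows consistent with each variant's true class: one primary
# match covering 60-100% of the variant, plus occasional weaker secondary
# matches that exercise the best-overlap assignment rule.
simulate_repeat_matches <- function(ids, class, svlen) {
  families <- list(
    tandem = c("(AT)n", "(CAG)n", "Low_complexity_1"),
    LTR = c("ERVK-LTR1", "ERVK-LTR2", "ERVL-LTR3"),
    "LINE/CR1" = c("CR1-E1", "CR1-X2")
  )
  rows <- list()
  for (i in seq_along(ids)) {
    if (class[i] == "no_match") next
    fam <- families[[class[i]]]
    ov <- as.integer(round(svlen[i] * stats::runif(1, 0.6, 1.0)))
    rows[[length(rows) + 1L]] <- data.frame(
      variant_id = ids[i], repeat_name = sample(fam, 1L),
      repeat_class = class[i], overlap_bp = max(1L, ov),
      score = round(stats::runif(1, 200, 2000)), stringsAsFactors = FALSE)
    if (stats::runif(1) < 0.25) {  # secondary, smaller-overlap match
      alt_class <- sample(setdiff(names(families), class[i]), 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = ids[i], repeat_name = sample(families[[alt_class]], 1L),
        repeat_class = alt_class,
        overlap_bp = max(1L, as.integer(round(ov * stats::runif(1, 0.1, 0.8)))),
        score = round(stats::runif(1, 100, 1000)), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(variant_id = character(), repeat_name = character(),
                      repeat_class = character(), overlap_bp = integer(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Simulate jittered multi-caller call sets from a set of true variants
#'
#' Emulates independent SV callers re-discovering the same loci: each caller
#' sees each variant with probability `1 - dropout`, with its breakpoint
#' displaced by Gaussian noise. Used to exercise consensus merging.
#'
#' @param records an [sv_records] table of true calls.
#' @param n_callers number of callers.
#' @param dropout per-caller miss probability.
#' @param jitter_sd breakpoint noise SD in bp.
#' @param seed integer seed.
#' @return named list of [sv_records] tables, one per caller.
#' @export
simulate_caller_sets <- function(records, n_callers = 3L, dropout = 0.1,
                                 jitter_sd = 100, seed = 1L) {
  set.seed(substream_seed(seed, "callers"))
  out <- list()
  for (k in seq_len(n_callers)) {
    keep <- stats::runif(nrow(records)) >= dropout
    r <- records[keep, , drop = FALSE]
    shift <- as.integer(round(stats::rnorm(nrow(r), 0, jitter_sd)))
    r$pos <- pmax(1L, r$pos + shift)
    r$end <- ifelse(r$svtype == "INS", r$pos, r$pos + r$svlen)
    r$id <- paste0("caller", k, "_", r$id)
    r <- r[order(r$chrom, r$pos), , drop = FALSE]
    out[[paste0("caller", k)]] <- validate_sv_records(r)
  }
  out
}

#' Simulate a pair of LTR sequences diverged since insertion
#'
#' The two long terminal repeats of a full-length LTR retrotransposon are
#' identical at insertion time; substitutions accumulate independently on each
#' copy afterwards, so the number of differences after `t` million years is
#' Poisson with mean `2 * mu * L * t`.
#'
#' @param age_myr insertion age in million years (>= 0).
#' @param ltr_len LTR length L in bp.
#' @param rate neutral substitution rate per site per million years.
#' @param seed integer seed.
#' @return list with `left`, `right` (character sequences of length `ltr_len`)
#'   and `n_diff`, the planted difference count.
#' @export
simulate_ltr_pair <- function(age_myr, ltr_len = 296L, rate = 0.0158, seed = 1L) {
  stopifnot(age_myr >= 0, ltr_len >= 1, rate > 0)
  lambda <- 2 * rate * ltr_len * age_myr
  if (lambda > ltr_len) stop("expected differences exceed LTR length; saturation not modeled", call. = FALSE)
  set.seed(substream_seed(seed, "ltr"))
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, ltr_len, replace = TRUE)
  k <- stats::rpois(1L, lambda)
  k <- min(k, ltr_len)
  right <- anc
  if (k > 0) {
    sites <- sample.int(ltr_len, k)
    right[sites] <- vapply(right[sites],
                           function(b) sample(setdiff(bases, b), 1L), character(1))
  }
  list(left = paste(anc, collapse = ""), right = paste(right, collapse = ""),
       n_diff = k)
}

#' Simulate phenotype/expression values from genotype dosages
#'
#' `y = beta_a * additive + beta_d * dominance + N(0, noise_sd)` per
#' individual, with the additive component counting non-inserted minor-allele
#' copies and the dominance component flagging heterozygotes (the coding used
#' for insertion genotype-phenotype association).
#'
#' @param dosages named integer vector of alt-allele dosages in `{0,1,2}`.
#' @param beta_a additive effect per non-inserted allele copy.
#' @param beta_d dominance (heterozygote) effect.
#' @param noise_sd residual SD (>= 0).
#' @param insertion_is_reference flag passed to [code_genotypes()].
#' @param seed integer seed.
#' @return data.frame with columns `individual`, `phenotype`, `additive`,
#'   `dominance`.
#' @export
simulate_phenotypes <- function(dosages, beta_a, beta_d, noise_sd,
                                insertion_is_reference = FALSE, seed = 1L) {
  stopifnot(is.finite(beta_a), is.finite(beta_d), noise_sd >= 0)
  coded <- code_genotypes(dosages, insertion_is_reference = insertion_is_reference)
  set.seed(substream_seed(seed, "phenotypes"))
  y <- beta_a * coded$additive + beta_d * coded$dominance +
    stats::rnorm(nrow(coded), 0, noise_sd)
  data.frame(individual = coded$individual, phenotype = y,
             additive = coded$additive, dominance = coded$dominance,
             stringsAsFactors = FALSE)
}
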