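# Genotype-phenotype association with additive + dominance genotype coding
# and AICc/BIC model comparison.

#' Code dosage genotypes into additive and dominance components
#'
#' The additive component counts copies of the non-inserted (minor) allele —
#' 0, 1 or 2 — and the dominance component flags heterozygotes (homozygous =
#' 0, heterozygous = 1). When the insertion is the reference allele (an
#' insertion called as a deletion relative to a reference that carries it),
#' the alt dosage already counts non-inserted copies; otherwise it is
#' reflected as `2 - dosage`. Missing dosages are dropped with a message.
#'
#' @param dosages named integer vector of alt-allele dosages (0/1/2/NA).
#' @param insertion_is_reference is the insertion allele the reference allele?
#' @return data.frame with columns `individual`, `additive`, `dominance`.
#' @export
code_genotypes <- function(dosages, insertion_is_reference = FALSE) {
  miss <- is.na(dosages)
  if (any(miss)) {
    message(sum(miss), " individual(s) with missing genotype dropped")
    dosages <- dosages[!miss]
  }
  stopifnot(all(dosages %in% 0:2))
  additive <- if (insertion_is_reference) as.integer(dosages) else 2L - as.integer(dosages)
  data.frame(individual = names(dosages) %||% as.character(seq_along(dosages)),
             additive = additive,
             dominance = as.integer(dosages == 1L),
             stringsAsFactors = FALSE)
}

#' Fit an ordinary least squares model and its information criteria
#'
#' Wraps `stats::lm()` and reports the Gaussian log-likelihood, AIC,
#' small-sample-corrected AICc (`AIC + 2p(p+1)/(n-p-1)`), BIC and R-squared.
#' The parameter count `p` includes the intercept and the residual variance.
#'
#' @param formula model formula.
#' @param data data.frame holding response and covariates.
#' @return a list of class `sv_model_fit` with elements `model` (the `lm`
#'   fit), `formula`, `n`, `p`, `logLik`, `AIC`, `AICc`, `BIC`, `r_squared`,
#'   `coefficients` (summary table).
#' @export
fit_linear_model <- function(formula, data) {
  fit <- stats::lm(formula, data = data)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- stats::nobs(fit)
  ll <- stats::logLik(fit)
  p <- attr(ll, "df")  # coefficients + residual variance
  if (n <= p) stop("need n > p observations", call. = FALSE)
  aic <- stats::AIC(fit)
  aicc <- aic + 2 * p * (p + 1) / (n - p - 1)
  structure(list(model = fit, formula = formula, n = n, p = p,
                 logLik = as.numeric(ll), AIC = aic, AICc = aicc,
                 BIC = stats::BIC(fit),
                 r_squared = summary(fit)$r.squared,
                 coefficients = summary(fit)$coefficients),
            class = "sv_model_fit")
}

#' @export
print.sv_model_fit <- function(x, ...) {
  cat("Linear model fit (n =", x$n, ", p =", x$p, ")\n")
  cat(sprintf("  logLik %.4f  AIC %.4f  AICc %.4f  BIC %.4f  R2 %.4f\n",
              x$logLik, x$AIC, x$AICc, x$BIC, x$r_squared))
  stats::printCoefmat(x$coefficients)
  invisible(x)
}

#' Compare two model fits by AICc, with BIC reported alongside
#'
#' `delta_aicc = AICc(B) - AICc(A)` for candidate model A against alternative
#' B; A is selected when `delta_aicc >= threshold` (default 2). The BIC
#' difference is reported the same way and may disagree with the AICc verdict.
#' Both fits must be on the same response subset (equal n).
#'
#' @param fit_A candidate [fit_linear_model()] fit.
#' @param fit_B alternative fit on the same data subset.
#' @param aicc_threshold selection threshold on delta AICc (default 2).
#' @return list with `delta_aicc`, `delta_bic`, `select_A_by_aicc`,
#'   `select_A_by_bic`, `agreement`.
#' @export
compare_models <- function(fit_A, fit_B, aicc_threshold = 2) {
  if (fit_A$n != fit_B$n) {
    stop("model fits use different numbers of observations; ",
         "fit both on the same subset of the data", call. = FALSE)
  }
  d_aicc <- fit_B$AICc - fit_A$AICc
  d_bic <- fit_B$BIC - fit_A$BIC
  list(delta_aicc = d_aicc, delta_bic = d_bic,
       select_A_by_aicc = d_aicc >= aicc_threshold,
       select_A_by_bic = d_bic >= aicc_threshold,
       agreement = (d_aicc >= aicc_threshold) == (d_bic >= aicc_threshold))
}

#' Association between expression (or any phenotype) and a coded genotype
#'
#' OLS of the response on the additive component, optionally with the
#' dominance component, reporting the two-sided additive-coefficient p-value.
#'
#' @param values named numeric response (e.g. normalized expression), names
#'   matching coded-genotype individuals.
#' @param coded data.frame from [code_genotypes()].
#' @param include_dominance add the dominance indicator (default FALSE).
#' @return a `sv_model_fit` with extra elements `p_value` and `slope` for the
#'   additive term.
#' @export
expression_association <- function(values, coded, include_dominance = FALSE) {
  df <- merge(data.frame(individual = names(values), y = as.numeric(values),
                         stringsAsFactors = FALSE),
              coded, by = "individual")
  if (nrow(df) < 3L) stop("need >= 3 individuals with genotype and phenotype", call. = FALSE)
  if (length(unique(df$additive)) < 2L) stop("only one genotype class present", call. = FALSE)
  form <- if (include_dominance) y ~ additive + dominance else y ~ additive
  fit <- fit_linear_model(form, df)
  fit$slope <- unname(stats::coef(fit$model)["additive"])
  fit$p_value <- fit$coefficients["additive", "Pr(>|t|)"]
  fit
}
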