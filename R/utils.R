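#' @keywords internal
"_PACKAGE"

SV_TYPES <- c("INS", "DEL", "INV")

REPEAT_CLASSES <- c("tandem", "LTR", "LINE/CR1", "SINE", "DNA", "other", "no_match")

#' Derive a reproducible substream seed from a global seed and a stream name
#'
#' A single user-facing integer seed is fanned out to named substreams so that
#' adding a simulation stage never perturbs the draws of another stage.
#'
#' @param seed integer global seed.
#' @param stream character stream name.
#' @return an integer seed below 2^31.
#' @keywords internal
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(stream) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 131L)
  as.integer((abs(seed) + h) %% .Machine$integer.max)
}

#' Percentage of a count relative to a total
#'
#' Convenience used by retention and overlap summaries: `100 * part / total`.
#'
#' @param part,total non-negative counts, `total > 0`.
#' @return percentage on the 0-100 scale.
#' @export
#' @examples
#' percent_of(41868, 47346)
percent_of <- function(part, total) {
  stopifnot(is.numeric(part), is.numeric(total), total > 0)
  100 * part / total
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
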