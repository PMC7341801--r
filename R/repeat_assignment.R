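# Reduce multi-hit repeat tables to one repeat family/class per variant and
# tabulate class composition.

#' Assign the single best repeat match per variant
#'
#' Among a variant's matches the one with the highest overlap (bp of the
#' variant sequence covered) wins; ties break by higher alignment score, then
#' lexicographic repeat name. Variants without any match are assigned
#' `no_match`. Assignment is deterministic regardless of input row order.
#'
#' @param matches repeat-match data.frame (see [read_repeat_table()]).
#' @param variant_ids ids of all variants to annotate (including unmatched).
#' @return data.frame with columns `variant_id`, `repeat_name`,
#'   `repeat_class`, `overlap_bp`, `score`; one row per variant.
#' @export
assign_best_repeat <- function(matches, variant_ids) {
  out <- data.frame(variant_id = as.character(variant_ids),
                    repeat_name = NA_character_, repeat_class = "no_match",
                    overlap_bp = 0L, score = NA_real_, stringsAsFactors = FALSE)
  if (nrow(matches)) {
    m <- matches[order(matches$variant_id, -matches$overlap_bp,
                       -xtfrm(matches$score), matches$repeat_name), , drop = FALSE]
    best <- m[!duplicated(m$variant_id), , drop = FALSE]
    hit <- match(out$variant_id, best$variant_id)
    got <- !is.na(hit)
    out$repeat_name[got] <- best$repeat_name[hit[got]]
    out$repeat_class[got] <- best$repeat_class[hit[got]]
    out$overlap_bp[got] <- best$overlap_bp[hit[got]]
    out$score[got] <- best$score[hit[got]]
  }
  out
}

#' Repeat-class composition of a set of assignments
#'
#' @param assignments data.frame from [assign_best_repeat()].
#' @return data.frame with columns `repeat_class`, `n`, `percent` (summing to
#'   100 within rounding), ordered by decreasing count.
#' @export
class_composition <- function(assignments) {
  if (!nrow(assignments)) stop("no assignments to tabulate", call. = FALSE)
  tab <- table(assignments$repeat_class)
  out <- data.frame(repeat_class = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$percent <- percent_of(out$n, sum(out$n))
  out[order(-out$n, out$repeat_class), , drop = FALSE]
}
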