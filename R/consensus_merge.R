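# Multi-caller consensus merging and post-calling filters: SURVIVOR-style
# single-linkage clustering of breakpoints within a distance window, a
# distinct-caller support threshold, read-support/length filters, and
# low-mapping-quality region masking.

#' Named merge parameter presets
#'
#' Two presets mirror common long-read and short-read merging configurations:
#' `"lr"` keeps every caller's calls of at least 50 bp (`1000 1 1 0 0 50`) and
#' `"sr"` requires two callers to agree within 1 kb (`1000 2 1 0 0 0`).
#'
#' @param name `"lr"` or `"sr"`.
#' @return list of `max_dist`, `min_callers`, `require_type_match`, `min_size`.
#' @export
merge_preset <- function(name = c("sr", "lr")) {
  name <- match.arg(name)
  if (name == "lr") {
    list(max_dist = 1000L, min_callers = 1L, require_type_match = TRUE, min_size = 50L)
  } else {
    list(max_dist = 1000L, min_callers = 2L, require_type_match = TRUE, min_size = 0L)
  }
}

#' Merge SV call sets from multiple callers by breakpoint proximity
#'
#' Calls are clustered per chromosome (and per SV type when
#' `require_type_match`) by single linkage on start positions: two calls join
#' the same cluster when their breakpoints lie within `max_dist` bp. Because
#' linkage is transitive, chained clusters may span more than `max_dist` —
#' intentional, matching the semantics of breakpoint-window merging tools.
#' Clusters supported by fewer than `min_callers` distinct callers, or whose
#' representative is shorter than `min_size`, are dropped. The representative
#' is the member with the median SV length (ties resolved by leftmost
#' position, then id).
#'
#' @param call_sets named list of [sv_records] tables, one per caller; each
#'   must be sorted by `(chrom, pos)`.
#' @param max_dist maximum breakpoint distance in bp (default 1000).
#' @param require_type_match cluster only same-type calls (default TRUE).
#' @param min_callers minimum number of distinct supporting callers.
#' @param min_size minimum representative SV length in bp.
#' @return a `data.frame` of merged calls: representative record columns plus
#'   `n_callers`, `callers` and `member_ids` (comma-separated).
#' @export
merge_call_sets <- function(call_sets, max_dist = 1000L, require_type_match = TRUE,
                            min_callers = 2L, min_size = 0L) {
  if (!length(call_sets)) stop("at least one call set is required", call. = FALSE)
  if (is.null(names(call_sets)) || any(!nzchar(names(call_sets)))) {
    names(call_sets) <- paste0("caller", seq_along(call_sets))
  }
  for (nm in names(call_sets)) {
    r <- call_sets[[nm]]
    o <- order(r$chrom, r$pos)
    if (!identical(o, seq_len(nrow(r)))) stop("call set '", nm, "' is not sorted by (chrom, pos)", call. = FALSE)
  }
  all <- do.call(rbind, lapply(names(call_sets), function(nm) {
    r <- as.data.frame(call_sets[[nm]])
    if (nrow(r)) r$caller <- nm else r$caller <- character(0)
    r
  }))
  if (!nrow(all)) {
    return(data.frame(chrom = character(), pos = integer(), id = character(),
                      svtype = character(), svlen = integer(), end = integer(),
                      seq = character(), support = integer(),
                      n_callers = integer(), callers = character(),
                      member_ids = character(), stringsAsFactors = FALSE))
  }
  key <- if (require_type_match) paste(all$chrom, all$svtype) else all$chrom
  out <- list()
  for (k in sort(unique(key))) {
    g <- all[key == k, , drop = FALSE]
    g <- g[order(g$pos, g$id), , drop = FALSE]
    gap <- c(0L, diff(g$pos))
    cluster <- cumsum(gap > max_dist)
    for (cl in unique(cluster)) {
      mem <- g[cluster == cl, , drop = FALSE]
      if (length(unique(mem$caller)) < min_callers) next
      med <- stats::median(mem$svlen)
      cand <- mem[order(abs(mem$svlen - med), mem$pos, mem$id), , drop = FALSE]
      rep <- cand[1L, , drop = FALSE]
      if (rep$svlen < min_size) next
      rep$n_callers <- length(unique(mem$caller))
      rep$callers <- paste(sort(unique(mem$caller)), collapse = ",")
      rep$member_ids <- paste(mem$id, collapse = ",")
      rep$caller <- NULL
      out[[length(out) + 1L]] <- rep
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), pos = integer(), id = character(),
                      svtype = character(), svlen = integer(), end = integer(),
                      seq = character(), support = integer(),
                      n_callers = integer(), callers = character(),
                      member_ids = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$pos, res$id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter SV records on supporting-read count and length
#'
#' Keeps a record iff `min_support <= support <= max_support` and
#' `svlen <= max_len`; input order is preserved. Very high read support is as
#' suspect as very low support (collapsed repeats attract excess reads), hence
#' the upper bound.
#'
#' @param records an [sv_records] table with `support` populated.
#' @param min_support,max_support inclusive read-support bounds (5, 60).
#' @param max_len maximum SV length in bp (100 kb).
#' @return the retained subset of `records`.
#' @export
filter_support_and_length <- function(records, min_support = 5L, max_support = 60L,
                                      max_len = 100000L) {
  if (anyNA(records$support)) {
    stop("missing support for variant(s): ",
         paste(utils::head(records$id[is.na(records$support)], 5), collapse = ", "),
         call. = FALSE)
  }
  keep <- records$support >= min_support & records$support <= max_support &
    records$svlen <= max_len
  records[keep, , drop = FALSE]
}

#' Drop SV records overlapping low-mapping-quality regions
#'
#' A record is removed when its interval `[pos, end]` intersects any masked
#' interval on the same chromosome by at least 1 bp; adjacency is not overlap.
#' Chromosomes absent from the track are treated as unmasked with a warning.
#'
#' @param records an [sv_records] table.
#' @param track data.frame of masked intervals with columns `chrom`, `start`,
#'   `end` (1-based inclusive, e.g. from [read_bed()]), typically regions
#'   where low-MQ read coverage exceeds a depth threshold.
#' @return the retained subset of `records`.
#' @export
mask_low_mq <- function(records, track) {
  if (!nrow(records)) return(records)
  if (any(track$end < track$start)) stop("invalid mask intervals", call. = FALSE)
  absent <- setdiff(unique(records$chrom), unique(track$chrom))
  if (length(absent)) {
    warning("chromosome(s) absent from low-MQ track, treated as unmasked: ",
            paste(absent, collapse = ", "))
  }
  drop <- logical(nrow(records))
  for (ch in intersect(unique(records$chrom), unique(track$chrom))) {
    ri <- which(records$chrom == ch)
    ti <- track[track$chrom == ch, , drop = FALSE]
    q <- IRanges::IRanges(start = records$pos[ri], end = records$end[ri])
    s <- IRanges::IRanges(start = ti$start, end = ti$end)
    hit <- IRanges::overlapsAny(q, s)
    drop[ri] <- hit
  }
  records[!drop, , drop = FALSE]
}
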