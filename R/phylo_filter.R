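# Phylogenetically informed genotype filtering. Two deeply diverged clades
# share essentially no polymorphism by descent, and under the infinite sites
# model the same variant is not expected to recur independently in both; a
# variant genotyped as segregating in both clades is therefore most likely a
# genotyping artifact (or a hypermutable site, which this filter deliberately
# sacrifices). Each clade's variant set is screened against the *other* clade
# as an outgroup, tolerating a small number of discordant outgroup genotypes.

#' Classify one variant against an outgroup clade
#'
#' Two outgroup consistency modes exist. `homref_outgroup`: the variant passes
#' when at most `tolerance` outgroup individuals carry a non-reference
#' genotype (used when screening the focal clade's segregating variants
#' against a clade where the variant should be absent). `fixed_outgroup`: the
#' outgroup must be fixed for either allele; the majority homozygous state
#' `s` in `{0, 2}` is determined among non-missing calls (tie resolves to 0)
#' and the variant passes when at most `tolerance` outgroup individuals
#' deviate from `s` (used when the outgroup diverged long ago and may be fixed
#' for either state).
#'
#' Missing outgroup calls are excluded from the error count by default:
#' counting dropout as discordance would conflate two different failure modes.
#'
#' @param dosage_row named dosage vector covering all mapped individuals.
#' @param clades a [clade_map].
#' @param focal_clade `"A"` or `"B"`; the outgroup is the other clade.
#' @param mode `"homref_outgroup"` or `"fixed_outgroup"`.
#' @param tolerance maximum tolerated discordant outgroup genotypes; defaults
#'   to the outgroup clade's tolerance from the clade map.
#' @param missing_as_error count missing outgroup calls as errors (default
#'   FALSE).
#' @return list with `retained`, `error_count`, `outgroup_state` (for
#'   `fixed_outgroup`), `n_outgroup_used`.
#' @export
classify_variant <- function(dosage_row, clades, focal_clade,
                             mode = c("homref_outgroup", "fixed_outgroup"),
                             tolerance = NULL, missing_as_error = FALSE) {
  mode <- match.arg(mode)
  stopifnot(focal_clade %in% c("A", "B"))
  outgroup_clade <- setdiff(c("A", "B"), focal_clade)
  focal_ids <- clade_individuals(clades, focal_clade)
  out_ids <- clade_individuals(clades, outgroup_clade)
  if (!length(focal_ids)) stop("focal clade is empty", call. = FALSE)
  if (!length(out_ids)) stop("outgroup clade is empty", call. = FALSE)
  if (is.null(tolerance)) tolerance <- clade_tolerance(clades, outgroup_clade)
  og <- dosage_row[out_ids]
  miss <- is.na(og)
  obs <- og[!miss]
  state <- NA_integer_
  if (mode == "homref_outgroup") {
    errors <- sum(obs != 0L)
  } else {
    n_hom_ref <- sum(obs == 0L)
    n_hom_alt <- sum(obs == 2L)
    state <- if (n_hom_alt > n_hom_ref) 2L else 0L  # tie -> reference
    errors <- sum(obs != state)
  }
  if (missing_as_error) errors <- errors + sum(miss)
  list(retained = errors <= tolerance, error_count = as.integer(errors),
       outgroup_state = state, n_outgroup_used = length(obs))
}

#' Apply the phylogenetic filter to a whole genotype matrix
#'
#' The clade-A variant set keeps variants whose clade-B outgroup is
#' homozygous reference up to `tolerance(B)` errors; the clade-B set keeps
#' variants whose clade-A outgroup is fixed for either allele up to
#' `tolerance(A)` errors. The asymmetry reflects polarization against the
#' reference genome: a variant truly private to the deep outgroup lineage can
#' be fixed for either allele there, whereas the reference-proximal clade is
#' expected to be uniformly homozygous reference for variants private to the
#' other clade.
#'
#' @param genotypes a [genotype_matrix].
#' @param clades a [clade_map] covering all matrix individuals.
#' @param missing_as_error passed to [classify_variant()].
#' @return list with `verdicts` (data.frame: `variant_id`, `retained_A`,
#'   `retained_B`, `retained`, `error_count_A` (clade-A analysis, outgroup B),
#'   `error_count_B`, `reason` in
#'   `{clean, within_tolerance, cross_clade, all_missing}`), `retained_A`,
#'   `retained_B`, `retained_union` (id vectors) and `counts`.
#' @export
apply_phylo_filter <- function(genotypes, clades, missing_as_error = FALSE) {
  inds <- colnames(genotypes)
  unmapped <- setdiff(inds, clades$individual)
  if (length(unmapped)) {
    stop("individual(s) missing from clade map: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  idsA <- clade_individuals(clades, "A"); idsA <- intersect(inds, idsA)
  idsB <- clade_individuals(clades, "B"); idsB <- intersect(inds, idsB)
  if (!length(idsA) || !length(idsB)) stop("both clades must be represented in the matrix", call. = FALSE)
  tolA <- clade_tolerance(clades, "A"); tolB <- clade_tolerance(clades, "B")

  gA <- genotypes[, idsA, drop = FALSE]
  gB <- genotypes[, idsB, drop = FALSE]
  missA <- is.na(gA); missB <- is.na(gB)

  # clade-A analysis: outgroup B homozygous reference up to tolB errors
  errB <- rowSums(gB != 0L, na.rm = TRUE) +
    if (missing_as_error) rowSums(missB) else 0L
  retained_A <- errB <= tolB

  # clade-B analysis: outgroup A fixed for either allele up to tolA errors
  nRef <- rowSums(gA == 0L, na.rm = TRUE)
  nAlt <- rowSums(gA == 2L, na.rm = TRUE)
  state <- ifelse(nAlt > nRef, 2L, 0L)
  nonmissA <- rowSums(!missA)
  errA <- nonmissA - ifelse(state == 2L, nAlt, nRef) +
    if (missing_as_error) rowSums(missA) else 0L
  retained_B <- errA <= tolA

  all_missing <- rowSums(!is.na(genotypes)) == 0L
  retained <- (retained_A | retained_B) & !all_missing
  clean <- (retained_A & errB == 0L) | (retained_B & errA == 0L)
  reason <- ifelse(all_missing, "all_missing",
                   ifelse(!retained, "cross_clade",
                          ifelse(clean, "clean", "within_tolerance")))
  verdicts <- data.frame(
    variant_id = rownames(genotypes),
    retained_A = retained_A & !all_missing,
    retained_B = retained_B & !all_missing,
    retained = retained,
    error_count_A = as.integer(errB),  # errors in outgroup B for clade-A set
    error_count_B = as.integer(errA),  # errors in outgroup A for clade-B set
    reason = reason, stringsAsFactors = FALSE)
  list(verdicts = verdicts,
       retained_A = verdicts$variant_id[verdicts$retained_A],
       retained_B = verdicts$variant_id[verdicts$retained_B],
       retained_union = verdicts$variant_id[verdicts$retained],
       counts = c(input = nrow(verdicts),
                  retained = sum(verdicts$retained),
                  excluded = sum(!verdicts$retained)))
}

#' Distance from a variant to the nearest chromosome end
#'
#' `min(pos, length - end)`, in bp; vectorized over records.
#'
#' @param records an [sv_records] table.
#' @param chrom_table a [chrom_table()] covering all record chromosomes.
#' @return numeric vector of distances (>= 0).
#' @export
distance_to_chrom_end <- function(records, chrom_table) {
  len <- chrom_table$length[match(records$chrom, chrom_table$chrom)]
  if (anyNA(len)) {
    stop("chromosome(s) absent from table: ",
         paste(unique(records$chrom[is.na(len)]), collapse = ", "), call. = FALSE)
  }
  if (any(records$end > len)) stop("record end exceeds chromosome length", call. = FALSE)
  pmin(records$pos, len - records$end)
}

#' Summarize retained/excluded variants by SV type and chromosome-end distance
#'
#' Excluded variants in real data are enriched for deletions and cluster near
#' repeat-dense chromosome ends; this table makes that pattern inspectable.
#' Distance bins are equal-width over the observed distance range.
#'
#' @param verdicts verdict data.frame from [apply_phylo_filter()].
#' @param records matching [sv_records].
#' @param chrom_table a [chrom_table()].
#' @param n_bins number of equal-width distance bins.
#' @return data.frame with columns `svtype`, `dist_bin` (integer 1..n_bins),
#'   `retained`, `excluded`.
#' @export
retention_summary <- function(verdicts, records, chrom_table, n_bins = 10L) {
  stopifnot(all(records$id %in% verdicts$variant_id))
  v <- verdicts[match(records$id, verdicts$variant_id), ]
  d <- distance_to_chrom_end(records, chrom_table)
  brk <- seq(0, max(d) + 1, length.out = n_bins + 1L)
  bin <- as.integer(cut(d, breaks = brk, include.lowest = TRUE, right = FALSE))
  agg <- expand.grid(svtype = sort(unique(records$svtype)),
                     dist_bin = seq_len(n_bins), stringsAsFactors = FALSE)
  agg$retained <- mapply(function(t, b) sum(records$svtype == t & bin == b & v$retained),
                         agg$svtype, agg$dist_bin)
  agg$excluded <- mapply(function(t, b) sum(records$svtype == t & bin == b & !v$retained),
                         agg$svtype, agg$dist_bin)
  agg
}
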