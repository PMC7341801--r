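# End-to-end pipeline driver: simulate -> merge -> phylo-filter -> annotate ->
# popgen -> date-ltr -> associate, with plain-file handoff between stages so
# each stage is independently inspectable and resumable.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every stage enabled and module
#' defaults: phylogenetic-filter tolerances 4 (larger outgroup) and 2, the
#' two-of-three 1-kb consensus merge preset, the 99th F_ST percentile, 1-Mb
#' windows and mu = 0.0158/site/Myr for LTR dating.
#'
#' @param out_dir output directory for all stage files.
#' @param seed global integer seed.
#' @return a nested configuration list.
#' @export
pipeline_config <- function(out_dir = tempfile("svclades_run_"), seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    stages = c("simulate", "merge", "phylo_filter", "annotate", "popgen",
               "date_ltr", "associate"),
    simulate = list(n_clade_A = 8L, n_clade_B = 24L, m_variants = 1000L,
                    fp_cross_clade_rate = 0.05, genotyping_error_rate = 0.01,
                    missing_rate = 0.02),
    merge = list(preset = "sr", n_callers = 3L, dropout = 0.1, jitter_sd = 100),
    phylo_filter = list(tolerance_A = 2L, tolerance_B = 4L, missing_as_error = FALSE),
    popgen = list(percentile = 99, window = 1000000L, n_components = 2L),
    date_ltr = list(age_myr = 0.5, ltr_len = 296L, mu = 0.0158),
    associate = list(beta_a = -1.5, beta_d = 0.5, noise_sd = 1.0)
  )
}

stage_log <- function(log, stage, n_in, n_out, files, t0) {
  entry <- list(stage = stage, n_in = n_in, n_out = n_out,
                files = as.list(files),
                wall_seconds = round(as.numeric(Sys.time()) - t0, 3))
  message(sprintf("[%s] in=%s out=%s files=%s", stage, n_in, n_out,
                  paste(basename(unlist(files)), collapse = ",")))
  c(log, stats::setNames(list(entry), stage))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes the enabled stages in dependency order, writing VCF/TSV/BED/YAML
#' outputs into `config$out_dir` and a JSON manifest of per-stage inputs,
#' outputs and record counts. Identical configuration and seed give
#' byte-identical text outputs.
#'
#' @param config configuration list from [pipeline_config()], or a path to a
#'   YAML file with the same structure.
#' @return the manifest (named list of stage entries), invisibly; also written
#'   to `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- pipeline_config()
  for (nm in names(base)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- base[[nm]]
    } else if (is.list(base[[nm]])) {
      for (sub in names(base[[nm]])) {
        if (is.null(config[[nm]][[sub]])) config[[nm]][[sub]] <- base[[nm]][[sub]]
      }
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$out_dir, ...)
  manifest <- list()
  stages <- config$stages
  seed <- as.integer(config$seed)

  cohort <- NULL
  if ("simulate" %in% stages) {
    t0 <- as.numeric(Sys.time())
    sp <- config$simulate
    params <- sim_params(n_clade_A = sp$n_clade_A, n_clade_B = sp$n_clade_B,
                         m_variants = sp$m_variants,
                         fp_cross_clade_rate = sp$fp_cross_clade_rate,
                         genotyping_error_rate = sp$genotyping_error_rate,
                         missing_rate = sp$missing_rate, seed = seed)
    cohort <- simulate_cohort(params)
    write_sv_vcf(cohort$records, cohort$genotypes, p("cohort.vcf"),
                 chrom_table = params$chrom_table)
    utils::write.table(cohort$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_repeat_table(cohort$repeats, p("repeats.tsv"))
    write_clade_map(cohort$clades, p("clades.yaml"))
    utils::write.table(params$chrom_table, p("chroms.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    manifest <- stage_log(manifest, "simulate", NA_integer_, nrow(cohort$records),
                          p(c("cohort.vcf", "truth.tsv", "repeats.tsv",
                              "clades.yaml", "chroms.tsv")), t0)
  }

  if ("merge" %in% stages) {
    t0 <- as.numeric(Sys.time())
    if (is.null(cohort)) stop("merge stage requires the simulate stage", call. = FALSE)
    mc <- config$merge
    sets <- simulate_caller_sets(cohort$records, n_callers = mc$n_callers,
                                 dropout = mc$dropout, jitter_sd = mc$jitter_sd,
                                 seed = seed)
    preset <- merge_preset(mc$preset)
    merged <- merge_call_sets(sets, max_dist = preset$max_dist,
                              require_type_match = preset$require_type_match,
                              min_callers = preset$min_callers,
                              min_size = preset$min_size)
    utils::write.table(merged, p("merged.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <- stage_log(manifest, "merge", sum(vapply(sets, nrow, 0L)),
                          nrow(merged), p("merged.tsv"), t0)
  }

  verdicts <- NULL; retained_ids <- NULL
  if ("phylo_filter" %in% stages) {
    t0 <- as.numeric(Sys.time())
    vcf <- read_sv_vcf(p("cohort.vcf"))
    clades <- read_clade_map(p("clades.yaml"))
    pfc <- config$phylo_filter
    if (!is.null(pfc$tolerance_A) || !is.null(pfc$tolerance_B)) {
      tol <- attr(clades, "tolerances")
      tol["A"] <- pfc$tolerance_A %||% tol["A"]
      tol["B"] <- pfc$tolerance_B %||% tol["B"]
      attr(clades, "tolerances") <- tol
    }
    pf <- apply_phylo_filter(vcf$genotypes, clades,
                             missing_as_error = isTRUE(config$phylo_filter$missing_as_error))
    verdicts <- pf$verdicts
    retained_ids <- pf$retained_union
    keep <- vcf$records$id %in% retained_ids
    write_sv_vcf(vcf$records[keep, ], vcf$genotypes[keep, , drop = FALSE],
                 p("retained.vcf"))
    utils::write.table(pf$verdicts, p("verdicts.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    chroms <- read_chrom_table(p("chroms.tsv"))
    utils::write.table(retention_summary(pf$verdicts, vcf$records, chroms),
                       p("retention_summary.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <- stage_log(manifest, "phylo_filter", nrow(vcf$records),
                          length(retained_ids),
                          p(c("retained.vcf", "verdicts.tsv", "retention_summary.tsv")), t0)
  }

  assignments <- NULL
  if ("annotate" %in% stages) {
    t0 <- as.numeric(Sys.time())
    matches <- read_repeat_table(p("repeats.tsv"))
    retained <- read_sv_vcf(p("retained.vcf"))
    assignments <- assign_best_repeat(matches, retained$records$id)
    utils::write.table(assignments, p("assignments.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(class_composition(assignments), p("composition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- stage_log(manifest, "annotate", nrow(matches), nrow(assignments),
                          p(c("assignments.tsv", "composition.tsv")), t0)
  }

  if ("popgen" %in% stages) {
    t0 <- as.numeric(Sys.time())
    retained <- read_sv_vcf(p("retained.vcf"))
    clades <- read_clade_map(p("clades.yaml"))
    chroms <- read_chrom_table(p("chroms.tsv"))
    pg <- config$popgen
    geno <- retained$genotypes
    classes <- if (!is.null(assignments)) {
      stats::setNames(assignments$repeat_class, assignments$variant_id)
    } else NULL
    idsB <- intersect(colnames(geno), clade_individuals(clades, "B"))
    afs <- folded_afs(geno[, idsB, drop = FALSE], classes = classes)
    utils::write.table(afs, p("afs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    pops <- stats::setNames(clades$population, clades$individual)
    fst <- fst_scan(geno[, idsB, drop = FALSE], pops)
    utils::write.table(fst, p("fst.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    out <- fst_outliers(fst, percentile = pg$percentile)
    rec_out <- retained$records[retained$records$id %in% out$outliers, , drop = FALSE]
    write_bed(data.frame(chrom = rec_out$chrom, start = rec_out$pos,
                         end = rec_out$end), p("fst_outliers.bed"))
    wd <- window_density(retained$records, chroms, window = pg$window)
    utils::write.table(wd, p("window_density.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    pca <- genotype_pca(geno, n_components = pg$n_components)
    utils::write.table(data.frame(individual = rownames(pca$scores),
                                  round(pca$scores, 6)),
                       p("pca.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- stage_log(manifest, "popgen", nrow(retained$records),
                          length(out$outliers),
                          p(c("afs.tsv", "fst.tsv", "fst_outliers.bed",
                              "window_density.tsv", "pca.tsv")), t0)
  }

  if ("date_ltr" %in% stages) {
    t0 <- as.numeric(Sys.time())
    dl <- config$date_ltr
    pair <- simulate_ltr_pair(dl$age_myr, ltr_len = dl$ltr_len, rate = dl$mu,
                              seed = seed)
    diffs <- count_ltr_differences(pair$left, pair$right)
    age <- estimate_insertion_age(diffs$k, diffs$L, mu = dl$mu)
    res <- data.frame(k = diffs$k, L = diffs$L, mu = dl$mu,
                      age_myr = age$age_myr, age_years = age$age_years)
    utils::write.table(res, p("ltr_age.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <- stage_log(manifest, "date_ltr", 1L, 1L, p("ltr_age.tsv"), t0)
  }

  if ("associate" %in% stages) {
    t0 <- as.numeric(Sys.time())
    ac <- config$associate
    retained <- read_sv_vcf(p("retained.vcf"))
    geno <- retained$genotypes
    # pick the retained variant with the most balanced genotype classes
    het <- rowSums(geno == 1L, na.rm = TRUE)
    cand <- which.max(het + pmin(rowSums(geno == 0L, na.rm = TRUE),
                                 rowSums(geno == 2L, na.rm = TRUE)))
    dos <- geno[cand, ]
    dos <- dos[!is.na(dos)]
    phen <- simulate_phenotypes(dos, beta_a = ac$beta_a, beta_d = ac$beta_d,
                                noise_sd = ac$noise_sd, seed = seed)
    vals <- stats::setNames(phen$phenotype, phen$individual)
    coded <- code_genotypes(dos)
    fit_add <- expression_association(vals, coded, include_dominance = FALSE)
    fit_full <- expression_association(vals, coded, include_dominance = TRUE)
    null_fit <- fit_linear_model(y ~ 1, data.frame(y = phen$phenotype))
    cmp <- compare_models(fit_add, null_fit)
    res <- data.frame(variant_id = rownames(geno)[cand], n = fit_add$n,
                      slope = fit_add$slope, p_value = fit_add$p_value,
                      aicc_additive = fit_add$AICc, aicc_full = fit_full$AICc,
                      delta_aicc_vs_null = cmp$delta_aicc,
                      selected_by_aicc = cmp$select_A_by_aicc)
    utils::write.table(res, p("association.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <- stage_log(manifest, "associate", length(dos), 1L,
                          p("association.tsv"), t0)
  }

  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
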