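# End-to-end orchestration: read -> QC -> score -> describe -> associate ->
# report, with a JSON run manifest for provenance.

#' Pipeline configuration
#'
#' @param genotypes Path to the genotype VCF.
#' @param weights Path to the scoring file.
#' @param phenotypes Path to the phenotype CSV.
#' @param out_dir Output directory (must differ from every input path).
#' @param thresholds A [qc_thresholds()] object.
#' @param seed Integer seed (plot jitter; recorded in the manifest).
#' @param stage_model,biomarker_models,extended_models,emm,plots Logical
#'   toggles for the analysis stages.
#' @param ambiguity_policy Passed to [align_effect_alleles()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes, weights, phenotypes, out_dir,
                            thresholds = qc_thresholds(), seed = 1L,
                            stage_model = TRUE, biomarker_models = TRUE,
                            extended_models = TRUE, emm = TRUE,
                            plots = TRUE,
                            ambiguity_policy = c("exclude", "keep")) {
  inputs <- c(genotypes, weights, phenotypes)
  if (normalizePath(out_dir, mustWork = FALSE) %in%
      vapply(inputs, normalizePath, "", mustWork = FALSE))
    stop("output directory must be distinct from the input paths")
  if (!inherits(thresholds, "qc_thresholds"))
    stop("thresholds must come from qc_thresholds()")
  structure(list(genotypes = genotypes, weights = weights,
                 phenotypes = phenotypes, out_dir = out_dir,
                 thresholds = thresholds, seed = as.integer(seed),
                 stage_model = stage_model,
                 biomarker_models = biomarker_models,
                 extended_models = extended_models, emm = emm,
                 plots = plots,
                 ambiguity_policy = match.arg(ambiguity_policy)),
            class = "pipeline_config")
}

#' Descriptive cohort table
#'
#' Per AMD stage and overall: sample count, age mean/SD/median/min/max,
#' sex counts with percentages, and (when scores are supplied) the mean and
#' SD of each score. Percentages are recomputed from the integer counts in
#' the same table and rounded to one decimal. For the intermediate-stage
#' subset, biomarker prevalences (count and percentage of non-missing
#' flags) are reported alongside. With a single sample the SD is reported
#' as missing, not zero.
#'
#' @param cohort A cohort table.
#' @param scores Optional `score_matrix`.
#' @return A list of class `cohort_description`: `stages` (one row per
#'   stage plus `overall`) and `biomarkers` (intermediate-stage
#'   prevalences).
#' @export
describe_cohort <- function(cohort, scores = NULL) {
  if (nrow(cohort) == 0) stop("empty cohort")
  groups <- c(as.list(setNames(STAGE_LEVELS, STAGE_LEVELS)),
              list(overall = STAGE_LEVELS))
  one <- function(stages, label) {
    d <- cohort[cohort$stage %in% stages, , drop = FALSE]
    n <- nrow(d)
    n_f <- sum(d$sex == "female")
    n_m <- sum(d$sex == "male")
    row <- data.frame(
      group = label, n = n,
      age_mean = if (n > 0) mean(d$age) else NA_real_,
      age_sd = if (n > 1) sd(d$age) else NA_real_,
      age_median = if (n > 0) median(d$age) else NA_real_,
      age_min = if (n > 0) min(d$age) else NA_real_,
      age_max = if (n > 0) max(d$age) else NA_real_,
      n_female = n_f, pct_female = if (n > 0) round(100 * n_f / n, 1)
        else NA_real_,
      n_male = n_m, pct_male = if (n > 0) round(100 * n_m / n, 1)
        else NA_real_)
    if (!is.null(scores)) {
      sc <- scores[match(d$sample_id, scores$sample_id), , drop = FALSE]
      for (nm in score_names()) {
        row[[paste0(nm, "_mean")]] <- if (n > 0) mean(sc[[nm]]) else NA_real_
        row[[paste0(nm, "_sd")]] <- if (n > 1) sd(sc[[nm]]) else NA_real_
      }
    }
    row
  }
  stage_tab <- do.call(rbind, Map(one, groups, names(groups)))
  rownames(stage_tab) <- NULL

  int <- cohort[cohort$stage == "intermediate", , drop = FALSE]
  bm <- do.call(rbind, lapply(BIOMARKERS, function(b) {
    flags <- int[[b]]
    n_tot <- sum(!is.na(flags))
    n_pres <- sum(flags, na.rm = TRUE)
    data.frame(biomarker = b, n_present = n_pres, n_assessed = n_tot,
               pct = if (n_tot > 0) round(100 * n_pres / n_tot, 1)
                 else NA_real_)
  }))
  structure(list(stages = stage_tab, biomarkers = bm),
            class = "cohort_description")
}

#' @method print cohort_description
#' @export
print.cohort_description <- function(x, ...) {
  cat("Cohort description (per stage and overall):\n")
  tab <- x$stages
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(v) round(v, 3))
  print(tab, row.names = FALSE)
  cat("\nBiomarker prevalence (intermediate stage):\n")
  print(x$biomarkers, row.names = FALSE)
  invisible(x)
}

write_description <- function(desc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  num <- vapply(desc$stages, is.numeric, TRUE)
  st <- desc$stages
  st[num] <- lapply(st[num], function(v) formatC(v, digits = 17,
                                                 format = "g"))
  writeLines("# stage summary", con)
  utils::write.table(st, con, sep = ",", quote = FALSE, row.names = FALSE)
  writeLines("# biomarker prevalence (intermediate stage)", con)
  utils::write.table(desc$biomarkers, con, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Reads the three inputs, applies variant QC, aligns and scores, writes
#' the descriptive table, fits the stage model with EMM contrasts, the
#' per-biomarker models for all six scores, and the extended
#' multi-biomarker models (variants A and B) for the global score, draws
#' the stage box plot, and records a JSON manifest (package version, seed,
#' thresholds, input checksums, QC counts). Every output is deterministic
#' for a fixed config.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  gm <- step("read_genotypes", read_genotypes(config$genotypes))
  wt <- step("read_weights", read_scoring_file(config$weights))
  cohort <- step("read_phenotypes", read_phenotypes(config$phenotypes))

  qc <- step("variant_qc", apply_variant_qc(gm, config$thresholds))
  utils::write.csv(qc$report, out("qc_report.csv"), row.names = FALSE,
                   quote = FALSE)
  counts <- qc_verdict_counts(qc$report)
  message("variant QC: ", paste(names(counts), as.integer(counts),
                                sep = "=", collapse = ", "))

  aligned <- step("scoring", impute_missing_dosage(
    align_effect_alleles(wt, qc$matrix, config$ambiguity_policy)))
  scores <- step("scoring", compute_all_scores(aligned))
  write_scores(scores, out("scores.csv"))

  desc <- describe_cohort(cohort, scores)
  write_description(desc, out("descriptive.csv"))

  results <- list(qc = qc, scores = scores, description = desc)
  if (config$stage_model) {
    fit <- step("stage_model", fit_stage_model(cohort, scores))
    write_results(fit, out("stage_model.csv"))
    results$stage_model <- fit
    if (config$emm) {
      con <- step("emm", emm_pairwise_contrasts(fit))
      utils::write.csv(format_num_df(con), out("emm_contrasts.csv"),
                       row.names = FALSE, quote = FALSE)
      results$emm <- con
    }
  }
  if (config$biomarker_models) {
    fits <- step("biomarker_models", fit_biomarker_models(cohort, scores))
    write_results(fits, out("biomarker_models.csv"))
    results$biomarker_models <- fits
  }
  if (config$extended_models) {
    ext <- step("extended_models", list(
      A = fit_extended_models(cohort, scores, include_atrophy = FALSE),
      B = tryCatch(fit_extended_models(cohort, scores,
                                       include_atrophy = TRUE),
                   error = function(e) {
                     warning("extended model B skipped: ",
                             conditionMessage(e))
                     NULL
                   })))
    ext <- Filter(Negate(is.null), ext)
    write_results(ext, out("extended_models.csv"))
    results$extended_models <- ext
  }
  if (config$plots)
    step("plot", plot_scores_by_stage(scores, cohort,
                                      out("prs_by_stage.png"),
                                      seed = config$seed))

  manifest <- list(
    package = "pathprs",
    version = as.character(utils::packageVersion("pathprs")),
    seed = config$seed,
    thresholds = unclass(config$thresholds),
    inputs = lapply(list(genotypes = config$genotypes,
                         weights = config$weights,
                         phenotypes = config$phenotypes),
                    function(p) list(path = p,
                                     md5 = unname(tools::md5sum(p)))),
    n_samples = length(gm$samples),
    n_variants_input = nrow(gm$variants),
    qc_counts = as.list(setNames(as.integer(counts), names(counts))),
    n_variants_scored = nrow(aligned$weights))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

format_num_df <- function(df) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 17,
                                                 format = "g"))
  df
}
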