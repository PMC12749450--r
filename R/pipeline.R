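#' Validate a pipeline run configuration
#'
#' When the pipeline starts from files rather than from the simulator,
#' every input path required by the requested stages must exist before any
#' stage runs (no partial outputs on a bad config).
#'
#' @param config Named list; see [run_pipeline()].
#' @param stages Character vector of requested stages.
#' @return `config`, invisibly, if valid.
#' @export
validate_run_config <- function(config, stages) {
  known <- c("simulate", "score", "calibrate", "assoc", "mortality",
             "heightloss")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!"simulate" %in% stages) {
    need <- c("weights_path", "dosages_path", "pheno_path")
    if ("mortality" %in% stages) need <- c(need, "survival_path")
    if ("heightloss" %in% stages) need <- c(need, "longitudinal_path")
    for (key in need) {
      path <- config[[key]]
      if (is.null(path) || !file.exists(path))
        stop("config requires readable ", key, " (got: ",
             if (is.null(path)) "NULL" else path, ")")
    }
  }
  invisible(config)
}

write_stage_csv <- function(df, dir, name, manifest) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  c(manifest, stats::setNames(unname(tools::md5sum(path)), name))
}

#' Run the full height-GaP pipeline on a synthetic cohort
#'
#' Executes the stages in dependency order (simulate, score, calibrate,
#' early-life associations, mortality, height-loss sensitivity), writes
#' every table as CSV under `out_dir`, and writes `manifest.json` listing
#' each output with its md5 checksum, the seed and row counts.  Inputs are
#' never mutated; all outputs go to `out_dir` only.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [sim_config()] (the `seed` field seeds the run) or a
#'   named list of input paths for file-based stages.
#' @param stages Stages to run; default is the full synthetic pipeline.
#' @return The manifest, invisibly (named list: files with checksums, seed,
#'   counts).
#' @export
run_pipeline <- function(out_dir, config = sim_config(seed = 1),
                         stages = c("simulate", "score", "calibrate",
                                    "assoc", "mortality", "heightloss")) {
  validate_run_config(config, stages)
  if (!inherits(config, "sim_config"))
    stop("file-based pipeline runs are driven by the analysis scripts; ",
         "run_pipeline() executes the synthetic end-to-end pipeline")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  counts <- list()

  cohort <- simulate_cohort(config)
  utils::write.table(cohort$genotypes$weights,
                     file.path(out_dir, "weights.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, stats::setNames(
    unname(tools::md5sum(file.path(out_dir, "weights.tsv"))), "weights.tsv"))
  write_dosage_table(cohort$genotypes$dosages,
                     file.path(out_dir, "dosages.tsv"))
  files <- c(files, stats::setNames(
    unname(tools::md5sum(file.path(out_dir, "dosages.tsv"))), "dosages.tsv"))
  files <- write_stage_csv(cohort$pheno, out_dir, "pheno.csv", files)
  counts$n_samples <- nrow(cohort$pheno)

  files <- write_stage_csv(cohort$scores, out_dir, "scores.csv", files)
  files <- write_stage_csv(as.data.frame(cohort$calibration), out_dir,
                           "calibration.csv", files)
  gap_df <- as.data.frame(cohort$gap)
  gap_df$gap_sd <- gap_sd(cohort$gap)
  files <- write_stage_csv(gap_df, out_dir, "gap.csv", files)

  if ("assoc" %in% stages && !is.null(config$exposure_effects)) {
    adf <- cbind(cohort$pheno,
                 gap = cohort$gap$gap,
                 predicted_height = cohort$gap$predicted_height)
    specs <- list(
      exposure_spec("birthweight_kg", "continuous", "per_unit_decrement"),
      exposure_spec("deprivation_quintile", "ordinal", "quantile"),
      exposure_spec("breastfeeding_months", "categorical",
                    "category_vs_reference", reference = "6+",
                    comparison = "0"))
    assoc <- do.call(rbind, lapply(specs, function(sp)
      report_contrast(fit_exposure_models(adf, sp))))
    files <- write_stage_csv(assoc, out_dir, "assoc.csv", files)
    counts$n_exposures <- nrow(assoc)
  }

  if ("mortality" %in% stages) {
    z <- per_sd_deficit(cohort$gap)
    covars <- data.frame(age = cohort$pheno$age,
                         sex = cohort$pheno$sex,
                         cohort$pheno[paste0("PC", 1:5)],
                         predicted_height = cohort$gap$predicted_height)
    hr <- fit_cox(cohort$survival, z, covars)
    q <- sex_quartiles(cohort$gap$gap, cohort$pheno$sex)
    qc <- quartile_contrast(cohort$survival, q, covars)
    km <- km_by_quartile(cohort$survival, q)
    files <- write_stage_csv(rbind(cbind(model = "per_sd_model2", hr),
                                   cbind(model = "quartiles_model2", qc)),
                             out_dir, "hr.csv", files)
    files <- write_stage_csv(km$curves, out_dir, "km.csv", files)
    counts$n_events <- sum(cohort$survival$event)
  }

  if ("heightloss" %in% stages) {
    ch <- annualized_change(cohort$longitudinal, verbose = FALSE)
    files <- write_stage_csv(ch, out_dir, "annualized_change.csv", files)
    counts$n_longitudinal <- nrow(ch)
  }

  manifest <- list(seed = config$seed,
                   package_version =
                     as.character(utils::packageVersion("heightgap")),
                   stages = stages, counts = counts,
                   files = as.list(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
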