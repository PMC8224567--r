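#' Pipeline settings
#'
#' Numeric and model settings of the quantification pipeline in one place:
#' the GAG evaluation band, the B0 search configuration, the segmentation
#' knobs, the mixed-model formula and the subject used to train the
#' segmentation classifier.
#'
#' @param band GAG evaluation band (ppm).
#' @param mscf An `mscf_config`.
#' @param np_percentile NP/AF split depth percentile.
#' @param min_component Minimum connected-component size (voxels).
#' @param lmm_formula Mixed-model formula or NULL for the default of
#'   [fit_lmm()].
#' @param train_subject Index of the subject whose truth labels train the
#'   naive Bayes classifier.
#' @param correction_age Age (years) for corrected marginal means.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(band = gag_band(), mscf = mscf_config(),
                            np_percentile = 0.5, min_component = 6L,
                            lmm_formula = NULL, train_subject = 1L,
                            correction_age = 23.1) {
  structure(list(band = band, mscf = mscf, np_percentile = np_percentile,
                 min_component = min_component, lmm_formula = lmm_formula,
                 train_subject = as.integer(train_subject),
                 correction_age = correction_age),
            class = "pipeline_config")
}

# internal: train the disc/bone/background classifier from one subject's
# rendered stacks and truth labels
train_segmenter <- function(subject) {
  lab <- subject$phantom$labels
  cls <- ifelse(lab == 0L, "background", ifelse(lab == 1L, "bone", "disc"))
  train_nb(nb_features(subject$s0, subject$cest), as.vector(cls))
}

# internal: quantify one rendered subject -> b0 map, gag map, roi set
quantify_subject <- function(subject, model, cfg) {
  roiset <- segment_discs(subject$s0, subject$cest, model,
                          min_component = cfg$min_component,
                          np_percentile = cfg$np_percentile)
  mask <- matrix(FALSE, nrow(subject$s0), ncol(subject$s0))
  for (d in roiset$discs) mask[d$voxels] <- TRUE
  b0 <- compute_b0_map(subject$wassr, subject$s0, mask,
                       offsets = subject$wassr_offsets, cfg = cfg$mscf)
  gag <- mtrasym_map(subject$cest, subject$s0, b0, mask,
                     offsets = subject$cest_offsets, band = cfg$band)
  list(roiset = roiset, b0 = b0, gag = gag)
}

#' Run the full quantification and analysis pipeline on a simulated cohort
#'
#' End-to-end chain per subject: naive Bayes disc segmentation (classifier
#' trained on one designated subject's truth labels), WASSR maximum-symmetry
#' B0 mapping over the disc voxels, B0-corrected gag-score mapping over the
#' GAG band, ROI averaging into disc x region records; then the cohort
#' linear mixed model with age-corrected marginal means. Deterministic given
#' the cohort (no randomness in quantification). Stage failures halt with the
#' stage name and subject id.
#'
#' @param cohort A rendered `gag_cohort`.
#' @param config A `pipeline_config`.
#' @param out_dir Optional directory; when given, per-subject B0 and gag maps
#'   (NIfTI), the records CSV, the model reports and a provenance JSON are
#'   written there.
#' @param fit_model Fit the mixed model (TRUE); set FALSE to stop after
#'   record extraction (e.g. single-subject studies).
#' @return List of class `gag_report`: `records`, per-subject `maps` (b0,
#'   gag) and `roisets`, the `lmm` fit, `cohort_means` (age-corrected),
#'   `reports` (cohort x segment and affection tables) and `provenance`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL,
                         fit_model = TRUE) {
  stopifnot(inherits(cohort, "gag_cohort"), inherits(config, "pipeline_config"))
  if (!cohort$rendered) abort("cohort must be rendered to run the pipeline")
  ids <- names(cohort$subjects)

  model <- tryCatch(
    train_segmenter(cohort$subjects[[config$train_subject]]),
    error = function(e) abort("stage 'train' failed for %s: %s",
                              ids[config$train_subject], conditionMessage(e)))

  maps <- roisets <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    q <- tryCatch(quantify_subject(cohort$subjects[[id]], model, config),
                  error = function(e) abort("stage 'quantify' failed for %s: %s",
                                            id, conditionMessage(e)))
    maps[[id]] <- list(b0 = q$b0, gag = q$gag)
    roisets[[id]] <- q$roiset
  }

  records <- summarize_discs(lapply(maps, `[[`, "gag"), roisets,
                             cohort$metadata, truth = cohort$truth)

  lmm <- cohort_means <- reports <- NULL
  if (fit_model) {
    lmm <- tryCatch(fit_lmm(records, formula = config$lmm_formula),
                    error = function(e) abort("stage 'lmm' failed: %s",
                                              conditionMessage(e)))
    cohort_means <- corrected_means(lmm, ~cohort, age = config$correction_age)
    reports <- list(
      cohort_segment = cohort_segment_report(lmm, age = config$correction_age),
      affection = tryCatch(affection_report(records,
                                            age = config$correction_age),
                           error = function(e) NULL))
  }

  provenance <- list(
    package = "gagcest",
    version = as.character(utils::packageVersion("gagcest")),
    config_hash = fnv1a(config),
    design_seed = cohort$design$seed,
    n_subjects = length(ids),
    n_records = nrow(records))

  report <- structure(list(records = records, maps = maps, roisets = roisets,
                           lmm = lmm, cohort_means = cohort_means,
                           reports = reports, provenance = provenance,
                           config = config),
                      class = "gag_report")
  if (!is.null(out_dir)) write_report(report, cohort, out_dir)
  report
}

#' @exportS3Method base::print
print.gag_report <- function(x, ...) {
  cat(sprintf("<gag_report> %d records from %d subjects\n",
              nrow(x$records), length(x$roisets)))
  if (!is.null(x$cohort_means)) {
    cat("age-corrected cohort means:\n")
    print(x$cohort_means$means)
  }
  invisible(x)
}

# internal: write the report bundle to disk
write_report <- function(report, cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$records, file.path(out_dir, "disc_records.csv"),
                   row.names = FALSE)
  for (id in names(report$maps)) {
    sd <- file.path(out_dir, "maps", id)
    dir.create(sd, recursive = TRUE, showWarnings = FALSE)
    px <- cohort$subjects[[id]]$phantom$pixel_mm
    write_map(report$maps[[id]]$b0, file.path(sd, "b0.nii"), units = "ppm",
              pixel_mm = px)
    write_map(report$maps[[id]]$gag, file.path(sd, "gagcest.nii"),
              units = "percent", pixel_mm = px,
              extra = list(band_ppm = report$config$band))
  }
  if (!is.null(report$lmm)) {
    jsonlite::write_json(list(
      cohort_means = report$cohort_means$means,
      contrasts = report$cohort_means$contrasts,
      var_subject = report$lmm$var_subject,
      var_residual = report$lmm$var_residual,
      method = report$lmm$method, df = report$lmm$df_method),
      file.path(out_dir, "lmm_results.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE, dataframe = "rows")
    utils::write.csv(report$reports$cohort_segment$table,
                     file.path(out_dir, "cohort_segment_table.csv"),
                     row.names = FALSE)
    if (!is.null(report$reports$affection))
      utils::write.csv(report$reports$affection$table,
                       file.path(out_dir, "affection_table.csv"),
                       row.names = FALSE)
  }
  jsonlite::write_json(report$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
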