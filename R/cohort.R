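#' Two-cohort study design for the synthetic generator
#'
#' Defines the generative conditions of a simulated gagCEST study: cohort
#' sizes (default 16 controls, 10 scoliosis patients, i.e. 130 lumbar discs),
#' generative mean gag scores, between-subject and residual variation, age
#' and gender distributions, Pfirrmann-grade frequencies, Cobb-angle
#' distribution and the per-patient stable-vertebra levels.
#'
#' Generative region means are parameterised as cohort mean +/- half the
#' NP-AF difference, so the cohort marginal (averaged over the two regions)
#' equals `mean_control` / `mean_ais` exactly and the NP-AF gap equals
#' `np_af_diff`. True scores carry no age, gender or Pfirrmann effect, so
#' age-corrected cohort means in truth equal the generative cohort means.
#'
#' @param n_controls,n_patients Cohort sizes (>= 1).
#' @param mean_control,mean_ais Generative cohort mean gag scores (%).
#' @param np_af_diff Generative NP minus AF difference (%).
#' @param sd_subject Between-subject SD of the random intercept (%).
#' @param sd_residual Residual SD per disc x region observation (%).
#' @param age_control,age_ais c(mean, sd) of age (years) per cohort.
#' @param p_female Named vector of female probabilities per cohort.
#' @param p_pfirrmann3 Named vector of per-disc probabilities of grade 3
#'   (other discs are grade 2, the dominant grade in young spines).
#' @param cobb_mean,cobb_sd,cobb_range Major-curve Cobb angle distribution
#'   (degrees), truncated to `cobb_range`.
#' @param stable_vertebrae Optional character vector (one per patient);
#'   default [default_stable_vertebrae()].
#' @param seed Top-level integer seed; all randomness derives from it via
#'   [split_seed()].
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_controls = 16L, n_patients = 10L,
                          mean_control = 3.51, mean_ais = 2.76,
                          np_af_diff = 1.53,
                          sd_subject = 0.6, sd_residual = 0.5,
                          age_control = c(25.5, 1.7),
                          age_ais = c(18.3, 8.2),
                          p_female = c(control = 0.5, AIS = 0.6),
                          p_pfirrmann3 = c(control = 1 / 80, AIS = 2 / 50),
                          cobb_mean = 34.8, cobb_sd = 21.5,
                          cobb_range = c(11, 73),
                          stable_vertebrae = NULL,
                          seed = 1L) {
  if (n_controls < 1 || n_patients < 1) abort("cohort sizes must be >= 1")
  if (sd_subject < 0 || sd_residual < 0) abort("SDs must be >= 0")
  if (is.null(stable_vertebrae))
    stable_vertebrae <- default_stable_vertebrae(n_patients,
                                                 split_seed(seed, 63L))
  if (length(stable_vertebrae) != n_patients)
    abort("need one stable vertebra per patient")
  if (any(vertebra_index(stable_vertebrae) > 5L))
    abort("stable vertebrae must be lumbar (L1..L5)")
  structure(list(
    n_controls = as.integer(n_controls), n_patients = as.integer(n_patients),
    region_means = list(
      control = c(NP = mean_control + np_af_diff / 2,
                  AF = mean_control - np_af_diff / 2),
      AIS = c(NP = mean_ais + np_af_diff / 2,
              AF = mean_ais - np_af_diff / 2)),
    sd_subject = sd_subject, sd_residual = sd_residual,
    age = list(control = age_control, AIS = age_ais),
    p_female = p_female, p_pfirrmann3 = p_pfirrmann3,
    cobb_mean = cobb_mean, cobb_sd = cobb_sd, cobb_range = cobb_range,
    stable_vertebrae = stable_vertebrae,
    seed = as.integer(seed)
  ), class = "cohort_design")
}

# internal: truncated normal by resampling (fine for mild truncation)
rtruncnorm1 <- function(mean, sd, lo = -Inf, hi = Inf) {
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(hi, max(lo, mean))
}

# internal: synthetic endplate landmark pairs realising a given Cobb angle
cobb_landmarks <- function(angle_deg) {
  half <- angle_deg / 2 * pi / 180
  list(superior = rbind(c(0, 0), c(40, 40 * tan(half))),
       inferior = rbind(c(0, 0), c(40, -40 * tan(half))))
}

#' Simulate a two-cohort gagCEST study with known ground truth
#'
#' Draws, per subject, age, gender, a subject-level random intercept and per
#' disc x region residuals around the generative region means; assigns
#' Pfirrmann grades, stable vertebrae, Cobb angles and endplate landmarks
#' (patients); and, when `render = TRUE`, builds a spine phantom whose
#' regions are calibrated to the drawn true scores, a fresh smooth B0 field,
#' and CEST/WASSR/S0 acquisitions. Drawn scores below 0 are truncated at 0
#' and logged; scores above the amplitude-feasibility bound of the pool model
#' are truncated there and logged (both rare under the defaults).
#'
#' @param design A `cohort_design`.
#' @param render Render image stacks (TRUE) or produce only the truth table
#'   and metadata (FALSE; fast path for statistical studies).
#' @param geometry Phantom geometry for rendering.
#' @param noise_sd Acquisition noise SD on the normalized signal.
#' @param b0_amplitude Maximum |delta-B0| of each subject's field (ppm).
#' @param b0_smoothness_mm B0 field smoothness length scale (mm).
#' @return An object of class `gag_cohort`: `design`, `truth` (one row per
#'   disc x region: subject, cohort, age, gender, segment, region, Pfirrmann
#'   grade, stable vertebra, affection, true gag score), `metadata` (one row
#'   per subject) and `subjects` (rendered stacks and landmarks when
#'   `render = TRUE`).
#' @export
simulate_cohort <- function(design, render = TRUE,
                            geometry = spine_geometry(),
                            noise_sd = 0.01, b0_amplitude = 0.3,
                            b0_smoothness_mm = 60) {
  stopifnot(inherits(design, "cohort_design"))
  n_sub <- design$n_controls + design$n_patients
  cohorts <- rep(c("control", "AIS"), c(design$n_controls, design$n_patients))
  ids <- sprintf("sub-%02d", seq_len(n_sub))
  feas_max <- max_feasible_score()

  truth <- vector("list", n_sub)
  meta <- vector("list", n_sub)
  subjects <- vector("list", n_sub)
  names(subjects) <- ids
  n_trunc_lo <- n_trunc_hi <- 0L

  patient_idx <- 0L
  for (i in seq_len(n_sub)) {
    co <- cohorts[i]
    old <- .Random.seed_exists()
    set.seed(split_seed(design$seed, i))
    age <- rtruncnorm1(design$age[[co]][1], design$age[[co]][2], lo = 10)
    gender <- if (stats::runif(1) < design$p_female[[co]]) "female" else "male"
    b_subj <- stats::rnorm(1, 0, design$sd_subject)
    grades <- ifelse(stats::runif(5) < design$p_pfirrmann3[[co]], 3L, 2L)
    scores <- matrix(NA_real_, 5, 2, dimnames = list(NULL, c("NP", "AF")))
    for (r in c("NP", "AF")) {
      mu <- design$region_means[[co]][[r]] + b_subj
      scores[, r] <- stats::rnorm(5, mu, design$sd_residual)
    }
    n_trunc_lo <- n_trunc_lo + sum(scores < 0)
    n_trunc_hi <- n_trunc_hi + sum(scores > feas_max)
    scores[scores < 0] <- 0
    scores[scores > feas_max] <- feas_max

    if (co == "AIS") {
      patient_idx <- patient_idx + 1L
      sv <- design$stable_vertebrae[patient_idx]
      affect <- classify_affection(disc_segments(), rep(sv, 5))
      cobb <- rtruncnorm1(design$cobb_mean, design$cobb_sd,
                          design$cobb_range[1], design$cobb_range[2])
      lmk <- cobb_landmarks(cobb)
    } else {
      sv <- NA_character_; affect <- rep(NA_character_, 5)
      cobb <- NA_real_; lmk <- NULL
    }

    truth[[i]] <- data.frame(
      subject = ids[i], cohort = co, age = age, gender = gender,
      segment = rep(disc_segments(), times = 2),
      region = rep(c("NP", "AF"), each = 5),
      pfirrmann = rep(grades, times = 2),
      stable_vertebra = sv,
      affection = rep(affect, times = 2),
      gag_true = c(scores[, "NP"], scores[, "AF"]),
      stringsAsFactors = FALSE
    )
    meta[[i]] <- data.frame(
      subject = ids[i], cohort = co, age = age, gender = gender,
      stable_vertebra = sv, cobb_major = cobb, stringsAsFactors = FALSE)

    if (render) {
      phantom <- make_spine_phantom(
        geometry, seed = split_seed(design$seed, 1000L + i),
        np_gag = scores[, "NP"], af_gag = scores[, "AF"])
      b0 <- make_b0_field(dim(phantom$labels), amplitude = b0_amplitude,
                          smoothness_mm = b0_smoothness_mm,
                          pixel_mm = phantom$pixel_mm,
                          seed = split_seed(design$seed, 2000L + i))
      acq <- render_subject(phantom, b0, noise_sd = noise_sd,
                            seed = split_seed(design$seed, 3000L + i))
      acq$landmarks <- lmk
      acq$id <- ids[i]
      subjects[[i]] <- acq
    } else {
      subjects[[i]] <- list(id = ids[i], landmarks = lmk)
    }
    restore_rng(old)
  }

  if (n_trunc_lo > 0)
    log_msg("simulate_cohort: %d drawn score(s) < 0 truncated at 0", n_trunc_lo)
  if (n_trunc_hi > 0)
    log_msg("simulate_cohort: %d drawn score(s) above the feasibility bound %.2f%% truncated",
            n_trunc_hi, feas_max)

  structure(list(design = design,
                 truth = do.call(rbind, truth),
                 metadata = do.call(rbind, meta),
                 subjects = subjects,
                 rendered = render),
            class = "gag_cohort")
}

#' @exportS3Method base::print
print.gag_cohort <- function(x, ...) {
  cat(sprintf("<gag_cohort> %d controls + %d patients (%d disc x region truth rows)%s\n",
              x$design$n_controls, x$design$n_patients, nrow(x$truth),
              if (x$rendered) ", rendered" else ", truth only"))
  invisible(x)
}

#' Draw disc-level records directly from a cohort design
#'
#' Statistical fast path: the truth table of [simulate_cohort()] with
#' `render = FALSE`, returned in the column layout of [summarize_discs()]
#' (column `gag` instead of `gag_true`). Used for mixed-model calibration
#' studies where the imaging chain is not under test.
#'
#' @param design A `cohort_design`.
#' @return Data frame of disc x region records.
#' @export
simulate_disc_records <- function(design) {
  co <- simulate_cohort(design, render = FALSE)
  rec <- co$truth
  names(rec)[names(rec) == "gag_true"] <- "gag"
  rec
}
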