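# Shared fixtures, built once per test run. Small 96-pixel grids keep unit
# tests fast; acceptance tests use the default acquisition geometry.

options(gagcest.quiet = TRUE)

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

small_geometry <- function() spine_geometry(96)

# one rendered subject on the small grid: default gag truth, B0 field, noise
small_subject <- function() {
  fixture("small_subject", function() {
    ph <- make_spine_phantom(small_geometry(), seed = 11)
    b0 <- make_b0_field(dim(ph$labels), amplitude = 0.3, smoothness_mm = 60,
                        pixel_mm = ph$pixel_mm, seed = 12)
    render_subject(ph, b0, noise_sd = 0.01, seed = 13)
  })
}

# noiseless, B0-free rendering of the same phantom
small_subject_clean <- function() {
  fixture("small_subject_clean", function() {
    ph <- make_spine_phantom(small_geometry(), seed = 11)
    render_subject(ph, b0 = NULL, noise_sd = 0, seed = 13)
  })
}

# naive Bayes segmenter trained on the small subject's truth labels
small_model <- function() {
  fixture("small_model", function() {
    acq <- small_subject()
    lab <- acq$phantom$labels
    cls <- ifelse(lab == 0L, "background", ifelse(lab == 1L, "bone", "disc"))
    train_nb(nb_features(acq$s0, acq$cest), as.vector(cls))
  })
}

# small rendered cohort (3 controls + 2 patients) for pipeline-level tests
small_cohort <- function() {
  fixture("small_cohort", function() {
    simulate_cohort(cohort_design(n_controls = 3, n_patients = 2, seed = 7,
                                  stable_vertebrae = c("L3", "L5")),
                    geometry = small_geometry())
  })
}

# ROI-averaged z-spectrum of one phantom label from a rendered subject
roi_spectrum <- function(acq, label) {
  idx <- which(acq$phantom$labels == label)
  sig <- colMeans(matrix(acq$cest, length(acq$phantom$labels),
                         length(acq$cest_offsets))[idx, , drop = FALSE])
  zs_normalize(sig, mean(acq$s0[idx]), acq$cest_offsets)
}
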