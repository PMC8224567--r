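test_that("spine phantoms have five NP-in-AF discs and are reproducible", {
  ph <- make_spine_phantom(spine_geometry(188), seed = 1)
  np_labels <- 10 + 1:5
  af_labels <- 20 + 1:5
  expect_true(all(np_labels %in% ph$labels))
  expect_true(all(af_labels %in% ph$labels))

  ph2 <- make_spine_phantom(spine_geometry(188), seed = 1)
  expect_identical(ph$labels, ph2$labels)
  ph3 <- make_spine_phantom(spine_geometry(188), seed = 2)
  expect_false(identical(ph$labels, ph3$labels))

  # each NP core is strictly enclosed: its 4-neighbourhood stays in NP u AF
  n <- nrow(ph$labels)
  for (s in 1:5) {
    np <- which(ph$labels == 10 + s)
    disc <- c(np, which(ph$labels == 20 + s))
    nb <- c(np - 1, np + 1, np - n, np + n)
    expect_true(all(nb %in% disc))
    expect_lt(length(np), length(disc))  # NP area < whole-disc area
  }
})

test_that("small grids still carry five discs; infeasible grids are rejected", {
  ph <- make_spine_phantom(spine_geometry(64), seed = 3)
  for (s in 1:5) {
    np_area <- sum(ph$labels == 10 + s)
    disc_area <- np_area + sum(ph$labels == 20 + s)
    expect_gte(np_area, 3)
    expect_lt(np_area, disc_area)
  }
  expect_error(spine_geometry(40), ">= 64")
})

test_that("phantom truth amplitudes reproduce the requested gag scores", {
  ph <- make_spine_phantom(spine_geometry(96), np_gag = c(4, 3.5, 3, 2.5, 2),
                           af_gag = 1.5)
  for (r in seq_len(nrow(ph$truth))) {
    p <- pool_set(c(0, 1), c(1.2, 0.5), c(0.85, ph$truth$amplitude[r]))
    expect_equal(analytic_mtrasym(p), ph$truth$gag[r], tolerance = 1e-10)
  }
  expect_error(make_spine_phantom(spine_geometry(96), np_gag = -1), ">= 0")
})

test_that("B0 fields are smooth, bounded, seeded and zero at zero amplitude", {
  f0 <- make_b0_field(c(96, 96), amplitude = 0)
  expect_true(all(f0 == 0))

  f <- make_b0_field(c(96, 96), amplitude = 0.3, seed = 5)
  expect_lte(max(abs(f)), 0.3)
  expect_identical(f, make_b0_field(c(96, 96), amplitude = 0.3, seed = 5))
  expect_false(identical(f, make_b0_field(c(96, 96), amplitude = 0.3, seed = 6)))
  # smoothness: neighbouring pixels differ far less than the amplitude
  expect_lt(max(abs(diff(f))), 0.03)
  expect_error(make_b0_field(c(96, 96), amplitude = -0.1), ">= 0")
})

test_that("rendered stacks are reproducible and normalized signals stay physical", {
  acq <- small_subject()
  acq2 <- render_subject(acq$phantom, acq$b0, noise_sd = 0.01, seed = 13)
  expect_identical(acq$cest, acq2$cest)
  lab <- acq$phantom$labels
  idx <- which(lab > 9)
  zmat <- matrix(acq$cest, length(lab), length(acq$cest_offsets))[idx, ] /
    acq$s0[idx]
  expect_true(all(zmat > 0 & zmat < 1 + 5 * acq$noise_sd))
})

test_that("cohort generator reproduces the two-cohort design counts", {
  co <- simulate_cohort(cohort_design(16, 10, seed = 3), render = FALSE)
  discs <- unique(co$truth[, c("subject", "cohort", "segment")])
  expect_equal(nrow(discs), 130)
  expect_equal(sum(discs$cohort == "control"), 80)
  expect_equal(sum(discs$cohort == "AIS"), 50)
  expect_equal(nrow(co$truth), 260)  # NP and AF record per disc
  # reproducibility from the single top-level seed
  co2 <- simulate_cohort(cohort_design(16, 10, seed = 3), render = FALSE)
  expect_identical(co$truth, co2$truth)
})

test_that("degenerate design with zero variances hits the generative means exactly", {
  d <- cohort_design(2, 2, sd_subject = 0, sd_residual = 0, seed = 1)
  co <- simulate_cohort(d, render = FALSE)
  ctrl_np <- co$truth$gag_true[co$truth$cohort == "control" &
                               co$truth$region == "NP"]
  expect_true(all(ctrl_np == d$region_means$control[["NP"]]))
})

test_that("cohort truth means converge to the generative means at large n", {
  d <- cohort_design(50, 50, seed = 21)
  co <- simulate_cohort(d, render = FALSE)
  for (coh in c("control", "AIS")) {
    for (reg in c("NP", "AF")) {
      v <- co$truth$gag_true[co$truth$cohort == coh & co$truth$region == reg]
      gen <- d$region_means[[coh]][[reg]]
      se <- sqrt(d$sd_subject^2 / 50 + d$sd_residual^2 / length(v))
      expect_lt(abs(mean(v) - gen), 3 * se)
    }
  }
})
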