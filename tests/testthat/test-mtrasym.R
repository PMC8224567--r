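test_that("asymmetry of a symmetric spectrum is zero; direct differences are exact", {
  offs <- seq(-3, 3, 0.2)
  zsym <- simulate_zspectrum(pool_set(0, 1.2, 0.8), offs, noise_sd = 0)
  expect_lt(max(abs(mtrasym_curve(zsym))), 1e-12)
  expect_equal(gag_score(zsym), 0, tolerance = 1e-10)

  # hand-built spectrum with Z(-1.4) = 0.95, Z(1.4) = 0.90
  sig <- rep(0.9, length(offs))
  sig[offs == -1.4] <- 0.95
  z <- zspectrum(offs, sig)
  expect_equal(mtrasym_curve(z, 0, delta = 1.4), 0.05)
})

test_that("B0-corrected curve matches the analytic pool asymmetry pointwise", {
  offs <- cest_offsets()
  pools <- default_pools(gag_amplitude = 0.095)
  z <- simulate_zspectrum(pools, offs, db0 = 0.2, noise_sd = 0)
  curve <- mtrasym_curve(z, db0 = 0.2)
  band <- gag_band()
  truth <- 0.095 * (lorentzian(band, 1, 0.5) - lorentzian(-band, 1, 0.5))
  expect_lt(max(abs(curve - truth)), 5e-4)
})

test_that("gag score is linear in the GAG amplitude and scale-invariant", {
  offs <- cest_offsets()
  z1 <- simulate_zspectrum(default_pools(0.04), offs, noise_sd = 0)
  z2 <- simulate_zspectrum(default_pools(0.08), offs, noise_sd = 0)
  expect_equal(gag_score(z2), 2 * gag_score(z1), tolerance = 1e-6)

  raw <- z1$signals * 2.4
  expect_equal(gag_score(zs_normalize(raw, 2.4, offs)), gag_score(z1),
               tolerance = 1e-12)
})

test_that("mirroring a spectrum about zero negates the gag score", {
  offs <- cest_offsets()
  z <- simulate_zspectrum(default_pools(0.06), offs, db0 = 0.1, noise_sd = 0.005,
                          seed = 44)
  mirrored <- zspectrum(offs, rev(z$signals))
  expect_equal(gag_score(mirrored, db0 = -0.1), -gag_score(z, db0 = 0.1),
               tolerance = 1e-9)
})

test_that("band outside the sampled range fails loudly", {
  z <- simulate_zspectrum(default_pools(0.05), seq(-2, 2, 0.2), noise_sd = 0)
  expect_error(gag_score(z, db0 = 0.5), "wider offset range")
  expect_error(mtrasym_curve(z, 0, delta = numeric(0)), "empty")
})

test_that("gag maps recover region truth on a noiseless phantom and are ~0 without GAG", {
  acq <- small_subject_clean()
  lab <- acq$phantom$labels
  mask <- lab > 9
  b0 <- matrix(0, nrow(lab), ncol(lab))
  map <- mtrasym_map(acq$cest, acq$s0, b0, mask, acq$cest_offsets)
  for (r in seq_len(nrow(acq$phantom$truth))) {
    roi <- lab == acq$phantom$truth$label[r]
    expect_lt(abs(mean(map[roi]) - acq$phantom$truth$gag[r]), 0.05)
  }

  ph0 <- make_spine_phantom(small_geometry(), seed = 11, np_gag = 0, af_gag = 0)
  acq0 <- render_subject(ph0, b0 = NULL, noise_sd = 0, seed = 1)
  map0 <- mtrasym_map(acq0$cest, acq0$s0, b0, ph0$labels > 9, acq0$cest_offsets)
  expect_lt(max(abs(map0), na.rm = TRUE), 0.05)
})

test_that("B0 correction brings every disc region closer to truth than no correction", {
  # field with |dB0| >= 0.1 ppm everywhere, so leaving it uncorrected must
  # visibly bias every region (a near-zero local field would make the
  # comparison a coin flip)
  ph <- make_spine_phantom(small_geometry(), seed = 11)
  b0 <- 0.2 + make_b0_field(dim(ph$labels), amplitude = 0.1,
                            smoothness_mm = 60, pixel_mm = ph$pixel_mm,
                            seed = 55)
  acq <- render_subject(ph, b0, noise_sd = 0.01, seed = 56)
  lab <- acq$phantom$labels
  mask <- lab > 9
  b0_est <- compute_b0_map(acq$wassr, acq$s0, mask, acq$wassr_offsets)
  map_on <- mtrasym_map(acq$cest, acq$s0, b0_est, mask, acq$cest_offsets)
  map_off <- mtrasym_map(acq$cest, acq$s0, 0 * b0_est, mask, acq$cest_offsets)
  for (r in seq_len(nrow(acq$phantom$truth))) {
    roi <- lab == acq$phantom$truth$label[r]
    tr <- acq$phantom$truth$gag[r]
    expect_lt(abs(mean(map_on[roi], na.rm = TRUE) - tr),
              abs(mean(map_off[roi], na.rm = TRUE) - tr))
  }
})

test_that("ROI-level recovery is unbiased over many simulated discs", {
  # 120 disc-level acquisitions: random B0 within +/-0.3 ppm, noise sd 0.01
  errs <- vapply(seq_len(120), function(i) {
    set.seed(7000 + i)
    db0 <- runif(1, -0.3, 0.3)
    target <- runif(1, 1, 5)
    a <- calibrate_gag_amplitude(target)
    wz <- simulate_zspectrum(pool_set(0, 0.5, 0.7), wassr_offsets(), db0 = db0,
                             noise_sd = 0.01, seed = 7500 + i)
    cz <- simulate_zspectrum(default_pools(a), cest_offsets(), db0 = db0,
                             noise_sd = 0.01, seed = 8000 + i)
    gag_score(cz, db0 = mscf_offset(wz)) - target
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.1)
})
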