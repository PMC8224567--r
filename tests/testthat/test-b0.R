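test_that("maximum-symmetry estimator recovers known centers", {
  offs <- wassr_offsets()
  # symmetric spectrum centered at 0
  z0 <- simulate_zspectrum(pool_set(0, 0.5, 0.7), offs, db0 = 0, noise_sd = 0)
  expect_lt(abs(mscf_offset(z0)), 0.002)

  # noiseless displaced line, checked against a brute-force cost-grid oracle
  z <- simulate_zspectrum(pool_set(0, 0.5, 0.7), offs, db0 = 0.17, noise_sd = 0)
  est <- mscf_offset(z)
  expect_lt(abs(est - 0.17), 0.005)

  sf <- splinefun(z$offsets, z$signals, method = "natural")
  grid <- seq(-0.5, 0.5, 0.001)
  cost <- vapply(grid, function(d) {
    m <- 2 * d - offs
    ok <- m >= min(offs) & m <= max(offs)
    mean((sf(m[ok]) - z$signals[ok])^2)
  }, numeric(1))
  expect_lt(abs(est - grid[which.min(cost)]), 0.002)
})

test_that("estimator is unbiased under noise (Monte Carlo at center -0.30)", {
  offs <- wassr_offsets()
  pool <- pool_set(0, 0.5, 0.7)
  ests <- vapply(seq_len(200), function(i) {
    z <- simulate_zspectrum(pool, offs, db0 = -0.30, noise_sd = 0.01,
                            seed = 5000 + i)
    mscf_offset(z)
  }, numeric(1))
  expect_lt(abs(mean(ests) + 0.30), 0.01)
  expect_lt(sd(ests), 0.05)
})

test_that("estimator is translation-equivariant and scale-invariant", {
  offs <- wassr_offsets()
  pool <- pool_set(0, 0.5, 0.7)
  base <- mscf_offset(simulate_zspectrum(pool, offs, db0 = 0, noise_sd = 0))
  for (d in c(-0.3, -0.12, 0.08, 0.25)) {
    z <- simulate_zspectrum(pool, offs, db0 = d, noise_sd = 0)
    expect_lt(abs(mscf_offset(z) - d - base), 0.005)
  }
  z <- simulate_zspectrum(pool, offs, db0 = 0.2, noise_sd = 0.005, seed = 31)
  raw <- z$signals * 3.7
  znorm <- zs_normalize(raw, 3.7, offs)
  expect_equal(mscf_offset(znorm), mscf_offset(z), tolerance = 1e-9)
})

test_that("recovery error grows monotonically with noise level", {
  offs <- wassr_offsets()
  pool <- pool_set(0, 0.5, 0.7)
  rmse <- vapply(c(0.002, 0.02, 0.08), function(ns) {
    errs <- vapply(1:40, function(i) {
      z <- simulate_zspectrum(pool, offs, db0 = 0.1, noise_sd = ns,
                              seed = 900 + i)
      mscf_offset(z) - 0.1
    }, numeric(1))
    sqrt(mean(errs^2))
  }, numeric(1))
  expect_true(all(diff(rmse) > 0))
})

test_that("configuration and degenerate inputs are rejected loudly", {
  expect_error(mscf_config(search_bound = 0), "> 0")
  expect_error(mscf_config(coarse_step = 0.6), "search bound")
  expect_error(mscf_config(fine_step = 0.05), "fine step")
  z <- zspectrum(c(-1, 0, 1), c(0.5, 0.2, 0.5))
  expect_error(mscf_offset(z), ">= 7")
})

test_that("B0 maps recover an injected smooth field and respect the mask", {
  acq <- small_subject_clean()
  lab <- acq$phantom$labels
  mask <- lab > 9
  # zero injected field, noiseless: map ~ 0 on the mask, NA off it
  map0 <- compute_b0_map(acq$wassr, acq$s0, mask, acq$wassr_offsets)
  expect_lt(max(abs(map0[mask])), 1e-6)
  expect_true(all(is.na(map0[!mask])))

  b0 <- make_b0_field(dim(lab), amplitude = 0.3, smoothness_mm = 60,
                      pixel_mm = acq$phantom$pixel_mm, seed = 17)
  acq_b <- render_subject(acq$phantom, b0, noise_sd = 0, seed = 1)
  map <- compute_b0_map(acq_b$wassr, acq_b$s0, mask, acq_b$wassr_offsets)
  expect_lt(max(abs((map - b0)[mask])), 0.005)
})

test_that("voxel failures are recorded with coordinates, not zeroed", {
  acq <- small_subject()
  mask <- acq$phantom$labels > 9
  s0_bad <- acq$s0
  bad_vox <- which(mask)[1]
  s0_bad[bad_vox] <- 0
  map <- compute_b0_map(acq$wassr, s0_bad, mask, acq$wassr_offsets)
  fails <- attr(map, "failures")
  expect_equal(nrow(fails), 1)
  expect_equal(fails$row, (bad_vox - 1) %% nrow(acq$s0) + 1)
  expect_true(is.na(map[bad_vox]))
})
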