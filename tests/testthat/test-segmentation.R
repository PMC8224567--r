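test_that("NP/AF split partitions the disc with an enclosed interior core", {
  mask <- matrix(FALSE, 30, 30)
  mask[10:20, 8:24] <- TRUE
  parts <- split_np_af(mask)
  expect_true(all(!(parts$np & parts$af)))
  expect_identical(parts$np | parts$af, mask)
  expect_lt(sum(parts$np), sum(mask))
  expect_gt(sum(parts$np), 0)
  # boundary ring belongs to AF
  expect_true(all(parts$af[10, 8:24]))
  expect_error(split_np_af(matrix(FALSE, 5, 5)), "empty")
})

test_that("Gaussian NB places the boundary between two symmetric classes and honours priors", {
  set.seed(101)
  x <- c(rnorm(300, 0), rnorm(300, 4))
  lab <- rep(c("a", "b"), each = 300)
  m <- train_nb(data.frame(f = x), lab)
  # decision flips between the class means
  grid <- data.frame(f = seq(-2, 6, 0.01))
  pred <- predict(m, grid)
  flip <- grid$f[max(which(pred == "a"))]
  expect_lt(abs(flip - 2), 0.5)

  expect_error(train_nb(data.frame(f = x), rep("a", 600)), ">= 2 classes")

  # uninformative features: prediction follows the larger prior
  m2 <- train_nb(data.frame(f = c(1, 1, 1, 1, 1) + rnorm(5, 0, 1e-8)),
                 c("a", "a", "a", "b", "b"))
  expect_equal(as.character(predict(m2, data.frame(f = 1))), "a")
})

test_that("hand NB agrees with the reference Gaussian naive Bayes implementation", {
  set.seed(202)
  n <- 400
  df <- data.frame(f1 = c(rnorm(n, 0), rnorm(n, 2), rnorm(n, -1)),
                   f2 = c(rnorm(n, 1), rnorm(n, 1.5), rnorm(n, 3)))
  lab <- rep(c("a", "b", "c"), each = n)
  mine <- predict(train_nb(df, lab), df)
  ref <- predict(e1071::naiveBayes(df, factor(lab)), df)
  expect_gt(mean(as.character(mine) == as.character(ref)), 0.995)
})

test_that("phantom segmentation is accurate, deterministic and correctly partitioned", {
  acq <- small_subject()
  model <- small_model()
  feats <- nb_features(acq$s0, acq$cest)
  lab <- acq$phantom$labels
  cls <- ifelse(lab == 0L, "background", ifelse(lab == 1L, "bone", "disc"))
  expect_gt(mean(as.character(predict(model, feats)) == as.vector(cls)), 0.95)

  rs <- segment_discs(acq$s0, acq$cest, model)
  expect_equal(length(rs$discs), 5)
  vr <- verify_rois(rs, reference = lab)
  expect_true(all(vr$report$dice >= 0.9))
  for (d in rs$discs) {
    expect_lt(length(d$np), length(d$voxels))
    expect_setequal(c(d$np, d$af), d$voxels)
  }
  rs2 <- segment_discs(acq$s0, acq$cest, model)
  expect_identical(rs, rs2)
})

test_that("an unexpected sixth component flags the ROI set for verification", {
  acq <- small_subject()
  # paint a disc-like decoy away from the spine by copying disc signals
  src <- which(acq$phantom$labels == 13)[1:20]
  n <- nrow(acq$s0)
  dest <- 15 * n + (20:39)   # column 16, rows 21..40: background
  acq2 <- acq
  acq2$s0[dest] <- acq$s0[src]
  cm <- matrix(acq2$cest, length(acq2$s0), dim(acq2$cest)[3])
  cm[dest, ] <- cm[src, ]
  acq2$cest <- array(cm, dim = dim(acq$cest))
  rs <- segment_discs(acq2$s0, acq2$cest, small_model())
  expect_equal(rs$status, "needs verification")
  expect_gt(rs$n_components, 5)
})

test_that("ROI verification allows translations only and reports Dice", {
  acq <- small_subject()
  rs <- segment_discs(acq$s0, acq$cest, small_model())
  same <- verify_rois(rs)
  expect_identical(same$roiset, rs)
  expect_true(all(same$report$status == "auto"))

  moved <- verify_rois(rs, edits = list(list(segment = "L2/L3",
                                             shift = c(2, 0))))
  i <- which(moved$report$segment == "L2/L3")
  expect_equal(moved$report$status[i], "repositioned")
  expect_equal(moved$report$n_voxels[i],
               length(rs$discs[[i]]$voxels))  # size preserved

  expect_error(verify_rois(rs, edits = list(list(segment = "L1/L2",
                                                 shift = c(-1000, 0)))),
               "outside the image")
})
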