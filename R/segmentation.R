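#' Partition a disc mask into NP core and AF rim
#'
#' The nucleus pulposus is taken as the interior of the disc: pixels whose
#' Euclidean distance to the disc boundary (distance transform) is at or above
#' the 50th percentile of the positive depths. The remainder is the annulus
#' fibrosus. The threshold percentile is configurable; the same rule is used
#' by the phantom generator and by segmentation, so simulated truth and
#' recovered ROIs share one NP/AF boundary definition.
#'
#' @param mask Logical matrix marking one disc.
#' @param percentile Depth percentile defining the NP (default 0.5).
#' @return List of logical matrices `np` and `af` (disjoint, union = mask).
#' @export
split_np_af <- function(mask, percentile = 0.5) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask != 0
  if (!any(mask)) abort("empty disc mask")
  d <- EBImage::distmap(EBImage::Image(mask * 1))
  d <- as.matrix(EBImage::imageData(d))
  depths <- d[mask]
  thr <- stats::quantile(depths, percentile, names = FALSE)
  if (thr <= min(depths)) thr <- min(depths) + 1e-9
  np <- mask & d >= thr
  if (!any(np)) np <- mask & d == max(depths)
  list(np = np, af = mask & !np)
}

#' Per-voxel features for disc classification
#'
#' Four features per voxel: unsaturated S0 intensity, mean saturated signal
#' normalized by S0 (mean of the CEST stack over offsets divided by S0), and
#' normalized row and column position. Position features encode the prior
#' that the spine occupies a known part of the sagittal field of view.
#'
#' @param s0 S0 matrix.
#' @param cest CEST stack (rows x cols x offsets), raw signals.
#' @return Data frame with columns `s0`, `mean_sat`, `row`, `col`.
#' @export
nb_features <- function(s0, cest) {
  n <- nrow(s0); m <- ncol(s0)
  msat <- apply(cest, c(1, 2), mean)
  s0c <- pmax(s0, 1e-6)
  data.frame(
    s0 = as.vector(s0),
    mean_sat = as.vector(msat / s0c),
    row = as.vector(matrix(seq_len(n) / n, n, m)),
    col = as.vector(matrix(seq_len(m) / m, n, m, byrow = TRUE))
  )
}

#' Train a Gaussian naive Bayes voxel classifier
#'
#' Maximum-likelihood Gaussian class-conditionals per feature with class
#' priors from the label frequencies. Per-class variances are floored at 1e-6
#' of the pooled feature variance so a constant feature within one class
#' cannot produce a degenerate likelihood.
#'
#' @param features Data frame of numeric features (one row per voxel).
#' @param labels Class labels (factor or character), at least two classes.
#' @return An `nb_model` with per-class means, variances and priors.
#' @export
train_nb <- function(features, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) abort("naive Bayes training needs >= 2 classes")
  if (nrow(features) != length(labels)) abort("features/labels length mismatch")
  X <- as.matrix(features)
  classes <- levels(labels)
  floor_var <- 1e-6 * apply(X, 2, stats::var)
  floor_var[!is.finite(floor_var) | floor_var <= 0] <- 1e-12
  mu <- var <- matrix(NA_real_, length(classes), ncol(X),
                      dimnames = list(classes, colnames(X)))
  for (cl in classes) {
    Xc <- X[labels == cl, , drop = FALSE]
    mu[cl, ] <- colMeans(Xc)
    v <- apply(Xc, 2, stats::var)
    v[!is.finite(v)] <- 0
    var[cl, ] <- pmax(v, floor_var)
  }
  structure(list(classes = classes, mean = mu, var = var,
                 prior = as.vector(table(labels) / length(labels)),
                 features = colnames(X)),
            class = "nb_model")
}

#' Predict voxel classes with a naive Bayes model
#'
#' Vectorized maximum-posterior classification: log-posterior per class is the
#' log prior plus the sum of Gaussian log-likelihoods over features. Ties
#' (identical posteriors) resolve to the class with the larger prior.
#'
#' @param object An `nb_model`.
#' @param newdata Data frame with the model's feature columns.
#' @param ... Unused.
#' @return Factor of predicted classes, one per row of `newdata`.
#' @export
predict.nb_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  n <- nrow(X)
  # order classes by decreasing prior so which.max tie-breaks toward it
  ord <- order(object$prior, decreasing = TRUE)
  lp <- matrix(0, n, length(object$classes))
  for (j in seq_along(ord)) {
    k <- ord[j]
    ll <- log(object$prior[k])
    for (f in seq_along(object$features)) {
      ll <- ll + stats::dnorm(X[, f], object$mean[k, f],
                              sqrt(object$var[k, f]), log = TRUE)
    }
    lp[, j] <- ll
  }
  factor(object$classes[ord[max.col(lp, ties.method = "first")]],
         levels = object$classes)
}

#' Segment the five lumbar discs of a rendered subject
#'
#' Classifies every voxel with the naive Bayes model, extracts connected
#' components of the disc class, matches components to the five expected
#' segments by the vertical order of their centroids (ties broken toward the
#' larger component) and partitions each disc into NP and AF with
#' [split_np_af()]. If the number of disc components differs from five the
#' ROI set is flagged for verification rather than silently merged; the five
#' largest components are still matched by vertical order so downstream steps
#' can proceed under review.
#'
#' @param s0 S0 matrix of the subject.
#' @param cest CEST stack (raw).
#' @param model An `nb_model` trained with disc/bone/background classes.
#' @param disc_class Name of the disc class in the model (default "disc").
#' @param min_component Minimum component size in voxels (smaller components
#'   are treated as noise and dropped before matching; default 6).
#' @param np_percentile Passed to [split_np_af()].
#' @return An object of class `roi_set`: per-disc voxel index sets, NP/AF
#'   subsets, segment labels, and a status field ("auto" or
#'   "needs verification").
#' @export
segment_discs <- function(s0, cest, model, disc_class = "disc",
                          min_component = 6L, np_percentile = 0.5) {
  stopifnot(inherits(model, "nb_model"))
  n <- nrow(s0); m <- ncol(s0)
  feats <- nb_features(s0, cest)
  pred <- predict(model, feats)
  disc_mask <- matrix(pred == disc_class, n, m)
  comp <- EBImage::bwlabel(EBImage::Image(disc_mask * 1))
  comp <- as.matrix(EBImage::imageData(comp))
  sizes <- tabulate(comp[comp > 0])
  keep <- which(sizes >= min_component)
  ncomp <- length(keep)
  status <- if (ncomp == 5L) "auto" else "needs verification"
  if (ncomp == 0L) abort("no disc components found")

  cent_row <- vapply(keep, function(k) mean((which(comp == k) - 1L) %% n + 1L),
                     numeric(1))
  # order superior -> inferior (small row index = superior); tie: larger area
  ord <- keep[order(cent_row, -sizes[keep])]
  use <- ord[seq_len(min(5L, length(ord)))]

  discs <- vector("list", length(use))
  for (i in seq_along(use)) {
    mk <- comp == use[i]
    parts <- split_np_af(mk, np_percentile)
    discs[[i]] <- list(
      segment = disc_segments()[i],
      voxels = which(mk),
      np = which(parts$np),
      af = which(parts$af),
      status = "auto"
    )
  }
  structure(list(discs = discs, status = status, n_components = ncomp,
                 dim = c(n, m)),
            class = "roi_set")
}

#' @exportS3Method base::print
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d discs (components found: %d), status: %s\n",
              length(x$discs), x$n_components, x$status))
  for (d in x$discs)
    cat(sprintf("  %s: %d voxels (NP %d, AF %d) [%s]\n", d$segment,
                length(d$voxels), length(d$np), length(d$af), d$status))
  invisible(x)
}

#' Dice overlap coefficient of two voxel sets
#'
#' @param a,b Integer vectors of voxel indices (or logical masks).
#' @return 2|a intersect b| / (|a| + |b|); 0 when both are empty.
#' @export
dice <- function(a, b) {
  if (is.logical(a)) a <- which(a)
  if (is.logical(b)) b <- which(b)
  if (length(a) + length(b) == 0) return(0)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Verify and optionally reposition disc ROIs
#'
#' Mirrors a reader's verification step: ROIs may be translated (repositioned)
#' but never resized — an edit that changes the voxel count is rejected. When
#' a reference label matrix is supplied (e.g. phantom truth) the report lists
#' the Dice overlap of each disc ROI against its true disc (NP + AF labels).
#'
#' @param roiset A `roi_set`.
#' @param reference Optional integer label matrix with phantom label codes.
#' @param edits Optional list of edits, each `list(segment =, shift = c(dr, dc))`.
#' @return List with the (possibly edited) `roi_set` and a per-disc report
#'   data frame (segment, n_voxels, status, dice when a reference is given).
#' @export
verify_rois <- function(roiset, reference = NULL, edits = NULL) {
  stopifnot(inherits(roiset, "roi_set"))
  n <- roiset$dim[1]
  shift_idx <- function(idx, dr, dc) {
    r <- (idx - 1L) %% n + 1L
    c0 <- (idx - 1L) %/% n + 1L
    r2 <- r + dr; c2 <- c0 + dc
    if (any(r2 < 1L | r2 > n | c2 < 1L | c2 > roiset$dim[2]))
      abort("repositioning moves the ROI outside the image")
    (c2 - 1L) * n + r2
  }
  for (e in edits) {
    i <- which(vapply(roiset$discs, function(d) d$segment, "") == e$segment)
    if (length(i) != 1L) abort("edit names unknown segment %s", e$segment)
    d <- roiset$discs[[i]]
    nv_before <- length(d$voxels)
    d$voxels <- shift_idx(d$voxels, e$shift[1], e$shift[2])
    d$np <- shift_idx(d$np, e$shift[1], e$shift[2])
    d$af <- shift_idx(d$af, e$shift[1], e$shift[2])
    if (length(d$voxels) != nv_before)
      abort("reposition edits must preserve ROI size (translation only)")
    d$status <- "repositioned"
    roiset$discs[[i]] <- d
  }
  rep_df <- data.frame(
    segment = vapply(roiset$discs, function(d) d$segment, ""),
    n_voxels = vapply(roiset$discs, function(d) length(d$voxels), 0L),
    status = vapply(roiset$discs, function(d) d$status, ""),
    stringsAsFactors = FALSE
  )
  if (!is.null(reference)) {
    rep_df$dice <- vapply(seq_along(roiset$discs), function(i) {
      s <- i
      truth_idx <- which(reference == lbl_np(s) | reference == lbl_af(s))
      dice(roiset$discs[[i]]$voxels, truth_idx)
    }, numeric(1))
  }
  list(roiset = roiset, report = rep_df)
}
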