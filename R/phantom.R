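#' Spine phantom geometry
#'
#' Geometry of the synthetic sagittal lumbar phantom: a single mid-sagittal
#' slice with five intervertebral discs (L1/L2 to L5/S1) stacked between six
#' vertebral bodies. Defaults emulate a 300-mm field of view on a 188 x 188
#' grid (1.6-mm pixels). All block sizes scale with the grid so smaller test
#' grids remain valid.
#'
#' @param n Grid side length in pixels (square grid), >= 64.
#' @param fov_mm Field of view in mm; pixel size is `fov_mm / n`.
#' @return A list of geometry parameters (class `spine_geometry`).
#' @export
spine_geometry <- function(n = 188, fov_mm = 300) {
  if (n < 64) abort("grid side must be >= 64 pixels to hold five discs with usable NP cores")
  sc <- n / 188
  g <- list(
    n = as.integer(n),
    pixel_mm = fov_mm / n,
    body_h = max(6L, as.integer(round(17 * sc))),   # vertebral body height (px)
    disc_h = max(5L, as.integer(round(9 * sc))),    # disc slot height (px)
    body_w = max(8L, as.integer(round(22 * sc))),   # vertebral body width (px)
    disc_ax = max(4L, as.integer(round(12 * sc))),  # disc ellipse semi-axis, AP (px)
    jitter_px = if (n >= 100) 2L else 0L
  )
  g$disc_az <- max(2L, as.integer(floor(g$disc_h / 2)))
  total_h <- 6L * g$body_h + 5L * g$disc_h
  if (total_h + 2L * g$jitter_px > n)
    abort("five discs and six vertebral bodies do not fit a %d-pixel grid", n)
  class(g) <- "spine_geometry"
  g
}

# label codes
LBL_BACKGROUND <- 0L
LBL_BONE <- 1L
lbl_np <- function(s) 10L + as.integer(s)
lbl_af <- function(s) 20L + as.integer(s)

#' Generate a synthetic sagittal spine phantom
#'
#' Builds an integer label grid (0 background, 1 bone, 10+s NP, 20+s AF for
#' segment s in 1..5) with five elliptical discs between rectangular
#' vertebral bodies, together with the per-region true gag scores and the
#' Lorentzian pool parameters that will render them. The NP core of each disc
#' is the interior of the disc by the distance-transform median rule (the same
#' rule the segmentation module uses), so every NP is spatially enclosed by
#' its AF rim. Disc positions receive a small seed-controlled jitter so
#' subjects differ geometrically.
#'
#' @param geometry A `spine_geometry`.
#' @param seed Integer seed (jitter only); the phantom is deterministic given
#'   the seed.
#' @param np_gag,af_gag True gag scores (%) for NP and AF; scalars or length-5
#'   vectors (one per segment, superior to inferior).
#' @param water_amplitude,water_width Water pool parameters for disc tissue.
#' @param mt Include a broad symmetric MT pool in disc tissue.
#' @return An object of class `spine_phantom`: label matrix, pixel size,
#'   truth table (segment, region, label, gag score, calibrated amplitude)
#'   and rendering pools.
#' @export
make_spine_phantom <- function(geometry = spine_geometry(), seed = 1L,
                               np_gag = 3.9, af_gag = 2.37,
                               water_amplitude = 0.85, water_width = 1.2,
                               mt = FALSE) {
  stopifnot(inherits(geometry, "spine_geometry"))
  g <- geometry
  n <- g$n
  np_gag <- rep_len(np_gag, 5L)
  af_gag <- rep_len(af_gag, 5L)
  if (any(np_gag < 0) || any(af_gag < 0)) abort("gag scores must be >= 0")

  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  on.exit(restore_rng(old), add = TRUE)
  jx <- if (g$jitter_px > 0) sample.int(2L * g$jitter_px + 1L, 1L) - g$jitter_px - 1L else 0L
  jy <- if (g$jitter_px > 0) sample.int(3L, 5L, replace = TRUE) - 2L else rep(0L, 5L)

  labels <- matrix(LBL_BACKGROUND, n, n)
  cx <- round(n / 2) + jx
  total_h <- 6L * g$body_h + 5L * g$disc_h
  y0 <- round((n - total_h) / 2)

  # vertebral bodies (rows = superior -> inferior)
  half_w <- floor(g$body_w / 2)
  xs <- max(1L, cx - half_w):min(n, cx + half_w)
  for (b in 0:5) {
    top <- y0 + b * (g$body_h + g$disc_h)
    ys <- max(1L, top):min(n, top + g$body_h - 1L)
    labels[ys, xs] <- LBL_BONE
  }

  # discs: ellipses centered in each slot, partitioned NP/AF by interior depth
  row_idx <- matrix(seq_len(n), n, n)
  col_idx <- matrix(seq_len(n), n, n, byrow = TRUE)
  for (s in 1:5) {
    slot_top <- y0 + s * g$body_h + (s - 1L) * g$disc_h
    cy <- slot_top + (g$disc_h - 1L) / 2 + jy[s]
    mask <- ((col_idx - cx) / g$disc_ax)^2 + ((row_idx - cy) / g$disc_az)^2 <= 1
    if (sum(mask) < 12L)
      abort("grid too small: disc %d has fewer than 12 pixels", s)
    parts <- split_np_af(mask)
    if (sum(parts$np) < 3L)
      abort("grid too small: disc %d NP core has fewer than 3 pixels", s)
    labels[parts$af] <- lbl_af(s)
    labels[parts$np] <- lbl_np(s)
  }

  truth <- data.frame(
    segment = rep(disc_segments(), each = 2L),
    region = rep(c("NP", "AF"), times = 5L),
    label = as.integer(t(cbind(lbl_np(1:5), lbl_af(1:5)))),
    stringsAsFactors = FALSE
  )
  truth$gag <- as.numeric(t(cbind(np_gag, af_gag)))
  truth$amplitude <- vapply(truth$gag, calibrate_gag_amplitude,
                            numeric(1), water_amplitude = water_amplitude)

  structure(list(
    labels = labels,
    pixel_mm = g$pixel_mm,
    geometry = g,
    truth = truth,
    water_amplitude = water_amplitude,
    water_width = water_width,
    mt = mt,
    seed = as.integer(seed)
  ), class = "spine_phantom")
}

#' @exportS3Method base::print
print.spine_phantom <- function(x, ...) {
  cat(sprintf("<spine_phantom> %dx%d grid, %.2f mm pixels, 5 discs\n",
              nrow(x$labels), ncol(x$labels), x$pixel_mm))
  print(x$truth[, c("segment", "region", "gag")])
  invisible(x)
}

#' Generate a smooth B0 inhomogeneity field
#'
#' Gaussian white noise smoothed with a separable Gaussian kernel of the given
#' spatial length scale, then rescaled so the largest absolute offset equals
#' `amplitude` (ppm). Amplitude 0 returns an all-zero field. Deterministic
#' given the seed.
#'
#' @param shape c(rows, cols) of the field.
#' @param amplitude Maximum absolute water-frequency offset (ppm), >= 0.
#' @param smoothness_mm Smoothing length scale (mm).
#' @param pixel_mm Pixel size (mm).
#' @param seed Integer seed.
#' @return Matrix of per-pixel water center-frequency offsets (ppm).
#' @export
make_b0_field <- function(shape, amplitude = 0.3, smoothness_mm = 60,
                          pixel_mm = 1.6, seed = 1L) {
  if (!is.finite(amplitude) || amplitude < 0) abort("B0 amplitude must be >= 0")
  nr <- shape[1]; nc <- shape[2]
  if (amplitude == 0) return(matrix(0, nr, nc))
  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  on.exit(restore_rng(old), add = TRUE)
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  sigma <- max(1, smoothness_mm / pixel_mm / 2)
  kmat <- function(m) {
    d <- outer(seq_len(m), seq_len(m), function(i, j) (i - j)^2)
    k <- exp(-d / (2 * sigma^2))
    k / rowSums(k)
  }
  f <- kmat(nr) %*% w %*% t(kmat(nc))
  f * (amplitude / max(abs(f)))
}

# internal: per-pixel rendering parameters derived from a phantom's labels
phantom_voxel_params <- function(phantom) {
  lab <- phantom$labels
  idx <- which(lab > 0L)
  a_water <- numeric(length(idx))
  w_water <- numeric(length(idx))
  a_gag <- numeric(length(idx))
  s0 <- numeric(length(idx))
  lv <- lab[idx]
  is_bone <- lv == LBL_BONE
  a_water[is_bone] <- 0.9; w_water[is_bone] <- 1.5; s0[is_bone] <- 0.35
  for (r in seq_len(nrow(phantom$truth))) {
    sel <- lv == phantom$truth$label[r]
    a_water[sel] <- phantom$water_amplitude
    w_water[sel] <- phantom$water_width
    a_gag[sel] <- phantom$truth$amplitude[r]
    s0[sel] <- if (phantom$truth$region[r] == "NP") 1.0 else 0.75
  }
  list(idx = idx, a_water = a_water, w_water = w_water, a_gag = a_gag, s0 = s0)
}

#' Render CEST, WASSR and S0 acquisitions of a phantom
#'
#' Simulates the saturation-offset image stacks of one subject: a CEST stack
#' (default 31 offsets on +/-3 ppm), a low-power WASSR stack (default 21
#' offsets on +/-1 ppm, narrow water line only) and an unsaturated S0 image.
#' Each tissue pixel's z-spectrum is the Lorentzian pool model shifted by the
#' local B0 offset; Gaussian noise of SD `noise_sd` is added on the
#' normalized signal and raw signals are S0 times the noisy spectrum.
#'
#' @param phantom A `spine_phantom`.
#' @param b0 B0 field matrix (ppm) of the same shape, or NULL for a uniform
#'   field of 0.
#' @param cest_offs,wassr_offs Offset grids (ppm).
#' @param noise_sd Noise SD on the normalized signal (default 0.01).
#' @param seed Integer seed for the noise draws.
#' @param wassr_width,wassr_amplitude Width (ppm) and amplitude of the
#'   direct-saturation line in the WASSR acquisition.
#' @return A list with `cest` (rows x cols x n_offsets raw array), `wassr`,
#'   `s0` matrix, the offset grids, the B0 field and the phantom.
#' @export
render_subject <- function(phantom, b0 = NULL,
                           cest_offs = cest_offsets(),
                           wassr_offs = wassr_offsets(),
                           noise_sd = 0.01, seed = 1L,
                           wassr_width = 0.5, wassr_amplitude = 0.7) {
  stopifnot(inherits(phantom, "spine_phantom"))
  n <- nrow(phantom$labels); m <- ncol(phantom$labels)
  if (is.null(b0)) b0 <- matrix(0, n, m)
  if (!all(dim(b0) == c(n, m))) abort("B0 field shape does not match phantom")
  if (!is.finite(noise_sd) || noise_sd < 0) abort("noise_sd must be >= 0")

  p <- phantom_voxel_params(phantom)
  db0 <- b0[p$idx]

  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  on.exit(restore_rng(old), add = TRUE)

  s0_map <- matrix(0.03, n, m)
  s0_map[p$idx] <- p$s0
  s0_map <- s0_map * (1 + stats::rnorm(n * m, 0, noise_sd))
  s0_map[s0_map <= 0] <- 1e-4

  render_stack <- function(offs, gag = TRUE, aw = NULL, ww = NULL) {
    stack <- array(0, dim = c(n, m, length(offs)))
    bg <- matrix(0.03, n, m)
    for (j in seq_along(offs)) {
      x <- offs[j] - db0
      z <- 1 - (if (is.null(aw)) p$a_water else aw) *
        lorentzian(x, 0, if (is.null(ww)) p$w_water else ww)
      if (gag) z <- z - p$a_gag * lorentzian(x, 1.0, 0.5)
      plane <- bg
      plane[p$idx] <- p$s0 * z
      plane <- plane + matrix(stats::rnorm(n * m, 0, noise_sd), n, m) * s0_base(p, n, m)
      stack[, , j] <- plane
    }
    stack
  }

  cest <- render_stack(cest_offs, gag = TRUE)
  wassr <- render_stack(wassr_offs, gag = FALSE,
                        aw = wassr_amplitude, ww = wassr_width)

  list(cest = cest, wassr = wassr, s0 = s0_map,
       cest_offsets = cest_offs, wassr_offsets = wassr_offs,
       b0 = b0, phantom = phantom, noise_sd = noise_sd)
}

# internal: per-pixel S0 scale for noise (noise is additive on the normalized
# signal, so the raw-signal noise scales with S0)
s0_base <- function(p, n, m) {
  s <- matrix(0.03, n, m)
  s[p$idx] <- p$s0
  s
}
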