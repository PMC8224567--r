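#' Maximum-symmetry B0 estimation settings
#'
#' Controls the search for the water center frequency in a WASSR spectrum:
#' the symmetric search bound (ppm), the coarse grid step, and the local fine
#' grid step used before the final parabolic refinement. The default bound of
#' 0.5 ppm sits well inside the +/-1 ppm WASSR sampling range.
#'
#' @param search_bound Half-width of the search interval (ppm), > 0.
#' @param coarse_step Coarse grid spacing (ppm), in (0, search_bound).
#' @param fine_step Local fine grid spacing (ppm), in (0, coarse_step].
#' @return A list of class `mscf_config`.
#' @export
mscf_config <- function(search_bound = 0.5, coarse_step = 0.01,
                        fine_step = 0.002) {
  if (search_bound <= 0) abort("search bound must be > 0")
  if (coarse_step <= 0 || coarse_step >= search_bound)
    abort("coarse step must be in (0, search bound)")
  if (fine_step <= 0 || fine_step > coarse_step)
    abort("fine step must be in (0, coarse step]")
  structure(list(search_bound = search_bound, coarse_step = coarse_step,
                 fine_step = fine_step), class = "mscf_config")
}

# internal: symmetry cost over a grid of candidate centers.
# C(delta) = mean_i [Zhat(2*delta - w_i) - Z(w_i)]^2 over mirrored points that
# fall inside the sampled range. The mean (not the raw sum) keeps candidates
# with fewer usable pairs comparable; candidates with < 5 usable pairs are
# excluded.
mscf_cost <- function(sf, offsets, signals, deltas, min_pairs = 5L) {
  rng <- range(offsets)
  nmirror <- outer(2 * deltas, offsets, "-")   # n_delta x n_offsets
  ok <- nmirror >= rng[1] - 1e-12 & nmirror <= rng[2] + 1e-12
  vals <- matrix(NA_real_, nrow(nmirror), ncol(nmirror))
  vals[ok] <- sf(nmirror[ok])
  sq <- (vals - matrix(signals, nrow(nmirror), ncol(nmirror), byrow = TRUE))^2
  counts <- rowSums(ok)
  cost <- rowSums(sq * ok, na.rm = TRUE) / counts
  cost[counts < min_pairs] <- NA_real_
  cost
}

#' Estimate the water center frequency by maximum symmetry
#'
#' Implements the WASSR maximum-symmetry (MSCF) estimator: the water center
#' offset delta is the value that makes the spectrum most mirror-symmetric,
#' i.e. minimizes C(delta) = mean_i [Zhat(2 delta - omega_i) - Z(omega_i)]^2,
#' where Zhat is the spline-interpolated spectrum and the mean runs over
#' offsets whose mirrored coordinate stays inside the sampled range.
#' Search: coarse grid, then a local fine grid, then parabolic interpolation
#' of the cost minimum. Exact cost ties resolve toward the smallest |delta|.
#'
#' @param wassr A normalized `zspectrum` (WASSR acquisition), at least 7
#'   offsets.
#' @param cfg An `mscf_config`.
#' @return Estimated water center-frequency offset delta-B0 (ppm).
#' @export
mscf_offset <- function(wassr, cfg = mscf_config()) {
  stopifnot(inherits(wassr, "zspectrum"))
  if (length(wassr$offsets) < 7) abort("MSCF needs >= 7 WASSR offsets")
  sf <- zs_spline(wassr)
  pick <- function(deltas) {
    cost <- mscf_cost(sf, wassr$offsets, wassr$signals, deltas)
    if (all(is.na(cost)))
      abort("no candidate center has enough mirrored points inside the sampled range")
    cmin <- min(cost, na.rm = TRUE)
    cand <- which(!is.na(cost) & cost <= cmin + 1e-15)
    cand[which.min(abs(deltas[cand]))]
  }
  b <- cfg$search_bound
  coarse <- sort(unique(c(seq(-b, b, by = cfg$coarse_step), 0)))
  i1 <- pick(coarse)
  d1 <- coarse[i1]

  fine <- seq(max(-b, d1 - cfg$coarse_step), min(b, d1 + cfg$coarse_step),
              by = cfg$fine_step)
  i2 <- pick(fine)
  d2 <- fine[i2]

  # parabolic refinement when the fine minimum is interior
  if (i2 > 1 && i2 < length(fine)) {
    tri <- fine[(i2 - 1):(i2 + 1)]
    cv <- mscf_cost(sf, wassr$offsets, wassr$signals, tri)
    if (!anyNA(cv)) {
      denom <- cv[1] - 2 * cv[2] + cv[3]
      if (is.finite(denom) && denom > 0) {
        d2 <- tri[2] + 0.5 * cfg$fine_step * (cv[1] - cv[3]) / denom
      }
    }
  }
  max(-b, min(b, d2))
}

#' Compute a per-voxel B0 map from a WASSR stack
#'
#' Normalizes each masked voxel's WASSR spectrum by its S0 value and applies
#' [mscf_offset()]. Voxels outside the mask are NA; voxels whose estimation
#' fails (non-positive S0, degenerate spectrum) are recorded with their
#' coordinates in the `failures` attribute, set NA in the map and reported —
#' never silently zeroed.
#'
#' @param wassr WASSR stack (rows x cols x offsets), raw signals.
#' @param s0 S0 matrix.
#' @param mask Logical matrix of voxels to process.
#' @param offsets WASSR offsets (ppm).
#' @param cfg An `mscf_config`.
#' @return Matrix of delta-B0 estimates (ppm) with NA outside the mask;
#'   attribute `failures` holds a data frame of failed voxels (row, col,
#'   reason).
#' @export
compute_b0_map <- function(wassr, s0, mask, offsets = wassr_offsets(),
                           cfg = mscf_config()) {
  n <- nrow(s0); m <- ncol(s0)
  if (!all(dim(mask) == c(n, m))) abort("mask shape mismatch")
  if (dim(wassr)[3] != length(offsets))
    abort("WASSR stack has %d volumes but %d offsets", dim(wassr)[3],
          length(offsets))
  map <- matrix(NA_real_, n, m)
  fail <- list()
  idx <- which(mask)
  wmat <- matrix(wassr, n * m, length(offsets))
  for (v in idx) {
    res <- tryCatch({
      z <- zs_normalize(wmat[v, ], s0[v], offsets,
                        id = sprintf("voxel (%d,%d)", (v - 1) %% n + 1,
                                     (v - 1) %/% n + 1))
      mscf_offset(z, cfg)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fail[[length(fail) + 1L]] <- data.frame(
        row = (v - 1) %% n + 1, col = (v - 1) %/% n + 1,
        reason = conditionMessage(res), stringsAsFactors = FALSE)
    } else map[v] <- res
  }
  failures <- if (length(fail)) do.call(rbind, fail) else
    data.frame(row = integer(), col = integer(), reason = character())
  if (nrow(failures) > 0)
    log_msg("B0 map: %d voxel(s) failed and were set missing", nrow(failures))
  attr(map, "failures") <- failures
  map
}
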