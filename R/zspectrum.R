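#' Construct a z-spectrum
#'
#' A z-spectrum holds the water signal after saturation at a set of frequency
#' offsets, together with the unsaturated reference signal S0. Offsets must be
#' strictly increasing; signals are dimensionless (equal to the raw signal
#' divided by S0 once normalized).
#'
#' @param offsets Saturation offsets (ppm), strictly increasing.
#' @param signals Signal values, same length as `offsets`.
#' @param s0 Unsaturated reference signal, > 0 (1 once normalized).
#' @return An object of class `zspectrum`.
#' @export
zspectrum <- function(offsets, signals, s0 = 1) {
  if (length(offsets) != length(signals))
    abort("offsets and signals lengths differ (%d vs %d)",
          length(offsets), length(signals))
  if (any(!is.finite(offsets))) abort("offsets must be finite")
  if (any(diff(offsets) <= 0)) abort("offsets must be strictly increasing")
  if (!is.finite(s0) || s0 <= 0) abort("s0 must be finite and > 0")
  if (any(!is.finite(signals))) abort("signals must be finite")
  structure(list(offsets = as.numeric(offsets),
                 signals = as.numeric(signals),
                 s0 = as.numeric(s0)),
            class = "zspectrum")
}

#' @exportS3Method base::print
print.zspectrum <- function(x, ...) {
  cat(sprintf("<zspectrum> %d offsets in [%.2f, %.2f] ppm, s0 = %.4g\n",
              length(x$offsets), min(x$offsets), max(x$offsets), x$s0))
  invisible(x)
}

#' Normalize raw signals by the unsaturated reference
#'
#' Divides the raw saturated signals by S0, the signal without presaturation,
#' yielding the z-spectrum Z(omega). Idempotent once s0 = 1.
#'
#' @param raw Raw signal values.
#' @param s0 Unsaturated signal, > 0.
#' @param offsets Offsets (ppm) for the resulting spectrum.
#' @param id Optional identifier (voxel / ROI) used in error messages.
#' @return A normalized `zspectrum` (s0 field set to 1).
#' @export
zs_normalize <- function(raw, s0, offsets, id = NULL) {
  where <- if (is.null(id)) "" else sprintf(" at %s", id)
  if (!is.finite(s0) || s0 <= 0)
    abort("cannot normalize%s: s0 = %s is not a positive finite value",
          where, format(s0))
  if (any(!is.finite(raw)))
    abort("cannot normalize%s: raw signals contain non-finite values", where)
  zspectrum(offsets, raw / s0, s0 = 1)
}

# internal: natural cubic spline interpolant of a spectrum
zs_spline <- function(z) {
  stats::splinefun(z$offsets, z$signals, method = "natural")
}

#' Interpolate a z-spectrum at arbitrary offsets
#'
#' Natural cubic spline through the sampled points; exact at sample offsets.
#' Queries outside the sampled range are refused — extrapolated spectrum
#' values would silently corrupt asymmetry estimates at the band edges.
#'
#' @param z A `zspectrum`.
#' @param query Offsets (ppm) at which to evaluate.
#' @return Interpolated signal values.
#' @export
zs_interpolate <- function(z, query) {
  stopifnot(inherits(z, "zspectrum"))
  rng <- range(z$offsets)
  if (any(query < rng[1] - 1e-12 | query > rng[2] + 1e-12))
    abort("interpolation query outside sampled range [%.3f, %.3f] ppm (no extrapolation)",
          rng[1], rng[2])
  zs_spline(z)(query)
}

#' Re-center a z-spectrum by a frequency offset
#'
#' Resamples the spectrum so that a water line displaced by `delta` ppm (the
#' local B0 offset) is moved back to 0: Z_out(omega) = Z_in(omega + delta),
#' evaluated by spline interpolation on the unchanged offset grid. Grid points
#' whose source coordinate falls outside the sampled range become NA rather
#' than being extrapolated; if `required_range` is supplied and any of it is
#' lost, an error advises acquiring a wider offset range.
#'
#' @param z A `zspectrum`.
#' @param delta Frequency shift (ppm), e.g. the voxel's estimated B0 offset.
#' @param required_range Optional c(lo, hi) in ppm that must remain covered
#'   (e.g. +/- the outer edge of the gag band).
#' @return A `zspectrum` on the same offset grid (possibly with NA at edges
#'   when `required_range` is NULL).
#' @export
zs_shift <- function(z, delta, required_range = NULL) {
  stopifnot(inherits(z, "zspectrum"))
  if (!is.finite(delta)) abort("shift delta must be finite")
  src <- z$offsets + delta
  rng <- range(z$offsets)
  ok <- src >= rng[1] - 1e-12 & src <= rng[2] + 1e-12
  if (!is.null(required_range)) {
    need <- z$offsets >= required_range[1] & z$offsets <= required_range[2]
    if (any(need & !ok))
      abort(paste0("shift of %.3f ppm pushes offsets needed for [%.2f, %.2f] ppm ",
                   "outside the sampled range; acquire a wider offset range"),
            delta, required_range[1], required_range[2])
  }
  out <- rep(NA_real_, length(src))
  out[ok] <- zs_spline(z)(src[ok])
  zz <- z
  zz$signals <- out
  zz
}

#' Simulate a z-spectrum from a Lorentzian pool set
#'
#' Renders Z(omega) = 1 - sum_k A_k L(omega - db0; c_k, w_k) at the requested
#' offsets, optionally adding Gaussian noise on the normalized signal. S0 is 1
#' by construction (the model is defined on the normalized scale).
#'
#' @param pools A `pool_set`.
#' @param offsets Saturation offsets (ppm).
#' @param db0 True water center-frequency offset (ppm) of this voxel.
#' @param noise_sd SD of additive Gaussian noise on the normalized signal.
#' @param seed Optional integer seed for the noise draw.
#' @return A `zspectrum` with s0 = 1.
#' @export
simulate_zspectrum <- function(pools, offsets = cest_offsets(), db0 = 0,
                               noise_sd = 0, seed = NULL) {
  stopifnot(inherits(pools, "pool_set"))
  if (any(!is.finite(offsets))) abort("offsets must be finite")
  if (!is.finite(noise_sd) || noise_sd < 0) abort("noise_sd must be >= 0")
  sig <- rep(1, length(offsets))
  for (k in seq_along(pools$centers)) {
    sig <- sig - pools$amplitudes[k] *
      lorentzian(offsets - db0, pools$centers[k], pools$widths[k])
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- .Random.seed_exists()
      set.seed(seed)
      on.exit(restore_rng(old), add = TRUE)
    }
    sig <- sig + stats::rnorm(length(sig), 0, noise_sd)
  }
  zspectrum(offsets, sig, s0 = 1)
}

# internal RNG bookkeeping so seeded helpers do not clobber the caller's stream
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
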