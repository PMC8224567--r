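#' Gyromagnetic conversion at 3 Tesla
#'
#' Frequency per ppm of chemical shift for protons at 3 T. All frequencies in
#' this package are expressed in ppm; this constant is provided for users who
#' need Hz and is never applied implicitly.
#'
#' @format Numeric scalar, Hz per ppm.
#' @export
HZ_PER_PPM_3T <- 127.7

#' Default GAG-specific evaluation band
#'
#' Offsets (ppm) over which MTR asymmetry is averaged to produce a gag score:
#' 0.9 to 1.9 ppm in 0.1-ppm steps, endpoints inclusive (11 points). The range
#' targets the hydroxyl protons of glycosaminoglycan; the 0.1-ppm quadrature
#' grid is a package choice.
#'
#' @return Numeric vector of offsets in ppm.
#' @export
gag_band <- function() seq(0.9, 1.9, by = 0.1)

#' Default saturation-offset grids
#'
#' CEST acquisitions sample 31 offsets uniformly on -3..3 ppm; WASSR
#' acquisitions sample 21 offsets on -1..1 ppm.
#'
#' @return Numeric vector of offsets in ppm, ascending.
#' @export
cest_offsets <- function() seq(-3, 3, length.out = 31)

#' @rdname cest_offsets
#' @export
wassr_offsets <- function() seq(-1, 1, length.out = 21)

#' Derive a child seed from a top-level seed
#'
#' All randomness in the simulators flows from one top-level integer seed.
#' Independent random streams (per subject, per stage) use child seeds derived
#' deterministically by a multiplicative-congruential step modulo 2^31 - 1, so
#' the whole pipeline is reproducible from a single integer.
#'
#' @param seed Top-level integer seed.
#' @param stream Non-negative integer index of the sub-stream.
#' @return An integer seed in [1, 2^31 - 2].
#' @export
split_seed <- function(seed, stream = 0L) {
  m <- 2147483647  # 2^31 - 1
  x <- (as.numeric(seed) %% m) + 1
  for (i in seq_len(2L + (as.integer(stream) %% 64L))) {
    x <- (x * 48271) %% m
  }
  x <- (x + 7919 * as.numeric(stream)) %% m
  as.integer(x %% (m - 2) + 1)
}

# internal: stop() with a consistent prefix
abort <- function(...) stop(sprintf(...), call. = FALSE)

# internal: lightweight logging to stderr, silenced via option
log_msg <- function(...) {
  if (isTRUE(getOption("gagcest.quiet", FALSE))) return(invisible(NULL))
  message(sprintf(...))
}

#' Lumbar disc segment labels
#'
#' The five lumbar segments in anatomical (superior to inferior) order.
#'
#' @return Character vector of length 5.
#' @export
disc_segments <- function() c("L1/L2", "L2/L3", "L3/L4", "L4/L5", "L5/S1")

# internal: vertebra index on the ladder L1..L5, S1 = 1..6
vertebra_index <- function(v) {
  lv <- c(L1 = 1L, L2 = 2L, L3 = 3L, L4 = 4L, L5 = 5L, S1 = 6L)
  v <- toupper(trimws(v))
  idx <- lv[v]
  if (any(is.na(idx))) abort("unknown vertebra label(s): %s",
                             paste(v[is.na(idx)], collapse = ", "))
  unname(idx)
}

# internal: indices (sup, inf) of the vertebrae adjacent to a disc segment
segment_vertebrae <- function(segment) {
  seg <- match(segment, disc_segments())
  if (any(is.na(seg))) abort("unknown disc segment(s): %s",
                             paste(segment[is.na(seg)], collapse = ", "))
  cbind(sup = seg, inf = seg + 1L)
}
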