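#' Cobb angle from endplate tangent landmarks
#'
#' The Cobb angle is the acute angle between the tangent along the superior
#' endplate of the superior end vertebra and the tangent along the inferior
#' endplate of the inferior end vertebra. Each tangent is given by a pair of
#' landmark points (x, y).
#'
#' @param superior 2 x 2 matrix (rows = points, cols = x, y) on the superior
#'   endplate tangent.
#' @param inferior 2 x 2 matrix on the inferior endplate tangent.
#' @return Angle in degrees, in [0, 90].
#' @examples
#' sup <- rbind(c(0, 0), c(10, 2))   # slope +0.2
#' inf <- rbind(c(0, 0), c(10, -2))  # slope -0.2
#' cobb_angle(sup, inf)              # 2 * atan(0.2) in degrees
#' @export
cobb_angle <- function(superior, inferior) {
  line_dir <- function(p, which) {
    p <- as.matrix(p)
    if (!all(dim(p) == c(2, 2))) abort("%s landmarks must be a 2 x 2 matrix", which)
    d <- p[2, ] - p[1, ]
    if (sqrt(sum(d^2)) < 1e-12)
      abort("%s endplate landmarks are coincident; cannot define a tangent", which)
    d
  }
  u <- line_dir(superior, "superior")
  v <- line_dir(inferior, "inferior")
  cosang <- abs(sum(u * v)) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  cosang <- min(1, max(0, cosang))
  acos(cosang) * 180 / pi
}

#' Classify a disc as affected or unaffected by the scoliotic curve
#'
#' In scoliosis patients, discs proximal (superior) to the stable vertebra of
#' the most distal curve are part of the deformity ("affected"); discs at or
#' distal to it are "unaffected". A disc lies entirely proximal to the stable
#' vertebra when its inferior adjacent vertebra is at or above it on the
#' L1..L5, S1 ladder; a disc touching the stable vertebra's superior endplate
#' therefore counts as affected, while the disc below it does not. L5/S1 can
#' never be affected when the stable vertebra is lumbar.
#'
#' @param segment Disc segment label(s), e.g. "L1/L2".
#' @param stable_vertebra Stable vertebra label, e.g. "L4" (lumbar: L1..L5).
#' @return Character vector "affected" / "unaffected".
#' @examples
#' classify_affection("L1/L2", "L4")  # affected
#' classify_affection("L4/L5", "L4")  # unaffected
#' @export
classify_affection <- function(segment, stable_vertebra) {
  sv <- vertebra_index(stable_vertebra)
  if (any(sv > 5L)) abort("stable vertebra must be lumbar (L1..L5)")
  inf <- segment_vertebrae(segment)[, "inf"]
  unname(ifelse(inf <= sv, "affected", "unaffected"))
}

#' Per-segment affected-disc counts for a set of patients
#'
#' Pure bookkeeping over patient metadata: applies [classify_affection()] to
#' every lumbar segment of every patient and tabulates affected discs per
#' segment and overall.
#'
#' @param stable_vertebrae Character vector, one stable vertebra per patient.
#' @return List with `per_segment` (named integer vector over the five
#'   segments), `total` affected discs, `n_discs` and `percent` affected.
#' @export
affection_table <- function(stable_vertebrae) {
  segs <- disc_segments()
  counts <- vapply(segs, function(s) {
    sum(classify_affection(rep(s, length(stable_vertebrae)),
                           stable_vertebrae) == "affected")
  }, integer(1))
  total <- sum(counts)
  n <- 5L * length(stable_vertebrae)
  list(per_segment = counts, total = total, n_discs = n,
       percent = 100 * total / n)
}

#' Default stable-vertebra assignment for simulated patients
#'
#' The generator's per-patient stable-vertebra levels. For 10 patients the
#' multiset {L1 x1, L2 x3, L3 x2, L4 x1, L5 x3} is assigned deterministically;
#' it reproduces the reference affected-disc distribution (9/6/4/3/0 across
#' L1/L2..L5/S1, 22 of 50 discs = 44%) under [classify_affection()]. For
#' other patient counts levels are sampled with the same proportions.
#'
#' @param n_patients Number of patients.
#' @param seed Seed used only when sampling (n != 10).
#' @return Character vector of stable vertebra labels.
#' @export
default_stable_vertebrae <- function(n_patients, seed = 1L) {
  base <- c("L1", "L2", "L2", "L2", "L3", "L3", "L4", "L5", "L5", "L5")
  if (n_patients == 10L) return(base)
  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  on.exit(restore_rng(old), add = TRUE)
  sample(c("L1", "L2", "L3", "L4", "L5"), n_patients, replace = TRUE,
         prob = c(1, 3, 2, 1, 3) / 10)
}
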