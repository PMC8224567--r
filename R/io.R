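#' Write a saturation-offset stack as NIfTI with a JSON sidecar
#'
#' The stack is stored as a 4D NIfTI volume (rows x cols x 1 x offsets); the
#' saturation offsets live in a JSON sidecar `{"offsets_ppm": [...],
#' "s0_index": null}` because the NIfTI header has no standard slot for them.
#'
#' @param stack rows x cols x offsets array of raw signals.
#' @param offsets Offsets (ppm), one per stack volume.
#' @param path Output path for the NIfTI file (`.nii`).
#' @param sidecar_path Output path for the sidecar; default replaces the
#'   extension with `.json`.
#' @param pixel_mm Pixel size recorded in the header (mm).
#' @return Invisibly, the NIfTI path.
#' @export
write_stack <- function(stack, offsets, path, sidecar_path = NULL,
                        pixel_mm = 1.6) {
  if (dim(stack)[3] != length(offsets))
    abort("stack has %d volumes but %d offsets", dim(stack)[3], length(offsets))
  if (is.null(sidecar_path)) sidecar_path <- sub("\\.nii(\\.gz)?$", ".json", path)
  arr <- array(stack, dim = c(dim(stack)[1], dim(stack)[2], 1L, dim(stack)[3]))
  img <- RNifti::asNifti(arr, pixdim = c(pixel_mm, pixel_mm, 1, 1))
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(offsets_ppm = offsets, s0_index = NULL),
                       sidecar_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a saturation-offset stack and its sidecar
#'
#' Validates that the sidecar offset count matches the stack's 4th dimension
#' and returns offsets in ascending ppm order, re-ordering the volumes
#' consistently (and logging) if the sidecar listed them descending or
#' shuffled.
#'
#' @param path NIfTI path.
#' @param sidecar_path Sidecar path; default derived from `path`.
#' @return List with `stack` (rows x cols x offsets) and `offsets` (ppm,
#'   ascending).
#' @export
read_stack <- function(path, sidecar_path = NULL) {
  if (is.null(sidecar_path)) sidecar_path <- sub("\\.nii(\\.gz)?$", ".json", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4) arr <- arr[, , 1, , drop = TRUE]
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  offs <- as.numeric(side$offsets_ppm)
  if (length(offs) != dim(arr)[3])
    abort("sidecar lists %d offsets but stack has %d volumes",
          length(offs), dim(arr)[3])
  ord <- order(offs)
  if (any(ord != seq_along(offs))) {
    log_msg("read_stack: re-ordering %s to ascending offsets", basename(path))
    arr <- arr[, , ord, drop = FALSE]
    offs <- offs[ord]
  }
  list(stack = arr, offsets = offs)
}

#' Write a single 2D map (B0, gag score, labels) as NIfTI
#'
#' Units and provenance go into the header description and a JSON sidecar.
#'
#' @param map Matrix (NA allowed).
#' @param path Output `.nii` path.
#' @param units Unit string recorded in the sidecar (e.g. "ppm", "percent").
#' @param extra Named list of extra sidecar fields (e.g. band, b0 map id).
#' @param pixel_mm Pixel size (mm).
#' @return Invisibly, the path.
#' @export
write_map <- function(map, path, units, extra = list(), pixel_mm = 1.6) {
  img <- RNifti::asNifti(array(map, dim = c(nrow(map), ncol(map), 1L)),
                         pixdim = c(pixel_mm, pixel_mm, 1))
  RNifti::writeNifti(img, path)
  side <- c(list(units = units), extra)
  jsonlite::write_json(side, sub("\\.nii(\\.gz)?$", ".json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Per-subject NIfTI stacks (CEST, WASSR, S0) with JSON sidecars under
#' `subjects/<id>/`, plus `truth.csv`, `metadata.csv` and the design as
#' `design.yaml`.
#'
#' @param cohort A rendered `gag_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gag_cohort"))
  if (!cohort$rendered) abort("cohort was simulated with render = FALSE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$subjects)) {
    sub <- cohort$subjects[[id]]
    sd <- file.path(dir, "subjects", id)
    dir.create(sd, recursive = TRUE, showWarnings = FALSE)
    px <- sub$phantom$pixel_mm
    write_stack(sub$cest, sub$cest_offsets, file.path(sd, "cest.nii"),
                pixel_mm = px)
    write_stack(sub$wassr, sub$wassr_offsets, file.path(sd, "wassr.nii"),
                pixel_mm = px)
    write_map(sub$s0, file.path(sd, "s0.nii"), units = "a.u.", pixel_mm = px)
    write_map(sub$phantom$labels, file.path(sd, "labels.nii"),
              units = "label", pixel_mm = px,
              extra = list(coding = "0 background, 1 bone, 10+s NP, 20+s AF"))
    write_map(sub$b0, file.path(sd, "b0_true.nii"), units = "ppm",
              pixel_mm = px)
  }
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  dn <- cohort$design
  yaml::write_yaml(list(
    n_controls = dn$n_controls, n_patients = dn$n_patients,
    region_means = lapply(dn$region_means, as.list),
    sd_subject = dn$sd_subject, sd_residual = dn$sd_residual,
    stable_vertebrae = dn$stable_vertebrae, seed = dn$seed),
    file.path(dir, "design.yaml"))
  invisible(dir)
}

# internal: tiny FNV-1a hash for provenance records
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}
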