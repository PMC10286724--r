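#' Voxel volume container
#'
#' A 3D binary occupancy grid with isotropic physical spacing, the material
#' map of a scanned or synthetic bone. By convention the third array index is
#' the slicing (proximodistal) axis after [orient_volume()]; physical
#' positions refer to voxel centers and voxel indices are 1-based in R.
#'
#' @param occupancy logical or 0/1 3D array.
#' @param spacing isotropic voxel edge length in mm.
#' @param origin physical position (mm) of the center of voxel (1,1,1).
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(occupancy, spacing, origin = c(0, 0, 0)) {
  if (length(dim(occupancy)) != 3L) stopf("occupancy must be a 3D array")
  if (!is.logical(occupancy)) occupancy <- array(occupancy != 0, dim = dim(occupancy))
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0) {
    stopf("spacing must be a single positive number (mm)")
  }
  if (!any(occupancy)) stopf("volume has no occupied voxels")
  structure(
    list(occupancy = occupancy, spacing = spacing, origin = as.numeric(origin)),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf(
    "<voxel_volume> %d x %d x %d voxels @ %.4g mm (%d occupied)\n",
    d[1], d[2], d[3], x$spacing, sum(x$occupancy)
  ))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$occupancy)

#' Write a voxel volume as a TIFF stack with a JSON sidecar
#'
#' One 8-bit page per slice along the third axis; the sidecar records the
#' isotropic spacing and origin, which plain TIFF cannot carry reliably.
#'
#' @param volume a [voxel_volume()].
#' @param path output `.tif` path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  d <- dim(volume$occupancy)
  pages <- lapply(seq_len(d[3]), function(k) {
    # tiff writes matrices row-major top-down; store slice as [y, x]
    t(volume$occupancy[, , k]) * 1
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  jsonlite::write_json(
    list(spacing_mm = volume$spacing, origin_mm = volume$origin,
         dim = d, axis_order = "xyz"),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a voxel volume written by [write_volume()]
#'
#' @param path `.tif` path with a `<path>.json` sidecar.
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stopf("volume file not found: %s", path)
  if (!file.exists(sidecar)) stopf("missing spacing sidecar: %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
  occ <- array(FALSE, dim = d)
  for (k in seq_along(pages)) occ[, , k] <- t(pages[[k]]) > 0.5
  voxel_volume(occ, spacing = meta$spacing_mm,
               origin = meta$origin_mm %||% c(0, 0, 0))
}

#' Physical coordinates (mm) of occupied voxel centers
#' @noRd
occupied_coords <- function(volume) {
  idx <- which(volume$occupancy, arr.ind = TRUE)
  sweep(
    (idx - 1) * volume$spacing, 2,
    volume$origin, `+`
  )
}
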