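# On-disk formats: NIfTI-1 volumes (32-bit float, RAS affine) with a
# JSON sidecar of identical basename carrying the non-spatial metadata
# (quantity, nuclide, time stamps, ...) that NIfTI cannot hold.

.sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

.grid_affine <- function(grid) {
  aff <- diag(4)
  aff[1, 1] <- grid$spacing[1]
  aff[2, 2] <- grid$spacing[2]
  aff[3, 3] <- grid$spacing[3]
  aff[1:3, 4] <- grid$origin
  aff
}

.write_nifti_array <- function(values, grid, path, datatype = "float") {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- grid$spacing
  aff <- structure(.grid_affine(grid), code = 2L)
  RNifti::sform(img) <- aff
  RNifti::qform(img) <- aff
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

.read_nifti_array <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  sp <- c(aff[1, 1], aff[2, 2], aff[3, 3])
  if (any(abs(aff[1:3, 1:3] - diag(sp)) > 1e-4))
    stop("format error: non-axis-aligned affine in ", path)
  if (any(sp <= 0))
    stop("format error: non-RAS (negative-spacing) affine in ", path)
  grid <- voxel_grid(dim(img)[1:3], sp, aff[1:3, 4])
  list(values = array(as.numeric(img), dim(img)[1:3]), grid = grid)
}

#' Write a volume image as NIfTI-1 + JSON sidecar
#'
#' Values are stored as 32-bit floats with an RAS affine; `quantity` and
#' `meta` go to a sidecar `.json` with the same basename.
#'
#' @param image a [volume_image()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @export
write_volume <- function(image, path) {
  .write_nifti_array(image$values, image$grid, path)
  jsonlite::write_json(
    list(quantity = image$quantity, meta = image$meta),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a volume image written by [write_volume()]
#'
#' @param path path to the `.nii`/`.nii.gz` file.
#' @return A [volume_image()]; grid metadata and sidecar fields are
#'   restored. Values are as precise as the 32-bit on-disk floats.
#' @export
read_volume <- function(path) {
  raw <- .read_nifti_array(path)
  side <- .sidecar_path(path)
  if (!file.exists(side)) stop("format error: missing sidecar ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  volume_image(raw$values, raw$grid, quantity = meta$quantity,
               meta = as.list(meta$meta))
}

#' Write a VOI mask as integer NIfTI-1 + JSON sidecar
#' @param mask a [voi_mask()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @export
write_mask <- function(mask, path) {
  .write_nifti_array(mask$labels, mask$grid, path, datatype = "int16")
  jsonlite::write_json(list(names = as.list(mask$names)),
                       .sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a VOI mask written by [write_mask()]
#' @param path path to the `.nii`/`.nii.gz` file.
#' @export
read_mask <- function(path) {
  raw <- .read_nifti_array(path)
  side <- .sidecar_path(path)
  if (!file.exists(side)) stop("format error: missing sidecar ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  voi_mask(array(as.integer(round(raw$values)), raw$grid$shape), raw$grid,
           unlist(meta$names))
}

#' Write a projection set as multi-frame NIfTI + JSON sidecar
#'
#' Views are stacked along the third axis; angles, per-view times,
#' window and seed go to the sidecar.
#'
#' @param p a projection set (see [forward_project()]).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @export
write_projections <- function(p, path) {
  g <- voxel_grid(dim(p$views), c(p$geom$det_pitch_mm, p$geom$det_pitch_mm, 1))
  .write_nifti_array(p$views, g, path)
  side <- list(angles_deg = p$angles_deg,
               time_per_view_s = p$geom$time_per_view_s,
               n_views = p$geom$n_views, heads = p$geom$heads,
               span_deg = p$geom$span_deg, radius_mm = p$geom$radius_mm,
               det_pitch_mm = p$geom$det_pitch_mm,
               window = p$window, nuclide = p$nuclide,
               noise = p$noise, seed = p$seed)
  jsonlite::write_json(side, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a projection set written by [write_projections()]
#' @param path path to the `.nii`/`.nii.gz` file.
#' @export
read_projections <- function(path) {
  raw <- .read_nifti_array(path)
  side <- .sidecar_path(path)
  if (!file.exists(side)) stop("format error: missing sidecar ", side)
  m <- jsonlite::read_json(side, simplifyVector = TRUE)
  geom <- acquisition_geometry(
    n_views = m$n_views, heads = m$heads, span_deg = m$span_deg,
    radius_mm = m$radius_mm, time_per_view_s = m$time_per_view_s,
    det_pitch_mm = m$det_pitch_mm)
  projection_set(raw$values, geom, window = m$window, nuclide = m$nuclide,
                 noise = isTRUE(m$noise),
                 seed = if (is.null(m$seed)) NA_integer_ else m$seed)
}
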