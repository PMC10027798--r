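# Shared voxel-grid data model and geometry rasterization.
#
# All modules share one convention: world coordinates in mm, axis order
# (x, y, z), and the voxel-centre convention (the grid origin is the
# world position of the centre of voxel index (1,1,1)).

#' Construct a voxel grid
#'
#' @param shape integer triple, number of voxels per axis (x, y, z).
#' @param spacing voxel size in mm; a scalar is recycled to all axes.
#' @param origin world position (mm) of the centre of voxel (1,1,1).
#'   Default `NULL` centres the grid on the world origin.
#' @return An object of class `voxel_grid` with fields `shape`,
#'   `spacing`, `origin`.
#' @export
voxel_grid <- function(shape, spacing, origin = NULL) {
  shape <- as.integer(round(shape))
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(shape) == 3L, length(spacing) == 3L)
  if (any(shape < 1L)) stop("grid shape must be >= 1 in every axis")
  if (any(spacing <= 0)) stop("grid spacing must be > 0 in every axis")
  if (is.null(origin)) origin <- -(shape - 1) / 2 * spacing
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L)
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d, spacing (%.4g, %.4g, %.4g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' World coordinates of the voxel centres along each axis
#' @param grid a [voxel_grid()].
#' @return list of three numeric vectors (mm).
#' @export
grid_axes <- function(grid) {
  lapply(1:3, function(k)
    grid$origin[k] + (seq_len(grid$shape[k]) - 1) * grid$spacing[k])
}

#' Voxel volume in ml
#' @param grid a [voxel_grid()].
#' @export
voxel_volume_ml <- function(grid) prod(grid$spacing) / 1000

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("voxel grids do not match")
  invisible(TRUE)
}

.quantities <- c("activity_conc_Bq_per_ml", "counts", "density_g_per_ml",
                 "mu_per_mm", "dose_Gy", "dose_Sv_RBE", "suv",
                 "tia_Bq_h_per_ml")

#' Construct a scalar volume image
#'
#' A 3-D scalar field (activity concentration, density, attenuation,
#' dose, ...) on a voxel grid, with a free-form metadata record
#' (nuclide, time stamp, applied RBE, ...).
#'
#' @param values 3-D numeric array matching `grid$shape`.
#' @param grid a [voxel_grid()].
#' @param quantity one of `"activity_conc_Bq_per_ml"`, `"counts"`,
#'   `"density_g_per_ml"`, `"mu_per_mm"`, `"dose_Gy"`, `"dose_Sv_RBE"`,
#'   `"suv"`, `"tia_Bq_h_per_ml"`.
#' @param meta named list of free-form metadata.
#' @export
volume_image <- function(values, grid, quantity, meta = list()) {
  quantity <- match.arg(quantity, .quantities)
  values <- as.array(values)
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("values shape does not equal grid shape")
  if (quantity %in% c("activity_conc_Bq_per_ml", "density_g_per_ml",
                      "mu_per_mm") && any(values < 0))
    stop(quantity, " values must be >= 0")
  structure(list(grid = grid, values = values, quantity = quantity,
                 meta = meta),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s, %d x %d x %d, range [%.4g, %.4g]\n",
              x$quantity, x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Construct a labelled VOI mask
#'
#' @param labels 3-D integer array (0 = background) matching `grid`.
#' @param grid a [voxel_grid()].
#' @param names named integer vector mapping VOI names to labels, e.g.
#'   `c(kidney_left = 1L, kidney_right = 2L)`.
#' @export
voi_mask <- function(labels, grid, names) {
  storage.mode(labels) <- "integer"
  if (!identical(as.integer(dim(labels)), grid$shape))
    stop("labels shape does not equal grid shape")
  present <- setdiff(sort(unique(as.integer(labels))), 0L)
  if (!all(present %in% names))
    stop("every nonzero label must have a name")
  structure(list(grid = grid, labels = labels, names = names),
            class = "voi_mask")
}

#' Look up a mask label by name or number
#' @param mask a [voi_mask()].
#' @param label integer label or VOI name.
#' @export
mask_label <- function(mask, label) {
  if (is.character(label)) {
    if (!label %in% names(mask$names)) stop("unknown VOI name: ", label)
    label <- mask$names[[label]]
  }
  label <- as.integer(label)
  if (!any(mask$labels == label)) stop("label ", label, " absent from mask")
  label
}

#' Geometric primitive for rasterization
#'
#' @param kind `"sphere"`, `"cylinder"` (axis along z) or `"ellipsoid"`.
#' @param center world centre (mm).
#' @param radius sphere/cylinder radius (mm).
#' @param height cylinder height (mm).
#' @param semi_axes ellipsoid semi-axes (mm triple).
#' @export
geometry_spec <- function(kind = c("sphere", "cylinder", "ellipsoid"),
                          center, radius = NULL, height = NULL,
                          semi_axes = NULL) {
  kind <- match.arg(kind)
  center <- as.numeric(center)
  stopifnot(length(center) == 3L)
  size <- switch(kind,
    sphere = {
      stopifnot(!is.null(radius), radius > 0)
      list(radius = radius)
    },
    cylinder = {
      stopifnot(!is.null(radius), radius > 0, !is.null(height), height > 0)
      list(radius = radius, height = height)
    },
    ellipsoid = {
      stopifnot(!is.null(semi_axes), length(semi_axes) == 3L,
                all(semi_axes > 0))
      list(semi_axes = as.numeric(semi_axes))
    })
  structure(c(list(kind = kind, center = center), size),
            class = "geometry_spec")
}

#' Analytic volume of a geometric primitive in ml
#' @param spec a [geometry_spec()].
#' @export
geometry_volume_ml <- function(spec) {
  v <- switch(spec$kind,
    sphere = 4 / 3 * pi * spec$radius^3,
    cylinder = pi * spec$radius^2 * spec$height,
    ellipsoid = 4 / 3 * pi * prod(spec$semi_axes))
  v / 1000
}

#' Rasterize a geometric solid onto a voxel grid
#'
#' Voxel membership is decided by centre inclusion (no partial-volume
#' weighting), matching common CT-contouring practice.
#'
#' @param spec a [geometry_spec()].
#' @param grid a [voxel_grid()].
#' @param label integer label to assign (default 1).
#' @param name VOI name for the label.
#' @return A binary [voi_mask()].
#' @export
rasterize_geometry <- function(spec, grid, label = 1L, name = "voi") {
  inside <- .inside_geometry(spec, grid)
  if (!any(inside))
    stop("geometry lies entirely outside the grid: empty mask")
  labels <- array(0L, grid$shape)
  labels[inside] <- as.integer(label)
  voi_mask(labels, grid, stats::setNames(as.integer(label), name))
}

.inside_geometry <- function(spec, grid) {
  ax <- grid_axes(grid)
  dx <- ax[[1]] - spec$center[1]
  dy <- ax[[2]] - spec$center[2]
  dz <- ax[[3]] - spec$center[3]
  switch(spec$kind,
    sphere = {
      r2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
      r2 <= spec$radius^2
    },
    cylinder = {
      rad <- outer(dx^2, dy^2, `+`) <= spec$radius^2
      axok <- abs(dz) <= spec$height / 2
      outer(rad, axok, `&`)
    },
    ellipsoid = {
      a <- spec$semi_axes
      q <- outer(outer((dx / a[1])^2, (dy / a[2])^2, `+`), (dz / a[3])^2, `+`)
      q <= 1
    })
}

#' Summary statistics of an image inside one VOI
#'
#' @param image a [volume_image()].
#' @param mask a [voi_mask()] on the identical grid.
#' @param label integer label or VOI name.
#' @return list with `mean`, `sd` (sample sd), `max`, `volume_ml`,
#'   `n_voxels`.
#' @export
mask_stats <- function(image, mask, label) {
  stop_if_grid_mismatch(image$grid, mask$grid)
  label <- mask_label(mask, label)
  v <- image$values[mask$labels == label]
  list(mean = mean(v),
       sd = if (length(v) > 1L) stats::sd(v) else 0,
       max = max(v),
       volume_ml = length(v) * voxel_volume_ml(image$grid),
       n_voxels = length(v))
}

#' Merge several single-label masks into one labelled mask
#'
#' @param masks list of [voi_mask()] objects on one common grid.
#' @param error_on_overlap stop if two masks claim one voxel.
#' @export
merge_masks <- function(masks, error_on_overlap = TRUE) {
  stopifnot(length(masks) >= 1L)
  grid <- masks[[1]]$grid
  labels <- array(0L, grid$shape)
  nm <- integer(0)
  for (m in masks) {
    stop_if_grid_mismatch(grid, m$grid)
    hit <- m$labels != 0L
    if (error_on_overlap && any(labels[hit] != 0L))
      stop("overlapping VOIs while merging masks")
    labels[hit] <- m$labels[hit]
    nm <- c(nm, m$names)
  }
  if (anyDuplicated(nm)) stop("duplicate labels while merging masks")
  voi_mask(labels, grid, nm)
}
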