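#' DCE-MRI examination container
#'
#' A `dce_series` holds one dynamic contrast-enhanced examination: a single
#' pre-contrast T1-weighted volume followed by the post-contrast volumes in
#' acquisition order, on a common voxel grid. Volumes are stored as 3D
#' arrays indexed `[x, y, z]`; axis 2 (`y`) is the anterior-posterior axis
#' with `y` increasing towards posterior, so world coordinates written in mm
#' always refer to this fixed orientation. Voxel `[1, 1, 1]` has world
#' coordinate `origin`, and voxel centres step by `spacing`.
#'
#' @param volumes list of 3D numeric arrays, pre-contrast first; all must
#'   share the same dimensions.
#' @param spacing numeric(3), voxel spacing in mm (all > 0).
#' @param origin numeric(3), world coordinate (mm) of the first voxel centre.
#' @param require_min_post if `TRUE`, enforce the ingest contract of at
#'   least three post-contrast volumes. Intermediate processing steps may
#'   construct series with fewer.
#' @return An object of class `dce_series`.
#' @export
dce_series <- function(volumes, spacing, origin = c(0, 0, 0),
                       require_min_post = FALSE) {
  stopifnot(is.list(volumes), length(volumes) >= 2L)
  dims <- lapply(volumes, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("all volumes must be 3D arrays")
  if (!all(vapply(dims, function(d) all(d == dims[[1]]), TRUE)))
    stop("all volumes must share the same grid shape")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive reals (mm)")
  if (require_min_post && length(volumes) < 4L)
    stop("a DCE examination requires at least three post-contrast volumes")
  structure(
    list(volumes = volumes, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$volumes[[1]])
  cat(sprintf("<dce_series> %d volumes (1 pre + %d post), grid %dx%dx%d, spacing %.2fx%.2fx%.2f mm\n",
              length(x$volumes), n_post(x), d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Number of post-contrast volumes in an examination
#' @param series a [dce_series()].
#' @return integer count of post-contrast volumes.
#' @export
n_post <- function(series) length(series$volumes) - 1L

#' Binary tumor mask aligned to an examination grid
#'
#' @param grid 3D array coercible to logical; `TRUE` marks tumor voxels.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param origin numeric(3) world coordinate of the first voxel centre.
#' @return An object of class `tumor_mask` with the voxel volume (mm^3)
#'   precomputed.
#' @export
tumor_mask <- function(grid, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(dim(grid)) == 3L, length(spacing) == 3L, all(spacing > 0))
  g <- array(as.logical(grid), dim = dim(grid))
  if (anyNA(g)) stop("mask grid contains NA")
  structure(
    list(grid = g, spacing = as.numeric(spacing), origin = as.numeric(origin),
         voxel_volume_mm3 = prod(spacing)),
    class = "tumor_mask")
}

#' @export
print.tumor_mask <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<tumor_mask> grid %dx%dx%d, %d voxels, %.1f mm^3\n",
              d[1], d[2], d[3], sum(x$grid), mask_volume(x)))
  invisible(x)
}

#' Tumor volume in mm^3
#' @param mask a [tumor_mask()].
#' @return voxel count times voxel volume, in mm^3.
#' @export
mask_volume <- function(mask) sum(mask$grid) * mask$voxel_volume_mm3

# World coordinates (mm) of voxel centres along one axis.
#' @noRd
axis_coords <- function(obj, axis) {
  n <- if (inherits(obj, "tumor_mask")) dim(obj$grid)[axis]
       else dim(obj$volumes[[1]])[axis]
  obj$origin[axis] + (seq_len(n) - 1) * obj$spacing[axis]
}
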