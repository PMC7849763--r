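#' 3D attenuation volume
#'
#' A `vol3d` is a numeric 3D array of linear attenuation coefficients
#' (mm^-1) with isotropic-or-not voxel spacing in mm. The volume is centered
#' on the rotation axis: the center of voxel `(1,1,1)` sits at
#' `-extent/2 + spacing/2` in world coordinates, axes ordered x (left-right),
#' y (posterior-anterior), z (inferior-superior).
#'
#' @param data numeric 3D array.
#' @param spacing voxel spacing in mm, length 3 (recycled from length 1).
#' @return a `vol3d` object.
#' @export
vol3d <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  spacing <- rep_len(as.double(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be positive and finite", call. = FALSE)
  structure(data, spacing = spacing, class = c("vol3d", "array"))
}

#' @export
print.vol3d <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<vol3d> %d x %d x %d voxels @ %s mm, range [%.4g, %.4g] mm^-1\n",
              d[1], d[2], d[3], paste(format(vol_spacing(x)), collapse = " x "),
              min(x), max(x)))
  invisible(x)
}

#' Voxel spacing of a volume or DVF, in mm
#' @param x a `vol3d` or `dvf3d`.
#' @return numeric length-3 spacing.
#' @export
vol_spacing <- function(x) attr(x, "spacing", exact = TRUE)

#' World coordinates of voxel centers along one axis
#'
#' The volume is centered on the isocenter, so coordinates run symmetrically
#' about zero.
#'
#' @param n number of voxels along the axis.
#' @param spacing voxel spacing (mm).
#' @return numeric vector of voxel-center positions (mm).
#' @export
axis_coords <- function(n, spacing) (seq_len(n) - (n + 1) / 2) * spacing

# rebuild a vol3d with the metadata of `like`
as_vol_like <- function(data, like) {
  if (!is.array(data)) dim(data) <- dim(like)
  vol3d(data, vol_spacing(like))
}

#' Dense deformation vector field
#'
#' A `dvf3d` stores per-voxel displacements in mm as a 4D array
#' `[nx, ny, nz, 3]` on the same grid as its companion volume. Fields follow
#' the pull-back convention used throughout the package: a field tagged
#' `"0->t"` produces the phase-t image from the reference by
#' `out(x) = mu0(x + v(x))`.
#'
#' @param data numeric 4D array with last dimension 3, or `NULL` with `dim`
#'   given to create a zero field.
#' @param spacing voxel spacing in mm.
#' @param direction `"0->t"` or `"t->0"`.
#' @param phase integer phase index (0-based), informational.
#' @param dim grid dimensions when `data` is `NULL`.
#' @return a `dvf3d` object.
#' @export
dvf3d <- function(data = NULL, spacing = c(1, 1, 1), direction = "0->t",
                  phase = NA_integer_, dim = NULL) {
  if (is.null(data)) {
    if (is.null(dim)) stop("either `data` or `dim` is required", call. = FALSE)
    data <- array(0, c(dim, 3L))
  }
  if (!is.array(data) || length(dim(data)) != 4L || dim(data)[4] != 3L)
    stop("`data` must be a 4D array with 3 components", call. = FALSE)
  if (any(!is.finite(data)))
    stop("displacement field contains non-finite values", call. = FALSE)
  direction <- match.arg(direction, c("0->t", "t->0"))
  spacing <- rep_len(as.double(spacing), 3L)
  structure(data, spacing = spacing, direction = direction,
            phase = as.integer(phase), class = c("dvf3d", "array"))
}

#' @export
print.dvf3d <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<dvf3d %s> %d x %d x %d voxels, max |v| = %.3f mm\n",
              attr(x, "direction"), d[1], d[2], d[3], max(abs(x))))
  invisible(x)
}

dvf_grid_dim <- function(dvf) dim(dvf)[1:3]

as_dvf_like <- function(data, like, direction = attr(like, "direction"),
                        phase = attr(like, "phase")) {
  if (!is.array(data)) dim(data) <- dim(like)
  dvf3d(data, vol_spacing(like), direction = direction, phase = phase)
}

check_same_grid <- function(a, b) {
  da <- dim(a)[1:3]; db <- dim(b)[1:3]
  if (!identical(as.integer(da), as.integer(db)))
    stop(sprintf("grid mismatch: %s vs %s", paste(da, collapse = "x"),
                 paste(db, collapse = "x")), call. = FALSE)
  sa <- vol_spacing(a); sb <- vol_spacing(b)
  if (!is.null(sa) && !is.null(sb) && max(abs(sa - sb)) > 1e-9)
    stop("voxel spacing mismatch", call. = FALSE)
  invisible(TRUE)
}

#' Resample a volume to a new grid over the same physical extent
#'
#' Trilinear, cell-center aligned; spacing is rescaled so the world extent is
#' preserved. Used by the multiresolution Demons pyramid.
#'
#' @param volume a `vol3d`.
#' @param new_dim target grid dimensions (length 3).
#' @return a `vol3d` on the new grid.
#' @export
resample_volume <- function(volume, new_dim) {
  d <- dim(volume)
  new_dim <- as.integer(new_dim)
  out <- cpp_resample(as.double(volume), as.integer(d), new_dim)
  dim(out) <- new_dim
  vol3d(out, vol_spacing(volume) * d / new_dim)
}

# central-difference spatial gradient of a volume, per-axis, units 1/mm * value
vol_gradient <- function(volume) {
  a <- unclass(volume)
  d <- dim(a)
  sp <- vol_spacing(volume)
  g <- array(0, c(d, 3L))
  idx <- function(n) list(lo = c(1L, seq_len(n - 1L)), hi = c(seq_len(n - 1L) + 1L, n),
                          den = c(1, rep(2, n - 2L), 1))
  ix <- idx(d[1]); g[, , , 1] <- (a[ix$hi, , ] - a[ix$lo, , ]) / (ix$den * sp[1])
  iy <- idx(d[2]); g[, , , 2] <- aperm(
    (aperm(a, c(2, 1, 3))[iy$hi, , ] - aperm(a, c(2, 1, 3))[iy$lo, , ]) / (iy$den * sp[2]),
    c(2, 1, 3))
  iz <- idx(d[3]); g[, , , 3] <- aperm(
    (aperm(a, c(3, 2, 1))[iz$hi, , ] - aperm(a, c(3, 2, 1))[iz$lo, , ]) / (iz$den * sp[3]),
    c(3, 2, 1))
  g
}
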