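#' Exact voxel decomposition of one cone-beam ray
#'
#' Siddon-style ray tracing: the source-to-pixel segment is clipped to the
#' volume grid and decomposed into the voxels it crosses with their exact
#' intersection lengths (the nonzero entries `a_in` of one row of the system
#' matrix). Rays that miss the grid return zero rows.
#'
#' @param geometry a [cone_beam_geometry()].
#' @param dim,spacing volume grid descriptor.
#' @param pixel detector pixel index `c(iu, iv)`, 1-based.
#' @param angle gantry angle, radians.
#' @return data.frame with voxel indices `i, j, k` (1-based) and
#'   `length` (mm).
#' @export
trace_ray <- function(geometry, dim, spacing, pixel, angle) {
  if (pixel[1] < 1 || pixel[1] > geometry$nu ||
      pixel[2] < 1 || pixel[2] > geometry$nv)
    stop("detector pixel outside the panel", call. = FALSE)
  if (any(dim < 1L)) stop("empty volume grid", call. = FALSE)
  res <- cpp_trace_ray(as.integer(dim), rep_len(as.double(spacing), 3L),
                       geometry$sad, geometry$sdd, geometry$nu, geometry$nv,
                       geometry$du, geometry$dv,
                       as.integer(pixel[1]) - 1L, as.integer(pixel[2]) - 1L,
                       angle)
  as.data.frame(res)
}

new_proj_stack <- function(data, angles, phase = NA_integer_) {
  structure(data, angles = as.double(angles), phase = as.integer(phase),
            class = c("proj_stack", "array"))
}

#' @export
print.proj_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<proj_stack> %d x %d px x %d views, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], min(x), max(x)))
  invisible(x)
}

#' Forward projection (line integrals) of a volume
#'
#' Computes `p_i = sum_n a_in mu_n` for every detector pixel and view using
#' the exact ray-tracing system matrix. Values are dimensionless line
#' integrals (mm^-1 times mm), i.e. log-transformed projections.
#'
#' @param volume a [vol3d()].
#' @param geometry a [cone_beam_geometry()].
#' @param angles gantry angles (radians) to project at; defaults to the
#'   geometry's first phase.
#' @param phase optional phase label stored on the stack.
#' @return a `proj_stack`: array `[nu, nv, n_views]` with an `angles`
#'   attribute.
#' @export
forward_project <- function(volume, geometry, angles = NULL,
                            phase = NA_integer_) {
  if (is.null(angles)) angles <- geometry$angles[[1]]
  p <- cpp_forward_project(as.double(volume), as.integer(dim(volume)),
                           vol_spacing(volume), geometry$sad, geometry$sdd,
                           geometry$nu, geometry$nv, geometry$du, geometry$dv,
                           as.double(angles))
  dim(p) <- c(geometry$nu, geometry$nv, length(angles))
  new_proj_stack(p, angles, phase)
}

#' Adjoint (back) projection
#'
#' Applies the exact transpose of the forward projector: each pixel value is
#' smeared along its traced ray with the intersection-length weights, so
#' `<A x, y> == <x, t(A) y>` to rounding error.
#'
#' @param projections a `proj_stack` (array with an `angles` attribute).
#' @param geometry a [cone_beam_geometry()].
#' @param dim,spacing target volume grid.
#' @return a [vol3d()] holding `t(A) p`.
#' @export
back_project <- function(projections, geometry, dim, spacing) {
  d <- base::dim(projections)
  if (d[1] != geometry$nu || d[2] != geometry$nv)
    stop("projection stack does not match the detector grid", call. = FALSE)
  angles <- attr(projections, "angles", exact = TRUE)
  if (length(angles) != d[3])
    stop("angle list does not match the view count", call. = FALSE)
  v <- cpp_back_project(as.double(projections), as.integer(dim),
                        rep_len(as.double(spacing), 3L),
                        geometry$sad, geometry$sdd, geometry$nu, geometry$nv,
                        geometry$du, geometry$dv, as.double(angles))
  dim(v) <- as.integer(dim)
  vol3d(v, spacing)
}

#' Phase-sorted projection set
#'
#' Container for per-phase stacks of log-transformed line integrals with
#' their gantry angles and the shared acquisition geometry.
#'
#' @param stacks list of `proj_stack` objects, one per phase (phase 0 first).
#' @param geometry the [cone_beam_geometry()] they were measured with.
#' @return a `projection_set`.
#' @export
projection_set <- function(stacks, geometry) {
  stopifnot(length(stacks) >= 1L)
  for (s in stacks) {
    if (any(!is.finite(s))) stop("projections contain non-finite values", call. = FALSE)
    if (dim(s)[3] != length(attr(s, "angles")))
      stop("view count does not match angle list", call. = FALSE)
  }
  structure(list(stacks = stacks, geometry = geometry),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("<projection_set> %d phase(s), %s views each, detector %d x %d\n",
              length(x$stacks),
              paste(unique(vapply(x$stacks, function(s) dim(s)[3], 1L)),
                    collapse = "/"),
              x$geometry$nu, x$geometry$nv))
  invisible(x)
}

#' @export
length.projection_set <- function(x) length(x$stacks)

#' Simulate the phase-sorted projections of a set of phase volumes
#'
#' Forward-projects each breathing-phase volume at its own gantry angles,
#' optionally adding Gaussian noise on the line integrals (a Poisson-derived
#' approximation used for robustness experiments; off by default).
#'
#' @param volumes list of [vol3d()] phase volumes (phase 0 first).
#' @param geometry a [cone_beam_geometry()] with one angle vector per phase.
#' @param noise_sd Gaussian noise standard deviation on the line integrals
#'   (0 = noise-free).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return a [projection_set()].
#' @export
simulate_projections <- function(volumes, geometry, noise_sd = 0, seed = 1L) {
  if (length(volumes) != n_phases_geom(geometry))
    stop("one angle vector per phase volume is required", call. = FALSE)
  stacks <- vector("list", length(volumes))
  for (t in seq_along(volumes)) {
    s <- forward_project(volumes[[t]], geometry, geometry$angles[[t]],
                         phase = t - 1L)
    if (noise_sd > 0) {
      set.seed(seed + t)
      s <- new_proj_stack(s + array(stats::rnorm(length(s), 0, noise_sd), dim(s)),
                          attr(s, "angles"), t - 1L)
    }
    stacks[[t]] <- s
  }
  projection_set(stacks, geometry)
}
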