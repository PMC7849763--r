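#' Circular cone-beam acquisition geometry
#'
#' Full-fan circular trajectory with a flat-panel detector. The gantry rotates
#' about the volume's z axis; at angle `a` the source sits at
#' `(SAD cos a, SAD sin a, 0)` and the detector plane is at distance
#' `SDD - SAD` beyond the axis, its `u` axis in-plane and `v` axis along z.
#' Defaults follow conventional LINAC-mounted CBCT values (SAD 1000 mm,
#' SDD 1500 mm).
#'
#' @param nu,nv detector columns and rows (pixels).
#' @param du,dv detector pixel pitch, mm.
#' @param angles gantry angles in radians: a list with one numeric vector per
#'   breathing phase (phase-sorted acquisition), or a single numeric vector
#'   for a static scan.
#' @param sad source-to-axis distance, mm.
#' @param sdd source-to-detector distance, mm.
#' @return a `cone_beam_geometry` object.
#' @export
cone_beam_geometry <- function(nu, nv, du = 1, dv = 1, angles,
                               sad = 1000, sdd = 1500) {
  if (!(sdd > sad && sad > 0)) stop("need SDD > SAD > 0", call. = FALSE)
  if (du <= 0 || dv <= 0) stop("detector pitch must be > 0", call. = FALSE)
  if (!is.list(angles)) angles <- list(angles)
  if (any(vapply(angles, length, 1L) < 1L))
    stop("need at least one angle per phase", call. = FALSE)
  structure(list(nu = as.integer(nu), nv = as.integer(nv),
                 du = du, dv = dv, angles = lapply(angles, as.double),
                 sad = sad, sdd = sdd),
            class = "cone_beam_geometry")
}

#' @export
print.cone_beam_geometry <- function(x, ...) {
  cat(sprintf("<cone_beam_geometry> %d x %d px @ %g x %g mm, SAD %g / SDD %g mm, %d phase(s) x %s views\n",
              x$nu, x$nv, x$du, x$dv, x$sad, x$sdd, length(x$angles),
              paste(unique(vapply(x$angles, length, 1L)), collapse = "/")))
  invisible(x)
}

n_phases_geom <- function(geometry) length(geometry$angles)

#' Phase-interleaved gantry angles for a phase-sorted scan
#'
#' Emulates phase sorting of a single slow rotation: consecutive projections
#' cycle through the breathing phases, so each phase receives
#' `views_per_phase` angles spread quasi-uniformly over the arc.
#'
#' @param n_phases number of breathing phases.
#' @param views_per_phase projections per phase.
#' @param arc total gantry arc in radians (default full rotation).
#' @return list of angle vectors, one per phase.
#' @export
phase_angle_set <- function(n_phases = 10L, views_per_phase = 20L,
                            arc = 2 * pi) {
  total <- n_phases * views_per_phase
  step <- arc / total
  lapply(seq_len(n_phases) - 1L, function(t)
    ((seq_len(views_per_phase) - 1L) * n_phases + t) * step)
}

#' Geometry sized to cover a volume grid
#'
#' Chooses a detector large enough that every voxel of the (centered) volume
#' projects inside the panel at every gantry angle, with a small margin.
#'
#' @param dim volume grid dimensions.
#' @param spacing voxel spacing, mm.
#' @param angles per-phase angle list (see [phase_angle_set()]).
#' @param pitch detector pixel pitch, mm (used for both axes).
#' @param sad,sdd source-to-axis / source-to-detector distances, mm.
#' @param margin fractional detector size margin.
#' @return a [cone_beam_geometry()].
#' @export
geometry_for_volume <- function(dim, spacing, angles, pitch = NULL,
                                sad = 1000, sdd = 1500, margin = 0.08) {
  ext <- dim * spacing
  if (is.null(pitch)) pitch <- max(spacing) * sdd / sad
  mag <- sdd / sad
  half_xy <- sqrt(ext[1]^2 + ext[2]^2) / 2
  nu <- 2L * as.integer(ceiling(half_xy * mag * (1 + margin) / pitch)) + 1L
  nv <- 2L * as.integer(ceiling(ext[3] / 2 * mag * (1 + margin) / pitch)) + 1L
  cone_beam_geometry(nu = nu, nv = nv, du = pitch, dv = pitch,
                     angles = angles, sad = sad, sdd = sdd)
}
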