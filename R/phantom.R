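#' Specification of the 10-phase digital thorax phantom
#'
#' A geometric-primitive stand-in for a programmable anthropomorphic breathing
#' phantom: elliptical-cylinder torso, two ellipsoidal lungs, a heart resting
#' between them, a hemispherical (paraboloid-capped) diaphragm dome, rib
#' rings, one intrapulmonary vessel and one tumor. Breathing follows a cosine
#' waveform over the respiratory period; lung contents (and the heart) move
#' mostly superior-inferior while the chest wall and ribs move only
#' anterior-posterior, producing a tangential sliding discontinuity at the
#' pleural interface. Organ positions scale with the grid extent so the same
#' anatomy is available at desk scale (default `64 x 64 x 48` at 2 mm) and at
#' full scale (`256 x 256 x 150` at 1 mm).
#'
#' @param grid_shape volume grid dimensions (x, y, z voxels).
#' @param voxel_mm voxel spacing, mm.
#' @param n_phases number of breathing phases (>= 2).
#' @param period_s respiratory period, seconds (default 4 s).
#' @param diaphragm_si_mm peak superior-inferior diaphragm excursion, mm
#'   (default 20 mm).
#' @param chest_ap_mm peak anterior-posterior chest-wall excursion, mm
#'   (default 12 mm).
#' @param heart_si_mm peak superior-inferior heart excursion, mm.
#' @param attenuation named attenuation table, mm^-1 (body, lung, heart, rib,
#'   vessel, tumor); lung must be below body.
#' @param tumor_center tumor center as a fraction of the grid extent
#'   (x, y, z in -0.5..0.5).
#' @param tumor_radius_mm tumor radius, mm.
#' @param edge_mm soft-edge width of every organ boundary, mm (`NULL`: about
#'   three quarters of the largest voxel dimension, at least 1 mm). Soft
#'   edges keep the phantom band-limited so threshold-based feature
#'   extraction can interpolate to sub-voxel positions.
#' @param seed RNG seed recorded for any stochastic downstream use (the
#'   phantom itself is deterministic).
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 48L), voxel_mm = c(2, 2, 2),
                         n_phases = 10L, period_s = 4, diaphragm_si_mm = 20,
                         chest_ap_mm = 12, heart_si_mm = 10,
                         attenuation = c(body = 0.035, lung = 0.005,
                                         heart = 0.042, rib = 0.065,
                                         vessel = 0.040, tumor = 0.050),
                         tumor_center = c(0.13, 0.08, 0.10),
                         tumor_radius_mm = 7, edge_mm = NULL, seed = 1L) {
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  voxel_mm <- rep_len(as.double(voxel_mm), 3L)
  if (n_phases < 2L) stop("`n_phases` must be >= 2", call. = FALSE)
  if (diaphragm_si_mm < 0) stop("`diaphragm_si_mm` must be >= 0", call. = FALSE)
  need <- c("body", "lung", "heart", "rib", "vessel", "tumor")
  if (!all(need %in% names(attenuation)))
    stop("attenuation table must name: ", paste(need, collapse = ", "), call. = FALSE)
  if (any(attenuation < 0)) stop("attenuation values must be >= 0", call. = FALSE)
  if (attenuation[["lung"]] >= attenuation[["body"]])
    stop("lung attenuation must be below body attenuation", call. = FALSE)
  if (is.null(edge_mm)) edge_mm <- max(1, 0.75 * max(voxel_mm))
  structure(list(grid_shape = grid_shape, voxel_mm = voxel_mm,
                 n_phases = as.integer(n_phases), period_s = period_s,
                 diaphragm_si_mm = diaphragm_si_mm, chest_ap_mm = chest_ap_mm,
                 heart_si_mm = heart_si_mm,
                 attenuation = attenuation[need],
                 tumor_center = rep_len(tumor_center, 3L),
                 tumor_radius_mm = tumor_radius_mm,
                 edge_mm = edge_mm, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s voxels @ %s mm, %d phases / %g s, SI %g mm, AP %g mm\n",
              paste(x$grid_shape, collapse = "x"),
              paste(x$voxel_mm, collapse = "x"),
              x$n_phases, x$period_s, x$diaphragm_si_mm, x$chest_ap_mm))
  invisible(x)
}

#' Cosine breathing weight of a phase
#'
#' `w(t) = (1 - cos(2 pi t / T)) / 2`, zero at the reference phase and
#' maximal (1) half a period later; all ground-truth displacements scale
#' with it.
#'
#' @param spec a [phantom_spec()].
#' @param phase 0-based phase index (vectorized).
#' @return weights in `[0, 1]`.
#' @export
phase_weight <- function(spec, phase) {
  (1 - cos(2 * pi * phase / spec$n_phases)) / 2
}

# organ layout in world mm, derived from the grid extent
phantom_layout <- function(spec) {
  E <- spec$grid_shape * spec$voxel_mm
  lung_c <- c(0.20 * E[1], 0.02 * E[2], 0.02 * E[3])
  lung_r <- c(0.155 * E[1], 0.23 * E[2], 0.38 * E[3])
  zb <- lung_c[3] - lung_r[3]
  za <- lung_c[3] + lung_r[3]
  Lz <- za - zb
  # heart over the left lung so its inferior edge always has lung below it
  heart_c <- c(-0.17 * E[1], 0, 0.05 * E[3])
  heart_r <- c(0.12 * E[1], 0.14 * E[2], 0.12 * E[3])
  list(
    E = E,
    torso_r = c(0.42 * E[1], 0.34 * E[2]),
    lungL_c = c(-lung_c[1], lung_c[2], lung_c[3]), lung_r = lung_r,
    lungR_c = lung_c,
    zb = zb, za = za, Lz = Lz,
    z_taper = zb + 0.5 * Lz,                     # SI amplitude = full below this
    heart_c = heart_c, heart_r = heart_r,
    heart_edge_z0 = heart_c[3] - heart_r[3],
    dome_apex = zb + 0.45 * Lz,
    dome_depth = 0.6 * Lz,
    rib_r = c(0.38 * E[1], 0.30 * E[2]), rib_tube_mm = 2.0,
    rib_z = (c(-0.27, -0.09, 0.09, 0.27)) * E[3],
    vessel_c = c(0.22 * E[1], -0.03 * E[2]), vessel_rad_mm = 2.5,
    vessel_z = c(zb + 0.15 * Lz, zb + 0.65 * Lz),
    tumor_c = spec$tumor_center * E,
    ap_s0 = 0.78                                  # AP ramp starts at this torso radius
  )
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# soft inside-indicator from a normalized radius s (s = 1 on the surface);
# r_eff converts (1 - s) to an approximate distance in mm
soft_in <- function(s, r_eff, edge) clamp01(0.5 + (1 - s) * r_eff / edge)

coord_arrays <- function(spec) {
  d <- spec$grid_shape; sp <- spec$voxel_mm
  x <- axis_coords(d[1], sp[1]); y <- axis_coords(d[2], sp[2])
  z <- axis_coords(d[3], sp[3])
  list(X = array(x, d),
       Y = array(rep(y, each = d[1]), d),
       Z = array(rep(z, each = d[1] * d[2]), d))
}

# analytic ground-truth displacement (pull-back, mm) at world coordinates,
# for breathing weight w
phantom_motion_at <- function(spec, L, X, Y, Z, w) {
  if (w == 0) {
    zero <- array(0, dim(X))
    return(list(vx = zero, vy = zero, vz = zero))
  }
  band <- max(spec$voxel_mm)
  # interior (pleural cavity contents): lungs plus the heart's swept ellipsoid
  sL <- sqrt(((X - L$lungL_c[1]) / L$lung_r[1])^2 +
             ((Y - L$lungL_c[2]) / L$lung_r[2])^2 +
             ((Z - L$lungL_c[3]) / L$lung_r[3])^2)
  sR <- sqrt(((X - L$lungR_c[1]) / L$lung_r[1])^2 +
             ((Y - L$lungR_c[2]) / L$lung_r[2])^2 +
             ((Z - L$lungR_c[3]) / L$lung_r[3])^2)
  hs_c <- L$heart_c - c(0, 0, spec$heart_si_mm / 2)
  hs_r <- L$heart_r + c(2, 2, spec$heart_si_mm / 2 + 2)
  sH <- sqrt(((X - hs_c[1]) / hs_r[1])^2 + ((Y - hs_c[2]) / hs_r[2])^2 +
             ((Z - hs_c[3]) / hs_r[3])^2)
  rmin_l <- min(L$lung_r); rmin_h <- min(hs_r)
  dist_in <- pmax((1 - sL) * rmin_l, (1 - sR) * rmin_l, (1 - sH) * rmin_h)
  m <- clamp01(dist_in / band)                  # 1-voxel transition band
  # SI amplitude: full diaphragm excursion low in the cavity, tapering to 0 at
  # the apex; the heart column carries its own (smaller) amplitude
  a_z <- clamp01((L$za - Z) / (L$za - L$z_taper))
  fq <- sqrt(((X - L$heart_c[1]) / (L$heart_r[1] + 6))^2 +
             ((Y - L$heart_c[2]) / (L$heart_r[2] + 6))^2)
  hb <- soft_in(fq, min(L$heart_r[1:2] + 6), 6)
  A_si <- hb * spec$heart_si_mm + (1 - hb) * spec$diaphragm_si_mm * a_z
  vz <- A_si * w * m
  # AP chest-wall motion: ramps from the pleural margin to the anterior skin,
  # zero inside the cavity and over the posterior half (patient supine)
  st <- sqrt((X / L$torso_r[1])^2 + (Y / L$torso_r[2])^2)
  ramp <- clamp01((st - L$ap_s0) / (1 - L$ap_s0)) * clamp01(Y / 10)
  vy <- -spec$chest_ap_mm * w * ramp
  list(vx = array(0, dim(X)), vy = vy, vz = vz)
}

# static reference anatomy evaluated at arbitrary world coordinates
phantom_reference_at <- function(spec, L, X, Y, Z) {
  at <- spec$attenuation; e <- spec$edge_mm
  mu <- array(0, dim(X))
  mix <- function(mu, val, a) mu * (1 - a) + val * a
  # torso (elliptical cylinder, soft lateral surface, hard z ends at the grid)
  st <- sqrt((X / L$torso_r[1])^2 + (Y / L$torso_r[2])^2)
  mu <- mix(mu, at[["body"]], soft_in(st, min(L$torso_r), e))
  # lungs
  sL <- sqrt(((X - L$lungL_c[1]) / L$lung_r[1])^2 +
             ((Y - L$lungL_c[2]) / L$lung_r[2])^2 +
             ((Z - L$lungL_c[3]) / L$lung_r[3])^2)
  sR <- sqrt(((X - L$lungR_c[1]) / L$lung_r[1])^2 +
             ((Y - L$lungR_c[2]) / L$lung_r[2])^2 +
             ((Z - L$lungR_c[3]) / L$lung_r[3])^2)
  a_lung <- pmax(soft_in(sL, min(L$lung_r), e), soft_in(sR, min(L$lung_r), e))
  mu <- mix(mu, at[["lung"]], a_lung)
  # diaphragm dome intruding into the right lung base (body tissue)
  fp <- ((X - L$lungR_c[1]) / (0.85 * L$lung_r[1]))^2 +
        ((Y - L$lungR_c[2]) / (0.85 * L$lung_r[2]))^2
  zdome <- L$dome_apex - fp * L$dome_depth
  a_dome <- clamp01((zdome - Z) / e + 0.5) * a_lung * clamp01(2 - fp)
  mu <- mix(mu, at[["body"]], a_dome)
  # heart
  sH <- sqrt(((X - L$heart_c[1]) / L$heart_r[1])^2 +
             ((Y - L$heart_c[2]) / L$heart_r[2])^2 +
             ((Z - L$heart_c[3]) / L$heart_r[3])^2)
  mu <- mix(mu, at[["heart"]], soft_in(sH, min(L$heart_r), e))
  # vessel (vertical cylinder in the right lung)
  rv <- sqrt((X - L$vessel_c[1])^2 + (Y - L$vessel_c[2])^2)
  a_ves <- clamp01((L$vessel_rad_mm - rv) / e + 0.5) *
    clamp01((Z - L$vessel_z[1]) / e + 0.5) * clamp01((L$vessel_z[2] - Z) / e + 0.5)
  mu <- mix(mu, at[["vessel"]], a_ves)
  # tumor (sphere in the right lung)
  rt <- sqrt((X - L$tumor_c[1])^2 + (Y - L$tumor_c[2])^2 + (Z - L$tumor_c[3])^2)
  mu <- mix(mu, at[["tumor"]], clamp01((spec$tumor_radius_mm - rt) / e + 0.5))
  # rib rings in the chest wall
  sr <- sqrt((X / L$rib_r[1])^2 + (Y / L$rib_r[2])^2)
  drad <- abs(1 - sr) * min(L$rib_r)
  for (zr in L$rib_z) {
    drib <- sqrt(drad^2 + (Z - zr)^2)
    mu <- mix(mu, at[["rib"]], clamp01((L$rib_tube_mm - drib) / e + 0.5))
  }
  mu
}

# hard per-phase lung indicator at world coordinates (reference frame)
phantom_lung_hard_at <- function(spec, L, X, Y, Z) {
  inl <- (((X - L$lungL_c[1]) / L$lung_r[1])^2 +
          ((Y - L$lungL_c[2]) / L$lung_r[2])^2 +
          ((Z - L$lungL_c[3]) / L$lung_r[3])^2) <= 1 |
         (((X - L$lungR_c[1]) / L$lung_r[1])^2 +
          ((Y - L$lungR_c[2]) / L$lung_r[2])^2 +
          ((Z - L$lungR_c[3]) / L$lung_r[3])^2) <= 1
  fp <- ((X - L$lungR_c[1]) / (0.85 * L$lung_r[1]))^2 +
        ((Y - L$lungR_c[2]) / (0.85 * L$lung_r[2]))^2
  dome <- (Z <= L$dome_apex - fp * L$dome_depth) & (fp <= 2)
  heart <- (((X - L$heart_c[1]) / L$heart_r[1])^2 +
            ((Y - L$heart_c[2]) / L$heart_r[2])^2 +
            ((Z - L$heart_c[3]) / L$heart_r[3])^2) <= 1
  ves <- (sqrt((X - L$vessel_c[1])^2 + (Y - L$vessel_c[2])^2) <= L$vessel_rad_mm) &
         Z >= L$vessel_z[1] & Z <= L$vessel_z[2]
  tum <- ((X - L$tumor_c[1])^2 + (Y - L$tumor_c[2])^2 +
          (Z - L$tumor_c[3])^2) <= spec$tumor_radius_mm^2
  inl & !dome & !heart & !ves & !tum
}

#' Build one breathing phase of the digital thorax phantom
#'
#' Evaluates the analytic reference anatomy at coordinates displaced by the
#' phase's ground-truth motion (`mu_t(x) = mu_0(x + v_t(x))`, evaluated
#' exactly, not by resampling a grid), so each phase volume is consistent
#' with [ground_truth_motion()] up to interpolation error only.
#'
#' @param spec a [phantom_spec()].
#' @param phase 0-based phase index in `0 .. n_phases - 1`.
#' @return a [vol3d()] attenuation volume (mm^-1).
#' @export
build_phantom_phase <- function(spec, phase) {
  if (phase < 0 || phase >= spec$n_phases)
    stop(sprintf("phase %d out of range 0..%d", phase, spec$n_phases - 1L),
         call. = FALSE)
  L <- phantom_layout(spec)
  co <- coord_arrays(spec)
  w <- phase_weight(spec, phase)
  v <- phantom_motion_at(spec, L, co$X, co$Y, co$Z, w)
  mu <- phantom_reference_at(spec, L, co$X + v$vx, co$Y + v$vy, co$Z + v$vz)
  vol3d(mu, spec$voxel_mm)
}

#' All phases of the phantom
#' @param spec a [phantom_spec()].
#' @return list of [vol3d()], phase 0 first.
#' @export
build_phantom_4d <- function(spec) {
  lapply(seq_len(spec$n_phases) - 1L, function(t) build_phantom_phase(spec, t))
}

#' Analytic ground-truth motion of the phantom
#'
#' Returns, per phase: the pull-back deformation field `v^{0->t}` (mm) that
#' reproduces the phase volume from the reference (`warp_volume(mu0, v)`),
#' the binary lung mask, and the inferior heart-edge z-position; plus the
#' static pleural-interface voxel set where the tangential sliding
#' discontinuity lives.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `dvfs` (list of [dvf3d()], `"0->t"`),
#'   `lung_masks` (list of logical arrays), `heart_edge_z` (numeric, mm),
#'   `interface` (logical array of pleural boundary voxels) and
#'   `phase_weights`.
#' @export
ground_truth_motion <- function(spec) {
  L <- phantom_layout(spec)
  co <- coord_arrays(spec)
  d <- spec$grid_shape
  dvfs <- vector("list", spec$n_phases)
  masks <- vector("list", spec$n_phases)
  for (t in seq_len(spec$n_phases) - 1L) {
    w <- phase_weight(spec, t)
    v <- phantom_motion_at(spec, L, co$X, co$Y, co$Z, w)
    arr <- array(0, c(d, 3L))
    arr[, , , 1] <- v$vx; arr[, , , 2] <- v$vy; arr[, , , 3] <- v$vz
    dvfs[[t + 1L]] <- dvf3d(arr, spec$voxel_mm, direction = "0->t", phase = t)
    masks[[t + 1L]] <- phantom_lung_hard_at(spec, L, co$X + v$vx, co$Y + v$vy,
                                            co$Z + v$vz)
  }
  # pleural interface: boundary voxels of the static cavity contents
  # (both lungs plus the heart's swept ellipsoid), where the tangential
  # displacement discontinuity lives
  hs_c <- L$heart_c - c(0, 0, spec$heart_si_mm / 2)
  hs_r <- L$heart_r + c(2, 2, spec$heart_si_mm / 2 + 2)
  inl <- (((co$X - L$lungL_c[1]) / L$lung_r[1])^2 +
          ((co$Y - L$lungL_c[2]) / L$lung_r[2])^2 +
          ((co$Z - L$lungL_c[3]) / L$lung_r[3])^2) <= 1 |
         (((co$X - L$lungR_c[1]) / L$lung_r[1])^2 +
          ((co$Y - L$lungR_c[2]) / L$lung_r[2])^2 +
          ((co$Z - L$lungR_c[3]) / L$lung_r[3])^2) <= 1 |
         (((co$X - hs_c[1]) / hs_r[1])^2 +
          ((co$Y - hs_c[2]) / hs_r[2])^2 +
          ((co$Z - hs_c[3]) / hs_r[3])^2) <= 1
  lab <- inl
  erode6 <- function(m) {
    out <- m
    d <- dim(m)
    sh <- function(m, ax, by) {
      o <- array(FALSE, d)
      idx_src <- idx_dst <- lapply(d, seq_len)
      n <- d[ax]
      if (by > 0) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
      else { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
      o[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
        m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
      o
    }
    for (ax in 1:3) for (by in c(1, -1)) out <- out & sh(m, ax, by)
    out
  }
  interface <- lab & !erode6(lab)
  list(dvfs = dvfs, lung_masks = masks,
       heart_edge_z = heart_edge_truth(spec),
       interface = interface,
       phase_weights = phase_weight(spec, seq_len(spec$n_phases) - 1L))
}

#' Ground-truth inferior heart-edge trajectory
#'
#' The heart column carries a constant superior-inferior amplitude
#' (`heart_si_mm`), so the inferior heart edge sits at
#' `z0 - heart_si_mm * w(t)` exactly.
#'
#' @param spec a [phantom_spec()].
#' @return numeric vector of z positions (mm), one per phase.
#' @export
heart_edge_truth <- function(spec) {
  L <- phantom_layout(spec)
  L$heart_edge_z0 - spec$heart_si_mm *
    phase_weight(spec, seq_len(spec$n_phases) - 1L)
}

#' Region of interest around the heart's inferior edge
#'
#' Index ranges of a small box of columns through the heart center spanning
#' the edge's full excursion; used for threshold-based trajectory extraction.
#'
#' @param spec a [phantom_spec()].
#' @param margin_mm extra z margin, mm.
#' @return list with `xlim`, `ylim`, `zlim` (1-based index ranges) and
#'   `threshold` (midpoint of heart and lung attenuation).
#' @export
heart_edge_roi <- function(spec, margin_mm = 6) {
  L <- phantom_layout(spec)
  d <- spec$grid_shape; sp <- spec$voxel_mm
  to_idx <- function(mm, ax) {
    i <- round(mm / sp[ax] + (d[ax] + 1) / 2)
    pmin(pmax(i, 1L), d[ax])
  }
  xr <- to_idx(L$heart_c[1] + c(-0.3, 0.3) * L$heart_r[1], 1)
  yr <- to_idx(L$heart_c[2] + c(-0.25, 0.25) * L$heart_r[2], 2)
  zr <- to_idx(c(L$heart_edge_z0 - spec$heart_si_mm - margin_mm,
                 L$heart_edge_z0 + margin_mm), 3)
  list(xlim = xr, ylim = yr, zlim = zr,
       threshold = (spec$attenuation[["heart"]] + spec$attenuation[["lung"]]) / 2)
}
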