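#' Iterative reconstruction settings
#'
#' @param lambda SART relaxation factor in `(0, 1]`.
#' @param n_iter number of passes over all views.
#' @param lambda_decay multiplicative relaxation decay per pass.
#' @param positivity clamp negative attenuation to zero after each pass.
#' @param tv_weight total-variation step scale (0 disables the TV stage, in
#'   which case [tv_reconstruct()] reduces to plain SART).
#' @param tv_steps TV gradient-descent steps interleaved with each SART pass.
#' @param tol stop when the relative projection-residual decrease falls below
#'   this (0 = run the full budget).
#' @return a `recon_config` list.
#' @export
recon_config <- function(lambda = 0.8, n_iter = 20L, lambda_decay = 0.95,
                         positivity = TRUE, tv_weight = 0.3, tv_steps = 10L,
                         tol = 0) {
  if (!(lambda > 0 && lambda <= 1)) stop("need 0 < lambda <= 1", call. = FALSE)
  if (n_iter < 1L) stop("need n_iter >= 1", call. = FALSE)
  structure(list(lambda = lambda, n_iter = as.integer(n_iter),
                 lambda_decay = lambda_decay, positivity = positivity,
                 tv_weight = tv_weight, tv_steps = as.integer(tv_steps),
                 tol = tol),
            class = "recon_config")
}

eps_div <- 1e-10

as_stack_list <- function(projections) {
  if (inherits(projections, "projection_set")) projections$stacks
  else list(projections)
}

# volume-independent SART ingredients for one stack: ray intersection sums
# (forward projection of ones) and voxel weight sums (backprojection of the
# ray indicator); cached across passes
sart_cache_stack <- function(stack, geometry, d, sp) {
  angles <- attr(stack, "angles", exact = TRUE)
  ones <- vol3d(array(1, d), sp)
  raysum <- forward_project(ones, geometry, angles)
  wstack <- new_proj_stack(array(as.numeric(raysum > eps_div), dim(stack)),
                           angles)
  den <- back_project(wstack, geometry, d, sp)
  list(raysum = unclass(raysum), den = unclass(den), angles = angles)
}

# SART ingredients for one stack: ray-normalized residual backprojection and
# the voxel weight sum; rays with zero intersection sum are skipped
sart_terms <- function(volume, stack, geometry, cache = NULL) {
  d <- dim(volume); sp <- vol_spacing(volume)
  if (is.null(cache)) cache <- sart_cache_stack(stack, geometry, d, sp)
  p_est <- forward_project(volume, geometry, cache$angles)
  resid <- unclass(stack) - unclass(p_est)
  rn <- ifelse(cache$raysum > eps_div, resid / cache$raysum, 0)
  dim(rn) <- dim(stack)
  num <- back_project(new_proj_stack(rn, cache$angles), geometry, d, sp)
  list(num = unclass(num), den = cache$den,
       resid_norm = sqrt(sum(resid^2)))
}

#' One SART pass over all views
#'
#' Simultaneous algebraic update: every voxel moves by the relaxed,
#' doubly-normalized backprojection of all ray residuals,
#' `mu += lambda * [t(A)((p - A mu)/raysum)] / voxelsum`. Rays that miss the
#' volume and voxels hit by no ray are left untouched. A `projection_set`
#' pools every phase's views into the single pass.
#'
#' @param volume current estimate ([vol3d()]).
#' @param projections a `proj_stack` or [projection_set()].
#' @param geometry a [cone_beam_geometry()].
#' @param config a [recon_config()] (only `lambda` and `positivity` used).
#' @return updated [vol3d()] with attribute `resid_norm`.
#' @export
sart_pass <- function(volume, projections, geometry, config = recon_config()) {
  sart_pass_cached(volume, as_stack_list(projections), geometry, NULL,
                   config$lambda, config$positivity)
}

sart_pass_cached <- function(volume, stacks, geometry, caches, lambda,
                             positivity) {
  d <- dim(volume)
  num <- array(0, d); den <- array(0, d); rn2 <- 0
  for (si in seq_along(stacks)) {
    tm <- sart_terms(volume, stacks[[si]], geometry,
                     if (is.null(caches)) NULL else caches[[si]])
    num <- num + tm$num
    den <- den + tm$den
    rn2 <- rn2 + tm$resid_norm^2
  }
  upd <- ifelse(den > eps_div, num / den, 0)
  out <- unclass(volume) + lambda * upd
  if (positivity) out[out < 0] <- 0
  out <- as_vol_like(out, volume)
  attr(out, "resid_norm") <- sqrt(rn2)
  out
}

#' Plain SART reconstruction
#'
#' Repeated [sart_pass()]es with decaying relaxation, starting from zero (or
#' a supplied initial volume).
#'
#' @inheritParams sart_pass
#' @param dim,spacing grid of the reconstruction (ignored when `init` given).
#' @param init optional initial [vol3d()].
#' @return a [vol3d()] with attribute `resid_history`.
#' @export
sart_reconstruct <- function(projections, geometry, dim, spacing,
                             config = recon_config(), init = NULL) {
  vol <- if (is.null(init)) vol3d(array(0, dim), spacing) else init
  stacks <- as_stack_list(projections)
  d <- base::dim(vol); sp <- vol_spacing(vol)
  caches <- lapply(stacks, sart_cache_stack, geometry = geometry, d = d, sp = sp)
  lam <- config$lambda
  hist <- numeric(0)
  for (it in seq_len(config$n_iter)) {
    vol <- sart_pass_cached(vol, stacks, geometry, caches, lam,
                            config$positivity)
    hist <- c(hist, attr(vol, "resid_norm"))
    lam <- lam * config$lambda_decay
    if (config$tol > 0 && length(hist) > 1 &&
        abs(diff(utils::tail(hist, 2))) < config$tol * hist[1]) break
  }
  attr(vol, "resid_history") <- hist
  vol
}

#' Motion-compensated SART: one reference phase from all projections
#'
#' Each phase's ray residuals are backprojected and normalized in that
#' phase's own frame, then mapped into the reference (0%) frame through the
#' inverse deformation field's interpolation action before updating the
#' single reference volume — so all phases' projections sharpen one image.
#' With identity fields the update is exactly the pooled [sart_pass()].
#'
#' @param projections a [projection_set()] with one stack per phase
#'   (phase 0 first).
#' @param inverse_dvfs list of `"t->0"` [dvf3d()] fields, one per phase;
#'   `NULL` entries (and phase 0) mean identity.
#' @param geometry a [cone_beam_geometry()].
#' @param config a [recon_config()].
#' @param dim,spacing reconstruction grid (ignored when `init` given).
#' @param init optional initial reference volume.
#' @param forward_dvfs optional list of `"0->t"` fields used to deform the
#'   current reference into each phase for the residual; inverted from
#'   `inverse_dvfs` when omitted.
#' @return reference-phase [vol3d()] with attribute `resid_history`.
#' @export
msart_reconstruct <- function(projections, inverse_dvfs, geometry,
                              config = recon_config(), dim = NULL,
                              spacing = NULL, init = NULL,
                              forward_dvfs = NULL) {
  stacks <- projections$stacks
  np <- length(stacks)
  if (length(inverse_dvfs) != np)
    stop("need one inverse DVF entry per phase (NULL for identity)", call. = FALSE)
  if (is.null(init)) {
    if (is.null(dim) || is.null(spacing))
      stop("`dim` and `spacing` are required without `init`", call. = FALSE)
    init <- vol3d(array(0, dim), spacing)
  }
  d <- base::dim(init); sp <- vol_spacing(init)
  if (is.null(forward_dvfs))
    forward_dvfs <- lapply(inverse_dvfs, function(v)
      if (is.null(v) || max(abs(v)) == 0) NULL else invert_dvf(v))
  vol <- init
  lam <- config$lambda
  hist <- numeric(0)
  caches <- lapply(stacks, sart_cache_stack, geometry = geometry, d = d, sp = sp)
  # the mapped voxel-weight sums depend only on the fields: compute once
  den_mapped <- vector("list", np)
  for (t in seq_len(np)) {
    vi <- inverse_dvfs[[t]]
    den_mapped[[t]] <- if (is.null(vi) || max(abs(vi)) == 0) caches[[t]]$den
      else unclass(warp_volume(vol3d(caches[[t]]$den, sp), vi))
  }
  for (it in seq_len(config$n_iter)) {
    num <- array(0, d); den <- array(0, d); rn2 <- 0
    for (t in seq_len(np)) {
      vf <- forward_dvfs[[t]]
      vi <- inverse_dvfs[[t]]
      mu_t <- if (is.null(vf)) vol else warp_volume(vol, vf)
      tm <- sart_terms(mu_t, stacks[[t]], geometry, caches[[t]])
      if (is.null(vi) || max(abs(vi)) == 0) {
        num <- num + tm$num
      } else {
        num <- num + unclass(warp_volume(as_vol_like(tm$num, vol), vi))
      }
      den <- den + den_mapped[[t]]
      rn2 <- rn2 + tm$resid_norm^2
    }
    upd <- ifelse(den > eps_div, num / den, 0)
    out <- unclass(vol) + lam * upd
    if (config$positivity) out[out < 0] <- 0
    vol <- as_vol_like(out, vol)
    hist <- c(hist, sqrt(rn2))
    lam <- lam * config$lambda_decay
    if (config$tol > 0 && length(hist) > 1 &&
        abs(diff(utils::tail(hist, 2))) < config$tol * hist[1]) break
  }
  attr(vol, "resid_history") <- hist
  vol
}

# smoothed isotropic total variation and its gradient
tv_value <- function(a, sp, eps = 1e-8) {
  gx <- fwd_diff(a, 1, sp[1]); gy <- fwd_diff(a, 2, sp[2]); gz <- fwd_diff(a, 3, sp[3])
  sum(sqrt(gx^2 + gy^2 + gz^2 + eps^2))
}

tv_gradient <- function(a, sp, eps = 1e-8) {
  gx <- fwd_diff(a, 1, sp[1]); gy <- fwd_diff(a, 2, sp[2]); gz <- fwd_diff(a, 3, sp[3])
  mag <- sqrt(gx^2 + gy^2 + gz^2 + eps^2)
  px <- gx / mag; py <- gy / mag; pz <- gz / mag
  shift_back <- function(p, ax) {
    d <- dim(p); n <- d[ax]
    out <- array(0, d)
    hi <- slice.index(p, ax) >= 2L
    lo <- slice.index(p, ax) <= n - 1L
    out[hi] <- p[lo]
    out
  }
  (-px + shift_back(px, 1)) / sp[1] +
    (-py + shift_back(py, 2)) / sp[2] +
    (-pz + shift_back(pz, 3)) / sp[3]
}

#' Total-variation-regularized reconstruction (ASD-POCS style)
#'
#' Alternates a SART data pass with a few gradient-descent steps on smoothed
#' isotropic total variation; the TV step length starts at
#' `tv_weight * max |SART update|` and is Armijo-backtracked so TV never
#' increases. Used to produce noise-suppressed per-phase initial images.
#'
#' @inheritParams sart_reconstruct
#' @return a [vol3d()] with attribute `resid_history`.
#' @export
tv_reconstruct <- function(projections, geometry, dim, spacing,
                           config = recon_config(), init = NULL) {
  vol <- if (is.null(init)) vol3d(array(0, dim), spacing) else init
  sp <- vol_spacing(vol)
  stacks <- as_stack_list(projections)
  caches <- lapply(stacks, sart_cache_stack, geometry = geometry,
                   d = base::dim(vol), sp = sp)
  lam <- config$lambda
  hist <- numeric(0)
  for (it in seq_len(config$n_iter)) {
    prev <- unclass(vol)
    vol <- sart_pass_cached(vol, stacks, geometry, caches, lam,
                            config$positivity)
    hist <- c(hist, attr(vol, "resid_norm"))
    if (config$tv_weight > 0 && config$tv_steps > 0L) {
      a <- unclass(vol)
      step <- config$tv_weight * max(abs(a - prev))
      for (s in seq_len(config$tv_steps)) {
        g <- tv_gradient(a, sp)
        gmax <- max(abs(g))
        if (gmax < eps_div || step < eps_div) break
        f0 <- tv_value(a, sp)
        accepted <- FALSE
        st <- step
        for (ls in 1:6) {
          cand <- a - st * g / gmax
          if (tv_value(cand, sp) < f0) { a <- cand; accepted <- TRUE; break }
          st <- st / 2
        }
        if (!accepted) break
      }
      if (config$positivity) a[a < 0] <- 0
      vol <- as_vol_like(a, vol)
    }
    lam <- lam * config$lambda_decay
  }
  attr(vol, "resid_history") <- hist
  vol
}
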