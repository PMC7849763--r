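#' Settings of the projection-matching field optimizer
#'
#' The symmetric energy minimized for each non-reference phase is
#' `f1(v_f) = ||p_t - A mu0(x + v_f)||^2 + beta phi(v_f)` and
#' `f2(v_i) = ||p_0 - A mu_t(x + v_i)||^2 + beta phi(v_i)`, with
#' `mu_t = warp(mu0, v_f)` the current phase-t estimate, under the
#' inverse-consistency constraint that the pair composes to the identity.
#' The constraint is enforced by periodically replacing each field with the
#' average of itself and its partner's inversion rather than a Lagrangian
#' penalty.
#'
#' @param beta regularizer weight; `NULL` auto-balances it so the
#'   regularization term starts at `beta_fraction` of the data-fidelity term.
#' @param beta_fraction fraction used by the auto-balancing.
#' @param regularizer `"bilateral"` (sliding-preserving) or `"isotropic"`.
#' @param max_iter iteration budget (200 is adequate for full convergence;
#'   interleaved pipeline calls use fewer per outer cycle).
#' @param proj_interval iterations between consistency projections.
#' @param tol relative total-energy decrease (over `tol_window` iterations)
#'   below which the optimizer stops.
#' @param tol_window window for the convergence test.
#' @param ls_max maximum Armijo backtracking trials.
#' @param ls_c Armijo sufficient-decrease constant.
#' @param step0_vox initial trial step as a fraction of the voxel size.
#' @return an `energy_config` list.
#' @export
energy_config <- function(beta = NULL, beta_fraction = 0.1,
                          regularizer = c("bilateral", "isotropic"),
                          max_iter = 200L, proj_interval = 10L, tol = 1e-4,
                          tol_window = 10L, ls_max = 8L, ls_c = 1e-4,
                          step0_vox = 0.5) {
  if (!is.null(beta) && beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  structure(list(beta = beta, beta_fraction = beta_fraction,
                 regularizer = match.arg(regularizer),
                 max_iter = as.integer(max_iter),
                 proj_interval = as.integer(proj_interval),
                 tol = tol, tol_window = as.integer(tol_window),
                 ls_max = as.integer(ls_max), ls_c = ls_c,
                 step0_vox = step0_vox),
            class = "energy_config")
}

#' Projection-matching data fidelity of a deformation field
#'
#' Warps the reference image by the field, forward-projects it at the target
#' phase's gantry angles and returns the squared l2 residual against the
#' measured line integrals. Independent of any regularizer settings.
#'
#' @param v a [dvf3d()] (pull-back, reference-to-target).
#' @param mu0 reference-phase [vol3d()].
#' @param p_t measured `proj_stack` of the target phase.
#' @param geometry a [cone_beam_geometry()].
#' @return scalar squared residual.
#' @export
data_fidelity <- function(v, mu0, p_t, geometry) {
  check_same_grid(v, mu0)
  mu_w <- warp_volume(mu0, v)
  p_est <- forward_project(mu_w, geometry, attr(p_t, "angles", exact = TRUE))
  sum((unclass(p_t) - unclass(p_est))^2)
}

#' Gradient of [data_fidelity()] with respect to the field
#'
#' Chain rule through projector and interpolator:
#' `-2 * [t(A)(p_t - A mu_w)] * d mu_w / d v_i`, where the last factor is the
#' exact derivative of the trilinear interpolant of `mu0` at the warped
#' coordinates (zero where samples clamp at the boundary, and outside the
#' support of the traced rays).
#'
#' @inheritParams data_fidelity
#' @return 4D array shaped like the field.
#' @export
fidelity_gradient <- function(v, mu0, p_t, geometry) {
  check_same_grid(v, mu0)
  d <- dim(mu0); sp <- vol_spacing(mu0)
  angles <- attr(p_t, "angles", exact = TRUE)
  wj <- warp_with_jacobian(mu0, v)
  p_est <- forward_project(as_vol_like(wj$value, mu0), geometry, angles)
  resid <- unclass(p_t) - unclass(p_est)
  bp <- unclass(back_project(new_proj_stack(resid, angles), geometry, d, sp))
  g <- array(0, c(d, 3L))
  g[, , , 1] <- -2 * bp * wj$gx
  g[, , , 2] <- -2 * bp * wj$gy
  g[, , , 3] <- -2 * bp * wj$gz
  g
}

reg_value <- function(v_arr, spacing, intensity, params, kind, wcache = NULL) {
  if (kind == "bilateral") {
    if (!is.null(wcache))
      return(cpp_bilateral_phi_cached(as.double(v_arr), wcache,
                                      as.integer(dim(v_arr)[1:3]), spacing,
                                      params$sigma_x, params$sigma_v,
                                      params$halfwidth))
    bilateral_phi(dvf3d(v_arr, spacing), intensity, params)
  } else isotropic_phi(dvf3d(v_arr, spacing))
}

reg_grad <- function(v_arr, spacing, intensity, params, kind, wcache = NULL) {
  if (kind == "bilateral") {
    if (!is.null(wcache)) {
      g <- cpp_bilateral_grad_cached(as.double(v_arr), wcache,
                                     as.integer(dim(v_arr)[1:3]), spacing,
                                     params$sigma_x, params$sigma_v,
                                     params$halfwidth)
      dim(g) <- dim(v_arr)
      return(g)
    }
    bilateral_phi_grad(dvf3d(v_arr, spacing), intensity, params)
  } else isotropic_phi_grad(dvf3d(v_arr, spacing))
}

bilateral_wcache <- function(intensity, params) {
  cpp_bilateral_wcache(as.double(intensity), as.integer(dim(intensity)[1:3]),
                       vol_spacing(intensity), params$sigma_x,
                       params$sigma_mu, params$halfwidth)
}

# one Polak-Ribiere NCG step with Armijo backtracking on the energy closure;
# state carries g_prev, dir_prev, step_prev. Returns the (possibly unchanged)
# field plus bookkeeping.
ncg_step <- function(v, energy_fn, grad_fn, state, cfg, min_sp, e_cur = NULL) {
  g <- grad_fn(v)
  if (is.null(state$g_prev) || state$restart) {
    dir <- -g
  } else {
    denom <- sum(state$g_prev^2)
    beta_pr <- if (denom > 0) max(0, sum(g * (g - state$g_prev)) / denom) else 0
    dir <- -g + beta_pr * state$dir_prev
    if (sum(dir * g) >= 0) dir <- -g
  }
  gd <- sum(g * dir)
  dmax <- max(abs(dir))
  e0 <- if (is.null(e_cur)) energy_fn(v) else e_cur
  if (dmax == 0 || !is.finite(gd)) {
    state$g_prev <- g; state$dir_prev <- dir; state$restart <- TRUE
    return(list(v = v, accepted = FALSE, step = 0, e = e0, state = state))
  }
  step <- if (!is.null(state$step_prev) && state$step_prev > 0)
    2 * state$step_prev else cfg$step0_vox * min_sp / dmax
  accepted <- FALSE
  for (tryi in seq_len(cfg$ls_max)) {
    cand <- v + step * dir
    e1 <- energy_fn(cand)
    if (is.finite(e1) && e1 <= e0 + cfg$ls_c * step * gd) {
      v <- cand; accepted <- TRUE
      break
    }
    step <- step / 2
  }
  if (!accepted && !is.null(state$g_prev) && !state$restart) {
    # retry along steepest descent
    dir <- -g
    gd <- sum(g * dir)
    step <- cfg$step0_vox * min_sp / max(abs(dir))
    for (tryi in seq_len(cfg$ls_max)) {
      cand <- v + step * dir
      e1 <- energy_fn(cand)
      if (is.finite(e1) && e1 <= e0 + cfg$ls_c * step * gd) {
        v <- cand; accepted <- TRUE
        break
      }
      step <- step / 2
    }
  }
  state$g_prev <- g
  state$dir_prev <- dir
  state$restart <- !accepted
  state$step_prev <- if (accepted) step else NULL
  list(v = v, accepted = accepted, step = if (accepted) step else 0,
       e = if (accepted) e1 else e0, state = state)
}

#' Optimize a forward/inverse deformation pair by projection matching
#'
#' Alternating nonlinear conjugate gradient (Polak-Ribiere with Armijo
#' backtracking) on the two halves of the symmetric energy: each iteration
#' takes one accepted-or-rejected step on `f1` over the forward field and one
#' on `f2` over the inverse field. Every `proj_interval` iterations, and once
#' at the end, the pair is re-symmetrized by averaging each field with the
#' inversion of its partner (the inverse-consistency projection); CG memory
#' is reset afterwards. Steps are only ever accepted when they do not
#' increase their energy, so the accepted-step history is non-increasing
#' between projections.
#'
#' The intensity image entering the bilateral kernel is the current phase-t
#' estimate (the reference warped by the incoming forward field) for `f1`,
#' and the reference image itself for `f2`; both are held fixed for the
#' duration of the call and refresh at each outer pipeline interleave.
#'
#' @param v_fwd,v_inv initial fields ([dvf3d()], e.g. from
#'   [demons_register()]).
#' @param mu0 current reference-phase volume.
#' @param p_t,p_0 measured projection stacks of the target and reference
#'   phases.
#' @param geometry a [cone_beam_geometry()].
#' @param params a [bilateral_params()] (used when the regularizer is
#'   bilateral).
#' @param config an [energy_config()].
#' @return an `opt_state` list: optimized `v_fwd`, `v_inv`, `history`
#'   data.frame (per-iteration energies, with before/after totals per
#'   accepted step), `iterations`, `converged`, `beta`, and the final
#'   `consistency_mm`.
#' @export
ncg_optimize <- function(v_fwd, v_inv, mu0, p_t, p_0, geometry,
                         params = bilateral_params(),
                         config = energy_config()) {
  check_same_grid(v_fwd, mu0)
  check_same_grid(v_inv, mu0)
  sp <- vol_spacing(mu0)
  min_sp <- min(sp)
  kind <- config$regularizer
  mu_t_img <- warp_volume(mu0, v_fwd)    # frozen kernel intensity for f1
  vf <- unclass(v_fwd); vi <- unclass(v_inv)

  fid1 <- function(a) data_fidelity(as_dvf_like(a, v_fwd), mu0, p_t, geometry)
  fid2 <- function(a) data_fidelity(as_dvf_like(a, v_inv), mu_t_img, p_0, geometry)

  wc1 <- if (kind == "bilateral") bilateral_wcache(mu_t_img, params) else NULL
  wc2 <- if (kind == "bilateral") bilateral_wcache(mu0, params) else NULL

  beta <- config$beta
  defer_beta <- FALSE
  if (is.null(beta)) {
    r1 <- reg_value(vf, sp, mu_t_img, params, kind, wc1) +
      reg_value(vi, sp, mu0, params, kind, wc2)
    f1 <- fid1(vf) + fid2(vi)
    if (r1 > 0) {
      beta <- config$beta_fraction * f1 / r1
    } else {
      # zero-field initialization has zero penalty: balance against the
      # first iterate's penalty instead
      beta <- 0
      defer_beta <- TRUE
    }
  }

  # energies carry their fidelity/regularizer split as attributes so the
  # iteration log costs no extra evaluations
  e1_fn <- function(a) {
    fv <- fid1(a); rv <- reg_value(a, sp, mu_t_img, params, kind, wc1)
    structure(fv + beta * rv, fid = fv, reg = rv)
  }
  g1_fn <- function(a) fidelity_gradient(as_dvf_like(a, v_fwd), mu0, p_t, geometry) +
    beta * reg_grad(a, sp, mu_t_img, params, kind, wc1)
  e2_fn <- function(a) {
    fv <- fid2(a); rv <- reg_value(a, sp, mu0, params, kind, wc2)
    structure(fv + beta * rv, fid = fv, reg = rv)
  }
  g2_fn <- function(a) fidelity_gradient(as_dvf_like(a, v_inv), mu_t_img, p_0, geometry) +
    beta * reg_grad(a, sp, mu0, params, kind, wc2)

  st1 <- list(g_prev = NULL, dir_prev = NULL, restart = FALSE, step_prev = NULL)
  st2 <- st1
  hist <- vector("list", config$max_iter)
  fail_streak <- 0L
  converged <- FALSE
  resym <- function(vf, vi) {
    inv_of_fwd <- unclass(invert_dvf(as_dvf_like(vf, v_fwd), tol = 0.1,
                                     max_iter = 10L))
    vi2 <- (vi + inv_of_fwd) / 2
    inv_of_inv <- unclass(invert_dvf(as_dvf_like(vi2, v_inv), tol = 0.1,
                                     max_iter = 10L))
    vf2 <- (vf + inv_of_inv) / 2
    list(vf = vf2, vi = vi2)
  }
  it <- 0L
  totals <- numeric(0)
  e1_cur <- e1_fn(vf); e2_cur <- e2_fn(vi)
  while (it < config$max_iter) {
    it <- it + 1L
    e_before <- as.numeric(e1_cur) + as.numeric(e2_cur)
    s1 <- ncg_step(vf, e1_fn, g1_fn, st1, config, min_sp, e1_cur)
    vf <- s1$v; st1 <- s1$state; e1_cur <- s1$e
    s2 <- ncg_step(vi, e2_fn, g2_fn, st2, config, min_sp, e2_cur)
    vi <- s2$v; st2 <- s2$state; e2_cur <- s2$e
    r1v <- attr(e1_cur, "reg"); r2v <- attr(e2_cur, "reg")
    f1v <- attr(e1_cur, "fid"); f2v <- attr(e2_cur, "fid")
    e_after <- as.numeric(e1_cur) + as.numeric(e2_cur)
    projected <- config$proj_interval > 0L &&
      it %% config$proj_interval == 0L && it < config$max_iter
    hist[[it]] <- data.frame(iter = it, f1 = as.numeric(e1_cur),
                             f2 = as.numeric(e2_cur),
                             fidelity = f1v + f2v,
                             regularizer = r1v + r2v,
                             total_before = e_before, total_after = e_after,
                             step_fwd = s1$step, step_inv = s2$step,
                             accepted = s1$accepted || s2$accepted,
                             projected = projected)
    if (defer_beta && r1v + r2v > 0) {
      # deferred auto-balancing (zero-field start): the weight is fixed from
      # the first iterate's terms, after that iteration is logged
      beta <- config$beta_fraction * (f1v + f2v) / (r1v + r2v)
      defer_beta <- FALSE
      st1$restart <- TRUE; st2$restart <- TRUE
      e1_cur <- e1_fn(vf); e2_cur <- e2_fn(vi)
    }
    if (projected) {
      pr <- resym(vf, vi)
      vf <- pr$vf; vi <- pr$vi
      st1$restart <- TRUE; st2$restart <- TRUE
      st1$step_prev <- NULL; st2$step_prev <- NULL
      # refresh the phase-t kernel/image to the current warp of the reference
      mu_t_img <- warp_volume(mu0, as_dvf_like(vf, v_fwd))
      if (kind == "bilateral") wc1 <- bilateral_wcache(mu_t_img, params)
      e1_cur <- e1_fn(vf); e2_cur <- e2_fn(vi)
    }
    fail_streak <- if (s1$accepted || s2$accepted) 0L else fail_streak + 1L
    if (fail_streak >= 3L) break
    totals <- c(totals, e_after)
    nw <- config$tol_window
    if (length(totals) > nw && config$tol > 0) {
      drop <- totals[length(totals) - nw] - totals[length(totals)]
      if (is.finite(drop) && drop >= 0 &&
          drop < config$tol * abs(totals[length(totals) - nw])) {
        converged <- TRUE
        break
      }
    }
  }
  # final hard consistency projection: the forward field is the deliverable,
  # the returned inverse is its numerical inversion, so the pair composes to
  # the identity up to the inversion residual (wherever the field is
  # invertible)
  vi <- unclass(invert_dvf(as_dvf_like(vf, v_fwd), tol = 0.05,
                           max_iter = 15L))
  cons <- consistency_residual(as_dvf_like(vf, v_fwd), as_dvf_like(vi, v_inv))
  structure(list(
    v_fwd = as_dvf_like(vf, v_fwd),
    v_inv = as_dvf_like(vi, v_inv, direction = "t->0"),
    history = do.call(rbind, hist[!vapply(hist, is.null, TRUE)]),
    iterations = it, converged = converged, beta = beta,
    consistency_mm = cons$max), class = "opt_state")
}

#' @export
print.opt_state <- function(x, ...) {
  cat(sprintf("<opt_state> %d iterations, beta = %.3g, final consistency %.3g mm\n",
              x$iterations, x$beta, x$consistency_mm))
  invisible(x)
}
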