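# Shared fixtures, computed lazily and cached for the whole test run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = fixture_env))
    assign(name, expr, envir = fixture_env)
  get(name, envir = fixture_env)
}

# desk-scale phantom (the standard study conditions)
desk_spec <- function() memo("desk_spec", phantom_spec())

desk_phantom <- function() memo("desk_phantom", build_phantom_4d(desk_spec()))

desk_truth <- function() memo("desk_truth", ground_truth_motion(desk_spec()))

# small phantom for fast reconstruction tests
mini_spec <- function() memo("mini_spec",
  phantom_spec(grid_shape = c(32L, 32L, 24L), voxel_mm = c(4, 4, 4)))

mini_phantom <- function() memo("mini_phantom", build_phantom_4d(mini_spec()))

mini_truth <- function() memo("mini_truth", ground_truth_motion(mini_spec()))

mini_geometry <- function(views = 20L) memo(paste0("mini_geom_", views), {
  s <- mini_spec()
  geometry_for_volume(s$grid_shape, s$voxel_mm,
                      phase_angle_set(s$n_phases, views))
})

mini_projections <- function(views = 20L) memo(paste0("mini_proj_", views),
  simulate_projections(mini_phantom(), mini_geometry(views)))

# brute-force R reference for the bilateral penalty (triple loop)
bilateral_phi_loop <- function(dvf, intensity, params) {
  d <- dim(intensity)
  sp <- vol_spacing(intensity)
  hw <- params$halfwidth
  a <- unclass(dvf); mu <- unclass(intensity)
  tot <- 0
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
    for (oi in -hw:hw) for (oj in -hw:hw) for (ok in -hw:hw) {
      if (oi == 0 && oj == 0 && ok == 0) next
      i2 <- i + oi; j2 <- j + oj; k2 <- k + ok
      if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2] || k2 < 1 || k2 > d[3]) next
      r2 <- (oi * sp[1])^2 + (oj * sp[2])^2 + (ok * sp[3])^2
      gx <- exp(-r2 / (2 * params$sigma_x^2))
      gm <- exp(-(mu[i, j, k] - mu[i2, j2, k2])^2 / (2 * params$sigma_mu^2))
      for (c in 1:3) {
        dd <- a[i, j, k, c] - a[i2, j2, k2, c]
        tot <- tot + gx * gm * exp(-dd^2 / (2 * params$sigma_v^2)) * dd^2 / r2
      }
    }
  tot
}

# brute-force trilinear pull-back warp (scalar loop)
warp_loop <- function(volume, dvf) {
  d <- dim(volume); sp <- vol_spacing(volume)
  a <- unclass(volume); v <- unclass(dvf)
  out <- array(0, d)
  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    q <- c(i + v[i, j, k, 1] / sp[1], j + v[i, j, k, 2] / sp[2],
           k + v[i, j, k, 3] / sp[3])
    q <- pmin(pmax(q, 1), d)
    i0 <- clamp(floor(q[1]), 1, d[1] - 1); fx <- q[1] - i0
    j0 <- clamp(floor(q[2]), 1, d[2] - 1); fy <- q[2] - j0
    k0 <- clamp(floor(q[3]), 1, d[3] - 1); fz <- q[3] - k0
    c00 <- a[i0, j0, k0] * (1 - fx) + a[i0 + 1, j0, k0] * fx
    c10 <- a[i0, j0 + 1, k0] * (1 - fx) + a[i0 + 1, j0 + 1, k0] * fx
    c01 <- a[i0, j0, k0 + 1] * (1 - fx) + a[i0 + 1, j0, k0 + 1] * fx
    c11 <- a[i0, j0 + 1, k0 + 1] * (1 - fx) + a[i0 + 1, j0 + 1, k0 + 1] * fx
    out[i, j, k] <- (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
      (c01 * (1 - fy) + c11 * fy) * fz
  }
  out
}

rand_dvf <- function(d, sp, sd = 1, smooth = TRUE) {
  a <- array(rnorm(prod(d) * 3, 0, sd), c(d, 3L))
  if (smooth)
    for (c in 1:3)
      a[, , , c] <- array(recon4d:::cpp_gauss3(as.double(a[, , , c]),
                                               as.integer(d), c(1, 1, 1)), d)
  dvf3d(a, sp)
}
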