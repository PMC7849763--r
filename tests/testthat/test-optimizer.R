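make_fid_fixture <- function() {
  memo("fid_fixture", {
    set.seed(61)
    d <- c(8L, 8L, 8L); sp <- c(2, 2, 2)
    geom <- cone_beam_geometry(12, 12, 4, 4, list(c(0.4, 1.9)), 600, 1000)
    raw <- array(runif(prod(d), 0, 0.04), d)
    smooth <- array(recon4d:::cpp_gauss3(as.double(raw), d, c(1, 1, 1)), d)
    list(d = d, sp = sp, geom = geom, mu0 = vol3d(smooth, sp))
  })
}

test_that("data fidelity is zero at an exact projection match and ignores the regularizer", {
  fx <- make_fid_fixture()
  v <- rand_dvf(fx$d, fx$sp, 1)
  p_exact <- forward_project(warp_volume(fx$mu0, v), fx$geom)
  expect_equal(data_fidelity(v, fx$mu0, p_exact, fx$geom), 0, tolerance = 1e-20)
  g <- fidelity_gradient(v, fx$mu0, p_exact, fx$geom)
  expect_identical(max(abs(g)), 0)
})

test_that("fidelity gradient matches directional finite differences", {
  fx <- make_fid_fixture()
  set.seed(62)
  v <- dvf3d(array(rnorm(prod(fx$d) * 3, 0, 1), c(fx$d, 3L)), fx$sp)
  p_t <- forward_project(vol3d(array(runif(prod(fx$d), 0, 0.04), fx$d), fx$sp),
                         fx$geom)
  g <- fidelity_gradient(v, fx$mu0, p_t, fx$geom)
  E <- function(a) data_fidelity(dvf3d(a, fx$sp), fx$mu0, p_t, fx$geom)
  h <- 1e-4
  for (rep in 1:10) {
    dirn <- array(rnorm(length(v)), dim(v))
    dirn <- dirn / sqrt(sum(dirn^2))
    fd <- (E(unclass(v) + h * dirn) - E(unclass(v) - h * dirn)) / (2 * h)
    expect_equal(sum(g * dirn), fd, tolerance = 1e-3)
  }
})

test_that("fidelity gradient is supported on the traced rays only", {
  fx <- make_fid_fixture()
  v <- dvf3d(dim = fx$d, spacing = fx$sp)
  p_t <- forward_project(fx$mu0, fx$geom)
  p_off <- recon4d:::new_proj_stack(unclass(p_t) + 0.1, attr(p_t, "angles"))
  g <- fidelity_gradient(v, fx$mu0, p_off, fx$geom)
  ones <- recon4d:::new_proj_stack(array(1, dim(p_t)), attr(p_t, "angles"))
  support <- unclass(back_project(ones, fx$geom, fx$d, fx$sp)) > 0
  mag <- sqrt(apply(unclass(g)^2, 1:3, sum))
  expect_true(all(mag[!support] == 0))
})

test_that("the optimizer recovers a known translation from projections alone", {
  set.seed(63)
  d <- c(32L, 32L, 32L); sp <- c(2, 2, 2)
  geom <- cone_beam_geometry(28, 28, 4, 4,
                             list(seq(0, pi, length.out = 9)[1:8],
                                  seq(0, pi, length.out = 9)[1:8] + 0.2),
                             800, 1200)
  co <- expand.grid(x = axis_coords(32, 2), y = axis_coords(32, 2),
                    z = axis_coords(32, 2))
  blob <- function(cz) array(0.03 * exp(-((co$x)^2 + (co$y)^2 +
                                            (co$z - cz)^2) / 50), d)
  mu0 <- vol3d(blob(0), sp)
  shifted <- vol3d(blob(-4), sp)   # blob moved 4 mm inferior
  p_t <- forward_project(shifted, geom, geom$angles[[2]])
  p_0 <- forward_project(mu0, geom, geom$angles[[1]])
  z0 <- dvf3d(dim = d, spacing = sp)
  opt <- ncg_optimize(z0, z0, mu0, p_t, p_0, geom,
                      config = energy_config(beta = 0, max_iter = 30,
                                             regularizer = "isotropic",
                                             proj_interval = 10))
  # the recovered motion is judged on the output: the warped reference must
  # reproduce the displaced blob, i.e. its intensity centroid moves by the
  # translation (the field itself is only determined up to the aperture
  # ambiguity of a symmetric object)
  warped <- warp_volume(mu0, opt$v_fwd)
  zc <- array(rep(axis_coords(32, 2), each = 32 * 32), d)
  centroid_z <- function(v) sum(unclass(v) * zc) / sum(v)
  expect_lt(abs((centroid_z(warped) - centroid_z(mu0)) - (-4)), 1)  # 0.5 voxel
  # the measured projections are matched almost completely
  h <- opt$history
  expect_lt(h$fidelity[nrow(h)], 0.05 * h$total_before[1])
  # accepted steps never increase the logged energy
  acc <- h[h$accepted, ]
  expect_true(all(acc$total_after <= acc$total_before + 1e-9))
})

test_that("starting at the exact solution leaves the field unchanged", {
  fx <- make_fid_fixture()
  geom <- fx$geom
  v_true <- rand_dvf(fx$d, fx$sp, 0.5)
  p_t <- forward_project(warp_volume(fx$mu0, v_true), geom)
  p_0 <- forward_project(fx$mu0, geom)
  inv_true <- invert_dvf(v_true, tol = 1e-3, max_iter = 50)
  opt <- ncg_optimize(v_true, inv_true, fx$mu0, p_t, p_0, geom,
                      config = energy_config(beta = 0, max_iter = 5,
                                             regularizer = "isotropic",
                                             proj_interval = 0))
  expect_lt(max(abs(unclass(opt$v_fwd) - unclass(v_true))), 0.3)
  # on a smooth invertible field the returned pair composes to the identity
  expect_lt(opt$consistency_mm, 0.5)
})

test_that("energy configuration validates and exposes the documented defaults", {
  expect_identical(energy_config()$max_iter, 200L)
  expect_identical(energy_config()$regularizer, "bilateral")
  expect_error(energy_config(beta = -1), "beta")
  expect_error(energy_config(max_iter = 0), "max_iter")
})
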