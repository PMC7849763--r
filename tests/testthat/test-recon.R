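test_that("SART solves the single-voxel, single-ray system in one relaxed step", {
  # one 2 mm voxel on the axis, central detector pixel: a = 2 mm
  d <- c(1L, 1L, 1L); sp <- c(2, 2, 2)
  g <- cone_beam_geometry(1, 1, 1, 1, list(0), 500, 800)
  p <- recon4d:::new_proj_stack(array(0.4, c(1, 1, 1)), 0)
  mu0 <- vol3d(array(0, d), sp)
  one <- sart_pass(mu0, p, g, recon_config(lambda = 1))
  expect_equal(as.numeric(one), 0.2, tolerance = 1e-12)   # exact p/a
  half <- sart_pass(mu0, p, g, recon_config(lambda = 0.5))
  expect_equal(as.numeric(half), 0.1, tolerance = 1e-12)
})

test_that("consistent noise-free projections give strictly decreasing residuals", {
  vols <- mini_phantom()
  s <- mini_spec()
  g <- geometry_for_volume(s$grid_shape, s$voxel_mm, list(seq(0, 2 * pi, length.out = 61)[1:60]))
  p <- forward_project(vols[[1]], g)
  rec <- sart_reconstruct(p, g, s$grid_shape, s$voxel_mm,
                          recon_config(n_iter = 20, tv_weight = 0))
  h <- attr(rec, "resid_history")
  expect_length(h, 20)
  expect_true(all(diff(h) < 0))
})

test_that("zero projections leave a zero volume unchanged; positivity is preserved", {
  d <- c(8L, 8L, 8L); sp <- c(4, 4, 4)
  g <- cone_beam_geometry(8, 8, 8, 8, list(c(0, 1)), 600, 1000)
  z <- recon4d:::new_proj_stack(array(0, c(8, 8, 2)), g$angles[[1]])
  out <- sart_pass(vol3d(array(0, d), sp), z, g)
  expect_identical(max(abs(out)), 0)
  # a pass on real data never goes negative with the clamp enabled
  p <- forward_project(mini_phantom()[[1]], mini_geometry())
  rec <- sart_reconstruct(p, mini_geometry(), mini_spec()$grid_shape,
                          mini_spec()$voxel_mm, recon_config(n_iter = 3))
  expect_gte(min(rec), 0)
})

test_that("a volume that already matches the projections is a SART fixed point", {
  s <- mini_spec()
  vol <- mini_phantom()[[1]]
  g <- mini_geometry()
  p <- forward_project(vol, g)
  out <- sart_pass(vol, p, g, recon_config(lambda = 1, positivity = FALSE))
  expect_lt(max(abs(unclass(out) - unclass(vol))), 1e-10)
})

test_that("motion-compensated SART with identity fields is exactly pooled SART", {
  s <- mini_spec()
  proj <- mini_projections()
  cfg <- recon_config(n_iter = 2, tv_weight = 0)
  m <- msart_reconstruct(proj, vector("list", s$n_phases), mini_geometry(),
                         cfg, dim = s$grid_shape, spacing = s$voxel_mm)
  pooled <- sart_reconstruct(proj, mini_geometry(), s$grid_shape, s$voxel_mm, cfg)
  expect_identical(as.double(m), as.double(pooled))
  # a single phase with identity field reduces to sart_pass
  one_set <- projection_set(proj$stacks[1], mini_geometry())
  m1 <- msart_reconstruct(one_set, list(NULL), mini_geometry(),
                          recon_config(n_iter = 1, tv_weight = 0),
                          dim = s$grid_shape, spacing = s$voxel_mm)
  s1 <- sart_pass(vol3d(array(0, s$grid_shape), s$voxel_mm),
                  proj$stacks[[1]], mini_geometry(),
                  recon_config(n_iter = 1, tv_weight = 0))
  expect_identical(as.double(m1), as.double(s1))
  expect_error(msart_reconstruct(proj, vector("list", 3), mini_geometry(),
                                 cfg, dim = s$grid_shape,
                                 spacing = s$voxel_mm),
               "one inverse DVF")
})

test_that("sharing all phases through ground-truth fields beats single-phase SART", {
  s <- mini_spec()
  proj <- mini_projections()
  gt <- mini_truth()
  inv <- lapply(seq_len(s$n_phases), function(t)
    if (t == 1) NULL else invert_dvf(gt$dvfs[[t]], tol = 0.1))
  fwd <- c(list(NULL), gt$dvfs[-1])
  cfg <- recon_config(lambda = 1, n_iter = 25, lambda_decay = 1, tv_weight = 0)
  ms <- msart_reconstruct(proj, inv, mini_geometry(), cfg,
                          dim = s$grid_shape, spacing = s$voxel_mm,
                          forward_dvfs = fwd)
  s0 <- sart_reconstruct(proj$stacks[[1]], mini_geometry(), s$grid_shape,
                         s$voxel_mm, cfg)
  roi <- unclass(mini_phantom()[[1]]) > 0.5 * s$attenuation[["lung"]]
  expect_lt(relative_error(ms, mini_phantom()[[1]], roi),
            relative_error(s0, mini_phantom()[[1]], roi))
})

test_that("TV stage reduces total variation at matched data passes and vanishes at weight 0", {
  s <- mini_spec()
  set.seed(31)
  noisy <- simulate_projections(mini_phantom(), mini_geometry(),
                                noise_sd = 0.02, seed = 31)
  cfg_plain <- recon_config(n_iter = 8, tv_weight = 0)
  cfg_tv <- recon_config(n_iter = 8, tv_weight = 0.3, tv_steps = 8)
  plain <- tv_reconstruct(noisy$stacks[[1]], mini_geometry(), s$grid_shape,
                          s$voxel_mm, cfg_plain)
  tv <- tv_reconstruct(noisy$stacks[[1]], mini_geometry(), s$grid_shape,
                       s$voxel_mm, cfg_tv)
  tv_of <- function(v) recon4d:::tv_value(unclass(v), vol_spacing(v))
  expect_lt(tv_of(tv), tv_of(plain))
  # zero weight is bit-identical to plain SART
  sart <- sart_reconstruct(noisy$stacks[[1]], mini_geometry(), s$grid_shape,
                           s$voxel_mm, cfg_plain)
  expect_identical(as.double(plain), as.double(sart))
})
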