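test_that("geometry constructor enforces its invariants", {
  expect_error(cone_beam_geometry(10, 10, 1, 1, list(0), sad = 1500, sdd = 1000),
               "SDD > SAD")
  expect_error(cone_beam_geometry(10, 10, 0, 1, list(0)), "pitch")
  expect_error(cone_beam_geometry(10, 10, 1, 1, list(numeric(0))), "angle")
})

test_that("central axis-aligned ray decomposes a cube into its side length", {
  d <- c(10L, 10L, 10L); sp <- c(1, 1, 1)
  g <- cone_beam_geometry(21, 21, 1, 1, list(0), 500, 800)
  tr <- trace_ray(g, d, sp, c(11, 11), 0)
  expect_equal(sum(tr$length), 10, tolerance = 1e-10)
  expect_true(all(tr$length >= 0))
  # a ray far off the panel edge misses the grid entirely
  tr2 <- trace_ray(g, d, sp, c(1, 1), 0)
  expect_identical(nrow(tr2), 0L)
  expect_error(trace_ray(g, d, sp, c(0, 5), 0), "pixel")
})

test_that("traced lengths agree with a dense-sampling chord oracle", {
  set.seed(11)
  d <- c(5L, 5L, 5L); sp <- c(2, 3, 1.5)
  g <- cone_beam_geometry(9, 9, 8, 8, list(0), 300, 500)
  # oracle: clip the source->pixel segment against the box by bisection
  chord_oracle <- function(iu, iv, angle) {
    sad <- g$sad; odd <- g$sdd - g$sad
    u <- (iu - 1 - (g$nu - 1) / 2) * g$du
    v <- (iv - 1 - (g$nv - 1) / 2) * g$dv
    S <- c(sad * cos(angle), sad * sin(angle), 0)
    P <- c(-odd * cos(angle) - u * sin(angle),
           -odd * sin(angle) + u * cos(angle), v)
    lo <- -d * sp / 2; hi <- d * sp / 2
    inside <- function(t) {
      x <- S + t * (P - S)
      all(x >= lo & x <= hi)
    }
    ts <- seq(0, 1, length.out = 4001)
    ins <- vapply(ts, inside, logical(1))
    if (!any(ins)) return(0)
    refine <- function(ta, tb) { # bisect an inside/outside transition
      for (r in 1:40) {
        tm <- (ta + tb) / 2
        if (inside(tm) == inside(ta)) ta <- tm else tb <- tm
      }
      (ta + tb) / 2
    }
    i1 <- which(ins)[1]; i2 <- rev(which(ins))[1]
    t_in <- if (i1 == 1) ts[1] else refine(ts[i1 - 1], ts[i1])
    t_out <- if (i2 == length(ts)) ts[i2] else refine(ts[i2], ts[i2 + 1])
    (t_out - t_in) * sqrt(sum((P - S)^2))
  }
  for (rep in 1:12) {
    iu <- sample(g$nu, 1); iv <- sample(g$nv, 1)
    ang <- runif(1, 0, 2 * pi)
    tr <- trace_ray(g, d, sp, c(iu, iv), ang)
    expect_equal(sum(tr$length), chord_oracle(iu, iv, ang), tolerance = 1e-3)
  }
})

test_that("forward projection is mu * chord on uniform volumes and zero on zero", {
  d <- c(50L, 50L, 50L); sp <- c(2, 2, 2)      # 100 mm cube
  g <- cone_beam_geometry(31, 31, 3, 3, list(0), 1000, 1500)
  u <- vol3d(array(0.02, d), sp)
  p <- forward_project(u, g, 0)
  expect_equal(p[16, 16, 1], 2.0, tolerance = 1e-9)    # 0.02 * 100 mm
  z <- forward_project(vol3d(array(0, d), sp), g, 0)
  expect_identical(max(abs(z)), 0)
})

test_that("projection stacks carry the standard phase-sorted shapes", {
  g <- cone_beam_geometry(300, 240, 1, 1, phase_angle_set(10, 20), 1000, 1500)
  expect_length(g$angles, 10)
  expect_true(all(vapply(g$angles, length, 1L) == 20))
  small <- vol3d(array(0.01, c(8, 8, 8)), c(4, 4, 4))
  p <- forward_project(small, g, g$angles[[1]][1:2])
  expect_identical(dim(p), c(300L, 240L, 2L))
})

test_that("backprojection is the exact adjoint of the forward projector", {
  set.seed(12)
  d <- c(16L, 16L, 16L); sp <- c(2, 2, 2)
  g <- cone_beam_geometry(24, 24, 4, 4, list(c(0.3, 1.2, 2.5, 4.0)), 600, 1000)
  for (rep in 1:5) {
    x <- vol3d(array(runif(prod(d)), d), sp)
    y <- array(runif(24 * 24 * 4), c(24, 24, 4))
    Ax <- forward_project(x, g)
    Aty <- back_project(recon4d:::new_proj_stack(y, g$angles[[1]]), g, d, sp)
    lhs <- sum(unclass(Ax) * y)
    rhs <- sum(unclass(x) * unclass(Aty))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-10)
  }
  # adjoint of a single pixel lands only on that ray's traced voxels
  y1 <- array(0, c(24, 24, 4)); y1[13, 11, 2] <- 1
  bp <- back_project(recon4d:::new_proj_stack(y1, g$angles[[1]]), g, d, sp)
  tr <- trace_ray(g, d, sp, c(13, 11), g$angles[[1]][2])
  hit <- array(FALSE, d)
  hit[cbind(tr$i, tr$j, tr$k)] <- TRUE
  expect_true(all(unclass(bp)[!hit] == 0))
  expect_equal(unclass(bp)[cbind(tr$i, tr$j, tr$k)], tr$length)
  # zero projections backproject to a zero volume
  z <- back_project(recon4d:::new_proj_stack(array(0, c(24, 24, 4)),
                                             g$angles[[1]]), g, d, sp)
  expect_identical(max(abs(z)), 0)
})

test_that("both operators are linear", {
  set.seed(13)
  d <- c(12L, 12L, 12L); sp <- c(2, 2, 2)
  g <- cone_beam_geometry(16, 16, 4, 4, list(c(0.5, 2.0)), 600, 1000)
  a <- vol3d(array(runif(prod(d)), d), sp)
  b <- vol3d(array(runif(prod(d)), d), sp)
  pa <- forward_project(a, g); pb <- forward_project(b, g)
  pab <- forward_project(vol3d(2 * unclass(a) - 3 * unclass(b), sp), g)
  expect_equal(unclass(pab), 2 * unclass(pa) - 3 * unclass(pb),
               tolerance = 1e-12)
})

test_that("trace lengths are equivariant under quarter-turn gantry rotation", {
  d <- c(11L, 11L, 11L); sp <- c(2, 2, 2)   # cubic, rotation-symmetric grid
  g <- cone_beam_geometry(15, 15, 3, 3, list(0), 600, 1000)
  for (px in list(c(8, 8), c(5, 9), c(12, 4))) {
    t0 <- trace_ray(g, d, sp, px, 0.7)
    t1 <- trace_ray(g, d, sp, px, 0.7 + pi / 2)
    expect_equal(sum(t0$length), sum(t1$length), tolerance = 1e-3)
  }
})

test_that("simulated studies reject mismatched phase counts and flag bad stacks", {
  s <- mini_spec()
  g <- cone_beam_geometry(10, 10, 8, 8, phase_angle_set(3, 2), 1000, 1500)
  expect_error(simulate_projections(mini_phantom(), g), "one angle vector")
  st <- forward_project(mini_phantom()[[1]], mini_geometry(), phase = 0L)
  bad <- unclass(st); bad[1] <- NA
  expect_error(projection_set(list(recon4d:::new_proj_stack(
    bad, attr(st, "angles"))), mini_geometry()), "finite")
})
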