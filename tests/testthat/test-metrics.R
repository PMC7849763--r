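test_that("trajectory RMSE and MaxE follow the nine-phase formula", {
  expect_equal(trajectory_rmse_maxe(1:9, 1:9),
               c(rmse_mm = 0, maxe_mm = 0))
  # nine unit errors: the 1/3 prefactor makes the RMSE exactly 1 mm
  expect_equal(trajectory_rmse_maxe(rep(1, 9), rep(0, 9)),
               c(rmse_mm = 1, maxe_mm = 1))
  expect_equal(trajectory_rmse_maxe(c(3, rep(0, 8)), rep(0, 9)),
               c(rmse_mm = 1, maxe_mm = 3))
  expect_error(trajectory_rmse_maxe(1:9, 1:8), "length")
  expect_error(trajectory_rmse_maxe(c(NA, 1:8), 1:9), "missing")
  # printed prefactor is the nine-phase normalization: (1/3) sqrt(sum) == sqrt(mean)
  set.seed(41)
  for (rep in 1:5) {
    e <- rnorm(9)
    expect_equal(sqrt(sum(e^2)) / 3, sqrt(mean(e^2)))
  }
})

test_that("Dice has its identity, disjoint and overlap values, and is symmetric", {
  d <- c(10L, 10L, 5L)
  a <- array(FALSE, d); a[1:5, , ] <- TRUE
  expect_identical(dice(a, a), 1)
  b <- array(FALSE, d); b[6:10, , ] <- TRUE
  expect_identical(dice(a, b), 0)
  # |A| = |B| = 100, overlap 90
  a2 <- array(FALSE, d); a2[seq_len(100)] <- TRUE
  b2 <- array(FALSE, d); b2[11:110] <- TRUE
  expect_equal(dice(a2, b2), 0.9)
  expect_identical(dice(a2, b2), dice(b2, a2))
  expect_identical(dice(array(FALSE, d), array(FALSE, d)), 1)
  expect_error(dice(a, array(FALSE, c(2, 2, 2))), "mismatch")
})

test_that("relative error has its closed forms and matches a scalar loop", {
  set.seed(42)
  d <- c(8L, 8L, 8L)
  truth <- vol3d(array(runif(prod(d), 0.01, 0.05), d), c(1, 1, 1))
  expect_equal(relative_error(truth, truth), 0)
  expect_equal(relative_error(vol3d(unclass(truth) * 1.1, c(1, 1, 1)), truth),
               10, tolerance = 1e-9)
  expect_equal(relative_error(vol3d(unclass(truth) * 1.1, c(1, 1, 1)), truth,
                              root = FALSE), 1, tolerance = 1e-9)
  rec <- vol3d(unclass(truth) + array(rnorm(prod(d), 0, 0.01), d), c(1, 1, 1))
  num <- 0; den <- 0
  for (i in seq_len(prod(d))) {
    num <- num + (rec[i] - truth[i])^2
    den <- den + truth[i]^2
  }
  expect_equal(relative_error(rec, truth), 100 * sqrt(num / den),
               tolerance = 1e-12)
  # scaling the reconstruction toward the truth shrinks the root-form RE
  res <- sapply(c(1.5, 1.2, 1.05), function(s)
    relative_error(vol3d(unclass(truth) * s, c(1, 1, 1)), truth))
  expect_true(all(diff(res) < 0))
  expect_error(relative_error(truth, vol3d(array(0, d), c(1, 1, 1))),
               "zero-norm")
})

test_that("threshold trajectory extraction recovers the heart edge on truth volumes", {
  spec <- desk_spec()
  vols <- desk_phantom()
  roi <- heart_edge_roi(spec)
  truth <- heart_edge_truth(spec)
  for (m in c("extreme", "mean")) {
    traj <- extract_trajectory(vols, roi, "z", roi$threshold, "min", method = m)
    expect_true(all(is.finite(traj)))
    expect_lt(max(abs(traj - truth)), max(spec$voxel_mm))   # within one voxel
  }
  # constant volumes: flat trajectory, zero RMSE against itself
  cvol <- vol3d(array(0.05, spec$grid_shape), spec$voxel_mm)
  flat <- extract_trajectory(rep(list(cvol), 4), roi, "z", roi$threshold, "min")
  expect_equal(diff(range(flat)), 0)
  expect_equal(unname(trajectory_rmse_maxe(flat, flat)[1]), 0)
  # threshold above the global maximum: flagged missing for every phase
  miss <- extract_trajectory(vols[1:3], roi, "z", 1.0, "min")
  expect_true(all(is.na(miss)))
  expect_error(extract_trajectory(vols[1], list(xlim = c(0, 2), ylim = c(1, 2),
                                                zlim = c(1, 2)), "z", 0.01),
               "ROI")
})

test_that("automatic lung segmentation overlaps the ground-truth masks", {
  spec <- desk_spec()
  vols <- desk_phantom()
  gt <- desk_truth()
  thr <- (spec$attenuation[["lung"]] + spec$attenuation[["body"]]) / 2
  for (t in c(1, 6)) {
    seg <- lung_segment(vols[[t]], thr)
    expect_gt(dice(seg, gt$lung_masks[[t]]), 0.9)
    # both lungs present: the mask must span left and right halves
    nx <- spec$grid_shape[1]
    expect_gt(sum(seg[1:(nx / 2), , ]), 0)
    expect_gt(sum(seg[(nx / 2 + 1):nx, , ]), 0)
  }
})
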