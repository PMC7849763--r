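test_that("phantom spec validates its invariants", {
  expect_error(phantom_spec(n_phases = 1), "n_phases")
  expect_error(phantom_spec(diaphragm_si_mm = -1), "diaphragm")
  expect_error(phantom_spec(attenuation = c(body = 0.01, lung = 0.02,
                                            heart = 0.04, rib = 0.06,
                                            vessel = 0.04, tumor = 0.05)),
               "lung attenuation")
  expect_error(build_phantom_phase(phantom_spec(), 10), "out of range")
  expect_error(build_phantom_phase(phantom_spec(), -1), "out of range")
})

test_that("phase 0 is the static reference and grids have the requested size", {
  spec <- desk_spec()
  v0 <- build_phantom_phase(spec, 0)
  expect_identical(dim(v0), spec$grid_shape)
  # zero displacement at the reference phase: rebuilding is bit-identical
  expect_identical(unclass(v0), unclass(desk_phantom()[[1]]))
  # full-scale grid honored
  full <- phantom_spec(grid_shape = c(256L, 256L, 150L), voxel_mm = c(1, 1, 1))
  vf <- build_phantom_phase(full, 0)
  expect_identical(dim(vf), c(256L, 256L, 150L))
  expect_identical(vol_spacing(vf), c(1, 1, 1))
})

test_that("diaphragm apex travels the configured SI excursion between extreme phases", {
  spec <- desk_spec()
  L <- recon4d:::phantom_layout(spec)
  vols <- desk_phantom()
  thr <- (spec$attenuation[["body"]] + spec$attenuation[["lung"]]) / 2
  # column block over the right-lung dome, clear of the vessel and tumor
  xi <- round((L$lungR_c[1] + 2) / spec$voxel_mm[1] + (spec$grid_shape[1] + 1) / 2) + (-1:1)
  yi <- round((L$lungR_c[2] + 2) / spec$voxel_mm[2] + (spec$grid_shape[2] + 1) / 2) + (-1:1)
  apex_z <- function(vol) {
    zc <- axis_coords(dim(vol)[3], vol_spacing(vol)[3])
    sub <- unclass(vol)[xi, yi, ]
    zmax <- -Inf
    for (k in seq_along(zc)) {
      if (zc[k] > L$za - 2) break
      if (any(sub[, , k] >= thr)) zmax <- zc[k]
    }
    zmax
  }
  shift <- apex_z(vols[[1]]) - apex_z(vols[[6]])
  expect_lt(abs(shift - spec$diaphragm_si_mm), max(spec$voxel_mm) + 1e-9)
})

test_that("ground-truth motion is cosine-weighted, zero at reference, full at mid-cycle", {
  spec <- desk_spec()
  gt <- desk_truth()
  expect_identical(max(abs(gt$dvfs[[1]])), 0)
  expect_equal(gt$phase_weights[1], 0)
  expect_equal(gt$phase_weights[6], 1)   # half period for 10 phases
  # SI excursion attains the diaphragm setting within one voxel
  expect_lt(abs(max(abs(gt$dvfs[[6]][, , , 3])) - spec$diaphragm_si_mm),
            max(spec$voxel_mm))
  # AP excursion attains the chest setting at the anterior wall
  expect_lt(abs(max(abs(gt$dvfs[[6]][, , , 2])) - spec$chest_ap_mm), 1e-6)
})

test_that("warping the reference with the ground-truth fields reproduces each phase", {
  vols <- desk_phantom()
  gt <- desk_truth()
  for (t in c(3, 6, 9)) {
    w <- warp_volume(vols[[1]], gt$dvfs[[t]])
    rms <- sqrt(mean((unclass(w) - unclass(vols[[t]]))^2))
    # interpolation-dominated bound: well below the lung/body intensity gap
    expect_lt(rms, 0.003)
  }
})

test_that("SI displacement jumps across the pleural interface within two voxels", {
  spec <- desk_spec()
  gt <- desk_truth()
  L <- recon4d:::phantom_layout(spec)
  for (t in c(4, 6)) {             # mid-inhale and peak
    w <- phase_weight(spec, t - 1)
    vz <- gt$dvfs[[t]][, , , 3]
    yi <- round(L$lungR_c[2] / spec$voxel_mm[2] + (spec$grid_shape[2] + 1) / 2)
    zi <- round((L$zb + 0.3 * L$Lz) / spec$voxel_mm[3] + (spec$grid_shape[3] + 1) / 2)
    line <- vz[, yi, zi]
    jumps <- abs(diff(line, lag = 2))
    expect_gt(max(jumps), 0.5 * spec$diaphragm_si_mm * w)
  }
})

test_that("heart-edge trajectory is periodic with the configured amplitude", {
  spec <- desk_spec()
  he <- heart_edge_truth(spec)
  expect_length(he, spec$n_phases)
  # value at phase 0 equals the wrapped value at phase n
  expect_equal(he[1],
               recon4d:::phantom_layout(spec)$heart_edge_z0 -
                 spec$heart_si_mm * phase_weight(spec, spec$n_phases))
  expect_equal(max(he) - min(he), spec$heart_si_mm)
  # lung masks exist per phase and exclude the heart region
  gt <- desk_truth()
  expect_length(gt$lung_masks, spec$n_phases)
  expect_true(all(vapply(gt$lung_masks, sum, 1) > 0))
})

test_that("phantom generation is deterministic", {
  a <- build_phantom_phase(phantom_spec(), 4)
  b <- build_phantom_phase(phantom_spec(), 4)
  expect_identical(unclass(a), unclass(b))
})
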