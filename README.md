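# recon4d

Sliding-motion-compensated simultaneous 4D cone-beam CT reconstruction.

## The problem

A one-minute cone-beam CT scan sorted into ten breathing phases leaves each
phase with only ~20–40 projections — far too few to reconstruct on their
own. `recon4d` implements the simultaneous strategy: a motion-compensated
SART (mSART) reconstructs **one** high-quality reference phase `mu^0` from
**all** phases' projections,

```
mu_j^{0,(k+1)} = mu_j^{0,(k)}
  + lambda * sum_n d_jn^{t->0} [ sum_i a_in (p_i^t - sum_n a_in mu_n^{t,(k)}) / sum_n a_in ]
             / sum_i a_in
```

where `a_in` are exact Siddon ray-intersection lengths and `d_jn^{t->0}`
is the trilinear action of the inverse deformation field mapping phase `t`
onto the reference. The per-phase deformation fields (DVFs) are estimated
by projection matching: minimizing the symmetric, inverse-consistent energy

```
f1(v^{0->t}) = || p^t - A mu^0(x + v^{0->t}) ||_2^2 + beta * phi(v^{0->t})
f2(v^{t->0}) = || p^0 - A mu^t(x + v^{t->0}) ||_2^2 + beta * phi(v^{t->0})
```

with a Polak–Ribière nonlinear conjugate-gradient optimizer. The
regularizer `phi` is the package's focus: a **bilateral-filtering** penalty
whose spatial (`sigma_x` = 3 mm), image-intensity (`sigma_mu` =
0.03 mm^-1) and displacement (`sigma_v` = 2.5 mm) Gaussian kernels leave
the tangential velocity jump at the lung/chest-wall interface — sliding
motion — unpenalized, where the classical isotropic penalty
`sum (dv_i/dx_j)^2` would smooth it away. The final 4D set is synthesized
by warping the converged reference with each phase's forward field.

Intended users: medical-physics and image-reconstruction researchers who
need a transparent, fully scriptable reference implementation of
DVF-based 4D-CBCT with sliding-motion preservation — including a digital
thorax phantom with analytic ground-truth motion, so every stage is
testable without clinical data.

## What is in the package

* `phantom_spec()` / `build_phantom_4d()` / `ground_truth_motion()` — a
  10-phase digital thorax phantom (cosine breathing over 4 s, 20 mm SI
  diaphragm and 12 mm AP chest excursion, analytic sliding discontinuity
  at the pleural surface, heart-edge trajectory known in closed form).
* `cone_beam_geometry()`, `forward_project()`, `back_project()`,
  `trace_ray()` — exact ray-tracing cone-beam projector with a matched
  adjoint (`<Ax, y> = <x, A'y>` to rounding error).
* `sart_reconstruct()`, `tv_reconstruct()`, `msart_reconstruct()` —
  algebraic reconstruction, the TV-regularized initializer and the
  motion-compensated reference reconstruction.
* `demons_register()` — multiresolution additive Demons for the initial
  field pairs; `invert_dvf()`, `warp_volume()`, `consistency_residual()`.
* `bilateral_phi()` / `bilateral_phi_grad()`, `isotropic_phi()` /
  `isotropic_phi_grad()` — the two regularizers with analytic,
  finite-difference-validated gradients.
* `ncg_optimize()` — the alternating inverse-consistent NCG stage;
  `run_4dcbct()` — the full interleaved pipeline; `sigma_v_sweep()` — the
  displacement-kernel sensitivity study.
* `trajectory_rmse_maxe()`, `dice()`, `relative_error()`,
  `extract_trajectory()`, `lung_segment()` — the evaluation metrics.
* Readers/writers for NIfTI / MetaImage volumes, raw+JSON fields and
  projection sets; a YAML configuration loader (`parse_config()`); a thin
  CLI at `inst/cli/recon4d.R`.

## Worked example

A reduced study — 32x32x24 voxels at 4 mm, 10 phases x 10 views — runs in
under a minute and exercises every stage:

```r
library(recon4d)

cfg <- pipeline_config(
  phantom = phantom_spec(grid_shape = c(32, 32, 24), voxel_mm = c(4, 4, 4)),
  energy  = energy_config(max_iter = 6),
  outer   = 1, views_per_phase = 10)

study <- simulate_study(cfg)     # phantom + geometry + projections
run <- run_4dcbct(cfg, study$projections)
run
#> <recon4d_run> 10 phases, bilateral regularizer, 23.8 s

roi <- heart_edge_roi(cfg$phantom)
truth <- extract_trajectory(study$volumes, roi, "z", roi$threshold,
                            "min", method = "mean")
recon <- extract_trajectory(run$volumes, roi, "z", roi$threshold,
                            "min", method = "mean")
trajectory_rmse_maxe(recon[-1], truth[-1])
#>   rmse_mm   maxe_mm
#> 0.6440375 0.9873209
```

The two numbers are the root-mean-square and maximum error (mm, over the
nine non-reference phases) of the inferior heart-edge z-trajectory read
from the reconstruction against the same trajectory read from the phantom
truth — sub-voxel even at 4 mm voxels in this reduced configuration. At
the standard desk scale (64x64x48 at 2 mm, 20 views/phase) the bilateral
run tracks the edge to well under half a millimetre RMSE, and the energy
log in `run$energy` records the per-phase decrease of `f1 + f2`.

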