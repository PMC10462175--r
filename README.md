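# cineinr

One-shot joint reconstruction and motion estimation for respiratory
3D cine-MRI from extremely undersampled golden-mean Koosh-ball radial
k-space data — implemented end to end in R, together with the synthetic
dynamic thorax phantom and k-space simulation needed to build and test
the whole method without any external data.

The package is aimed at MR physics and image-reconstruction researchers
working on real-time respiratory imaging (e.g. for MR-guided
radiotherapy), and at anyone who wants a transparent, dependency-light
reference implementation of implicit-neural-representation (INR)
reconstruction with a PCA respiratory motion model.

## The model

A free-breathing radial acquisition is binned into cine frames of a few
spokes each (17 spokes at TR 5.8 ms → 98.6 ms frames). Each frame is far
too undersampled to reconstruct alone, so every frame is modelled as a
deformed copy of one reference-frame image,

    z_t(x) = z_ref(x + d_t(x)),

and the per-frame deformation is constrained to a patient-specific PCA
motion model,

    d_t(x) = e_0(x) + Σ_i Σ_axis w_{i,axis}(t) · e_i(x),

with three principal motion components × three Cartesian axes = nine
weightings per frame. Two coordinate networks are fitted jointly to the
measured k-space of this one scan:

* a **spatial INR** (multiresolution hash encoding + two sine-activated
  MLPs) representing the complex-valued reference image, and
* a **temporal INR** (1D hash encoding + nine ReLU MLPs) emitting the
  frame-dependent component weightings,

by minimising `Σ_t ‖F z_t − w_t‖² + λ·TV(z_ref)` in a three-stage
progressive schedule (image-domain warm start on the end-of-exhale bin,
k-space refinement, then joint optimisation). All gradients are
hand-derived; no autodiff framework is used. Respiratory self-navigation
(surrogate extraction from the k-space centre, phase sorting), demons
registration and an online-PCA path for scans without a prior 4D set are
included, as are the evaluation metrics (relative error, Dice, tumor
centre-of-mass error, sharpness).

## Worked example

The reduced synthetic study — a 32³ thorax phantom at 4-mm spacing with a
16-mm lung tumor, amplitude-varying breathing (20-mm diaphragm
peak-to-peak), 200 cine frames of 17 spokes — runs in a few minutes on one
CPU core:

```r
library(cineinr)

spec    <- phantom_spec(grid_shape = 32, spacing = 4, tumor_diameter = 16)
ref     <- build_reference_volume(spec)
phase   <- simulate_phase_map(phase_map_spec(seed = 1), spec$grid_shape, spec$spacing)
trace   <- generate_motion_trace("S1", duration_s = 200 * 0.0986,
                                 frame_dt_s = 0.0986, seed = 2)
phantom <- synthesize_cine_sequence(apply_phase_modulation(ref$volume, phase),
                                    trace, build_motion_basis(spec),
                                    ref$tumor_mask)
acq     <- simulate_acquisition(phantom, spokes_per_frame = 17)

model  <- phantom_motion_model(phantom)            # offline PCA motion model
config <- reduced_train_config(grid_n = 32, n_frames = 200, seed = 0)
result <- run_progressive_training(acq, model, config)

metrics <- evaluate_reconstruction(result, phantom, frames = seq(1, 200, by = 4))
round(colMeans(metrics[-1]), 3)
#>      re come_mm     dsc
#>   0.014   0.333   0.977
```

The numbers mean: the reconstructed cine sequence matches the
ground-truth frames to 1.4% relative error (squared-sum ratio), the tumor
position propagated by the solved motion is on average 0.33 mm from its
true location — well below the 4-mm voxel — and the propagated tumor
contour overlaps the truth with a Dice coefficient of 0.98.

A thin command-line wrapper covers the same workflow
(`inst/cli/cineinr simulate | reconstruct | evaluate`), writing phantom
bundles, acquisition containers, NIfTI volumes, metrics CSVs and a run
manifest.

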