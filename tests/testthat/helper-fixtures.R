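# Shared in-code fixtures. Everything is generated programmatically at
# test time; grids are kept small so the whole suite stays fast.

small_phantom_spec <- function(n = 32L, tumor = if (n < 24L) 8 else 16) {
  phantom_spec(grid_shape = n, spacing = 4, tumor_diameter = tumor, seed = 0L)
}

random_complex_volume <- function(n = 12L, spacing = 4, seed = 1L) {
  set.seed(seed)
  complex_volume(array(complex(real = rnorm(n^3), imaginary = rnorm(n^3)),
                       rep(n, 3)), spacing)
}

# smooth separable gaussian blob, optionally shifted along SI (mm)
gaussian_volume <- function(n, spacing, sigma_mm, center_si = 0) {
  co <- grid_coords_mm(rep(n, 3), spacing)
  v <- exp(-(((co[, 1] - center_si)^2 + co[, 2]^2 + co[, 3]^2) / (2 * sigma_mm^2)))
  complex_volume(array(v, rep(n, 3)), spacing)
}

# a small dynamic phantom plus single-coil acquisition for training tests
make_small_study <- function(n = 32L, nt = 100L, scenario = "S1", seed = 0L,
                             spokes_per_frame = 17L) {
  spec <- small_phantom_spec(n) # 8-mm tumor below 24^3 so it fits the lung
  ref <- build_reference_volume(spec)
  pm <- simulate_phase_map(phase_map_spec(seed = seed + 1L), spec$grid_shape,
                           spec$spacing)
  refc <- apply_phase_modulation(ref$volume, pm)
  trace <- generate_motion_trace(scenario, duration_s = nt * 0.0986,
                                 frame_dt_s = 0.0986, seed = seed + 2L)
  basis <- build_motion_basis(spec)
  phantom <- synthesize_cine_sequence(refc, trace, basis, ref$tumor_mask)
  acq <- simulate_acquisition(phantom, spokes_per_frame = spokes_per_frame,
                              method = "gridded")
  list(spec = spec, ref = ref, phantom = phantom, acq = acq, basis = basis)
}

# smooth random displacement fields for PCA tests
smooth_random_dvf <- function(n, spacing, seed, scale = 5) {
  set.seed(seed)
  d <- array(rnorm(n^3 * 3), c(rep(n, 3), 3))
  for (a in 1:3) d[, , , a] <- cineinr:::gaussian_smooth3(d[, , , a], 2) * scale
  dvf(d, spacing)
}
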