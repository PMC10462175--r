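# Synthetic thorax phantom: geometry, phase modulation, breathing traces,
# and ground-truth cine synthesis.

test_that("reference volume reproduces the study geometry and tumor size", {
  spec <- phantom_spec() # defaults: 100^3 at 4 mm, 30-mm tumor
  ref <- build_reference_volume(spec)
  expect_identical(grid_shape(ref$volume), c(100L, 100L, 100L))
  expect_equal(ref$volume$spacing, rep(4, 3))
  expected_vox <- (4 / 3) * pi * 15^3 / prod(spec$spacing)
  expect_lt(abs(sum(ref$tumor_mask) - expected_vox) / expected_vox, 0.05)
  # tumor sits inside the lung
  expect_false(any(ref$tumor_mask & !(ref$lung_mask | ref$tumor_mask)))
  # magnitude-only and nonnegative
  expect_true(all(Im(ref$volume$data) == 0))
  expect_true(all(Re(ref$volume$data) >= 0))
})

test_that("phantom construction is deterministic and validates the tumor", {
  a <- build_reference_volume(small_phantom_spec())
  b <- build_reference_volume(small_phantom_spec())
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$tumor_mask, b$tumor_mask)
  # a tumor reaching outside the grid errors
  expect_error(build_reference_volume(
    phantom_spec(grid_shape = 32, spacing = 4, tumor_diameter = 16,
                 tumor_center = c(120, 0, 0))), "grid")
  # a tumor outside the lung errors
  expect_error(build_reference_volume(
    phantom_spec(grid_shape = 32, spacing = 4, tumor_diameter = 16,
                 tumor_center = c(-40, 0, 0))), "lung")
})

test_that("phase map is normalised to [0, 2pi] with in-range wave numbers", {
  ph <- simulate_phase_map(phase_map_spec(seed = 5L), rep(32L, 3), 4)
  expect_equal(min(ph), 0)
  expect_equal(max(ph), 2 * pi)
  kn <- attr(ph, "wavenumbers")
  expect_length(kn, 4L)
  expect_true(all(kn >= 0.0033 & kn <= 0.02))
  expect_error(phase_map_spec(n_sinusoids = 0L), "n_sinusoids")
  # modulation is unit-modulus
  vol <- gaussian_volume(32, 4, 30)
  mod <- apply_phase_modulation(vol, ph)
  nz <- Mod(vol$data) > 1e-12
  expect_equal(max(abs(Mod(mod$data)[nz] - Mod(vol$data)[nz])), 0, tolerance = 1e-12)
})

test_that("single sinusoid along SI varies only along SI", {
  spec <- phase_map_spec(n_sinusoids = 1L, seed = 2L,
                         orientations = matrix(c(1, 0, 0), 1, 3))
  ph <- simulate_phase_map(spec, rep(16L, 3), 4)
  # constant over AP/LR at fixed SI
  for (i in c(1L, 8L, 16L))
    expect_lt(diff(range(ph[i, , ])), 1e-10)
  expect_gt(diff(range(ph[, 1, 1])), 1)
})

test_that("motion traces carry the scenario signatures", {
  # counting identity: 180 s at 98.6 ms -> 1826 frames
  tr <- generate_motion_trace("S1", 180, 0.0986, seed = 1L)
  expect_length(tr$times, 1826L)
  # trace covers the duration: (len-1)*dt < duration <= len*dt
  n <- length(tr$times)
  expect_lt((n - 1) * tr$frame_dt, 180)
  expect_gte(n * tr$frame_dt, 180)
  # S1: constant baseline
  expect_equal(diff(range(tr$baseline)), 0)
  # S2: -7 mm baseline step around 90 s
  tr2 <- generate_motion_trace("S2", 180, 0.0986, seed = 1L)
  expect_equal(mean(tr2$baseline[tr2$times > 100]) -
                 mean(tr2$baseline[tr2$times < 80]), -7, tolerance = 0.5)
  # S4 changes period after 60 s: count exhale troughs per half
  tr4 <- generate_motion_trace("S4", 180, 0.0986, seed = 1L)
  zero_runs <- function(x) sum(diff(x < 1) == 1)
  expect_gt(zero_runs(tr4$amplitude[tr4$times >= 60]),
            zero_runs(tr4$amplitude[tr4$times < 60]))
  # S5 amplitude decays
  tr5 <- generate_motion_trace("S5", 180, 0.0986, seed = 1L)
  expect_lt(max(tr5$amplitude[tr5$times > 150]), max(tr5$amplitude[tr5$times < 30]))
  expect_error(generate_motion_trace("S7", 180, 0.0986), "scenario")
  # seeded regeneration is bit-identical
  expect_identical(generate_motion_trace("S6", 60, 0.0986, seed = 9L),
                   generate_motion_trace("S6", 60, 0.0986, seed = 9L))
})

test_that("cine synthesis warps the reference by the trace-scaled basis", {
  spec <- small_phantom_spec()
  ref <- build_reference_volume(spec)
  basis <- build_motion_basis(spec)
  trace <- generate_motion_trace("S1", 20, 0.0986, seed = 3L)
  ph <- synthesize_cine_sequence(ref$volume, trace, basis, ref$tumor_mask)
  # frame images equal warp of the reference by the frame field, bit-exact
  t <- 57L
  expect_identical(phantom_frame(ph, t)$data,
                   warp_volume(ph$reference, phantom_frame_dvf(ph, t))$data)
  # 20-mm peak-to-peak SI displacement at the diaphragm apex
  apex <- diaphragm_apex_voxel(basis)
  si <- vapply(seq_along(trace$times), function(t)
    phantom_frame_dvf(ph, t)$displacement[apex[1], apex[2], apex[3], 1],
    numeric(1))
  expect_equal(diff(range(si)), 20, tolerance = 1)
  # zero-amplitude trace reproduces the reference in every frame
  tr0 <- trace
  tr0$amplitude[] <- 0; tr0$baseline[] <- 0
  ph0 <- synthesize_cine_sequence(ref$volume, tr0, basis)
  expect_identical(phantom_frame(ph0, 5L)$data, ref$volume$data)
  # grid mismatch errors
  small <- build_reference_volume(small_phantom_spec(n = 16L, tumor = 8))
  expect_error(synthesize_cine_sequence(small$volume, trace, basis), "grid")
})

test_that("tumor centre of mass follows the SI trace monotonically", {
  spec <- small_phantom_spec()
  ref <- build_reference_volume(spec)
  basis <- build_motion_basis(spec)
  trace <- generate_motion_trace("S1", 10, 0.0986, seed = 4L)
  ph <- synthesize_cine_sequence(ref$volume, trace, basis, ref$tumor_mask)
  mask <- binary_mask(ref$tumor_mask, spec$spacing)
  s <- ph$scale_series
  # frames at well-separated displacement amplitudes
  targets <- seq(min(s), max(s), length.out = 5)
  pick <- vapply(targets, function(tv) which.min(abs(s - tv)), integer(1))
  s <- s[pick]
  expect_true(all(diff(s) > 1))
  com_si <- vapply(pick, function(t) {
    m <- propagate_contour(mask, phantom_frame_dvf(ph, t))
    co <- grid_coords_mm(dim(m$data), m$spacing)
    mean(co[as.vector(m$data), 1])
  }, numeric(1))
  # pull convention: larger inhale displacement moves the tumor inferior
  expect_true(all(diff(com_si) < 0))
})
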