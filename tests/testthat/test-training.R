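# Losses, warm start, and the progressive training machinery.

test_that("k-space loss matches its closed forms", {
  set.seed(1)
  s <- matrix(complex(real = rnorm(40), imaginary = rnorm(40)), 20, 2)
  expect_equal(loss_kspace(s, s), 0)
  eps <- 0.37
  bump <- s
  bump[, 1] <- bump[, 1] + eps # uniform per-sample offset on one coil
  expect_equal(loss_kspace(bump, s), eps^2, tolerance = 1e-12)
  expect_gte(loss_kspace(matrix(rnorm(20) + 0i), matrix(rnorm(20) + 0i)), 0)
  expect_error(loss_kspace(s, s[1:10, ]), "shape")
  # analytic gradient agrees with finite differences
  g <- cineinr:::loss_kspace_grad(s, 0 * s)
  fd <- (loss_kspace(s + 1e-6, 0 * s) - loss_kspace(s, 0 * s)) / 1e-6
  expect_equal(sum(Re(g)), fd, tolerance = 1e-4)
})

test_that("total variation counts gradient magnitude", {
  expect_equal(loss_tv(complex_volume(array(3 - 2i, rep(6L, 3)), 4)), 0)
  # unit step across one plane in an N^3 volume: N^2 unit gradients
  N <- 6L
  step <- array(0, rep(N, 3)); step[4:6, , ] <- 1
  expect_equal(loss_tv(complex_volume(step, 4), eps = 1e-14), N^2,
               tolerance = 1e-4)
  # positive homogeneity
  z <- random_complex_volume(6, seed = 3L)
  expect_equal(loss_tv(complex_volume(2.5 * z$data, 4), eps = 1e-14),
               2.5 * loss_tv(z, eps = 1e-14), tolerance = 1e-6)
})

test_that("warm start reconstructs a static phantom from the exhale bin", {
  spec <- small_phantom_spec()
  ref <- build_reference_volume(spec)
  trace <- generate_motion_trace("S1", 100 * 0.0986, 0.0986, seed = 1L)
  trace$amplitude[] <- 0; trace$baseline[] <- 0 # motionless
  phantom <- synthesize_cine_sequence(ref$volume, trace, build_motion_basis(spec))
  acq <- simulate_acquisition(phantom, spokes_per_frame = 17L)
  # static data carry no respiratory signal; supply an external navigator
  nav <- sin(2 * pi * seq_len(nrow(acq$trajectory$spoke_dirs)) / 170)
  warm <- warm_start_reference(acq, surrogate = nav, n_bins = 10L)
  spokes0 <- attr(warm, "bin_spokes")
  # exactly the bin-0 spokes were selected (about a 10% budget)
  expect_identical(spokes0, which(sort_phases(nav, 10L) == 0L))
  expect_lt(abs(length(spokes0) / length(nav) - 0.1), 0.03)
  expect_lt(relative_error(warm, ref$volume), 0.15)
  # deterministic given the acquisition
  warm2 <- warm_start_reference(acq, surrogate = nav, n_bins = 10L)
  expect_identical(warm$data, warm2$data)
})

test_that("stage 2 alone identifies a 16^3 image from full k-space coverage", {
  spec <- small_phantom_spec(n = 16L, tumor = 8)
  ref <- build_reference_volume(spec)
  trace <- generate_motion_trace("S1", 1 * 0.0986, 0.0986, seed = 1L)
  trace$amplitude[] <- 0; trace$baseline[] <- 0
  phantom <- synthesize_cine_sequence(ref$volume, trace, build_motion_basis(spec))
  # one frame holding 900 spokes: fully sampled at this grid
  acq <- simulate_acquisition(phantom, spokes_per_frame = 900L,
                              method = "gridded")
  still <- compute_pca_basis(lapply(1:3, function(i) zero_dvf(rep(16L, 3), 4)),
                             n_pc = 3L)
  cfg <- reduced_train_config(grid_n = 16L, n_frames = 1L, seed = 0L,
                              stage_epochs = c(150L, 300L, 1L),
                              lambda_tv = 0, frames_per_epoch = 1L,
                              n_bins = 1L)
  res <- run_progressive_training(acq, still, cfg,
                                  surrogate = rep(0, 900))
  expect_lt(relative_error(res$reference, ref$volume), 0.05)
})

test_that("a joint training epoch updates both representations end to end", {
  st <- make_small_study(n = 16L, nt = 85L, seed = 5L)
  model <- phantom_motion_model(st$phantom)
  cfg <- reduced_train_config(grid_n = 16L, n_frames = 85L, seed = 1L,
                              stage_epochs = c(2L, 2L, 2L),
                              frames_per_epoch = 4L)
  nav <- rep(st$phantom$scale_series, each = 17L)
  res <- run_progressive_training(st$acq, model, cfg, surrogate = -nav)
  fresh_t <- temporal_inr(cfg$temporal_encoding, n_frames = 85L,
                          seed = cfg$seed + 23L)
  # temporal INR moved away from its initialisation (tables and MLPs)
  expect_gt(max(abs(res$temporal_model$tables[[1]] - fresh_t$tables[[1]])), 0)
  expect_gt(max(abs(res$temporal_model$mlps[[1]]$W1 - fresh_t$mlps[[1]]$W1)), 0)
  # loss history recorded per stage and finite
  expect_length(res$loss_history$stage3, 2L)
  expect_true(all(is.finite(unlist(res$loss_history))))
  # solved fields compose on demand with the model geometry
  d <- recon_frame_dvf(res, 3L)
  expect_identical(grid_shape(d), c(16L, 16L, 16L))
})

test_that("epoch partitioning barely changes the optimisation outcome", {
  st <- make_small_study(n = 16L, nt = 100L, seed = 7L)
  model <- phantom_motion_model(st$phantom)
  nav <- -rep(st$phantom$scale_series, each = 17L)
  # compare the deterministic end-point quality (mean cine relative error):
  # the raw minibatch loss fluctuates with the sampled frame subsets
  run_with <- function(epochs, fpe) {
    cfg <- reduced_train_config(grid_n = 16L, n_frames = 100L, seed = 2L,
                                stage_epochs = c(80L, 60L, epochs),
                                frames_per_epoch = fpe)
    res <- run_progressive_training(st$acq, model, cfg, surrogate = nav)
    ev <- evaluate_reconstruction(res, st$phantom, frames = seq(1, 100, by = 5))
    c(re = mean(ev$re), come = mean(ev$come_mm))
  }
  a <- run_with(60L, 10L)
  b <- run_with(30L, 20L) # doubled frames per epoch, halved epochs
  expect_lt(abs(a["re"] - b["re"]) / a["re"], 0.10)
  expect_lt(a["come"], 4); expect_lt(b["come"], 4) # both stay sub-voxel
})
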