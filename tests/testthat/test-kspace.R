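# k-space physics: trajectory, forward model, adjoint, reconstruction,
# surrogate extraction, phase sorting, frame binning.

test_that("kooshball trajectory crosses the origin with unit spoke directions", {
  tr <- kooshball_trajectory(100, 17, 4)
  expect_equal(max(abs(sqrt(rowSums(tr$spoke_dirs^2)) - 1)), 0, tolerance = 1e-12)
  mids <- (1:100 - 1) * 17 + 9
  expect_true(all(rowSums(tr$k_coords[mids, , drop = FALSE]^2) == 0))
  expect_equal(max(sqrt(rowSums(tr$k_coords^2))), 1 / 8, tolerance = 1e-12)
  expect_error(kooshball_trajectory(10, 16, 4), "odd")
})

test_that("golden-mean ordering covers the sphere better than a sequential sweep", {
  n <- 1000L
  gm <- kooshball_trajectory(n, 3, 4)$spoke_dirs
  # sequential-uniform comparator: polar angle swept uniformly once,
  # azimuth advancing through the same total number of turns
  z <- 1 - 2 * (seq_len(n) - 1) / (n - 1)
  az <- 2 * pi * (seq_len(n) - 1) / n
  rho <- sqrt(pmax(0, 1 - z^2))
  sq <- cbind(z, rho * cos(az), rho * sin(az))
  # max angular distance from a 1-degree test grid to the nearest spoke
  th <- seq(0.5, 179.5, by = 1) * pi / 180
  phi <- seq(0, 359, by = 1) * pi / 180
  gridd <- cbind(rep(cos(th), each = length(phi)),
                 rep(sin(th), each = length(phi)) * cos(phi),
                 rep(sin(th), each = length(phi)) * sin(phi))
  maxgap <- function(dirs) {
    worst <- 0
    dall <- rbind(dirs, -dirs) # spokes sample both hemispheres
    for (start in seq(1, nrow(gridd), by = 8192)) {
      blk <- gridd[start:min(start + 8191, nrow(gridd)), , drop = FALSE]
      best <- apply(blk %*% t(dall), 1, max)
      worst <- max(worst, max(acos(pmin(1, best))))
    }
    worst
  }
  expect_lt(maxgap(gm), maxgap(sq))
})

test_that("forward model matches its exact and analytic oracles", {
  vol <- random_complex_volume(16, seed = 3L)
  # DC sample equals the voxel sum under a uniform unit coil
  dc <- forward_model(vol, matrix(0, 1, 3), method = "exact")
  expect_equal(dc[1, 1], sum(vol$data), tolerance = 1e-10)
  # linearity
  tr <- kooshball_trajectory(20, 9, 4)
  v2 <- random_complex_volume(16, seed = 4L)
  lhs <- forward_model(complex_volume((2 - 1i) * vol$data + 0.5 * v2$data, 4),
                       tr$k_coords, method = "exact")
  rhs <- (2 - 1i) * forward_model(vol, tr$k_coords, method = "exact") +
    0.5 * forward_model(v2, tr$k_coords, method = "exact")
  expect_equal(max(Mod(lhs - rhs)) / max(Mod(rhs)), 0, tolerance = 1e-10)
  # real even-symmetric image: Hermitian-symmetric samples along each spoke
  ev <- gaussian_volume(16, 4, 20)
  se <- forward_model(ev, tr$k_coords, method = "exact")
  for (sp in 0:2) {
    line <- se[sp * 9 + 1:9, 1]
    expect_equal(line, Conj(rev(line)), tolerance = 1e-10)
  }
  # gridded path agrees with the exact non-uniform DFT
  trg <- kooshball_trajectory(50, 17, 4)
  sg <- forward_model(vol, trg$k_coords, method = "gridded")
  sx <- forward_model(vol, trg$k_coords, method = "exact")
  expect_lt(sqrt(sum(Mod(sg - sx)^2) / sum(Mod(sx)^2)), 1e-4)
  expect_error(forward_model(vol, trg$k_coords,
                             coil_maps = list(array(1 + 0i, rep(8L, 3)))),
               "grid")
})

test_that("forward and adjoint satisfy the inner-product identity", {
  set.seed(8)
  tr <- kooshball_trajectory(30, 13, 4)
  plan <- nufft_plan(tr$k_coords, rep(12L, 3), 4)
  for (rep_i in 1:3) {
    z <- array(complex(real = rnorm(12^3), imaginary = rnorm(12^3)), rep(12L, 3))
    s <- complex(real = rnorm(nrow(tr$k_coords)),
                 imaginary = rnorm(nrow(tr$k_coords)))
    lhs <- sum(Conj(s) * cineinr:::nufft_forward_op(plan, z))
    rhs <- sum(Conj(cineinr:::nufft_adjoint_op(plan, s)) * z)
    expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-6)
  }
})

test_that("NUFFT reconstruction resolves points and smooth objects", {
  # empty samples: zero volume with a warning
  expect_warning(r0 <- nufft_adjoint_recon(matrix(0 + 0i, 0, 1),
                                           matrix(0, 0, 3), rep(8L, 3), 4),
                 "empty")
  expect_true(all(Mod(r0$data) == 0))
  # point-spread: dominant central peak (beyond the intrinsic main lobe)
  N <- 16L
  ctr <- rep(N / 2 + 1, 3)
  delta <- array(0 + 0i, rep(N, 3)); delta[ctr[1], ctr[2], ctr[3]] <- 1
  tr <- kooshball_trajectory(2000, 17, 4)
  s <- forward_model(complex_volume(delta, 4), tr$k_coords, method = "gridded")
  rec <- nufft_adjoint_recon(s, tr$k_coords, rep(N, 3), 4)
  m <- Mod(rec$data)
  peak <- m[ctr[1], ctr[2], ctr[3]]
  lobe <- array(FALSE, rep(N, 3))
  lobe[ctr[1] + (-1:1), ctr[2] + (-1:1), ctr[3] + (-1:1)] <- TRUE
  expect_gt(peak / max(m[!lobe]), 10)
  # oversampled sanity: smooth phantom, 10,000 spokes on 32^3
  spec <- small_phantom_spec()
  ref <- build_reference_volume(spec)
  trb <- kooshball_trajectory(10000, 33, 4)
  plan <- nufft_plan(trb$k_coords, rep(32L, 3), 4, os = 1.25, width = 4L)
  sb <- forward_model(ref$volume, trb$k_coords, method = "gridded", plan = plan)
  recb <- nufft_adjoint_recon(sb, trb$k_coords, rep(32L, 3), 4, plan = plan)
  expect_lt(relative_error(recb, ref$volume), 0.1)
})

test_that("surrogate extraction recovers the respiratory source", {
  set.seed(11)
  fs <- 172
  t <- seq(0, 60, by = 1 / fs)
  src <- sin(2 * pi * 0.25 * t)
  # 24 channels: random mixtures + white noise at SNR 5, on a carrier
  # offset so channel magnitudes respond linearly
  ch <- outer(src, rnorm(24)) +
    matrix(rnorm(length(t) * 24, sd = sqrt(1 / 5)), length(t), 24) + 10
  sur <- extract_surrogate(ch, fs)
  expect_gt(abs(cor(as.numeric(sur), src)), 0.99)
  # band selection: 0.05 Hz drift loses to the 0.25 Hz respiratory source
  drift <- sin(2 * pi * 0.05 * t)
  ch2 <- outer(drift, rnorm(24)) + outer(src, rnorm(24)) + 10
  sur2 <- extract_surrogate(ch2, fs)
  expect_gt(abs(cor(as.numeric(sur2), src)), abs(cor(as.numeric(sur2), drift)))
  # a single clean channel comes back as itself (up to sign/scale)
  one <- matrix(src + 10, ncol = 1)
  sur3 <- extract_surrogate(one, fs)
  expect_gt(abs(cor(as.numeric(sur3), src)), 0.999)
  expect_error(extract_surrogate(matrix(1, 100, 3), fs), "constant")
  expect_error(extract_surrogate(one, 0.5), "fs")
})

test_that("phase sorting bins cycles with bin 0 at end of exhale", {
  tt <- seq(0, 120, by = 0.1)
  # pure sinusoid: every bin holds 10% (+/- 2%) of samples
  b <- sort_phases(sin(2 * pi * tt / 4), 10)
  occ <- tabulate(b + 1L, 10) / length(b)
  expect_true(all(abs(occ - 0.1) < 0.02))
  # n_bins = 1: everything in bin 0
  expect_true(all(sort_phases(sin(2 * pi * tt / 4), 1) == 0L))
  # exhale-dwelling trace: bin-0 samples sit on the exhale plateau
  s <- -20 * sin(pi * tt / 4)^4 # exhale (s = 0) at the top
  bs <- sort_phases(s, 10)
  expect_gt(mean(s[bs == 0] >= quantile(s, 0.9)), 0.85)
  expect_error(sort_phases(sin(2 * pi * seq(0, 2, by = 0.1) / 40), 10), "cycles")
})

test_that("frame binning partitions the spokes exactly", {
  st <- make_small_study(n = 16L, nt = 20L)
  acq <- st$acq
  expect_identical(frame_timing(17, 0.0058)$frame_dt, acq$frame_dt)
  all_rows <- unlist(lapply(seq_len(cineinr:::n_frames(acq)), function(t)
    cineinr:::frame_sample_rows(acq, t)))
  expect_identical(all_rows, seq_len(nrow(acq$samples)))
  # centre series picks the k = 0 sample of every spoke
  ctr <- cineinr:::center_sample_series(acq)
  expect_equal(nrow(ctr), nrow(acq$trajectory$spoke_dirs))
  mids <- which(rowSums(acq$trajectory$k_coords^2) == 0)
  expect_equal(as.vector(ctr[, 1]), as.vector(acq$samples[mids, 1]))
})
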