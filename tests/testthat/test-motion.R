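# DVF algebra: warping, demons registration, PCA basis, composition.

test_that("warp_volume honours the pull convention and its oracles", {
  vol <- random_complex_volume(12)
  # zero field: identity, bit-exact at grid points
  expect_identical(warp_volume(vol, zero_dvf(rep(12L, 3), 4))$data, vol$data)
  # +1 voxel SI (+4 mm at 4-mm spacing): integer roll with a zero slab
  d1 <- zero_dvf(rep(12L, 3), 4)
  d1$displacement[, , , 1] <- 4
  w1 <- warp_volume(vol, d1)
  oracle <- array(0 + 0i, rep(12L, 3))
  oracle[1:11, , ] <- vol$data[2:12, , ]
  expect_equal(w1$data, oracle)
  expect_true(all(w1$data[12, , ] == 0))
  # smooth gaussian, +2 mm: matches the analytic shift to <1% RMS
  g0 <- gaussian_volume(32, 4, 20)
  g2 <- gaussian_volume(32, 4, 20, center_si = -2)
  dg <- zero_dvf(rep(32L, 3), 4)
  dg$displacement[, , , 1] <- 2
  wg <- warp_volume(g0, dg)
  expect_lt(sqrt(sum(Mod(wg$data - g2$data)^2) / sum(Mod(g2$data)^2)), 0.01)
  # linear in the image argument
  v2 <- random_complex_volume(12, seed = 2L)
  d <- zero_dvf(rep(12L, 3), 4)
  d$displacement[] <- rnorm(length(d$displacement), sd = 3)
  lhs <- warp_volume(complex_volume(2 * vol$data + (1 - 2i) * v2$data, 4), d)$data
  rhs <- 2 * warp_volume(vol, d)$data + (1 - 2i) * warp_volume(v2, d)$data
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_error(warp_volume(vol, zero_dvf(rep(10L, 3), 4)), "grid")
})

test_that("demons registration recovers known transforms", {
  spec <- small_phantom_spec()
  ref <- build_reference_volume(spec)
  # identity case
  d0 <- register_inter_phase(ref$volume, ref$volume,
                             params = list(iters = 10L))
  expect_lt(max(abs(d0$displacement)) / 4, 0.1)
  # 2-voxel SI translation: warp the reference by a constant field
  dt <- zero_dvf(grid_shape(ref$volume), 4)
  dt$displacement[, , , 1] <- 8
  moved <- warp_volume(ref$volume, dt)
  d <- register_inter_phase(ref$volume, moved)
  body <- Mod(ref$volume$data) > 0.3
  # interior body only (boundary voxels see the zero-fill)
  body[c(1:4, 29:32), , ] <- FALSE
  mean_si <- mean(d$displacement[, , , 1][body])
  expect_lt(abs(mean_si - 8) / 4, 0.5)
  # round trip: warping the moving image by the field reproduces the fixed
  back <- warp_volume(ref$volume, d)
  expect_lt(relative_error(back, moved), 0.1)
  bad <- ref$volume; bad$data[1] <- NaN
  expect_error(register_inter_phase(bad, ref$volume), "finite")
})

test_that("PCA basis is orthonormal with descending variance", {
  dvfs <- lapply(1:5, function(i) smooth_random_dvf(10, 4, seed = i))
  model <- compute_pca_basis(dvfs, n_pc = 3L)
  for (i in 1:3) for (j in 1:3) {
    ip <- sum(model$components[[i]]$displacement *
                model$components[[j]]$displacement)
    expect_equal(ip, as.numeric(i == j), tolerance = 1e-6)
  }
  expect_true(all(diff(model$explained_variance) <= 1e-12))
  # mean is the elementwise average
  avg <- Reduce(`+`, lapply(dvfs, function(d) d$displacement)) / 5
  expect_equal(model$mean$displacement, avg, tolerance = 1e-12)
})

test_that("PCA rank-1 closed form and degenerate inputs", {
  u <- smooth_random_dvf(8, 4, seed = 42L)
  dvfs <- lapply(c(-2, 0.5, 1, 3), function(c) dvf(c * u$displacement, 4))
  model <- compute_pca_basis(dvfs, n_pc = 3L)
  un <- u$displacement / sqrt(sum(u$displacement^2))
  e1 <- model$components[[1]]$displacement
  expect_equal(abs(sum(e1 * un)), 1, tolerance = 1e-8)
  expect_equal(model$explained_variance[1] / sum(model$explained_variance), 1,
               tolerance = 1e-10)
  expect_equal(model$explained_variance[2:3], c(0, 0))
  # identical inputs: flagged degenerate, mean preserved, zero variance
  same <- lapply(1:4, function(i) u)
  dm <- compute_pca_basis(same, n_pc = 2L)
  expect_true(dm$degenerate)
  expect_equal(dm$mean$displacement, u$displacement)
  expect_equal(dm$explained_variance, c(0, 0))
  expect_true(all(vapply(dm$components,
                         function(cc) all(cc$displacement == 0), logical(1))))
})

test_that("PCA reconstruction error shrinks with more components", {
  dvfs <- lapply(1:6, function(i) smooth_random_dvf(8, 4, seed = 10L + i))
  errs <- vapply(1:5, function(npc) {
    m <- compute_pca_basis(dvfs, n_pc = npc)
    tot <- 0
    for (d in dvfs) {
      resid <- d$displacement - m$mean$displacement
      for (i in seq_len(npc)) {
        e <- m$components[[i]]$displacement
        resid <- resid - sum(resid * e) * e
      }
      tot <- tot + sum(resid^2)
    }
    tot / sum(vapply(dvfs, function(d)
      sum((d$displacement - m$mean$displacement)^2), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[5], 1e-5) # n_pc = n_bin - 1 reconstructs the training set
})

test_that("compose_dvf applies per-axis weights over the mean field", {
  dvfs <- lapply(1:5, function(i) smooth_random_dvf(8, 4, seed = 20L + i))
  model <- compute_pca_basis(dvfs, n_pc = 3L)
  # zero weights return the mean exactly
  expect_identical(compose_dvf(model, matrix(0, 3, 3))$displacement,
                   model$mean$displacement)
  # superposition
  w1 <- matrix(rnorm(9), 3, 3); w2 <- matrix(rnorm(9), 3, 3)
  lhs <- compose_dvf(model, w1)$displacement + compose_dvf(model, w2)$displacement -
    model$mean$displacement
  expect_equal(lhs, compose_dvf(model, w1 + w2)$displacement, tolerance = 1e-12)
  expect_error(compose_dvf(model, rep(0, 8)), "weights")
  # per-axis scaling spans more than global component scaling: scaling the
  # SI channel only differs from any single global weight
  wsi <- matrix(0, 3, 3); wsi[1, 1] <- 1
  dsi <- compose_dvf(model, wsi)$displacement - model$mean$displacement
  e1 <- model$components[[1]]$displacement
  expect_equal(dsi[, , , 1], e1[, , , 1], tolerance = 1e-12)
  expect_true(all(dsi[, , , 2:3] == 0))
  expect_gt(sum(e1[, , , 2:3]^2), 0)
})

test_that("per-axis projections reconstruct a training field up to residual", {
  # components with disjoint axis support make the projection identity exact
  n <- 8L
  u1 <- array(0, c(rep(n, 3), 3))
  u1[, , , 1] <- cineinr:::gaussian_smooth3(array(rnorm(n^3), rep(n, 3)), 2)
  u2 <- array(0, c(rep(n, 3), 3))
  u2[, , , 2] <- cineinr:::gaussian_smooth3(array(rnorm(n^3), rep(n, 3)), 2)
  dvfs <- lapply(list(c(1, 0.2), c(2, -1), c(-1, 0.5), c(0.3, 2)), function(cc)
    dvf(cc[1] * u1 + cc[2] * u2, 4))
  model <- compute_pca_basis(dvfs, n_pc = 3L)
  Dp <- dvfs[[2]]$displacement
  centred <- Dp - model$mean$displacement
  w <- matrix(0, 3, 3)
  for (i in 1:3) for (a in 1:3)
    w[i, a] <- sum(centred[, , , a] * model$components[[i]]$displacement[, , , a])
  rec <- compose_dvf(model, w)$displacement
  resid2 <- sum((Dp - rec)^2)
  expect_equal(resid2, sum(centred^2) - sum(w^2), tolerance = 1e-8)
  expect_lt(resid2 / sum(centred^2), 1e-10) # rank 2 set, 3 components
})
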