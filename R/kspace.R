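# k-space physics: golden-mean Koosh-ball radial trajectory, the
# (multi-coil) non-uniform Fourier forward model and its exact adjoint,
# Kaiser-Bessel gridding for large grids, density-compensated adjoint
# reconstruction, respiratory surrogate extraction from the k-space
# centre, and phase sorting.
#
# Conventions: k in cycles/mm, image coordinates in mm with the origin at
# the grid centre, forward exponent exp(-2*pi*1i * k.x).

# 2D golden means driving the spoke orientation order.
GOLDEN_MEAN_1 <- 0.465571231876768
GOLDEN_MEAN_2 <- 0.682327803828019

#' Golden-mean Koosh-ball radial trajectory
#'
#' Spoke `m` (0-based) points along polar `z = 1 - 2*frac(m*phi1)` and
#' azimuth `2*pi*frac(m*phi2)` with the two-dimensional golden means
#' `phi1 = 0.46557...`, `phi2 = 0.68233...`, so consecutive spokes spread
#' incoherently over the sphere. Readout points are uniformly spaced on
#' `[-k_max, k_max]` along each spoke with `k_max = 1/(2*spacing)`; an odd
#' sample count guarantees the k-space origin is sampled on every spoke.
#'
#' @param n_spokes number of radial readout lines.
#' @param samples_per_spoke odd number of readout points per spoke.
#' @param spacing image voxel spacing in mm (k_max uses its maximum).
#' @param TR repetition time in seconds (default 5.8 ms).
#' @return A `trajectory`: `spoke_dirs` (`n_spokes x 3` unit vectors),
#'   `k_coords` (`n_spokes*samples_per_spoke x 3`, spoke-major order),
#'   `samples_per_spoke`, `TR`, `k_max`.
#' @export
kooshball_trajectory <- function(n_spokes, samples_per_spoke, spacing,
                                 TR = 0.0058) {
  if (n_spokes < 1L) stop("n_spokes must be at least 1")
  if (samples_per_spoke %% 2L == 0L)
    stop("samples_per_spoke must be odd so the k-space origin is sampled")
  spacing <- rep_len(as.numeric(spacing), 3L)
  m <- seq_len(n_spokes) - 1
  z <- 1 - 2 * ((m * GOLDEN_MEAN_1) %% 1)
  az <- 2 * pi * ((m * GOLDEN_MEAN_2) %% 1)
  rho <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(si = z, ap = rho * cos(az), lr = rho * sin(az))
  k_max <- 1 / (2 * max(spacing))
  radii <- seq(-k_max, k_max, length.out = samples_per_spoke)
  k <- dirs[rep(seq_len(n_spokes), each = samples_per_spoke), , drop = FALSE] *
    rep(radii, times = n_spokes)
  structure(list(spoke_dirs = dirs, samples_per_spoke = as.integer(samples_per_spoke),
                 k_coords = k, TR = TR, k_max = k_max),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d spokes x %d samples, TR %.4g s, k_max %.4g /mm>\n",
              nrow(x$spoke_dirs), x$samples_per_spoke, x$TR, x$k_max))
  invisible(x)
}

#' Frame timing from spoke binning
#'
#' @param spokes_per_frame spokes binned into one cine frame.
#' @param TR repetition time in seconds.
#' @param duration_s optional scan duration; when given, the number of
#'   frames covering it is returned as well.
#' @return list with `frame_dt` (s) and, when `duration_s` is given,
#'   `n_frames = ceiling(duration_s / frame_dt)`.
#' @export
frame_timing <- function(spokes_per_frame, TR, duration_s = NULL) {
  out <- list(frame_dt = spokes_per_frame * TR)
  if (!is.null(duration_s)) out$n_frames <- ceiling(duration_s / out$frame_dt)
  out
}

# --- Kaiser-Bessel gridding plan --------------------------------------------

kb_beta <- function(width, os) {
  pi * sqrt((width / os)^2 * (os - 0.5)^2 - 0.8)
}

kb_kernel <- function(u, width, beta) {
  t <- 1 - (2 * u / width)^2
  out <- numeric(length(u))
  ok <- t > 0
  out[ok] <- besselI(beta * sqrt(t[ok]), 0) / besselI(beta, 0)
  out
}

# Fourier transform of the Kaiser-Bessel kernel at image position xi
# (cycles per k-grid sample), including all constants.
kb_kernel_ft <- function(xi, width, beta) {
  arg <- beta^2 - (pi * width * xi)^2
  out <- numeric(length(xi))
  pos <- arg > 0
  out[pos] <- sinh(sqrt(arg[pos])) / sqrt(arg[pos])
  neg <- !pos
  sq <- sqrt(-arg[neg])
  out[neg] <- ifelse(sq < 1e-12, 1, sin(sq) / sq)
  out * width / besselI(beta, 0)
}

#' Precompute a gridding interpolation plan for a set of k-space samples
#'
#' Builds the sparse Kaiser-Bessel interpolation operator between the
#' oversampled FFT grid and the non-Cartesian sample locations, plus the
#' deapodisation volume. The same plan serves the forward model and its
#' exact adjoint; per-frame sub-plans share the oversampled grid.
#'
#' @param k_coords `n x 3` matrix of sample frequencies in cycles/mm.
#' @param grid_shape,spacing image grid definition (even dimensions).
#' @param os oversampling factor (default 2).
#' @param width kernel width in oversampled grid units (default 6).
#' @param groups optional integer vector (length `n`) splitting the samples
#'   into sub-plans (e.g. frame indices); the plan then stores one sparse
#'   operator per group.
#' @return A `nufft_plan`.
#' @export
nufft_plan <- function(k_coords, grid_shape, spacing, os = 2, width = 6L,
                       groups = NULL) {
  grid_shape <- rep_len(as.integer(grid_shape), 3L)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(grid_shape %% 2L != 0L))
    stop("gridded NUFFT requires even grid dimensions; use the exact path")
  M <- as.integer(2 * ceiling(os * grid_shape / 2))
  beta <- kb_beta(width, mean(M / grid_shape))
  n <- nrow(k_coords)
  # per-axis neighbour indices and kernel weights
  axw <- vector("list", 3L); axj <- vector("list", 3L)
  for (a in 1:3) {
    kap <- k_coords[, a] * spacing[a] * M[a]
    j0 <- ceiling(kap - width / 2)
    js <- outer(j0, seq_len(width) - 1L, "+")
    axw[[a]] <- kb_kernel(kap - js, width, beta) * (1 - 2 * (abs(js) %% 2))
    dim(axw[[a]]) <- dim(js)
    axj[[a]] <- js %% M[a] # 0-based column index per axis
  }
  # assemble triplets over the width^3 neighbourhood
  nnz <- n * width^3
  ti <- integer(nnz); tj <- integer(nnz); tx <- numeric(nnz)
  pos <- 0L
  rows <- seq_len(n)
  for (ox in seq_len(width)) for (oy in seq_len(width)) for (oz in seq_len(width)) {
    idx <- pos + rows
    ti[idx] <- rows
    tj[idx] <- 1L + axj[[1]][, ox] + M[1] * (axj[[2]][, oy] + M[2] * axj[[3]][, oz])
    tx[idx] <- axw[[1]][, ox] * axw[[2]][, oy] * axw[[3]][, oz]
    pos <- pos + n
  }
  # deapodisation over the (cropped) image grid
  deap <- lapply(1:3, function(a) {
    v <- seq_len(grid_shape[a]) - 1 - grid_shape[a] / 2
    kb_kernel_ft(v / M[a], width, beta)
  })
  psi <- outer(outer(deap[[1]], deap[[2]]), deap[[3]])
  dim(psi) <- grid_shape
  crop <- lapply(1:3, function(a) ((M[a] - grid_shape[a]) %/% 2) + seq_len(grid_shape[a]))
  mk <- function(sel) {
    S <- Matrix::sparseMatrix(i = ti[sel], j = tj[sel], x = tx[sel],
                              dims = c(n, prod(M)), index1 = TRUE)
    list(S = S, St = Matrix::t(S))
  }
  ops <- if (is.null(groups)) list(all = mk(seq_len(nnz))) else {
    tgrp <- groups[ti]
    by_group <- split(seq_len(nnz), tgrp)
    sel_of <- split(seq_len(n), groups)
    remap <- integer(n)
    out <- lapply(names(by_group), function(g) {
      rowsel <- sel_of[[g]]
      keep <- by_group[[g]]
      remap[rowsel] <- seq_along(rowsel)
      S <- Matrix::sparseMatrix(i = remap[ti[keep]], j = tj[keep],
                                x = tx[keep], dims = c(length(rowsel), prod(M)),
                                index1 = TRUE)
      list(S = S, St = Matrix::t(S), rows = rowsel)
    })
    names(out) <- names(by_group)
    out
  }
  structure(list(grid_shape = grid_shape, spacing = spacing, M = M,
                 os = os, width = width, psi = psi, crop = crop,
                 ops = ops, n_samples = n),
            class = "nufft_plan")
}

# forward: image (complex 3D array, cropped grid) -> complex samples
nufft_forward_op <- function(plan, z, op = plan$ops[[1]]) {
  q <- array(0 + 0i, plan$M)
  q[plan$crop[[1]], plan$crop[[2]], plan$crop[[3]]] <- z / plan$psi
  Q <- fft(q)
  as.vector(op$S %*% Re(Q)) + 1i * as.vector(op$S %*% Im(Q))
}

# exact adjoint of nufft_forward_op: samples -> complex 3D array
nufft_adjoint_op <- function(plan, s, op = plan$ops[[1]]) {
  Q <- as.vector(op$St %*% Re(s)) + 1i * as.vector(op$St %*% Im(s))
  dim(Q) <- plan$M
  q <- fft(Q, inverse = TRUE)
  q[plan$crop[[1]], plan$crop[[2]], plan$crop[[3]]] / plan$psi
}

# exact non-uniform DFT (oracle path, small grids)
ndft_matrix <- function(k_coords, grid_shape, spacing) {
  X <- grid_coords_mm(grid_shape, spacing)
  exp(-2i * pi * (k_coords %*% t(X)))
}

#' Multi-coil non-uniform Fourier forward model
#'
#' Evaluates `w_c(k) = sum_x map_c(x) z(x) exp(-2*pi*1i * k.x)` per coil,
#' either as an exact non-uniform DFT (small grids, the reference path) or
#' via Kaiser-Bessel gridding on an oversampled FFT grid (same contract to
#' about 1e-4 relative accuracy at the default kernel).
#'
#' @param vol a [complex_volume()].
#' @param k_coords `n x 3` sample frequencies in cycles/mm (ignored when
#'   `plan` is given).
#' @param coil_maps list of complex sensitivity arrays on the image grid,
#'   or `NULL` for a single uniform unit coil.
#' @param method `"auto"` (exact up to 20^3 voxels, gridded beyond),
#'   `"exact"`, or `"gridded"`.
#' @param plan optional precomputed [nufft_plan()] for the gridded path.
#' @return complex matrix `n x n_coils`.
#' @export
forward_model <- function(vol, k_coords = NULL, coil_maps = NULL,
                          method = c("auto", "exact", "gridded"), plan = NULL) {
  method <- match.arg(method)
  shape <- grid_shape(vol)
  if (!is.null(coil_maps))
    for (cm in coil_maps)
      if (!identical(dim(cm), shape)) stop("coil map grid mismatch")
  if (is.null(coil_maps)) coil_maps <- list(array(1 + 0i, shape))
  if (method == "auto")
    method <- if (prod(shape) <= 20^3 && is.null(plan)) "exact" else "gridded"
  if (method == "gridded" && is.null(plan))
    plan <- nufft_plan(k_coords, shape, vol$spacing)
  if (method == "exact") E <- ndft_matrix(k_coords, shape, vol$spacing)
  out <- vapply(coil_maps, function(cm) {
    zc <- cm * vol$data
    if (method == "exact") as.vector(E %*% as.vector(zc))
    else nufft_forward_op(plan, zc)
  }, complex(if (is.null(plan)) nrow(k_coords) else nrow(plan$ops[[1]]$S)))
  if (is.null(dim(out))) out <- matrix(out, ncol = length(coil_maps))
  out
}

#' Density-compensated NUFFT reconstruction
#'
#' Gridding reconstruction used for warm starts and the online 4D bins.
#' Samples are weighted by the exact radial-shell density compensation
#' (the k-space volume each radial sample represents, `~|k|^2` away from
#' the origin, with the shared origin sample weighted by its central
#' cell). The default solver runs a few conjugate-gradient iterations on
#' the density-weighted normal equations, with the normal operator
#' applied exactly as a Toeplitz-embedded convolution (the kernel is one
#' adjoint evaluation of the weights on a doubled grid), so covered
#' frequencies are reconstructed with unit gain and a fully sampled point
#' object reaches peak about 1. `solver = "adjoint"` gives the plain
#' conjugate-sensitivity-combined adjoint, self-calibrated to unit DC
#' gain with a centred delta.
#'
#' @param samples complex matrix `n x n_coils` (or vector for one coil).
#' @param k_coords sample frequencies (cycles/mm).
#' @param grid_shape,spacing image grid definition.
#' @param coil_maps list of complex sensitivity arrays or `NULL`.
#' @param plan optional precomputed [nufft_plan()].
#' @param solver `"cg"` (default) or `"adjoint"`.
#' @param iters conjugate-gradient iterations (default 10).
#' @return A [complex_volume()].
#' @export
nufft_adjoint_recon <- function(samples, k_coords, grid_shape, spacing,
                                coil_maps = NULL, plan = NULL,
                                solver = c("cg", "adjoint"), iters = 10L) {
  solver <- match.arg(solver)
  grid_shape <- rep_len(as.integer(grid_shape), 3L)
  samples <- as.matrix(samples)
  if (nrow(samples) == 0L) {
    warning("empty sample set; returning zero volume")
    return(complex_volume(array(0, grid_shape), spacing))
  }
  if (is.null(coil_maps)) coil_maps <- list(array(1 + 0i, grid_shape))
  if (is.null(plan)) plan <- nufft_plan(k_coords, grid_shape, spacing)
  # per-sample k-volume of a radial shell of thickness dk at radius j*dk:
  # (j+1/2)^3 - (j-1/2)^3 ~ 3 j^2; the origin, sampled once per spoke
  # instead of twice, gets twice its central-cell volume (1/8)
  r <- sqrt(rowSums(k_coords^2))
  w <- rep(1, length(r))
  if (any(r > 0)) {
    dk <- min(r[r > 0])
    j <- r / dk
    w <- ifelse(j < 0.5, 2 * (1 / 8), (j + 0.5)^3 - (j - 0.5)^3)
  }
  den <- array(0, grid_shape)
  for (cm in coil_maps) den <- den + Mod(cm)^2
  den[den < 1e-12] <- 1e-12
  b <- array(0 + 0i, grid_shape)
  for (c in seq_along(coil_maps))
    b <- b + Conj(coil_maps[[c]]) * nufft_adjoint_op(plan, w * samples[, c])

  if (solver == "adjoint") {
    recon <- b / den
    # self-calibrate to unit DC gain with a centred delta
    delta <- array(0 + 0i, grid_shape)
    ctr <- grid_shape %/% 2 + 1L
    delta[ctr[1], ctr[2], ctr[3]] <- 1 + 0i
    cal <- array(0 + 0i, grid_shape)
    for (c in seq_along(coil_maps)) {
      sd <- nufft_forward_op(plan, coil_maps[[c]] * delta)
      cal <- cal + Conj(coil_maps[[c]]) * nufft_adjoint_op(plan, w * sd)
    }
    scale <- Mod(sum(cal / den))
    if (scale < 1e-30) scale <- 1
    return(complex_volume(recon / scale, spacing))
  }

  # CG on sum_c Mc^H (F^H W F) Mc z = b; F^H W F applied as a Toeplitz-
  # embedded convolution with kernel sum_s w_s exp(2i pi k_s . r)
  M2 <- 2L * grid_shape
  plan2 <- nufft_plan(k_coords, M2, spacing, os = 1.5, width = 4L)
  kern <- nufft_adjoint_op(plan2, w + 0i)
  T2 <- fft(shift_to_origin(kern, M2 %/% 2L + 1L))
  reg <- lapply(1:3, function(a) ((M2[a] - grid_shape[a]) %/% 2) + seq_len(grid_shape[a]))
  toep <- function(x) {
    pad <- array(0 + 0i, M2)
    pad[reg[[1]], reg[[2]], reg[[3]]] <- x
    cv <- fft(fft(pad) * T2, inverse = TRUE) / prod(M2)
    cv[reg[[1]], reg[[2]], reg[[3]]]
  }
  G <- function(x) {
    out <- array(0 + 0i, grid_shape)
    for (cm in coil_maps) out <- out + Conj(cm) * toep(cm * x)
    out
  }
  x <- array(0 + 0i, grid_shape)
  rr <- b
  p <- rr
  rs <- sum(Mod(rr)^2)
  rs0 <- rs
  for (it in seq_len(iters)) {
    if (rs < 1e-20 * rs0) break
    Gp <- G(p)
    alpha <- rs / Re(sum(Conj(p) * Gp))
    x <- x + alpha * p
    rr <- rr - alpha * Gp
    rs2 <- sum(Mod(rr)^2)
    p <- rr + (rs2 / rs) * p
    rs <- rs2
  }
  complex_volume(x, spacing)
}

# circularly shift an array so that index `at` moves to (1,1,...)
shift_to_origin <- function(arr, at) {
  d <- dim(arr)
  idx <- lapply(seq_along(d), function(a) ((seq_len(d[a]) - 1 + (at[a] - 1)) %% d[a]) + 1)
  arr[idx[[1]], idx[[2]], idx[[3]]]
}

# --- self-navigation ---------------------------------------------------------

#' Extract a respiratory surrogate from the k-space centre series
#'
#' Takes the per-channel time series of the k-space origin samples, low-pass
#' filters each channel's magnitude with a zero-phase Kaiser-window FIR
#' (cutoff 1 Hz, 60 dB stop-band), runs a PCA across channels, and returns
#' the principal component whose spectral density integrated over the
#' respiratory band 0.1-0.5 Hz is largest. The sign is fixed so that the
#' end-of-exhale plateau (where free breathing dwells) is the maximum.
#'
#' @param center_series complex (or numeric) matrix `n_t x n_channels`.
#' @param fs sampling frequency in Hz (> 1).
#' @return numeric surrogate of length `n_t` with attribute `fs`.
#' @export
extract_surrogate <- function(center_series, fs) {
  center_series <- as.matrix(center_series)
  if (fs <= 1) stop("fs must exceed 1 Hz for a 1-Hz low-pass")
  x <- Mod(center_series)
  n <- nrow(x)
  if (max(apply(x, 2, sd)) < 1e-12 * max(1, max(abs(x))))
    stop("constant centre series: no respiratory content")
  # Kaiser FIR low-pass, cutoff 1 Hz, ~60 dB stop-band
  trans <- 0.5 # Hz transition width
  ntaps <- min(2L * (n %/% 4L) + 1L,
               2L * ceiling((60 - 7.95) / (2 * 2.285 * 2 * pi * trans / fs) / 2) + 1L)
  ntaps <- max(ntaps, 5L)
  h <- signal::fir1(ntaps - 1L, 1 / (fs / 2), type = "low",
                    window = signal::kaiser(ntaps, 5.653))
  half <- (ntaps - 1L) %/% 2L
  filt <- apply(x, 2, function(col) {
    padded <- c(rev(col[seq_len(half) + 1L]), col,
                rev(col[n - seq_len(half)]))
    stats::filter(padded, h, sides = 2)[half + seq_len(n)]
  })
  filt <- as.matrix(filt)
  if (ncol(filt) > 1L) {
    pc <- prcomp(filt, center = TRUE, scale. = FALSE)
    scores <- pc$x
  } else {
    scores <- filt - mean(filt)
  }
  band_power <- apply(scores, 2, function(s) {
    P <- Mod(fft(s - mean(s)))^2
    f <- (seq_along(s) - 1) / length(s) * fs
    sum(P[f >= 0.1 & f <= 0.5])
  })
  s <- scores[, which.max(band_power)]
  # free breathing dwells at end of exhale; flip so that the densest
  # surrogate value (the dwell plateau) sits at the top
  dens <- stats::density(s)
  mode_q <- mean(s <= dens$x[which.max(dens$y)])
  if (mode_q < 0.5) s <- -s
  attr(s, "fs") <- fs
  s
}

#' Sort samples into respiratory phase bins
#'
#' Detects breathing cycles on the surrogate (inhale troughs bound the
#' cycles; the exhale extremum anchors phase zero), assigns each sample a
#' phase fraction by its time within the cycle, and bins the fraction into
#' `n_bins` bins with bin 0 centred at end-of-exhale.
#'
#' @param surrogate numeric surrogate signal (exhale plateau at the top,
#'   as produced by [extract_surrogate()]).
#' @param n_bins number of respiratory phases (default 10).
#' @return integer vector of bin labels in `0:(n_bins-1)`.
#' @export
sort_phases <- function(surrogate, n_bins = 10L) {
  s <- as.numeric(surrogate)
  n <- length(s)
  if (n_bins < 1L) stop("n_bins must be at least 1")
  if (n_bins == 1L) return(integer(n))
  # cycle segmentation via inhale troughs
  mid <- (max(s) + min(s)) / 2
  below <- s < mid
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  troughs <- integer(0)
  for (r in which(runs$values)) {
    seg <- starts[r]:ends[r]
    troughs <- c(troughs, seg[which.min(s[seg])])
  }
  if (length(troughs) < 2L) stop("no detectable breathing cycles in surrogate")
  # exhale anchor within each trough-to-trough cycle
  peaks <- vapply(seq_len(length(troughs) - 1L), function(i) {
    seg <- troughs[i]:troughs[i + 1L]
    seg[which.max(s[seg])]
  }, integer(1))
  period <- mean(diff(troughs))
  idx <- seq_len(n)
  frac <- numeric(n)
  anchor <- findInterval(idx, peaks)
  inner <- anchor >= 1L & anchor < length(peaks)
  frac[inner] <- (idx[inner] - peaks[anchor[inner]]) /
    (peaks[anchor[inner] + 1L] - peaks[anchor[inner]])
  pre <- anchor < 1L
  frac[pre] <- ((idx[pre] - peaks[1]) / period) %% 1
  post <- anchor >= length(peaks)
  frac[post] <- ((idx[post] - peaks[length(peaks)]) / period) %% 1
  # epsilon keeps samples landing exactly on a bin edge in the upper bin
  v <- ((frac + 1 / (2 * n_bins)) %% 1) * n_bins
  as.integer(pmin(floor(v + 1e-9), n_bins - 1L))
}
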