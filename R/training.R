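# Losses and the three-stage progressive optimisation that jointly fits
# the spatial INR (reference-frame image) and the temporal INR (per-frame
# motion-component weightings) to the acquired k-space data.
#
# Stage 1 fits the spatial INR to the warm-start image in the image
# domain; stage 2 refits it against the end-of-exhale k-space subset;
# stage 3 activates both INRs and matches every frame's k-space data
# through the motion model and the warp operator.

#' k-space data-fidelity loss
#'
#' Sum over coils of the mean squared complex-modulus difference between
#' predicted and measured samples.
#'
#' @param predicted,measured complex matrices `n x n_coils` (or vectors).
#' @return nonnegative scalar.
#' @export
loss_kspace <- function(predicted, measured) {
  predicted <- as.matrix(predicted); measured <- as.matrix(measured)
  if (!all(dim(predicted) == dim(measured))) stop("sample shape mismatch")
  sum(colMeans(Mod(predicted - measured)^2))
}

# gradient of loss_kspace w.r.t. predicted, packed complex
loss_kspace_grad <- function(predicted, measured) {
  2 * (predicted - measured) / nrow(as.matrix(predicted))
}

#' Smoothed isotropic total variation of a complex volume
#'
#' Computed with forward differences (last-slice gradients zero) on the
#' real and imaginary channels separately and summed; `eps` inside the
#' square root keeps the loss differentiable at flat regions.
#'
#' @param vol a [complex_volume()] or complex 3D array.
#' @param eps smoothing constant (default 1e-8).
#' @return nonnegative scalar.
#' @export
loss_tv <- function(vol, eps = 1e-8) {
  z <- if (is_complex_volume(vol)) vol$data else vol
  tv_channel(Re(z), eps)$value + tv_channel(Im(z), eps)$value
}

fwd_diff <- function(u, axis) {
  d <- dim(u)
  out <- array(0, d)
  idx <- vector("list", 3L)
  for (a in 1:3) idx[[a]] <- seq_len(d[a])
  src <- idx; src[[axis]] <- 2:d[axis]
  dst <- idx; dst[[axis]] <- 1:(d[axis] - 1)
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    u[src[[1]], src[[2]], src[[3]]] - u[dst[[1]], dst[[2]], dst[[3]]]
  out
}

tv_channel <- function(u, eps = 1e-8) {
  d1 <- fwd_diff(u, 1L); d2 <- fwd_diff(u, 2L); d3 <- fwd_diff(u, 3L)
  r <- sqrt(d1^2 + d2^2 + d3^2 + eps)
  # subtract the flat-region offset so a constant volume scores exactly 0
  list(value = sum(r) - length(r) * sqrt(eps), r = r,
       d1 = d1, d2 = d2, d3 = d3)
}

# gradient of the smoothed TV w.r.t. a complex array, packed complex
loss_tv_grad <- function(z, eps = 1e-8) {
  gch <- function(u) {
    tc <- tv_channel(u, eps)
    q1 <- tc$d1 / tc$r; q2 <- tc$d2 / tc$r; q3 <- tc$d3 / tc$r
    g <- -(q1 + q2 + q3)
    bk <- function(q, axis) {
      d <- dim(q); out <- array(0, d)
      idx <- lapply(d, seq_len)
      dst <- idx; dst[[axis]] <- 2:d[axis]
      src <- idx; src[[axis]] <- 1:(d[axis] - 1)
      out[dst[[1]], dst[[2]], dst[[3]]] <- q[src[[1]], src[[2]], src[[3]]]
      out
    }
    g + bk(q1, 1L) + bk(q2, 2L) + bk(q3, 3L)
  }
  complex(real = gch(Re(z)), imaginary = gch(Im(z)))
}

#' Training configuration
#'
#' Defaults follow the full-scale study protocol (stages of 500/1500/1000
#' epochs at learning rates 1e-3/2e-5/2e-6, TV weight 2e-4, 60 random
#' frames per joint epoch, 10 respiratory bins). [reduced_train_config()]
#' provides a desk-scale preset for small grids.
#'
#' @param stage_epochs integer triple of epochs per stage.
#' @param stage_lrs numeric triple of spatial-INR learning rates (reset at
#'   each stage start).
#' @param lambda_tv total-variation weight (applied in stages 2-3).
#' @param frames_per_epoch frames sampled per joint-stage epoch.
#' @param n_bins respiratory bins for phase sorting.
#' @param temporal_lr temporal-INR learning rate (defaults to the stage-3
#'   rate).
#' @param grad_clip global gradient-norm clip (default 1).
#' @param spatial_encoding,temporal_encoding [hash_config()]s for the two
#'   INRs.
#' @param omega0 sine frequency factor of the spatial INR.
#' @param seed integer seed for all training randomness.
#' @return A `train_config` list.
#' @export
train_config <- function(stage_epochs = c(500L, 1500L, 1000L),
                         stage_lrs = c(1e-3, 2e-5, 2e-6),
                         lambda_tv = 2e-4,
                         frames_per_epoch = 60L,
                         n_bins = 10L,
                         temporal_lr = NULL,
                         grad_clip = 1,
                         spatial_encoding = hash_config(input_dim = 3L),
                         temporal_encoding = hash_config(input_dim = 1L),
                         omega0 = 30,
                         seed = 0L) {
  if (length(stage_epochs) != 3L || length(stage_lrs) != 3L)
    stop("exactly three stages are configured")
  if (any(stage_epochs <= 0) || any(stage_lrs <= 0)) stop("stages must be positive")
  structure(list(stage_epochs = as.integer(stage_epochs), stage_lrs = stage_lrs,
                 lambda_tv = lambda_tv, frames_per_epoch = as.integer(frames_per_epoch),
                 n_bins = as.integer(n_bins),
                 temporal_lr = if (is.null(temporal_lr)) stage_lrs[3] else temporal_lr,
                 grad_clip = grad_clip, spatial_encoding = spatial_encoding,
                 temporal_encoding = temporal_encoding, omega0 = omega0,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale training preset
#'
#' Reduced encodings (8 levels, 2^14-entry tables, finest resolution twice
#' the grid) and shorter, faster-learning stages sized for grids around
#' 32^3 where far fewer optimisation steps are taken than in the
#' full-scale protocol.
#'
#' @param grid_n grid size per axis the preset should serve.
#' @param n_frames frame count (bounds the temporal finest resolution).
#' @param seed integer seed.
#' @param ... overrides passed on to [train_config()].
#' @return A `train_config`.
#' @export
reduced_train_config <- function(grid_n = 32L, n_frames = 200L, seed = 0L, ...) {
  preset <- list(
    stage_epochs = c(300L, 250L, 300L),
    stage_lrs = c(2e-3, 5e-4, 2e-4),
    lambda_tv = 1e-6,
    frames_per_epoch = 20L,
    temporal_lr = 2e-3,
    spatial_encoding = hash_config(n_levels = 8L, table_size_log2 = 14L,
                                   coarsest_resolution = 8L,
                                   finest_resolution = 2L * grid_n,
                                   input_dim = 3L),
    temporal_encoding = hash_config(n_levels = 8L, table_size_log2 = 12L,
                                    coarsest_resolution = 4L,
                                    finest_resolution = max(16L, n_frames %/% 2L),
                                    input_dim = 1L),
    seed = seed)
  do.call(train_config, modifyList(preset, list(...)))
}

#' Warm-start reference reconstruction
#'
#' Sorts the spokes into respiratory bins on the surrogate, selects the
#' end-of-exhale bin (bin 0), and reconstructs it with the
#' density-compensated adjoint.
#'
#' @param acq a `kspace_acquisition`.
#' @param surrogate optional surrogate signal (one value per spoke);
#'   extracted from the k-space centre series when `NULL`.
#' @param n_bins respiratory bins (default 10).
#' @param plan optional [nufft_plan()] covering the selected rows.
#' @return A [complex_volume()] with attributes `bin_spokes` (indices of
#'   the spokes used) and `bins` (per-spoke labels).
#' @export
warm_start_reference <- function(acq, surrogate = NULL, n_bins = 10L,
                                 plan = NULL) {
  if (is.null(surrogate))
    surrogate <- extract_surrogate(center_sample_series(acq), fs = 1 / acq$trajectory$TR)
  bins <- sort_phases(surrogate, n_bins)
  spokes0 <- which(bins == 0L)
  if (length(spokes0) == 0L) stop("end-of-exhale bin is empty")
  sps <- acq$trajectory$samples_per_spoke
  rows <- as.vector(outer(seq_len(sps), (spokes0 - 1L) * sps, "+"))
  vol <- nufft_adjoint_recon(acq$samples[rows, , drop = FALSE],
                             acq$trajectory$k_coords[rows, , drop = FALSE],
                             acq$grid_shape, acq$spacing, acq$coil_maps, plan)
  attr(vol, "bin_spokes") <- spokes0
  attr(vol, "bins") <- bins
  vol
}

# multi-coil forward through a single-group plan, image as complex array
coil_forward <- function(plan_op, plan, z, coil_maps) {
  vapply(coil_maps, function(cm) nufft_forward_op(plan, cm * z, plan_op),
         complex(nrow(plan_op$S)))
}

# adjoint of coil_forward applied to per-coil sample gradients
coil_adjoint <- function(plan_op, plan, g, coil_maps) {
  out <- 0 + 0i
  g <- as.matrix(g)
  for (c in seq_along(coil_maps))
    out <- out + Conj(coil_maps[[c]]) * nufft_adjoint_op(plan, g[, c], plan_op)
  out
}

#' Build an online PCA motion model from the acquisition itself
#'
#' Reconstructs all respiratory bins with the density-compensated adjoint,
#' registers the end-of-exhale bin to every other bin with demons
#' registration (yielding fields that deform the exhale reference into
#' each bin), and extracts the PCA basis.
#'
#' @param acq a `kspace_acquisition`.
#' @param n_bins respiratory bins.
#' @param n_pc principal components kept.
#' @param reg_params parameters for [register_inter_phase()].
#' @return A `pca_motion_model`.
#' @export
build_online_motion_model <- function(acq, n_bins = 10L, n_pc = 3L,
                                      reg_params = list()) {
  surrogate <- extract_surrogate(center_sample_series(acq), fs = 1 / acq$trajectory$TR)
  bins <- sort_phases(surrogate, n_bins)
  sps <- acq$trajectory$samples_per_spoke
  vols <- vector("list", n_bins)
  for (b in seq_len(n_bins) - 1L) {
    spokes <- which(bins == b)
    if (length(spokes) == 0L) stop(sprintf("respiratory bin %d is empty", b))
    rows <- as.vector(outer(seq_len(sps), (spokes - 1L) * sps, "+"))
    vols[[b + 1L]] <- nufft_adjoint_recon(acq$samples[rows, , drop = FALSE],
                                          acq$trajectory$k_coords[rows, , drop = FALSE],
                                          acq$grid_shape, acq$spacing, acq$coil_maps)
  }
  exhale <- vols[[1]]
  dvfs <- lapply(vols, function(v) register_inter_phase(exhale, v, reg_params))
  compute_pca_basis(dvfs, n_pc)
}

#' Three-stage progressive joint reconstruction
#'
#' Runs the full pipeline on one acquisition: surrogate extraction and
#' phase sorting, warm-start reconstruction of the end-of-exhale bin,
#' stage-1 image-domain fitting of the spatial INR, stage-2 k-space
#' refinement on the exhale subset (with total-variation regularisation),
#' and stage-3 joint optimisation of both INRs against every frame's
#' k-space data through the PCA motion model and the warp operator. Within
#' a stage-3 epoch the reference is rendered once, each sampled frame
#' contributes a k-space residual whose gradients flow to both networks
#' (the temporal INR steps per frame, the spatial INR once per epoch), and
#' training aborts with a diagnostic if the loss turns non-finite.
#'
#' @param acq a `kspace_acquisition`.
#' @param motion_model a `pca_motion_model` (offline prior), or `NULL` to
#'   build one online from the acquisition via
#'   [build_online_motion_model()].
#' @param config a [train_config()].
#' @param surrogate optional per-spoke respiratory signal used for phase
#'   sorting (an external navigator); self-navigation from the k-space
#'   centre is used when `NULL`.
#' @param verbose print per-stage progress.
#' @return A `recon_result`: `reference` ([complex_volume()]),
#'   `pc_weights` (`n_frames x 9`, effective weightings on the unit
#'   components), `motion_model`, `loss_history` (per-stage numeric
#'   vectors), `surrogate`, `bins`, `config`.
#' @export
run_progressive_training <- function(acq, motion_model = NULL,
                                     config = train_config(),
                                     surrogate = NULL,
                                     verbose = FALSE) {
  set.seed(config$seed)
  shape <- acq$grid_shape
  spacing <- acq$spacing
  nt <- n_frames(acq)
  coil_maps <- acq$coil_maps
  if (is.null(coil_maps)) coil_maps <- list(array(1 + 0i, shape))
  sps <- acq$trajectory$samples_per_spoke

  # self-navigated by default; an external respiratory signal (one value
  # per spoke) may be supplied instead, e.g. from a breathing belt
  if (is.null(surrogate))
    surrogate <- extract_surrogate(center_sample_series(acq),
                                   fs = 1 / acq$trajectory$TR)
  bins <- sort_phases(surrogate, config$n_bins)
  spokes0 <- which(bins == 0L)
  rows0 <- as.vector(outer(seq_len(sps), (spokes0 - 1L) * sps, "+"))

  plan0 <- nufft_plan(acq$trajectory$k_coords[rows0, , drop = FALSE],
                      shape, spacing)
  warm <- nufft_adjoint_recon(acq$samples[rows0, , drop = FALSE],
                              acq$trajectory$k_coords[rows0, , drop = FALSE],
                              shape, spacing, acq$coil_maps, plan0)
  if (is.null(motion_model))
    motion_model <- build_online_motion_model(acq, config$n_bins)

  sc <- max(Mod(warm$data))
  if (sc <= 0) stop("warm-start image is identically zero")
  target <- warm$data / sc
  meas <- acq$samples / sc

  # fixed-grid encoding plan shared by all stages
  splan <- hash_plan(grid_coords_norm(shape), config$spatial_encoding)
  smodel <- spatial_inr(config$spatial_encoding, config$omega0,
                        seed = config$seed + 11L)
  nvox <- prod(shape)
  loss_history <- list(stage1 = numeric(0), stage2 = numeric(0),
                       stage3 = numeric(0))
  check_finite <- function(l, stage, epoch) {
    if (!is.finite(l))
      stop(sprintf("training diverged (non-finite loss) at stage %d epoch %d",
                   stage, epoch))
  }

  # ---- stage 1: image-domain fit to the warm start -------------------------
  opt <- adam_init(smodel[c("tables", "real", "imag")])
  for (ep in seq_len(config$stage_epochs[1])) {
    fw <- spatial_forward_cached(splan, smodel)
    diff <- fw$values - as.vector(target)
    l <- mean(Mod(diff)^2)
    check_finite(l, 1L, ep)
    loss_history$stage1[ep] <- l
    g <- 2 * diff / nvox
    grads <- spatial_backward(smodel, fw, g)
    st <- adam_step(smodel[c("tables", "real", "imag")], grads, opt,
                    lr = config$stage_lrs[1], clip = config$grad_clip)
    smodel[c("tables", "real", "imag")] <- st$params
    opt <- st$state
    if (verbose && ep %% 100L == 0L)
      message(sprintf("stage 1 epoch %d: loss %.4g", ep, l))
  }

  # ---- stage 2: k-space fit on the end-of-exhale subset --------------------
  meas0 <- meas[rows0, , drop = FALSE]
  opt <- adam_init(smodel[c("tables", "real", "imag")])
  for (ep in seq_len(config$stage_epochs[2])) {
    fw <- spatial_forward_cached(splan, smodel)
    z <- fw$values; dim(z) <- shape
    pred <- coil_forward(plan0$ops[[1]], plan0, z, coil_maps)
    l <- loss_kspace(pred, meas0) + config$lambda_tv * loss_tv(z)
    check_finite(l, 2L, ep)
    loss_history$stage2[ep] <- l
    gz <- coil_adjoint(plan0$ops[[1]], plan0, loss_kspace_grad(pred, meas0),
                       coil_maps) +
      config$lambda_tv * loss_tv_grad(z)
    grads <- spatial_backward(smodel, fw, as.vector(gz))
    st <- adam_step(smodel[c("tables", "real", "imag")], grads, opt,
                    lr = config$stage_lrs[2], clip = config$grad_clip)
    smodel[c("tables", "real", "imag")] <- st$params
    opt <- st$state
    if (verbose && ep %% 100L == 0L)
      message(sprintf("stage 2 epoch %d: loss %.4g", ep, l))
  }

  # ---- stage 3: joint spatial + temporal optimisation ----------------------
  sample_frame <- sample_frames(acq)
  planF <- nufft_plan(acq$trajectory$k_coords, shape, spacing,
                      os = 1.5, width = 4L, groups = sample_frame)
  tmodel <- temporal_inr(config$temporal_encoding, n_frames = nt,
                         seed = config$seed + 23L)
  scales <- motion_model$scales
  comp_mat <- lapply(1:3, function(a) # nvox x n_comp per axis
    vapply(motion_model$components,
           function(cc) as.numeric(cc$displacement[, , , a]), numeric(nvox)))
  mean_disp <- matrix(motion_model$mean$displacement, ncol = 3L)
  frame_coord <- function(t) -1 + (2 * (t - 1) + 1) / nt
  idx0 <- as.matrix(expand.grid(seq_len(shape[1]), seq_len(shape[2]),
                                seq_len(shape[3]), KEEP.OUT.ATTRS = FALSE))
  opt_s <- adam_init(smodel[c("tables", "real", "imag")])
  opt_t <- adam_init(tmodel[c("tables", "mlps")])
  fpe <- min(config$frames_per_epoch, nt)
  for (ep in seq_len(config$stage_epochs[3])) {
    frames <- sample.int(nt, fpe)
    fw <- spatial_forward_cached(splan, smodel)
    zref <- fw$values; dim(zref) <- shape
    g_ref <- array(0 + 0i, shape)
    l_ep <- 0
    for (t in frames) {
      tf <- temporal_forward_cached(frame_coord(t), tmodel, train_mode = TRUE)
      wmat <- matrix(tf$w[1, ], nrow = 3L, ncol = 3L, byrow = TRUE) * scales
      disp <- mean_disp
      for (a in 1:3) disp[, a] <- disp[, a] + comp_mat[[a]] %*% wmat[, a]
      pos <- idx0 + sweep(disp, 2L, spacing, "/")
      wc <- warp_core(zref, pos)
      zt <- wc$values; dim(zt) <- shape
      op <- planF$ops[[as.character(t)]]
      rows_t <- op$rows
      pred <- coil_forward(op, planF, zt, coil_maps)
      mt <- meas[rows_t, , drop = FALSE]
      l_ep <- l_ep + loss_kspace(pred, mt)
      gt <- coil_adjoint(op, planF, loss_kspace_grad(pred, mt), coil_maps)
      g_ref <- g_ref + warp_backward_vol(wc$cache, as.vector(gt)) / fpe
      gpos <- warp_backward_pos(wc$cache, as.vector(gt))
      gdisp <- sweep(gpos, 2L, spacing, "/")
      dw <- matrix(0, 3L, 3L)
      for (a in 1:3) dw[, a] <- crossprod(comp_mat[[a]], gdisp[, a]) * scales
      tg <- temporal_backward(tmodel, tf, matrix(as.vector(t(dw)), 1L, 9L))
      stt <- adam_step(tmodel[c("tables", "mlps")], tg, opt_t,
                       lr = config$temporal_lr, clip = config$grad_clip)
      tmodel[c("tables", "mlps")] <- stt$params
      opt_t <- stt$state
    }
    l_ep <- l_ep / fpe + config$lambda_tv * loss_tv(zref)
    check_finite(l_ep, 3L, ep)
    loss_history$stage3[ep] <- l_ep
    g_ref <- g_ref + config$lambda_tv * loss_tv_grad(zref)
    grads <- spatial_backward(smodel, fw, as.vector(g_ref))
    st <- adam_step(smodel[c("tables", "real", "imag")], grads, opt_s,
                    lr = config$stage_lrs[3], clip = config$grad_clip)
    smodel[c("tables", "real", "imag")] <- st$params
    opt_s <- st$state
    if (verbose && ep %% 50L == 0L)
      message(sprintf("stage 3 epoch %d: loss %.4g", ep, l_ep))
  }

  # effective per-frame weightings on the unit components (eval mode)
  w_raw <- temporal_forward(vapply(seq_len(nt), frame_coord, numeric(1)), tmodel)
  pc_weights <- sweep(w_raw, 2L, rep(scales, each = 3L), "*")
  reference <- render_volume(smodel, shape, spacing)
  reference$data <- reference$data * sc
  structure(list(reference = reference, pc_weights = pc_weights,
                 motion_model = motion_model, loss_history = loss_history,
                 surrogate = surrogate, bins = bins, scale = sc,
                 spatial_model = smodel, temporal_model = tmodel,
                 config = config),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("<recon_result: %d frames, grid %s, final stage-3 loss %.4g>\n",
              nrow(x$pc_weights), paste(grid_shape(x$reference), collapse = "x"),
              tail(x$loss_history$stage3, 1)))
  invisible(x)
}

#' Solved deformation field of one reconstructed frame
#' @param result a `recon_result`.
#' @param t frame index.
#' @return The composed [dvf()].
#' @export
recon_frame_dvf <- function(result, t) {
  compose_dvf(result$motion_model, result$pc_weights[t, ])
}

#' Reconstructed cine frame
#' @inheritParams recon_frame_dvf
#' @return The frame [complex_volume()].
#' @export
recon_frame <- function(result, t) {
  warp_volume(result$reference, recon_frame_dvf(result, t))
}
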