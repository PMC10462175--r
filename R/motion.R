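# DVF algebra: warping under the pull convention z_t(x) = z_ref(x + d(x)),
# demons inter-phase registration, PCA motion basis, and frame-DVF
# composition from per-axis component weightings.

# --- trilinear warp core -----------------------------------------------------
#
# Positions are float 1-based voxel indices per axis. Out-of-grid corners
# contribute zero. The heavy lifting lives in C++ (src/kernels.cpp); the
# cache holds the base corner indices and fractional offsets the backward
# passes need, plus the image the positions sampled.
warp_core <- function(vol_data, pos) {
  d <- dim(vol_data)
  if (!is.complex(vol_data)) vol_data <- vol_data + 0i
  fw <- cpp_warp_forward(as.vector(vol_data), as.integer(d), pos)
  list(values = fw$values,
       cache = list(dim = d, i0 = fw$i0, tf = fw$tf, vol = vol_data))
}

# Gradient of a real loss with respect to the image values: scatter of the
# interpolation weights. g is dL/d(out) as a complex vector (real part =
# gradient w.r.t. the real channel, imaginary part w.r.t. the imaginary).
warp_backward_vol <- function(cache, g) {
  out <- cpp_warp_backward_vol(as.integer(cache$dim), cache$i0, cache$tf, g)
  dim(out) <- cache$dim
  out
}

# Gradient with respect to the float sampling positions (per-axis, in voxel
# units): dL/d pos_a = Re(Conj(g) * d out/d pos_a).
warp_backward_pos <- function(cache, g) {
  cpp_warp_backward_pos(as.vector(cache$vol), as.integer(cache$dim),
                        cache$i0, cache$tf, g)
}

# Float sampling positions (1-based voxel indices) for a grid deformed by a
# displacement field in mm.
warp_positions <- function(shape, spacing, disp_mm) {
  idx <- as.matrix(expand.grid(seq_len(shape[1]), seq_len(shape[2]),
                               seq_len(shape[3]), KEEP.OUT.ATTRS = FALSE))
  idx + sweep(matrix(disp_mm, ncol = 3L), 2L, spacing, "/")
}

#' Warp a complex volume by a deformation field
#'
#' Applies the pull convention `out(x) = vol(x + d(x))` with trilinear
#' interpolation of the real and imaginary channels; samples falling outside
#' the grid contribute zero. The operation is linear in the image and
#' differentiable in both the image values and the displacement (the
#' training loop uses the analytic gradients directly).
#'
#' @param vol a [complex_volume()].
#' @param dvf_field a [dvf()] on the same grid.
#' @return The warped [complex_volume()].
#' @export
warp_volume <- function(vol, dvf_field) {
  check_same_grid(vol, dvf_field, "volume and DVF")
  shape <- grid_shape(vol)
  pos <- warp_positions(shape, vol$spacing, dvf_field$displacement)
  out <- warp_core(vol$data, pos)$values
  dim(out) <- shape
  complex_volume(out, vol$spacing)
}

# --- demons registration -----------------------------------------------------

block_downsample3 <- function(arr, f) {
  if (f == 1L) return(arr)
  d <- dim(arr)
  dn <- d %/% f
  arr <- arr[seq_len(dn[1] * f), seq_len(dn[2] * f), seq_len(dn[3] * f), drop = FALSE]
  dim(arr) <- c(f, dn[1], f, dn[2], f, dn[3])
  apply(arr, c(2, 4, 6), mean)
}

trilinear_resample3 <- function(arr, new_dim) {
  d <- dim(arr)
  ax <- lapply(1:3, function(a) {
    # map target voxel centres onto source voxel centres
    ((seq_len(new_dim[a]) - 0.5) / new_dim[a]) * d[a] + 0.5
  })
  pos <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]], KEEP.OUT.ATTRS = FALSE))
  pos <- pmin(pmax(pos, 1), matrix(rep(d, each = nrow(pos)), ncol = 3))
  out <- Re(warp_core(arr + 0i, pos)$values)
  dim(out) <- new_dim
  out
}

central_gradient3 <- function(arr) {
  d <- dim(arr)
  g <- array(0, c(d, 3L))
  idxp <- function(n) c(2:n, n); idxm <- function(n) c(1, 1:(n - 1))
  g[, , , 1] <- (arr[idxp(d[1]), , ] - arr[idxm(d[1]), , ]) / 2
  g[, , , 2] <- (arr[, idxp(d[2]), ] - arr[, idxm(d[2]), ]) / 2
  g[, , , 3] <- (arr[, , idxp(d[3])] - arr[, , idxm(d[3])]) / 2
  g
}

#' Deformable registration between two respiratory phases
#'
#' Multi-resolution demons registration on image magnitudes with Gaussian
#' diffusion regularisation. The returned field follows the pull
#' convention: `warp_volume(moving, d)` approximates `fixed`, i.e. the
#' field carries every fixed-grid point into the moving image. This is the
#' form needed to build inter-phase fields that deform the end-of-exhale
#' reference into the other respiratory bins.
#'
#' @param moving,fixed [complex_volume()]s on a common grid; magnitudes are
#'   used, phase is discarded.
#' @param params list of tuning values: `levels` (down-sampling factors,
#'   coarse to fine), `iters` per level, `sigma` of the Gaussian field
#'   regulariser in voxels.
#' @return A [dvf()] in mm.
#' @export
register_inter_phase <- function(moving, fixed, params = list()) {
  check_same_grid(moving, fixed, "moving and fixed")
  if (!all(is.finite(Mod(moving$data))) || !all(is.finite(Mod(fixed$data))))
    stop("non-finite input volumes")
  p <- modifyList(list(levels = c(4L, 2L, 1L), iters = 50L, sigma = 1), params)
  shape <- grid_shape(fixed)
  mov <- Mod(moving$data); fix <- Mod(fixed$data)
  sc <- max(fix)
  if (sc > 0) { mov <- mov / sc; fix <- fix / sc }
  levels <- p$levels[shape[1] %/% p$levels >= 8 | p$levels == 1L]
  u <- NULL # displacement in fine-level voxel units of the current level
  for (f in levels) {
    dl <- shape %/% f
    movl <- block_downsample3(mov, f)
    fixl <- block_downsample3(fix, f)
    u <- if (is.null(u)) array(0, c(dl, 3L)) else {
      un <- array(0, c(dl, 3L))
      for (a in 1:3) un[, , , a] <- trilinear_resample3(u[, , , a], dl) *
          (dl[a] / dim(u)[a])
      un
    }
    idx0 <- as.matrix(expand.grid(seq_len(dl[1]), seq_len(dl[2]),
                                  seq_len(dl[3]), KEEP.OUT.ATTRS = FALSE))
    for (it in seq_len(p$iters)) {
      pos <- idx0 + matrix(u, ncol = 3L)
      cur <- Re(warp_core(movl + 0i, pos)$values)
      dim(cur) <- dl
      r <- cur - fixl
      gr <- central_gradient3(cur)
      den <- gr[, , , 1]^2 + gr[, , , 2]^2 + gr[, , , 3]^2 + r^2
      den[den < 1e-12] <- 1e-12
      for (a in 1:3) {
        step <- -r * gr[, , , a] / den
        u[, , , a] <- gaussian_smooth3(u[, , , a] + step, p$sigma)
      }
    }
    # keep u for upsampling to the next (finer) level
  }
  # u is in voxel units of the last level; one level voxel spans
  # (shape/dl) grid voxels, i.e. (shape/dl)*spacing mm.
  dl <- dim(u)[1:3]
  disp <- array(0, c(shape, 3L))
  for (a in 1:3)
    disp[, , , a] <- trilinear_resample3(u[, , , a], shape) *
      (shape[a] / dl[a]) * fixed$spacing[a]
  dvf(disp, fixed$spacing)
}

# --- PCA motion model --------------------------------------------------------

#' Principal-component respiratory motion model
#'
#' Builds the motion basis from a set of inter-phase deformation fields:
#' the mean field plus the leading eigenvectors of the centred covariance,
#' computed through the bin-by-bin Gram matrix and unit-normalised under
#' the flattened Euclidean inner product over all voxels and components.
#' Any respiratory field is then approximated as the mean plus a weighted
#' sum of components.
#'
#' @param inter_phase_dvfs list of [dvf()]s on a common grid (one per
#'   respiratory bin, typically relative to end-of-exhale).
#' @param n_pc number of principal components kept (default 3).
#' @return An object of class `pca_motion_model`: `mean` (a [dvf()]),
#'   `components` (list of unit-norm [dvf()]s, zero-padded beyond the rank),
#'   `explained_variance` (non-increasing eigenvalues of the covariance),
#'   `scales` (`sqrt(explained_variance)`, the natural size of the
#'   per-component weightings), `n_bin`, and `degenerate` (TRUE when the
#'   input fields carry no variance).
#' @export
compute_pca_basis <- function(inter_phase_dvfs, n_pc = 3L) {
  nb <- length(inter_phase_dvfs)
  if (nb < 2L) stop("need at least 2 inter-phase DVFs")
  for (i in seq_len(nb)) check_same_grid(inter_phase_dvfs[[1]], inter_phase_dvfs[[i]], "DVFs")
  shape <- grid_shape(inter_phase_dvfs[[1]])
  spacing <- inter_phase_dvfs[[1]]$spacing
  X <- vapply(inter_phase_dvfs, function(d) as.numeric(d$displacement),
              numeric(prod(shape) * 3L))
  mu <- rowMeans(X)
  Xc <- X - mu
  G <- crossprod(Xc) / (nb - 1)
  eg <- eigen(G, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  tol <- max(ev) * 1e-10
  degenerate <- max(ev) <= 1e-24
  comps <- vector("list", n_pc)
  keep_ev <- numeric(n_pc)
  for (i in seq_len(n_pc)) {
    if (!degenerate && i <= nb && ev[i] > tol) {
      ei <- Xc %*% eg$vectors[, i]
      ei <- ei / sqrt(sum(ei^2))
      keep_ev[i] <- ev[i]
    } else {
      ei <- numeric(prod(shape) * 3L)
    }
    comps[[i]] <- dvf(array(ei, c(shape, 3L)), spacing)
  }
  structure(list(mean = dvf(array(mu, c(shape, 3L)), spacing),
                 components = comps,
                 explained_variance = keep_ev,
                 scales = sqrt(keep_ev),
                 n_bin = nb,
                 degenerate = degenerate),
            class = "pca_motion_model")
}

#' @export
print.pca_motion_model <- function(x, ...) {
  cat(sprintf("<pca_motion_model: %d components from %d bins%s>\n",
              length(x$components), x$n_bin,
              if (x$degenerate) ", degenerate (zero variance)" else ""))
  cat("  explained variance:", signif(x$explained_variance, 4), "\n")
  invisible(x)
}

#' Compose a frame deformation field from component weightings
#'
#' The frame field is the model mean plus each principal component scaled
#' independently along the three Cartesian axes:
#' `d = e0 + sum_i sum_axis w[i, axis] * e_i[axis]`. Three components times
#' three axes give the nine degrees of freedom the temporal network emits.
#'
#' @param model a `pca_motion_model`.
#' @param weights numeric `n_components x 3` matrix (rows = components,
#'   columns = SI, AP, LR), or a length `3*n_components` vector filled by
#'   row.
#' @return The composed [dvf()].
#' @export
compose_dvf <- function(model, weights) {
  nc <- length(model$components)
  if (is.null(dim(weights))) {
    if (length(weights) != 3L * nc)
      stop(sprintf("expected %d weights (%d components x 3 axes)", 3L * nc, nc))
    weights <- matrix(weights, nrow = nc, ncol = 3L, byrow = TRUE)
  }
  if (!all(dim(weights) == c(nc, 3L))) stop("weights must be n_components x 3")
  disp <- model$mean$displacement
  for (i in seq_len(nc)) {
    ci <- model$components[[i]]$displacement
    for (a in 1:3)
      if (weights[i, a] != 0)
        disp[, , , a] <- disp[, , , a] + weights[i, a] * ci[, , , a]
  }
  dvf(disp, model$mean$spacing)
}
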