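# Evaluation metrics: relative error of complex images, Dice similarity,
# tumor centre-of-mass error, contour propagation through solved fields,
# and sharpness measures of the reference frame.

#' Binary mask on an image grid
#' @param data logical (or 0/1 numeric) 3D array.
#' @param spacing voxel spacing in mm.
#' @return A `binary_mask`.
#' @export
binary_mask <- function(data, spacing) {
  if (length(dim(data)) != 3L) stop("mask must be a 3D array")
  structure(list(data = array(as.logical(data), dim(data)),
                 spacing = rep_len(as.numeric(spacing), 3L)),
            class = "binary_mask")
}

grid_shape.binary_mask <- function(x) dim(x$data)

#' Relative error between complex volumes
#'
#' The squared-sum ratio `sum |recon - truth|^2 / sum |truth|^2` on the
#' complex values (no outer square root).
#'
#' @param recon,truth [complex_volume()]s on the same grid.
#' @return nonnegative scalar.
#' @export
relative_error <- function(recon, truth) {
  check_same_grid(recon, truth, "recon and truth")
  den <- sum(Mod(truth$data)^2)
  if (den == 0) stop("truth volume has zero norm")
  sum(Mod(recon$data - truth$data)^2) / den
}

#' Dice similarity coefficient
#'
#' `2|A∩B| / (|A| + |B|)`; two empty masks are defined as perfectly
#' agreeing (DSC 1), flagged with a warning.
#'
#' @param a,b [binary_mask()]s on the same grid.
#' @return scalar in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data))) stop("mask grids differ")
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0L) {
    warning("both masks empty; DSC defined as 1")
    return(1)
  }
  2 * sum(a$data & b$data) / (na + nb)
}

#' Centre-of-mass error between two masks
#'
#' Euclidean distance in mm between the voxel-centre centroids.
#'
#' @param a,b nonempty [binary_mask()]s on the same grid and spacing.
#' @return distance in mm.
#' @export
come <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data))) stop("mask grids differ")
  if (sum(a$data) == 0L || sum(b$data) == 0L) stop("empty mask in COME")
  coords <- grid_coords_mm(dim(a$data), a$spacing)
  ca <- colMeans(coords[as.vector(a$data), , drop = FALSE])
  cb <- colMeans(coords[as.vector(b$data), , drop = FALSE])
  sqrt(sum((ca - cb)^2))
}

#' Propagate a contour mask through a deformation field
#'
#' The mask is warped as a real-valued field under the pull convention and
#' re-thresholded at 0.5.
#'
#' @param mask a [binary_mask()].
#' @param dvf_field a [dvf()] on the same grid.
#' @return the propagated [binary_mask()].
#' @export
propagate_contour <- function(mask, dvf_field) {
  if (!identical(dim(mask$data), grid_shape(dvf_field))) stop("grid mismatch")
  vol <- complex_volume(array(as.numeric(mask$data), dim(mask$data)),
                        mask$spacing)
  w <- warp_volume(vol, dvf_field)
  binary_mask(Re(w$data) >= 0.5, mask$spacing)
}

#' Sharpness metrics of a reference-frame image
#'
#' Gradient metric: mean over voxels of the Euclidean magnitude of the
#' central-difference spatial gradient of `|z|` (per voxel, replicated
#' boundaries). Variance metric: mean of the local population variances of
#' `|z|` over sliding cubic windows (interior voxels only). Higher values
#' indicate sharper, less motion-blurred images.
#'
#' @param vol a [complex_volume()].
#' @param window odd edge length of the local-variance window (default 3).
#' @return named numeric vector `c(gradient, variance)`.
#' @export
sharpness <- function(vol, window = 3L) {
  m <- Mod(vol$data)
  d <- dim(m)
  g <- central_gradient3(m)
  grad_metric <- mean(sqrt(g[, , , 1]^2 + g[, , , 2]^2 + g[, , , 3]^2))
  hw <- window %/% 2L
  ix <- (1L + hw):(d[1] - hw); iy <- (1L + hw):(d[2] - hw); iz <- (1L + hw):(d[3] - hw)
  s1 <- array(0, c(length(ix), length(iy), length(iz)))
  s2 <- s1
  for (ox in -hw:hw) for (oy in -hw:hw) for (oz in -hw:hw) {
    blk <- m[ix + ox, iy + oy, iz + oz]
    s1 <- s1 + blk
    s2 <- s2 + blk^2
  }
  nw <- window^3
  var_metric <- mean(s2 / nw - (s1 / nw)^2)
  c(gradient = grad_metric, variance = var_metric)
}

#' Evaluate a reconstruction against the ground-truth phantom
#'
#' Computes per-frame relative error of the reconstructed cine images and,
#' when a tumor mask is available, the tumor centre-of-mass error and Dice
#' coefficient between the mask propagated by the solved fields and the
#' mask propagated by the ground-truth fields.
#'
#' @param result a `recon_result` from [run_progressive_training()].
#' @param phantom the `dynamic_phantom` ground truth.
#' @param frames frame indices to evaluate (default: all).
#' @return data.frame with columns `frame`, `re`, and (with a tumor mask)
#'   `come_mm`, `dsc`.
#' @export
evaluate_reconstruction <- function(result, phantom, frames = NULL) {
  nt <- nrow(result$pc_weights)
  if (is.null(frames)) frames <- seq_len(nt)
  spacing <- phantom$reference$spacing
  has_mask <- !is.null(phantom$tumor_mask)
  if (has_mask) mask <- binary_mask(phantom$tumor_mask, spacing)
  out <- data.frame(frame = frames, re = NA_real_)
  if (has_mask) { out$come_mm <- NA_real_; out$dsc <- NA_real_ }
  for (i in seq_along(frames)) {
    t <- frames[i]
    d_sol <- recon_frame_dvf(result, t)
    d_gt <- phantom_frame_dvf(phantom, t)
    z_sol <- warp_volume(result$reference, d_sol)
    z_gt <- warp_volume(phantom$reference, d_gt)
    out$re[i] <- relative_error(z_sol, z_gt)
    if (has_mask) {
      m_sol <- propagate_contour(mask, d_sol)
      m_gt <- propagate_contour(mask, d_gt)
      out$come_mm[i] <- come(m_sol, m_gt)
      out$dsc[i] <- dsc(m_sol, m_gt)
    }
  }
  out
}
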