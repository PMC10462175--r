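# KSpaceAcquisition: spoke-ordered samples, coil maps, frame binning.

#' Assemble a k-space acquisition container
#'
#' @param trajectory a [kooshball_trajectory()] (or compatible) object.
#' @param samples complex matrix `n_samples x n_coils` in spoke-major order.
#' @param coil_maps list of complex sensitivity arrays, or `NULL` for one
#'   uniform unit coil.
#' @param spokes_per_frame spokes binned into each cine frame.
#' @param grid_shape,spacing image grid the acquisition refers to.
#' @return A `kspace_acquisition` with `frame_assignment` (per spoke) and
#'   `frame_dt = spokes_per_frame * TR`.
#' @export
kspace_acquisition <- function(trajectory, samples, coil_maps = NULL,
                               spokes_per_frame, grid_shape, spacing) {
  samples <- as.matrix(samples)
  n_spokes <- nrow(trajectory$spoke_dirs)
  sps <- trajectory$samples_per_spoke
  if (nrow(samples) != n_spokes * sps)
    stop("sample count does not match trajectory")
  if (n_spokes %% spokes_per_frame != 0L)
    stop("n_spokes must be a multiple of spokes_per_frame")
  grid_shape <- rep_len(as.integer(grid_shape), 3L)
  if (!is.null(coil_maps))
    for (cm in coil_maps)
      if (!identical(dim(cm), grid_shape)) stop("coil map grid mismatch")
  frame_assignment <- rep(seq_len(n_spokes %/% spokes_per_frame),
                          each = spokes_per_frame)
  structure(list(trajectory = trajectory, samples = samples,
                 coil_maps = coil_maps,
                 spokes_per_frame = as.integer(spokes_per_frame),
                 frame_assignment = frame_assignment,
                 frame_dt = spokes_per_frame * trajectory$TR,
                 grid_shape = grid_shape,
                 spacing = rep_len(as.numeric(spacing), 3L)),
            class = "kspace_acquisition")
}

#' @export
print.kspace_acquisition <- function(x, ...) {
  cat(sprintf(paste0("<kspace_acquisition: %d spokes (%d/frame, %d frames), ",
                     "%d coils, frame_dt %.4g s>\n"),
              nrow(x$trajectory$spoke_dirs), x$spokes_per_frame,
              max(x$frame_assignment),
              ncol(x$samples), x$frame_dt))
  invisible(x)
}

n_frames <- function(acq) max(acq$frame_assignment)

# per-sample frame labels (samples are spoke-major)
sample_frames <- function(acq) {
  rep(acq$frame_assignment, each = acq$trajectory$samples_per_spoke)
}

# rows of the sample matrix belonging to one frame
frame_sample_rows <- function(acq, t) which(sample_frames(acq) == t)

# k-space origin sample of every spoke, per coil (the self-navigation series)
center_sample_series <- function(acq) {
  sps <- acq$trajectory$samples_per_spoke
  mid <- (sps + 1L) %/% 2L
  rows <- mid + sps * (seq_len(nrow(acq$trajectory$spoke_dirs)) - 1L)
  acq$samples[rows, , drop = FALSE]
}

#' Simulate the k-space acquisition of a dynamic phantom
#'
#' Generates the golden-mean Koosh-ball trajectory covering the cine
#' sequence (spokes_per_frame spokes per frame) and evaluates the forward
#' model on every quasi-static frame image.
#'
#' @param phantom a `dynamic_phantom` from [synthesize_cine_sequence()].
#' @param spokes_per_frame spokes per cine frame (default 17).
#' @param TR repetition time in seconds (default 5.8 ms).
#' @param samples_per_spoke odd readout points per spoke; default one more
#'   than the largest grid dimension.
#' @param coil_maps list of complex sensitivity maps or `NULL` (single
#'   uniform coil).
#' @param method forward-model evaluation path, see [forward_model()].
#' @return A `kspace_acquisition`.
#' @export
simulate_acquisition <- function(phantom, spokes_per_frame = 17L, TR = 0.0058,
                                 samples_per_spoke = NULL, coil_maps = NULL,
                                 method = c("auto", "exact", "gridded")) {
  method <- match.arg(method)
  shape <- grid_shape(phantom$reference)
  spacing <- phantom$reference$spacing
  nt <- length(phantom$scale_series)
  if (is.null(samples_per_spoke)) {
    samples_per_spoke <- max(shape) + 1L
    if (samples_per_spoke %% 2L == 0L) samples_per_spoke <- samples_per_spoke + 1L
  }
  traj <- kooshball_trajectory(nt * spokes_per_frame, samples_per_spoke,
                               spacing, TR)
  sps <- samples_per_spoke
  sample_frame <- rep(rep(seq_len(nt), each = spokes_per_frame), each = sps)
  if (method == "auto") method <- if (prod(shape) <= 20^3) "exact" else "gridded"
  plan <- NULL
  if (method == "gridded")
    plan <- nufft_plan(traj$k_coords, shape, spacing, groups = sample_frame)
  n_coils <- if (is.null(coil_maps)) 1L else length(coil_maps)
  samples <- matrix(0 + 0i, nrow(traj$k_coords), n_coils)
  for (t in seq_len(nt)) {
    zt <- phantom_frame(phantom, t)
    rows <- which(sample_frame == t)
    samples[rows, ] <- if (method == "gridded")
      forward_model(zt, coil_maps = coil_maps, method = "gridded",
                    plan = within_plan(plan, t))
    else
      forward_model(zt, traj$k_coords[rows, , drop = FALSE], coil_maps,
                    method = "exact")
  }
  kspace_acquisition(traj, samples, coil_maps, spokes_per_frame, shape, spacing)
}

# view of a grouped plan exposing a single group's operator
within_plan <- function(plan, group) {
  plan$ops <- plan$ops[as.character(group)]
  plan
}
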