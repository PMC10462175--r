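# Synthetic dynamic thorax phantom: an analytic ellipsoid-composited
# magnitude volume (body, two lungs, diaphragm band, abdomen, spherical
# tumor), sinusoidal-superposition phase modulation, scripted breathing
# scenario traces, and the ground-truth cine sequence obtained by warping
# the end-of-exhale reference with trace-scaled motion basis fields.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Phantom geometry specification
#'
#' Defaults reproduce the study grid: 100^3 voxels at 4-mm isotropic
#' spacing with a 30-mm spherical lung tumor. Structure layout is defined
#' in fractions of the field of view so the same anatomy scales to reduced
#' grids; the tumor diameter stays absolute (mm).
#'
#' @param grid_shape integer (scalar or length 3) grid dimensions.
#' @param spacing voxel spacing in mm.
#' @param tumor_diameter tumor diameter in mm.
#' @param tumor_center tumor centre in mm (SI, AP, LR, centred coordinates);
#'   `NULL` places it in the lower lobe of the right lung.
#' @param tissue_intensities named magnitudes for body, abdomen, diaphragm,
#'   lung and tumor.
#' @param seed integer seed for any stochastic phantom elements.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(100L, 100L, 100L), spacing = 4,
                         tumor_diameter = 30, tumor_center = NULL,
                         tissue_intensities = c(body = 0.5, abdomen = 0.8,
                                                diaphragm = 0.95, lung = 0.2,
                                                tumor = 1.0),
                         seed = 0L) {
  grid_shape <- rep_len(as.integer(grid_shape), 3L)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(grid_shape < 8L)) stop("grid_shape must be at least 8 per axis")
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (tumor_diameter <= 0) stop("tumor_diameter must be positive")
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 tumor_diameter = tumor_diameter, tumor_center = tumor_center,
                 tissue_intensities = tissue_intensities, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Structure geometry in fractions of the half field of view per axis.
phantom_geometry <- function(spec) {
  h <- spec$grid_shape * spec$spacing / 2
  lungs <- list(
    right = list(center = c(0.22 * h[1], 0, 0.28 * h[3]),
                 semi = c(0.42 * h[1], 0.32 * h[2], 0.22 * h[3])),
    left = list(center = c(0.22 * h[1], 0, -0.28 * h[3]),
                semi = c(0.42 * h[1], 0.32 * h[2], 0.22 * h[3])))
  tumor_center <- spec$tumor_center
  if (is.null(tumor_center))
    tumor_center <- lungs$right$center + c(-0.4 * lungs$right$semi[1], 0, 0)
  list(h = h,
       body = list(center = c(-0.05 * h[1], 0, 0),
                   semi = c(0.85 * h[1], 0.62 * h[2], 0.72 * h[3])),
       lungs = lungs,
       z_diaphragm = -0.25 * h[1],
       diaphragm_band = 0.06 * h[1],
       tumor_center = tumor_center)
}

inside_ellipsoid <- function(coords, center, semi) {
  ((coords[, 1] - center[1]) / semi[1])^2 +
    ((coords[, 2] - center[2]) / semi[2])^2 +
    ((coords[, 3] - center[3]) / semi[3])^2 <= 1
}

#' Build the end-of-exhale reference volume and tumor mask
#'
#' Composites the analytic thorax structures into a magnitude volume
#' (returned as a [complex_volume()] with zero imaginary part) and
#' voxelises the spherical tumor into a binary mask.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` ([complex_volume()]), `tumor_mask` (logical
#'   array) and `lung_mask` (logical array).
#' @export
build_reference_volume <- function(spec) {
  g <- phantom_geometry(spec)
  coords <- grid_coords_mm(spec$grid_shape, spec$spacing)
  ti <- spec$tissue_intensities
  mag <- numeric(nrow(coords))
  body <- inside_ellipsoid(coords, g$body$center, g$body$semi)
  mag[body] <- ti[["body"]]
  abdomen <- body & coords[, 1] < g$z_diaphragm
  mag[abdomen] <- ti[["abdomen"]]
  dia <- body & coords[, 1] >= g$z_diaphragm &
    coords[, 1] < g$z_diaphragm + g$diaphragm_band
  mag[dia] <- ti[["diaphragm"]]
  lung <- inside_ellipsoid(coords, g$lungs$right$center, g$lungs$right$semi) |
    inside_ellipsoid(coords, g$lungs$left$center, g$lungs$left$semi)
  mag[lung] <- ti[["lung"]]
  r <- spec$tumor_diameter / 2
  dt2 <- (coords[, 1] - g$tumor_center[1])^2 + (coords[, 2] - g$tumor_center[2])^2 +
    (coords[, 3] - g$tumor_center[3])^2
  tumor <- dt2 <= r^2
  if (any(abs(g$tumor_center) + r > g$h))
    stop("tumor extends outside the image grid")
  if (any(tumor & !lung))
    stop("tumor is not fully inside the lung region; shrink or recentre it")
  mag[tumor] <- ti[["tumor"]]
  dim(mag) <- spec$grid_shape
  mag <- gaussian_smooth3(mag, 0.6) # soften tissue interfaces
  mag[mag < 0] <- 0
  mask <- tumor
  dim(mask) <- spec$grid_shape
  lung_mask <- lung & !tumor
  dim(lung_mask) <- spec$grid_shape
  list(volume = complex_volume(mag, spec$spacing), tumor_mask = mask,
       lung_mask = lung_mask)
}

#' Phase-map specification
#'
#' @param n_sinusoids number of superposed sinusoids (default 4).
#' @param wavenumber_range spatial-frequency interval in cycles/mm from
#'   which each sinusoid's wave number is drawn.
#' @param seed integer seed.
#' @param orientations optional `n_sinusoids x 3` matrix of fixed
#'   propagation directions (unit vectors); random when `NULL`.
#' @return A `phase_map_spec` list.
#' @export
phase_map_spec <- function(n_sinusoids = 4L, wavenumber_range = c(0.0033, 0.02),
                           seed = 0L, orientations = NULL) {
  if (n_sinusoids < 1L) stop("n_sinusoids must be at least 1")
  if (length(wavenumber_range) != 2L || any(wavenumber_range <= 0) ||
      diff(wavenumber_range) < 0)
    stop("wavenumber_range must be a positive ordered interval")
  structure(list(n_sinusoids = as.integer(n_sinusoids),
                 wavenumber_range = wavenumber_range, seed = as.integer(seed),
                 orientations = orientations),
            class = "phase_map_spec")
}

#' Simulate a spatial phase-modulation map
#'
#' Superposes `n_sinusoids` plane-wave sinusoids with random wave number,
#' orientation and phase shift, then min-max normalises the sum to
#' `[0, 2*pi]`. Applied downstream as the unit-modulus factor
#' `exp(1i * phase)`.
#'
#' @param spec a [phase_map_spec()].
#' @param grid_shape,spacing grid definition as in [complex_volume()].
#' @return 3D array of phase values in radians, with the drawn wave numbers
#'   attached as attribute `wavenumbers`.
#' @export
simulate_phase_map <- function(spec, grid_shape, spacing) {
  grid_shape <- rep_len(as.integer(grid_shape), 3L)
  coords <- grid_coords_mm(grid_shape, spacing)
  with_seed(spec$seed, {
    kn <- runif(spec$n_sinusoids, spec$wavenumber_range[1], spec$wavenumber_range[2])
    dirs <- spec$orientations
    if (is.null(dirs)) {
      dirs <- matrix(rnorm(3 * spec$n_sinusoids), ncol = 3L)
      dirs <- dirs / sqrt(rowSums(dirs^2))
    }
    shifts <- runif(spec$n_sinusoids, 0, 2 * pi)
    ph <- numeric(nrow(coords))
    for (i in seq_len(spec$n_sinusoids))
      ph <- ph + sin(2 * pi * kn[i] * (coords %*% dirs[i, ]) + shifts[i])
    rng <- range(ph)
    ph <- if (diff(rng) > 0) (ph - rng[1]) / diff(rng) * 2 * pi else ph * 0
    dim(ph) <- grid_shape
    attr(ph, "wavenumbers") <- kn
    ph
  })
}

#' Apply a phase map to a magnitude volume
#' @param vol a [complex_volume()] (its magnitude is used).
#' @param phase 3D phase array in radians on the same grid.
#' @return complex [complex_volume()] `|vol| * exp(1i * phase)`.
#' @export
apply_phase_modulation <- function(vol, phase) {
  if (!identical(dim(phase)[1:3], grid_shape(vol))) stop("phase grid mismatch")
  complex_volume(Mod(vol$data) * exp(1i * as.numeric(phase)), vol$spacing)
}

# --- breathing traces --------------------------------------------------------

sigmoid_step <- function(t, t0, delta, ramp = 2) {
  delta / (1 + exp(-(t - t0) / (ramp / 8)))
}

# Per-cycle period/amplitude schedules for the six scenarios. Amplitudes in
# mm of diaphragm displacement; the waveform within each cycle is
# A * sin^4(pi * (t - t0) / T), which dwells near zero (end of exhale) and
# peaks mid-cycle, matching the exhale-weighted shape of free breathing.
scenario_cycles <- function(scenario_id, duration_s) {
  t0 <- 0; cycles <- list()
  while (t0 < duration_s) {
    cyc <- switch(scenario_id,
      S1 = list(T = 4, A = 20 * runif(1, 0.9, 1)),
      S2 = list(T = 4, A = 20 * runif(1, 0.9, 1)),
      S3 = list(T = 4, A = 20 * runif(1, 0.75, 1)),
      S4 = if (t0 < 60) list(T = 4, A = 20 * runif(1, 0.9, 1))
           else list(T = 2.8, A = 13 * runif(1, 0.9, 1)),
      S5 = list(T = 6, A = 20 * (1 - 0.45 * min(t0 / duration_s, 1)) *
                  runif(1, 0.95, 1)),
      S6 = list(T = runif(1, 3, 5), A = 20 * runif(1, 0.7, 1)),
      stop(sprintf("unknown motion scenario '%s'", scenario_id)))
    cycles[[length(cycles) + 1L]] <- c(start = t0, T = cyc$T, A = cyc$A)
    t0 <- t0 + cyc$T
  }
  do.call(rbind, cycles)
}

scenario_baseline <- function(scenario_id, times) {
  switch(scenario_id,
    S1 = rep(0, length(times)),
    S2 = sigmoid_step(times, 90, -7),
    S3 = sigmoid_step(times, 60, -5) + sigmoid_step(times, 120, 3),
    S4 = rep(0, length(times)),
    S5 = rep(0, length(times)),
    S6 = 3 * sin(2 * pi * times / 90) + sigmoid_step(times, 100, -5),
    stop(sprintf("unknown motion scenario '%s'", scenario_id)))
}

#' Generate a breathing-scenario motion trace
#'
#' Produces the diaphragm SI displacement series of one of six scripted
#' free-breathing scenarios at the cine frame rate: S1 amplitude jitter on
#' a constant baseline; S2 adds a 7-mm downward baseline step near 90 s
#' (2-s sigmoid ramp); S3 amplitude variation plus baseline shifts; S4 a
#' period/amplitude change after 60 s; S5 slow breathing with gradually
#' decaying amplitude; S6 combined period, amplitude and baseline
#' variation.
#'
#' @param scenario_id one of `"S1"`..`"S6"`.
#' @param duration_s scan duration in seconds (default 180).
#' @param frame_dt_s frame temporal resolution in seconds (default 0.0986,
#'   i.e. 17 spokes at TR 5.8 ms).
#' @param seed integer seed driving the per-cycle randomness.
#' @return A `motion_trace`: `times` (s), `amplitude` (mm, the cyclic
#'   component), `baseline` (mm), `scenario_id`, `frame_dt`. Total
#'   diaphragm displacement is `amplitude + baseline`.
#' @export
generate_motion_trace <- function(scenario_id, duration_s = 180,
                                  frame_dt_s = 0.0986, seed = 0L) {
  if (!scenario_id %in% paste0("S", 1:6))
    stop(sprintf("unknown motion scenario '%s'", scenario_id))
  if (duration_s <= 0 || frame_dt_s <= 0) stop("duration and frame_dt must be positive")
  n <- ceiling(duration_s / frame_dt_s)
  times <- (seq_len(n) - 1L) * frame_dt_s
  with_seed(seed, {
    cyc <- scenario_cycles(scenario_id, duration_s)
    ci <- findInterval(times, cyc[, "start"])
    amp <- cyc[ci, "A"] * sin(pi * (times - cyc[ci, "start"]) / cyc[ci, "T"])^4
    structure(list(times = times, amplitude = amp,
                   baseline = scenario_baseline(scenario_id, times),
                   scenario_id = scenario_id, frame_dt = frame_dt_s),
              class = "motion_trace")
  })
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace %s: %d frames at %.4f s (%.1f s)>\n",
              x$scenario_id, length(x$times), x$frame_dt,
              length(x$times) * x$frame_dt))
  invisible(x)
}

# --- motion basis ------------------------------------------------------------

#' Analytic ground-truth motion basis fields
#'
#' Two smooth separable displacement modes: `u1`, a superior-inferior field
#' with magnitude 1 at the diaphragm surface, constant through the abdomen
#' and decaying with a Gaussian profile toward the lung apex; and `u2`, an
#' anterior-posterior chest-wall expansion mode, applied downstream at 20%
#' of `u1`'s weight. Both taper laterally with broad Gaussians so warps
#' stay smooth.
#'
#' @param spec a [phantom_spec()].
#' @param sigma_si Gaussian falloff of `u1` above the diaphragm, as a
#'   fraction of the half field of view (default 0.35).
#' @return list of two [dvf()]s with attribute `weights = c(1, 0.2)`.
#' @export
build_motion_basis <- function(spec, sigma_si = 0.35) {
  g <- phantom_geometry(spec)
  h <- g$h
  coords <- grid_coords_mm(spec$grid_shape, spec$spacing)
  n <- nrow(coords)
  zd <- g$z_diaphragm
  prof <- ifelse(coords[, 1] <= zd, 1,
                 exp(-((coords[, 1] - zd)^2) / (2 * (sigma_si * h[1])^2)))
  lat <- exp(-(coords[, 2] / (0.55 * h[2]))^2 - (coords[, 3] / (0.65 * h[3]))^2)
  u1 <- array(0, c(spec$grid_shape, 3L))
  u1[, , , 1] <- prof * lat
  u2 <- array(0, c(spec$grid_shape, 3L))
  u2[, , , 2] <- (coords[, 2] / h[2]) *
    exp(-((coords[, 1] - 0.15 * h[1]) / (0.45 * h[1]))^2) *
    exp(-(coords[, 3] / (0.7 * h[3]))^2)
  basis <- list(dvf(u1, spec$spacing), dvf(u2, spec$spacing))
  attr(basis, "weights") <- c(1, 0.2)
  basis
}

#' Voxel index of the diaphragm apex (maximum of the first basis mode)
#' @param basis output of [build_motion_basis()].
#' @return integer length-3 voxel index.
#' @export
diaphragm_apex_voxel <- function(basis) {
  u1 <- basis[[1]]$displacement[, , , 1]
  # the SI profile is 1 through the whole abdomen; take the most superior
  # voxel on the central axis where it is still ~1 (the dome apex)
  w <- which(u1 > 1 - 1e-9, arr.ind = TRUE)
  w[which.max(w[, 1]), ]
}

# --- dynamic phantom ---------------------------------------------------------

#' Synthesize the ground-truth cine sequence
#'
#' Combines the complex reference volume, a breathing trace and the motion
#' basis into a dynamic phantom: the frame-`t` ground-truth field is the
#' trace displacement `s(t) = amplitude(t) + baseline(t)` times the
#' weighted basis combination, and frame images are pull-warps of the
#' reference. Frames and fields are composed on demand (the sequence can
#' be long); use [phantom_frame()] and [phantom_frame_dvf()].
#'
#' @param phantom_ref complex [complex_volume()] reference (end of exhale).
#' @param trace a `motion_trace`.
#' @param basis_dvfs output of [build_motion_basis()] (or any list of
#'   [dvf()]s with a `weights` attribute) on the reference grid.
#' @param tumor_mask optional logical array annotating the reference.
#' @return A `dynamic_phantom`: `reference`, `tumor_mask`, `trace`,
#'   `motion_field` (the combined unit-amplitude [dvf()]), `scale_series`
#'   (mm displacement per frame).
#' @export
synthesize_cine_sequence <- function(phantom_ref, trace, basis_dvfs,
                                     tumor_mask = NULL) {
  w <- attr(basis_dvfs, "weights")
  if (is.null(w)) w <- rep(1, length(basis_dvfs))
  for (b in basis_dvfs) check_same_grid(phantom_ref, b, "reference and basis DVFs")
  disp <- 0
  for (i in seq_along(basis_dvfs))
    disp <- disp + w[i] * basis_dvfs[[i]]$displacement
  structure(list(reference = phantom_ref,
                 tumor_mask = tumor_mask,
                 trace = trace,
                 motion_field = dvf(disp, phantom_ref$spacing),
                 scale_series = trace$amplitude + trace$baseline),
            class = "dynamic_phantom")
}

#' @export
print.dynamic_phantom <- function(x, ...) {
  cat(sprintf("<dynamic_phantom: %d frames, grid %s>\n",
              length(x$scale_series),
              paste(grid_shape(x$reference), collapse = "x")))
  invisible(x)
}

#' Ground-truth deformation field of one frame
#' @param phantom a `dynamic_phantom`.
#' @param t frame index (1-based).
#' @return The frame [dvf()].
#' @export
phantom_frame_dvf <- function(phantom, t) {
  s <- phantom$scale_series[t]
  dvf(s * phantom$motion_field$displacement, phantom$reference$spacing)
}

#' Ground-truth image of one frame
#' @inheritParams phantom_frame_dvf
#' @return The frame [complex_volume()].
#' @export
phantom_frame <- function(phantom, t) {
  warp_volume(phantom$reference, phantom_frame_dvf(phantom, t))
}

#' Offline PCA motion model from the phantom ground truth
#'
#' Emulates a previously acquired, motion-binned 4D image set: the
#' phantom's motion field is sampled at `n_bins` phase points of one
#' nominal breathing cycle (amplitude = the trace maximum), giving the
#' inter-phase fields relative to end-of-exhale from which the PCA basis
#' is extracted.
#'
#' @param phantom a `dynamic_phantom`.
#' @param n_bins respiratory phases of the emulated prior set (default 10).
#' @param n_pc principal components kept (default 3).
#' @return A `pca_motion_model`.
#' @export
phantom_motion_model <- function(phantom, n_bins = 10L, n_pc = 3L) {
  A <- max(phantom$scale_series)
  s_p <- A * sin(pi * ((seq_len(n_bins) - 1) + 0.5) / n_bins)^4
  dvfs <- lapply(s_p, function(s)
    dvf(s * phantom$motion_field$displacement, phantom$reference$spacing))
  compute_pca_basis(dvfs, n_pc)
}
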