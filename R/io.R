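# Formats: complex volumes as paired real/imaginary NIfTI files with a
# JSON sidecar (NIfTI complex support is inconsistently honoured across
# tools), DVFs as 4D NIfTI (last axis = SI/AP/LR component, mm), and
# acquisitions / phantom bundles as self-describing directory containers
# of named NIfTI datasets plus a JSON metadata block.

nifti_with_spacing <- function(arr, spacing) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep_len(spacing, length(dim(arr)))
  img
}

#' Write a complex volume as a real/imaginary NIfTI pair
#'
#' Creates `<prefix>_real.nii.gz`, `<prefix>_imag.nii.gz` and a
#' `<prefix>.json` sidecar naming the pair and recording the spacing.
#'
#' @param vol a [complex_volume()].
#' @param prefix output path prefix.
#' @return the sidecar path, invisibly.
#' @export
write_complex_volume <- function(vol, prefix) {
  pr <- paste0(prefix, "_real.nii.gz"); pi_ <- paste0(prefix, "_imag.nii.gz")
  RNifti::writeNifti(nifti_with_spacing(Re(vol$data), vol$spacing), pr)
  RNifti::writeNifti(nifti_with_spacing(Im(vol$data), vol$spacing), pi_)
  side <- paste0(prefix, ".json")
  jsonlite::write_json(list(real = basename(pr), imag = basename(pi_),
                            spacing = vol$spacing),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Read a complex volume written by [write_complex_volume()]
#'
#' A magnitude-only file (sidecar without an imaginary member, or a bare
#' NIfTI path) is read with zero imaginary part.
#'
#' @param prefix path prefix (or sidecar path).
#' @return A [complex_volume()].
#' @export
read_complex_volume <- function(prefix) {
  side <- if (grepl("\\.json$", prefix)) prefix else paste0(prefix, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    dirn <- dirname(side)
    re <- RNifti::readNifti(file.path(dirn, meta$real))
    im <- if (!is.null(meta$imag) && file.exists(file.path(dirn, meta$imag)))
      RNifti::readNifti(file.path(dirn, meta$imag)) else array(0, dim(re))
    spacing <- as.numeric(meta$spacing)
  } else {
    re <- RNifti::readNifti(prefix)
    im <- array(0, dim(re))
    spacing <- RNifti::pixdim(re)[1:3]
  }
  complex_volume(array(complex(real = re, imaginary = im), dim(re)), spacing)
}

#' Write a deformation field as 4D NIfTI
#' @param d a [dvf()].
#' @param path output `.nii`/`.nii.gz` path.
#' @export
write_dvf <- function(d, path) {
  RNifti::writeNifti(nifti_with_spacing(d$displacement, c(d$spacing, 1)), path)
  invisible(path)
}

#' Read a deformation field written by [write_dvf()]
#' @param path NIfTI path.
#' @return A [dvf()].
#' @export
read_dvf <- function(path) {
  arr <- RNifti::readNifti(path)
  dvf(array(as.numeric(arr), dim(arr)), RNifti::pixdim(arr)[1:3])
}

#' Save an acquisition as a directory container
#'
#' Named datasets (`k_coords`, `samples_real`/`samples_imag`, coil maps)
#' are stored as NIfTI arrays beside a `meta.json` block with the timing
#' and binning attributes.
#'
#' @param acq a `kspace_acquisition`.
#' @param path directory to create.
#' @export
save_acquisition <- function(acq, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wn <- function(arr, name) RNifti::writeNifti(RNifti::asNifti(arr),
                                               file.path(path, paste0(name, ".nii.gz")))
  wn(acq$trajectory$k_coords, "k_coords")
  wn(acq$trajectory$spoke_dirs, "spoke_dirs")
  wn(Re(acq$samples), "samples_real")
  wn(Im(acq$samples), "samples_imag")
  n_coils <- ncol(acq$samples)
  if (!is.null(acq$coil_maps))
    for (c in seq_along(acq$coil_maps)) {
      wn(Re(acq$coil_maps[[c]]), sprintf("coil%02d_real", c))
      wn(Im(acq$coil_maps[[c]]), sprintf("coil%02d_imag", c))
    }
  jsonlite::write_json(
    list(TR = acq$trajectory$TR,
         samples_per_spoke = acq$trajectory$samples_per_spoke,
         k_max = acq$trajectory$k_max,
         spokes_per_frame = acq$spokes_per_frame,
         frame_dt = acq$frame_dt, n_coils = n_coils,
         has_coil_maps = !is.null(acq$coil_maps),
         grid_shape = acq$grid_shape, spacing = acq$spacing),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an acquisition container written by [save_acquisition()]
#' @param path container directory.
#' @return A `kspace_acquisition`.
#' @export
load_acquisition <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  rn <- function(name) {
    arr <- RNifti::readNifti(file.path(path, paste0(name, ".nii.gz")))
    array(as.numeric(arr), dim(arr))
  }
  k <- rn("k_coords"); dirs <- rn("spoke_dirs")
  traj <- structure(list(spoke_dirs = dirs,
                         samples_per_spoke = as.integer(meta$samples_per_spoke),
                         k_coords = k, TR = meta$TR, k_max = meta$k_max),
                    class = "trajectory")
  samples <- matrix(complex(real = rn("samples_real"), imaginary = rn("samples_imag")),
                    nrow = nrow(k), ncol = meta$n_coils)
  coil_maps <- NULL
  if (isTRUE(meta$has_coil_maps))
    coil_maps <- lapply(seq_len(meta$n_coils), function(c)
      array(complex(real = rn(sprintf("coil%02d_real", c)),
                    imaginary = rn(sprintf("coil%02d_imag", c))),
            meta$grid_shape))
  kspace_acquisition(traj, samples, coil_maps, meta$spokes_per_frame,
                     meta$grid_shape, meta$spacing)
}

#' Save a dynamic phantom bundle
#'
#' Directory container: the complex reference as a NIfTI pair, the tumor
#' mask and combined motion field as NIfTI, the trace as CSV, and a JSON
#' metadata block.
#'
#' @param phantom a `dynamic_phantom`.
#' @param path directory to create.
#' @export
save_phantom_bundle <- function(phantom, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_complex_volume(phantom$reference, file.path(path, "reference"))
  if (!is.null(phantom$tumor_mask))
    RNifti::writeNifti(nifti_with_spacing(phantom$tumor_mask + 0,
                                          phantom$reference$spacing),
                       file.path(path, "tumor_mask.nii.gz"))
  write_dvf(phantom$motion_field, file.path(path, "motion_field.nii.gz"))
  tr <- phantom$trace
  write.csv(data.frame(time_s = tr$times, amplitude_mm = tr$amplitude,
                       baseline_mm = tr$baseline),
            file.path(path, "trace.csv"), row.names = FALSE)
  jsonlite::write_json(list(scenario_id = tr$scenario_id, frame_dt = tr$frame_dt,
                            n_frames = length(tr$times),
                            has_tumor_mask = !is.null(phantom$tumor_mask)),
                       file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a dynamic phantom bundle written by [save_phantom_bundle()]
#' @param path container directory.
#' @return A `dynamic_phantom`.
#' @export
load_phantom_bundle <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  reference <- read_complex_volume(file.path(path, "reference"))
  tumor_mask <- NULL
  if (isTRUE(meta$has_tumor_mask)) {
    m <- RNifti::readNifti(file.path(path, "tumor_mask.nii.gz"))
    tumor_mask <- array(as.numeric(m) > 0.5, dim(m))
  }
  motion_field <- read_dvf(file.path(path, "motion_field.nii.gz"))
  trc <- read.csv(file.path(path, "trace.csv"))
  trace <- structure(list(times = trc$time_s, amplitude = trc$amplitude_mm,
                          baseline = trc$baseline_mm,
                          scenario_id = meta$scenario_id,
                          frame_dt = meta$frame_dt),
                     class = "motion_trace")
  synthesize_cine_sequence(reference, trace,
                           structure(list(motion_to_basis(motion_field)),
                                     weights = 1),
                           tumor_mask)
}

# wrap a stored combined field back into a single-element basis
motion_to_basis <- function(field) field

#' Write a run manifest
#'
#' Every orchestrated run records its configuration snapshot, seed, input
#' hashes, outputs and wall time so that reruns are reproducible.
#'
#' @param path output JSON path.
#' @param command the executed subcommand.
#' @param config a named list (configuration snapshot).
#' @param seed integer seed.
#' @param inputs named character vector of input paths (hashed when they
#'   exist).
#' @param outputs character vector of produced paths.
#' @param walltime_s elapsed seconds.
#' @export
write_manifest <- function(path, command, config, seed, inputs = character(0),
                           outputs = character(0), walltime_s = NA_real_) {
  hash_file <- function(f) {
    if (!file.exists(f) || dir.exists(f)) return(NA_character_)
    sprintf("size:%d", file.size(f))
  }
  jsonlite::write_json(
    list(tool = "cineinr", version = as.character(utils::packageVersion("cineinr")),
         command = command, seed = seed, config = config,
         inputs = if (length(inputs)) as.list(setNames(vapply(inputs, hash_file,
                                                              character(1)),
                                                       names(inputs))) else NULL,
         outputs = as.list(outputs), walltime_s = walltime_s,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
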