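#' Complex-valued image volume on a regular grid
#'
#' The basic image container: a 3D complex array together with its physical
#' voxel spacing in millimetres. The grid is centred on the physical origin
#' (see package conventions). Magnitude-only images are stored with a zero
#' imaginary part.
#'
#' @param data numeric or complex 3D array.
#' @param spacing numeric length-3 voxel spacing in mm (SI, AP, LR order),
#'   or a single number for isotropic grids.
#' @return An object of class `complex_volume` with elements `data`
#'   (complex array) and `spacing`.
#' @export
complex_volume <- function(data, spacing) {
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) stop("spacing must be positive")
  if (!is.complex(data)) {
    storage.mode(data) <- "double"
    data <- data + 0i
  }
  structure(list(data = data, spacing = spacing), class = "complex_volume")
}

#' @export
print.complex_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<complex_volume %dx%dx%d, spacing %s mm>\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

is_complex_volume <- function(x) inherits(x, "complex_volume")

#' Deformation vector field
#'
#' A per-voxel 3-component displacement field in millimetres, on the same
#' centred grid as the images it deforms. Component order is SI, AP, LR
#' (stored as the 4th array axis).
#'
#' @param displacement numeric 4D array `(nx, ny, nz, 3)` of displacements
#'   in mm.
#' @param spacing voxel spacing in mm, as in [complex_volume()].
#' @return An object of class `dvf` with elements `displacement`, `spacing`.
#' @export
dvf <- function(displacement, spacing) {
  d <- dim(displacement)
  if (length(d) != 4L || d[4] != 3L) stop("displacement must be (nx, ny, nz, 3)")
  if (!all(is.finite(displacement))) stop("displacement must be finite everywhere")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  storage.mode(displacement) <- "double"
  structure(list(displacement = displacement, spacing = spacing), class = "dvf")
}

#' @export
print.dvf <- function(x, ...) {
  d <- dim(x$displacement)
  cat(sprintf("<dvf %dx%dx%d, spacing %s mm, max |d| %.3f mm>\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = "x"),
              sqrt(max(rowSums(matrix(x$displacement, ncol = 3L)^2)))))
  invisible(x)
}

#' Zero deformation field on a given grid
#' @param grid_shape integer length-3 grid dimensions.
#' @param spacing voxel spacing in mm.
#' @return A [dvf()] with all-zero displacement.
#' @export
zero_dvf <- function(grid_shape, spacing) {
  dvf(array(0, dim = c(grid_shape, 3L)), spacing)
}

grid_shape <- function(x) {
  if (is_complex_volume(x)) dim(x$data) else dim(x$displacement)[1:3]
}

check_same_grid <- function(a, b, what = "inputs") {
  if (!identical(grid_shape(a), grid_shape(b)) ||
      max(abs(a$spacing - b$spacing)) > 1e-9)
    stop(sprintf("%s must share grid shape and spacing", what))
  invisible(TRUE)
}

#' Physical voxel-centre coordinates of a grid
#'
#' Returns the millimetre coordinates of all voxel centres for a centred
#' grid, as a matrix in array-flattening (column-major) order.
#'
#' @param grid_shape integer length-3 grid dimensions.
#' @param spacing voxel spacing in mm.
#' @return `prod(grid_shape) x 3` matrix of mm coordinates.
#' @export
grid_coords_mm <- function(grid_shape, spacing) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  ax <- lapply(1:3, function(a) (seq_len(grid_shape[a]) - 1 - grid_shape[a] / 2) * spacing[a])
  as.matrix(expand.grid(si = ax[[1]], ap = ax[[2]], lr = ax[[3]], KEEP.OUT.ATTRS = FALSE))
}

#' Normalised voxel-centre coordinates in [-1, 1]^3
#'
#' Half-voxel-offset convention: voxel `i` (1-based) maps to
#' `-1 + (2*(i-1)+1)/N`.
#'
#' @inheritParams grid_coords_mm
#' @return `prod(grid_shape) x 3` matrix of normalised coordinates.
#' @export
grid_coords_norm <- function(grid_shape, spacing = c(1, 1, 1)) {
  ax <- lapply(1:3, function(a) -1 + (2 * (seq_len(grid_shape[a]) - 1) + 1) / grid_shape[a])
  as.matrix(expand.grid(si = ax[[1]], ap = ax[[2]], lr = ax[[3]], KEEP.OUT.ATTRS = FALSE))
}

# Periodic Gaussian smoothing of a 3D (real) array via FFT; sigma in voxels,
# possibly per-axis. Used by registration and the motion basis construction.
gaussian_smooth3 <- function(arr, sigma) {
  d <- dim(arr)
  sigma <- rep_len(sigma, 3L)
  kern <- lapply(1:3, function(a) {
    if (sigma[a] <= 0) return(rep(1, d[a]))
    f <- c(0:(d[a] %/% 2), -((d[a] - d[a] %/% 2 - 1):1)) / d[a]
    exp(-2 * pi^2 * sigma[a]^2 * f^2)
  })
  K <- outer(outer(kern[[1]], kern[[2]]), kern[[3]])
  dim(K) <- d
  Re(fft(fft(arr) * K, inverse = TRUE)) / prod(d)
}
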