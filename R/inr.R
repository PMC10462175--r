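# Spatial INR: shared 3D hash encoding feeding two sine-activated MLPs
# (real and imaginary channel). Temporal INR: 1D hash encoding feeding
# nine parallel ReLU MLPs emitting the per-frame, per-axis weightings of
# the principal motion components. All forward/backward passes are
# hand-derived; no autodiff framework is involved.

# --- dense layers ------------------------------------------------------------

mlp_sine_init <- function(n_in, n_hidden, omega0, rng_unif) {
  list(W1 = matrix(rng_unif(n_in * n_hidden, 1 / n_in), n_in, n_hidden),
       b1 = numeric(n_hidden),
       W2 = matrix(rng_unif(n_hidden, sqrt(6 / n_hidden) / omega0), n_hidden, 1),
       b2 = numeric(1))
}

mlp_sine_forward <- function(p, x, omega0) {
  a1 <- sweep(x %*% p$W1, 2L, p$b1, "+")
  h <- sin(omega0 * a1)
  y <- as.numeric(h %*% p$W2) + p$b2
  list(y = y, a1 = a1, h = h, x = x)
}

mlp_sine_backward <- function(p, cache, dy, omega0) {
  dy <- matrix(dy, ncol = 1L)
  dW2 <- crossprod(cache$h, dy)
  db2 <- sum(dy)
  dh <- dy %*% t(p$W2)
  da1 <- dh * cos(omega0 * cache$a1) * omega0
  list(grads = list(W1 = crossprod(cache$x, da1), b1 = colSums(da1),
                    W2 = dW2, b2 = db2),
       dx = da1 %*% t(p$W1))
}

mlp_relu_init <- function(n_in, n_hidden, rng_unif) {
  list(W1 = matrix(rng_unif(n_in * n_hidden, sqrt(6 / n_in)), n_in, n_hidden),
       b1 = numeric(n_hidden),
       W2 = matrix(rng_unif(n_hidden * n_hidden, sqrt(6 / n_hidden)), n_hidden, n_hidden),
       b2 = numeric(n_hidden),
       W3 = matrix(rng_unif(n_hidden, sqrt(6 / n_hidden)), n_hidden, 1),
       b3 = numeric(1))
}

mlp_relu_forward <- function(p, x) {
  a1 <- sweep(x %*% p$W1, 2L, p$b1, "+"); h1 <- pmax(a1, 0)
  a2 <- sweep(h1 %*% p$W2, 2L, p$b2, "+"); h2 <- pmax(a2, 0)
  y <- as.numeric(h2 %*% p$W3) + p$b3
  list(y = y, x = x, a1 = a1, h1 = h1, a2 = a2, h2 = h2)
}

mlp_relu_backward <- function(p, cache, dy) {
  dy <- matrix(dy, ncol = 1L)
  dW3 <- crossprod(cache$h2, dy); db3 <- sum(dy)
  dh2 <- dy %*% t(p$W3)
  da2 <- dh2 * (cache$a2 > 0)
  dW2 <- crossprod(cache$h1, da2); db2 <- colSums(da2)
  dh1 <- da2 %*% t(p$W2)
  da1 <- dh1 * (cache$a1 > 0)
  list(grads = list(W1 = crossprod(cache$x, da1), b1 = colSums(da1),
                    W2 = dW2, b2 = db2, W3 = dW3, b3 = db3),
       dx = da1 %*% t(p$W1))
}

# --- spatial INR -------------------------------------------------------------

#' Construct a spatial implicit neural representation
#'
#' A shared multiresolution hash encoding followed by two independent
#' sine-activated MLPs (hidden width 32) for the real and imaginary image
#' channels. The sine layers use frequency factor `omega0` and the
#' layer-width-scaled uniform initialisation customary for periodic
#' activations.
#'
#' @param encoding a [hash_config()] with `input_dim = 3`.
#' @param omega0 sine frequency factor (default 30).
#' @param hidden hidden-layer width (default 32).
#' @param seed integer seed for parameter initialisation.
#' @return A `spatial_inr` holding `tables` and the two MLP parameter sets.
#' @export
spatial_inr <- function(encoding = hash_config(input_dim = 3L), omega0 = 30,
                        hidden = 32L, seed = 0L) {
  stopifnot(encoding$input_dim == 3L)
  n_in <- encoding$n_levels * encoding$features_per_entry
  with_seed(seed, {
    tables <- hash_tables_init(encoding, seed = seed + 1L)
    ru <- function(n, bound) runif(n, -bound, bound)
    structure(list(encoding = encoding, omega0 = omega0, hidden = as.integer(hidden),
                   tables = tables,
                   real = mlp_sine_init(n_in, hidden, omega0, ru),
                   imag = mlp_sine_init(n_in, hidden, omega0, ru)),
              class = "spatial_inr")
  })
}

#' Evaluate the spatial INR at a batch of coordinates
#'
#' @param coords `n x 3` matrix in `[-1, 1]^3`, or a precomputed
#'   [hash_plan()].
#' @param model a [spatial_inr()].
#' @return complex vector of length `n`.
#' @export
spatial_forward <- function(coords, model) {
  spatial_forward_cached(coords, model)$values
}

# forward pass retaining every intermediate needed for the backward pass
spatial_forward_cached <- function(coords, model) {
  plan <- if (inherits(coords, "hash_plan")) coords
          else hash_plan(as.matrix(coords), model$encoding)
  enc <- hash_encode(plan, model$tables)
  fr <- mlp_sine_forward(model$real, enc, model$omega0)
  fi <- mlp_sine_forward(model$imag, enc, model$omega0)
  list(values = complex(real = fr$y, imaginary = fi$y),
       plan = plan, fr = fr, fi = fi)
}

# backward pass: g is dL/d(values) packed as a complex vector
spatial_backward <- function(model, cache, g) {
  br <- mlp_sine_backward(model$real, cache$fr, Re(g), model$omega0)
  bi <- mlp_sine_backward(model$imag, cache$fi, Im(g), model$omega0)
  denc <- br$dx + bi$dx
  list(tables = hash_encode_backward(cache$plan, denc),
       real = br$grads, imag = bi$grads)
}

#' Render the spatial INR on a regular grid
#'
#' Queries all voxel centres (half-voxel-offset normalised coordinates) in
#' chunks; arbitrary grids are allowed, so the representation can be
#' rendered beyond its training resolution.
#'
#' @param model a [spatial_inr()].
#' @param grid_shape integer length-3 grid dimensions.
#' @param spacing voxel spacing in mm for the output volume.
#' @param chunk voxels per evaluation chunk.
#' @return A [complex_volume()].
#' @export
render_volume <- function(model, grid_shape, spacing, chunk = 65536L) {
  grid_shape <- rep_len(as.integer(grid_shape), 3L)
  coords <- grid_coords_norm(grid_shape)
  n <- nrow(coords)
  vals <- complex(n)
  for (start in seq(1L, n, by = chunk)) {
    sel <- start:min(start + chunk - 1L, n)
    vals[sel] <- spatial_forward(coords[sel, , drop = FALSE], model)
  }
  dim(vals) <- grid_shape
  complex_volume(vals, spacing)
}

# --- temporal INR ------------------------------------------------------------

#' Construct a temporal implicit neural representation
#'
#' A 1D multiresolution hash encoding of the scaled frame index feeding
#' nine parallel ReLU MLPs (two hidden layers of width 32, scalar output
#' each): one output per principal motion component and Cartesian axis.
#' In training mode the scaled frame index is perturbed with Gaussian
#' noise of standard deviation `sigma_t` (half the scaled frame interval
#' by default) so the representation stays continuous between frames.
#'
#' @param encoding a [hash_config()] with `input_dim = 1`.
#' @param n_frames number of cine frames (sets the default `sigma_t`).
#' @param hidden hidden width (default 32).
#' @param seed integer seed.
#' @return A `temporal_inr` with nine MLP parameter sets, shared `tables`,
#'   and `sigma_t`.
#' @export
temporal_inr <- function(encoding = hash_config(input_dim = 1L), n_frames,
                         hidden = 32L, seed = 0L) {
  stopifnot(encoding$input_dim == 1L)
  n_in <- encoding$n_levels * encoding$features_per_entry
  with_seed(seed, {
    tables <- hash_tables_init(encoding, seed = seed + 1L)
    ru <- function(n, bound) runif(n, -bound, bound)
    mlps <- lapply(1:9, function(i) mlp_relu_init(n_in, hidden, ru))
    structure(list(encoding = encoding, hidden = as.integer(hidden),
                   tables = tables, mlps = mlps,
                   sigma_t = 1 / n_frames),
              class = "temporal_inr")
  })
}

#' Evaluate the temporal INR
#'
#' @param frame_coords numeric vector of frame indices scaled to `[-1, 1]`.
#' @param model a [temporal_inr()].
#' @param train_mode when `TRUE`, indices are perturbed with Gaussian noise
#'   of sd `model$sigma_t` before encoding; evaluation mode is
#'   deterministic.
#' @return `n x 9` matrix of component weightings (columns ordered
#'   component-major: component 1 SI, AP, LR, component 2 SI, ...).
#' @export
temporal_forward <- function(frame_coords, model, train_mode = FALSE) {
  temporal_forward_cached(frame_coords, model, train_mode)$w
}

temporal_forward_cached <- function(frame_coords, model, train_mode = FALSE) {
  x <- as.numeric(frame_coords)
  if (any(abs(x) > 1 + 1e-9)) stop("frame coordinates must lie in [-1, 1]")
  if (train_mode) x <- pmin(pmax(x + rnorm(length(x), 0, model$sigma_t), -1), 1)
  plan <- hash_plan(matrix(x, ncol = 1L), model$encoding)
  enc <- hash_encode(plan, model$tables)
  caches <- lapply(model$mlps, function(p) mlp_relu_forward(p, enc))
  w <- vapply(caches, function(cc) cc$y, numeric(length(x)))
  if (is.null(dim(w))) w <- matrix(w, nrow = length(x))
  list(w = w, x = x, plan = plan, enc = enc, caches = caches)
}

# backward: dW is dL/dw (n x 9)
temporal_backward <- function(model, cache, dW) {
  denc <- 0
  mlp_grads <- vector("list", 9L)
  for (i in 1:9) {
    bi <- mlp_relu_backward(model$mlps[[i]], cache$caches[[i]], dW[, i])
    mlp_grads[[i]] <- bi$grads
    denc <- denc + bi$dx
  }
  list(tables = hash_encode_backward(cache$plan, denc), mlps = mlp_grads)
}

# --- Adam on nested parameter lists -----------------------------------------

tree_map <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- if (is.null(b)) lapply(seq_along(a), function(i) tree_map(f, a[[i]]))
           else lapply(seq_along(a), function(i) tree_map(f, a[[i]], b[[i]]))
    names(out) <- names(a)
    out
  } else if (is.null(b)) f(a) else f(a, b)
}

tree_sumsq <- function(a) {
  if (is.list(a)) sum(vapply(a, tree_sumsq, numeric(1))) else sum(a^2)
}

adam_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = Inf) {
  if (is.finite(clip)) {
    gn <- sqrt(tree_sumsq(grads))
    if (gn > clip) grads <- tree_map(function(g) g * (clip / gn), grads)
  }
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  upd <- tree_map(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps), state$m, state$v)
  params <- tree_map(function(p, u) p - lr * u, params, upd)
  list(params = params, state = state)
}
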