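# Multiresolution hash encoding: a geometric hierarchy of vertex grids,
# each backed by a learnable feature table addressed either densely (when
# the grid fits) or through a spatial hash, with d-linear interpolation of
# the surrounding vertex features and concatenation across levels.

HASH_PRIMES <- c(1, 2654435761, 805459861)

#' Hash-encoding configuration
#'
#' Defaults follow the standard recommended values: 16 levels, tables of
#' at most 2^19 entries, 2 features per entry, and per-level resolutions
#' growing geometrically from 16 to 10,509.
#'
#' @param n_levels number of resolution levels.
#' @param table_size_log2 log2 of the maximum entries per level.
#' @param features_per_entry feature dimensions per table entry.
#' @param coarsest_resolution,finest_resolution grid resolution endpoints.
#' @param input_dim coordinate dimensionality: 3 (spatial) or 1 (temporal).
#' @return A `hash_config`.
#' @export
hash_config <- function(n_levels = 16L, table_size_log2 = 19L,
                        features_per_entry = 2L, coarsest_resolution = 16L,
                        finest_resolution = 10509L, input_dim = 3L) {
  if (n_levels < 2L) stop("n_levels must be at least 2")
  if (finest_resolution < coarsest_resolution)
    stop("finest_resolution must not be below coarsest_resolution")
  if (!input_dim %in% c(1L, 3L)) stop("input_dim must be 1 or 3")
  structure(list(n_levels = as.integer(n_levels),
                 table_size_log2 = as.integer(table_size_log2),
                 features_per_entry = as.integer(features_per_entry),
                 coarsest_resolution = as.integer(coarsest_resolution),
                 finest_resolution = as.integer(finest_resolution),
                 input_dim = as.integer(input_dim)),
            class = "hash_config")
}

#' Per-level grid resolutions
#'
#' `N_l = floor(N_min * b^l)` with growth factor
#' `b = exp((log N_max - log N_min) / (n_levels - 1))`, so level 0 is the
#' coarsest resolution and the last level reaches the finest.
#'
#' @param config a [hash_config()].
#' @return integer vector of length `n_levels`.
#' @export
level_resolutions <- function(config) {
  L <- config$n_levels
  b <- exp((log(config$finest_resolution) - log(config$coarsest_resolution)) /
             (L - 1))
  # guard the floor against exact powers landing epsilon below an integer
  as.integer(floor(config$coarsest_resolution * b^(seq_len(L) - 1) + 1e-6))
}

# entries actually allocated at one level: dense when the full vertex grid
# fits in the table (injective indexing), hashed otherwise
level_table_entries <- function(config, resolution) {
  tmax <- 2^config$table_size_log2
  dense <- (resolution + 1)^config$input_dim <= tmax
  list(dense = dense,
       n = if (dense) (resolution + 1)^config$input_dim else tmax)
}

#' Initialise the learnable hash tables
#'
#' @param config a [hash_config()].
#' @param seed integer seed.
#' @return list of per-level matrices `(entries x features_per_entry)`
#'   initialised uniformly in `[-1e-4, 1e-4]`.
#' @export
hash_tables_init <- function(config, seed = 0L) {
  res <- level_resolutions(config)
  with_seed(seed, lapply(res, function(r) {
    n <- level_table_entries(config, r)$n
    matrix(runif(n * config$features_per_entry, -1e-4, 1e-4), n,
           config$features_per_entry)
  }))
}

# 32-bit xor-prime spatial hash, evaluated with exact double arithmetic
# and 16-bit halves (R has no unsigned 64-bit integers). v is an n x d
# matrix of 0-based vertex indices; returns 0-based table indices.
spatial_hash <- function(v, table_size_log2) {
  n <- nrow(v); d <- ncol(v)
  hi <- integer(n); lo <- integer(n)
  for (a in seq_len(d)) {
    pa <- (v[, a] * HASH_PRIMES[a]) %% 2^32
    hi <- bitwXor(hi, as.integer(pa %/% 65536))
    lo <- bitwXor(lo, as.integer(pa %% 65536))
  }
  t <- table_size_log2
  if (t <= 16L) lo %% 2^t else (hi %% 2^(t - 16L)) * 65536 + lo
}

# vertex -> 0-based table index for one level
vertex_index <- function(v, resolution, config) {
  ent <- level_table_entries(config, resolution)
  if (ent$dense) {
    idx <- v[, 1]
    if (config$input_dim == 3L)
      idx <- idx + (resolution + 1) * (v[, 2] + (resolution + 1) * v[, 3])
    idx
  } else {
    spatial_hash(v, config$table_size_log2)
  }
}

#' Precompute the interpolation plan of a coordinate batch
#'
#' For a fixed set of query coordinates (e.g. all voxel centres) the vertex
#' indices and interpolation weights per level never change; this plan
#' makes repeated encoding and its backward pass cheap during training.
#'
#' @param coords `n x input_dim` matrix in `[-1, 1]` (clamped outside).
#' @param config a [hash_config()].
#' @return A `hash_plan`.
#' @export
hash_plan <- function(coords, config) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (ncol(coords) != config$input_dim) stop("coordinate dimensionality mismatch")
  coords <- pmin(pmax(coords, -1), 1)
  res <- level_resolutions(config)
  d <- config$input_dim
  n <- nrow(coords)
  corner_bits <- as.matrix(expand.grid(rep(list(0:1), d)))
  levels <- lapply(res, function(r) {
    s <- (coords + 1) / 2 * r
    v0 <- pmin(floor(s), r - 1)
    tf <- s - v0
    nc <- 2^d
    idx <- matrix(0L, n, nc)
    w <- matrix(0, n, nc)
    for (c in seq_len(nc)) {
      b <- corner_bits[c, , drop = TRUE]
      vc <- sweep(v0, 2L, as.numeric(b), "+")
      idx[, c] <- as.integer(vertex_index(vc, r, config)) + 1L
      wc <- rep(1, n)
      for (a in seq_len(d)) wc <- wc * (if (b[a]) tf[, a] else 1 - tf[, a])
      w[, c] <- wc
    }
    list(idx = idx, w = w,
         n_entries = level_table_entries(config, r)$n)
  })
  structure(list(levels = levels, n = n, config = config), class = "hash_plan")
}

#' Evaluate the hash encoding
#'
#' Gathers the surrounding vertex features at every level, interpolates
#' them d-linearly, and concatenates across levels into a feature vector
#' of length `n_levels * features_per_entry`.
#'
#' @param coords `n x input_dim` matrix in `[-1, 1]` (clamped), or a
#'   precomputed [hash_plan()].
#' @param tables per-level feature tables from [hash_tables_init()].
#' @param config a [hash_config()] (ignored when a plan is supplied).
#' @return `n x (n_levels * features_per_entry)` feature matrix.
#' @export
hash_encode <- function(coords, tables, config = NULL) {
  plan <- if (inherits(coords, "hash_plan")) coords else {
    if (is.null(dim(coords))) coords <- matrix(coords, ncol = if (is.null(config)) 1L else config$input_dim)
    hash_plan(coords, config)
  }
  cfg <- plan$config
  Fdim <- cfg$features_per_entry
  out <- matrix(0, plan$n, cfg$n_levels * Fdim)
  for (l in seq_len(cfg$n_levels)) {
    lv <- plan$levels[[l]]
    out[, (l - 1) * Fdim + seq_len(Fdim)] <-
      cpp_hash_gather(lv$idx, lv$w, tables[[l]])
  }
  out
}

# gradient of a scalar loss w.r.t. the table entries, given dY = dL/d(features)
hash_encode_backward <- function(plan, dY) {
  cfg <- plan$config
  Fdim <- cfg$features_per_entry
  lapply(seq_len(cfg$n_levels), function(l) {
    lv <- plan$levels[[l]]
    dyl <- dY[, (l - 1) * Fdim + seq_len(Fdim), drop = FALSE]
    cpp_hash_scatter(lv$idx, lv$w, dyl, lv$n_entries)
  })
}
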