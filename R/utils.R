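`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a Gaussian FWHM to its standard deviation
#' @param fwhm full width at half maximum (mm)
#' @return standard deviation in the same units
#' @keywords internal
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Golub-Welsch Gauss-Hermite rule for the weight exp(-u^2); returned
# weights are normalized to sum to 1 so a quadrature of a Gaussian
# density is a weighted average.
gauss_hermite <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = 1))
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = e$vectors[1, ord]^2)
}

# Quadrature for an anisotropic Gaussian PSF: sigmas (3) along the unit
# world-space axes (columns of `axes`), n nodes per axis. Returns world-mm
# offsets (Q x 3) and weights (Q, summing to 1).
psf_quadrature <- function(sigmas, axes = diag(3), n = 3) {
  n <- rep(n, length.out = 3)
  gh <- lapply(n, gauss_hermite)
  pts <- lapply(1:3, function(a) sqrt(2) * gh[[a]]$nodes * sigmas[a])
  grid <- expand.grid(a = seq_len(n[1]), b = seq_len(n[2]),
                      c = seq_len(n[3]))
  offsets <- cbind(pts[[1]][grid$a], pts[[2]][grid$b],
                   pts[[3]][grid$c]) %*% t(axes)
  weights <- gh[[1]]$weights[grid$a] * gh[[2]]$weights[grid$b] *
    gh[[3]]$weights[grid$c]
  list(offsets = offsets, weights = weights / sum(weights))
}

# Normalized cross-correlation over jointly finite entries; NA when the
# overlap is degenerate (too small or zero variance).
ncc <- function(a, b) {
  keep <- is.finite(a) & is.finite(b)
  if (sum(keep) < 8) return(NA_real_)
  a <- a[keep]; b <- b[keep]
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(NA_real_)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb) * length(a) / (length(a) - 1)
}

# Evaluate an expression with a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and a stream index, kept within
# the 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 2654435761 + 97 * as.double(k)) %% 2147483647)
}

apply_affine <- function(m, pts) {
  pts <- matrix(pts, ncol = 3)
  t(m[1:3, 1:3] %*% t(pts) + m[1:3, 4])
}

voxel_spacing <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

# Affine for an axis-aligned grid: world = origin + spacing * index (0-based).
make_affine <- function(spacing, origin = c(0, 0, 0)) {
  m <- diag(4)
  diag(m)[1:3] <- spacing
  m[1:3, 4] <- origin
  m
}

affines_equal <- function(a, b, tol = 1e-4) {
  max(abs(a - b)) <= tol * max(1, max(abs(a)), max(abs(b)))
}

# World coordinates of every voxel of a grid (0-based indices), N x 3.
grid_world_coords <- function(affine, dim) {
  idx <- as.matrix(expand.grid(i = seq_len(dim[1]) - 1,
                               j = seq_len(dim[2]) - 1,
                               k = seq_len(dim[3]) - 1))
  apply_affine(affine, idx)
}
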