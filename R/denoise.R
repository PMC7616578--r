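#' Marchenko-Pastur PCA estimate for one patch matrix
#'
#' Classifies the eigenspectrum of the (uncentered) patch covariance into a
#' Marchenko-Pastur noise bulk and signal components: for a growing number
#' of candidate signal components `p`, the mean of the remaining eigenvalues
#' and the MP-edge-implied noise level `(lambda_max - lambda_min) / (4
#' sqrt(gamma))` are compared, and the first `p` at which the edge estimate
#' drops to (or below) the mean estimate defines the bulk. Ties at the
#' threshold are resolved by discarding (conservative).
#'
#' @param X patch matrix, voxels x measurements (rows >= columns)
#' @return list with `X` (denoised matrix), `sigma` (noise level estimate)
#'   and `ncomp` (retained signal components)
#' @export
mp_pca <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X)
  if (n < m) stop("precondition error: patch must have at least as many voxels as measurements")
  e <- eigen(crossprod(X) / n, symmetric = TRUE)
  lam <- e$values  # descending
  lam[lam < max(lam[1], 0) * 1e-10] <- 0  # numerically-zero eigenvalues
  p <- m - 1L
  sigsq <- 0
  for (cand in 0:(m - 1L)) {
    tail <- lam[(cand + 1L):m]
    sigsq1 <- mean(tail)
    gam <- (m - cand) / n
    sigsq2 <- (tail[1] - tail[length(tail)]) / (4 * sqrt(gam))
    if (sigsq2 <= sigsq1) {
      p <- cand
      sigsq <- sigsq1
      break
    }
    sigsq <- sigsq1
  }
  den <- if (p == 0L) {
    matrix(0, n, m)
  } else {
    V <- e$vectors[, seq_len(p), drop = FALSE]
    X %*% V %*% t(V)
  }
  list(X = den, sigma = sqrt(max(sigsq, 0)), ncomp = p)
}

#' MP-PCA patch denoising of a multi-echo dynamic series
#'
#' Slides a cubic patch over the volume; in each patch the voxels x
#' measurements matrix (measurements = flattened dynamic x echo pairs) is
#' decomposed, components within the Marchenko-Pastur noise bulk are nulled,
#' and the patch is reconstructed. Overlapping reconstructions are averaged
#' uniformly. Geometry and masks are untouched.
#'
#' @param series a `multi_echo_series` with at least 4 measurements per voxel
#' @param window_radius patch radius in voxels (patch side `2r + 1`)
#' @param stride patch-center stride in voxels (1 = every voxel)
#' @return list with `series` (denoised `multi_echo_series`) and `report`
#'   (class `denoise_report`: per-patch noise `sigma` map, retained
#'   component map, `window_radius`)
#' @export
mppca_denoise <- function(series, window_radius = 2, stride = 1) {
  nd <- n_dynamics(series); ne <- n_echoes(series)
  m <- nd * ne
  if (m < 4)
    stop(sprintf("precondition error: %d measurements per voxel; MP-PCA needs at least 4 (dynamics x echoes)", m))
  d3 <- dim(series$stacks[[1]][[1]]$values)
  w <- 2 * window_radius + 1
  npatch <- prod(pmin(w, d3))
  if (npatch < m)
    stop(sprintf("precondition error: window holds %d voxels but there are %d measurements; increase window_radius", npatch, m))
  aff <- series$stacks[[1]][[1]]$affine

  X4 <- array(0, c(d3, m))
  k <- 0
  for (d in seq_len(nd)) for (e in seq_len(ne)) {
    k <- k + 1
    X4[, , , k] <- series$stacks[[d]][[e]]$values
  }
  dim(X4) <- c(prod(d3), m)

  centers <- function(n) {
    if (n <= w) return(1L)
    cs <- unique(c(seq(1L, n - w + 1L, by = stride), n - w + 1L))
    cs
  }
  sx <- centers(d3[1]); sy <- centers(d3[2]); sz <- centers(d3[3])
  wx <- min(w, d3[1]); wy <- min(w, d3[2]); wz <- min(w, d3[3])

  acc <- matrix(0, prod(d3), m)
  cnt <- numeric(prod(d3))
  sig_acc <- numeric(prod(d3)); sig_cnt <- numeric(prod(d3))
  ncomp_acc <- numeric(prod(d3))
  lin <- array(seq_len(prod(d3)), d3)
  for (z0 in sz) for (y0 in sy) for (x0 in sx) {
    idx <- as.vector(lin[x0:(x0 + wx - 1), y0:(y0 + wy - 1),
                         z0:(z0 + wz - 1)])
    r <- mp_pca(X4[idx, , drop = FALSE])
    acc[idx, ] <- acc[idx, ] + r$X
    cnt[idx] <- cnt[idx] + 1
    sig_acc[idx] <- sig_acc[idx] + r$sigma
    sig_cnt[idx] <- sig_cnt[idx] + 1
    ncomp_acc[idx] <- ncomp_acc[idx] + r$ncomp
  }
  den <- acc / cnt
  sigma_map <- array(sig_acc / sig_cnt, d3)
  ncomp_map <- array(ncomp_acc / sig_cnt, d3)

  stacks <- vector("list", nd)
  k <- 0
  for (d in seq_len(nd)) {
    stacks[[d]] <- vector("list", ne)
    for (e in seq_len(ne)) {
      k <- k + 1
      src <- series$stacks[[d]][[e]]
      stacks[[d]][[e]] <- voxel_volume(array(den[, k], d3), src$affine,
                                       src$mask)
    }
  }
  out <- multi_echo_series(stacks, series$protocol, series$included)
  out$trace <- series$trace
  report <- structure(list(sigma = voxel_volume(sigma_map, aff),
                           ncomp = voxel_volume(ncomp_map, aff),
                           window_radius = window_radius),
                      class = "denoise_report")
  list(series = out, report = report)
}
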