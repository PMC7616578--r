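#' Slice-to-volume reconstruction
#'
#' Recovers per-slice rigid transforms from the motion-corrupted dynamic
#' stacks, solves a PSF-based super-resolution inverse problem for a
#' high-resolution isotropic volume, optionally applies a deformable
#' refinement, and can propagate the frozen transforms to any other channel
#' (notably per-dynamic T2* maps). Default settings: no intensity matching,
#' no robust slice statistics, 1.2 mm target resolution, deformable
#' control-point spacings of 12 and 5 mm, final-iteration regularization
#' weight 0.015.
#'
#' @name reconstruction
NULL

#' Reconstruction configuration
#'
#' @param resolution target isotropic voxel size in mm
#' @param cp_spacing control-point spacings (mm) of the coarse-to-fine
#'   deformable levels
#' @param lambda edge-preserving regularization weight of the
#'   super-resolution solver (relative to a unit-normalized data term)
#' @param last_iter_lambda regularization weight of the final iteration
#' @param intensity_matching per-slice intensity scaling (disabled by
#'   default; slice scale is fixed at 1)
#' @param robust_stats EM downweighting of outlier slices (disabled by
#'   default)
#' @param rounds interleaved registration / super-resolution rounds:
#'   round 1 registers each dynamic's stack to a reference-dynamic volume,
#'   round 2 re-registers each stack to the leave-one-out volume of the
#'   other dynamics, rounds 3+ refine per slice
#' @param sr_iters outer super-resolution iterations per round
#' @param cg_iters conjugate-gradient steps per outer iteration
#' @param huber_delta edge-preserving threshold, relative to the intensity
#'   scale
#' @param psf_inplane_factor in-plane PSF FWHM as a multiple of the in-plane
#'   voxel size
#' @param quad_points Gauss-Hermite nodes per PSF axis in the forward model
#' @param min_support minimum in-support voxels for a slice to be registered
#' @param exclude_ncc slices below this NCC after the final registration
#'   round are excluded
#' @param pad_mm padding of the target grid around the body bounding box
#' @param deformable run the deformable refinement stage
#' @param def_cap displacement cap of the deformable field (mm)
#' @param multi_start extra jittered optimizer starts per registration
#' @param slice_prior weight of the quadratic tether of per-slice transforms
#'   to their dynamic's stack transform (within-dynamic motion is near-rigid)
#' @param sr_damping weight of the damping of the super-resolution solve
#'   toward the PSF-weighted interpolation estimate (suppresses ringing of
#'   the ill-posed inversion)
#' @param seed seed for the optimizer start jitter
#' @return a list of class `recon_config`
#' @export
recon_config <- function(resolution = 1.2, cp_spacing = c(12, 5),
                         lambda = 0.02, last_iter_lambda = 0.015,
                         intensity_matching = FALSE, robust_stats = FALSE,
                         rounds = 3, sr_iters = 3, cg_iters = 8,
                         huber_delta = 0.05, psf_inplane_factor = 1.2,
                         quad_points = 3, min_support = 16,
                         exclude_ncc = 0.5, pad_mm = 10, deformable = TRUE,
                         def_cap = 10, multi_start = 2, slice_prior = 5e-4,
                         sr_damping = 0, seed = 1L) {
  structure(as.list(environment()), class = "recon_config")
}

# Per-slice voxel-space projection pieces for the compiled forward/adjoint:
# sample voxel = base + i*step1 + j*step2 (+ rotated quadrature offsets).
# rigids: list of 4x4 world->world matrices (slice world -> volume world).
slice_projection <- function(w2v, stack_affine, slice_idx, rigids, quad) {
  ns <- length(slice_idx)
  q <- nrow(quad$offsets)
  base <- matrix(0, ns, 3); step1 <- matrix(0, ns, 3); step2 <- matrix(0, ns, 3)
  quadvox <- matrix(0, ns, 3 * q)
  for (s in seq_len(ns)) {
    m <- w2v %*% rigids[[s]]
    h <- m %*% stack_affine
    base[s, ] <- (h %*% c(0, 0, slice_idx[s] - 1, 1))[1:3]
    step1[s, ] <- h[1:3, 1]
    step2[s, ] <- h[1:3, 2]
    quadvox[s, ] <- as.vector(t(quad$offsets %*% t(m[1:3, 1:3])))
  }
  list(base = base, step1 = step1, step2 = step2, quadvox = quadvox)
}

#' Slice acquisition model
#'
#' @param dynamic source dynamic index
#' @param slice slice index within the stack
#' @param rigid a [rigid_transform()] mapping slice world coordinates into
#'   volume world coordinates
#' @param psf_fwhm PSF FWHM in mm: in-plane x, in-plane y, through-plane
#' @param scale intensity factor; fixed at 1 while intensity matching is off
#' @return an object of class `slice_model`
#' @export
slice_model <- function(dynamic, slice, rigid = rigid_transform(),
                        psf_fwhm = c(3.75, 3.75, 3), scale = 1) {
  stopifnot(all(psf_fwhm > 0))
  structure(list(dynamic = dynamic, slice = slice, rigid = rigid,
                 psf_fwhm = psf_fwhm, scale = scale,
                 excluded = FALSE, ncc = NA_real_),
            class = "slice_model")
}

#' Simulate the acquisition of one slice from a volume
#'
#' The volume is rigidly mapped by `sm$rigid`, convolved with the
#' anisotropic Gaussian PSF and sampled on the slice grid. The operation is
#' linear in the volume, and a constant volume yields a constant slice
#' (the PSF weights are normalized). Samples whose PSF support falls mostly
#' outside the volume are NA and flagged in the `out_of_support` attribute.
#'
#' @param volume a `voxel_volume`
#' @param sm a [slice_model()]
#' @param target_grid list with `affine` (4x4 of the slice stack) and
#'   `nx`, `ny` (in-plane samples); `sm$slice` selects the slice
#' @param quad_points Gauss-Hermite nodes per PSF axis
#' @return `nx` x `ny` matrix with attribute `out_of_support`
#' @export
simulate_slice <- function(volume, sm, target_grid, quad_points = 3) {
  axes <- sweep(target_grid$affine[1:3, 1:3], 2,
                voxel_spacing(target_grid$affine), "/")
  quad <- psf_quadrature(fwhm_to_sigma(sm$psf_fwhm), axes, quad_points)
  geom <- slice_projection(solve(volume$affine), target_grid$affine,
                           sm$slice, list(rigid_matrix(sm$rigid)), quad)
  v <- cpp_psf_forward(volume$values, dim(volume$values), geom$base,
                       geom$step1, geom$step2, geom$quadvox, quad$weights,
                       target_grid$nx, target_grid$ny, NULL)
  out <- matrix(v[1, ] * sm$scale, target_grid$nx, target_grid$ny)
  attr(out, "out_of_support") <- !is.finite(out)
  out
}

# ---- internal slice-set machinery -----------------------------------------

# Assemble everything the compiled forward/adjoint needs for a set of
# slices against a target grid. values: S x P observation matrix (or NULL);
# weights: S x P or NULL; def_fields: per-dynamic deformable fields.
build_slice_set <- function(grid_affine, grid_dim, stack_affine, models,
                            quad, values = NULL, weights = NULL,
                            def_fields = NULL, nx, ny) {
  w2v <- solve(grid_affine)
  rigids <- lapply(models, function(m) rigid_matrix(m$rigid))
  ks <- vapply(models, function(m) m$slice, numeric(1))
  geom <- slice_projection(w2v, stack_affine, ks, rigids, quad)
  defvox <- NULL
  if (!is.null(def_fields)) {
    ns <- length(models); p <- nx * ny
    defvox <- matrix(0, ns * p, 3)
    ij <- as.matrix(expand.grid(i = seq_len(nx) - 1, j = seq_len(ny) - 1))
    any_def <- FALSE
    for (s in seq_len(ns)) {
      f <- def_fields[[models[[s]]$dynamic]]
      if (is.null(f)) next
      pw <- apply_affine(stack_affine,
                         cbind(ij[, 1], ij[, 2], ks[s] - 1))
      qw <- apply_affine(rigids[[s]], pw)
      u <- eval_deformable(f, qw)
      if (all(u == 0)) next
      defvox[((s - 1) * p + 1):(s * p), ] <- u %*% t(w2v[1:3, 1:3])
      any_def <- TRUE
    }
    if (!any_def) defvox <- NULL
  }
  list(geom = geom, defvox = defvox, values = values, weights = weights,
       nx = nx, ny = ny, grid_dim = grid_dim, quad = quad,
       models = models)
}

ss_forward <- function(ss, x) {
  cpp_psf_forward(x, ss$grid_dim, ss$geom$base, ss$geom$step1, ss$geom$step2,
                  ss$geom$quadvox, ss$quad$weights, ss$nx, ss$ny, ss$defvox)
}

ss_adjoint <- function(ss, val, wt = NULL, want_den = TRUE) {
  cpp_psf_adjoint(val, wt, ss$grid_dim, ss$geom$base, ss$geom$step1,
                  ss$geom$step2, ss$geom$quadvox, ss$quad$weights,
                  ss$nx, ss$ny, ss$defvox, want_den)
}

# Edge-preserving (Huber-like) IRLS weights for the finite differences of x.
huber_weights <- function(x, delta) {
  lapply(1:3, function(a) {
    d <- diff_along(x, a)
    1 / sqrt(1 + (d / delta)^2)
  })
}

diff_along <- function(x, axis) {
  d <- dim(x)
  idx1 <- lapply(d, seq_len)
  idx0 <- idx1
  idx1[[axis]] <- 2:d[axis]
  idx0[[axis]] <- 1:(d[axis] - 1)
  do.call(`[`, c(list(x), idx1)) - do.call(`[`, c(list(x), idx0))
}

# Gradient of the weighted first-difference penalty: L x with
# L = sum_axis D' diag(w) D (positive semidefinite).
laplacian_apply <- function(x, w) {
  out <- array(0, dim(x))
  d <- dim(x)
  for (a in 1:3) {
    flow <- w[[a]] * diff_along(x, a)
    idx1 <- lapply(d, seq_len); idx0 <- idx1
    idx1[[a]] <- 2:d[a]; idx0[[a]] <- 1:(d[a] - 1)
    # sequential updates with fresh reads: the two ranges overlap
    cur <- do.call(`[`, c(list(out), idx1))
    out <- do.call(`[<-`, c(list(out), idx1, list(cur + flow)))
    cur <- do.call(`[`, c(list(out), idx0))
    out <- do.call(`[<-`, c(list(out), idx0, list(cur - flow)))
  }
  out
}

# Iterative regularized least-squares inversion of the stacked slice
# forward model. Observations and weights live in ss. Returns the volume
# (array, original intensity units), the coverage mask and the per-outer-
# iteration data residual (RMS, original units).
sr_solve <- function(ss, lambda, iters, last_lambda, huber_delta, cg_iters,
                     x0 = NULL, mu = 0) {
  b <- ss$values
  w <- ss$weights
  if (is.null(w)) w <- matrix(1, nrow(b), ncol(b))
  w[!is.finite(b)] <- 0
  bz <- b; bz[!is.finite(bz)] <- 0
  # fixed NA pattern of the forward model
  pat <- ss_forward(ss, array(0, ss$grid_dim))
  w[!is.finite(pat)] <- 0
  if (all(w == 0)) stop("empty slice set: no usable samples intersect the grid")
  sc <- stats::quantile(abs(bz[w > 0]), 0.99, names = FALSE)
  if (!is.finite(sc) || sc <= 0) sc <- 1
  bn <- bz / sc

  ad <- ss_adjoint(ss, bn, w)
  den <- ad$den
  coverage <- den > 1e-6
  if (!any(coverage)) stop("empty slice set: no voxel coverage")
  dscale <- 1 / mean(den[coverage])
  # PSF-weighted scattered interpolation: both the cold start and the
  # anchor of a small damping term that suppresses the ringing of the
  # ill-posed inversion without blurring the data-supported solution
  xi <- ad$num / pmax(den, 1e-6)
  xi[!coverage] <- 0
  rhs0 <- dscale * ad$num + mu * xi
  x <- if (is.null(x0)) xi else x0 / sc

  resid_rms <- function(x) {
    r <- ss_forward(ss, x) - bn
    r[!is.finite(r)] <- 0
    sqrt(sum(w * r^2) / sum(w))
  }
  trace <- numeric(0)
  for (it in seq_len(iters)) {
    lam <- if (it == iters) last_lambda else lambda
    hw <- huber_weights(x, huber_delta)
    apply_op <- function(v) {
      pv <- ss_forward(ss, v)
      pv[!is.finite(pv)] <- 0
      dscale * ss_adjoint(ss, pv, w, want_den = FALSE)$num +
        lam * laplacian_apply(v, hw) + mu * v
    }
    # conjugate gradient on the normal equations
    r <- rhs0 - apply_op(x)
    p <- r
    rs <- sum(r * r)
    for (cg in seq_len(cg_iters)) {
      if (rs < 1e-14) break
      ap <- apply_op(p)
      alpha <- rs / sum(p * ap)
      if (!is.finite(alpha)) break
      x <- x + alpha * p
      r <- r - alpha * ap
      rs2 <- sum(r * r)
      p <- r + (rs2 / rs) * p
      rs <- rs2
    }
    trace <- c(trace, resid_rms(x) * sc)
  }
  list(volume = x * sc, coverage = coverage, residuals = trace)
}

# ---- rigid registration ----------------------------------------------------

# Optimize a rigid transform (shared by the listed slices) maximizing NCC
# between simulated and observed slices. Deterministic given `seed`.
register_rigid_ncc <- function(vol_values, vol_affine, stack_affine, ks, obs,
                               init, quad, nx, ny, center,
                               multi_start = 2, maxit = 300, seed = 1L,
                               jitter = c(2, 2, 2, 2, 2, 2),
                               prior = NULL, prior_weight = 0,
                               restarts = 3) {
  w2v <- solve(vol_affine)
  dimv <- dim(vol_values)
  ns <- length(ks)
  ones <- rep(1, ns)
  obs_fin <- is.finite(obs)
  fn <- function(par) {
    # all slices share the candidate rigid: one 4x4 composition per call
    m <- w2v %*% rigid_matrix(rigid_transform(par[1:3], par[4:6], center))
    h <- m %*% stack_affine
    base <- cbind(h[1, 4] + (ks - 1) * h[1, 3],
                  h[2, 4] + (ks - 1) * h[2, 3],
                  h[3, 4] + (ks - 1) * h[3, 3])
    step1 <- outer(ones, h[1:3, 1])
    step2 <- outer(ones, h[1:3, 2])
    qv <- outer(ones, as.vector(t(quad$offsets %*% t(m[1:3, 1:3]))))
    pred <- cpp_psf_forward(vol_values, dimv, base, step1, step2, qv,
                            quad$weights, nx, ny, NULL)
    keep <- obs_fin & is.finite(pred)
    n <- sum(keep)
    v <- if (n < 8) NA_real_ else {
      a <- pred[keep]; b <- obs[keep]
      sa <- sum(a); sb <- sum(b)
      va <- sum(a * a) - sa * sa / n
      vb <- sum(b * b) - sb * sb / n
      if (va <= 0 || vb <= 0) NA_real_ else
        (sum(a * b) - sa * sb / n) / sqrt(va * vb)
    }
    pen <- if (is.null(prior)) 0 else prior_weight * sum((par - prior)^2)
    (if (is.na(v)) 1 else -v) + pen
  }
  par0 <- c(init$rotation, init$translation)
  starts <- list(par0)
  if (multi_start > 0) {
    jit <- with_seed(derive_seed(seed, 7),
                     matrix(stats::runif(multi_start * 6, -1, 1),
                            multi_start, 6))
    for (i in seq_len(multi_start))
      starts[[i + 1]] <- par0 + jit[i, ] * jitter
  }
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, fn, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-9))
    # Nelder-Mead simplexes collapse in 6D; restart from the incumbent
    # until the objective stops improving
    for (rs in seq_len(restarts)) {
      o2 <- stats::optim(o$par, fn, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = 1e-9))
      if (o$value - o2$value < 1e-6) { o <- o2; break }
      o <- o2
    }
    if (is.null(best) || o$value < best$value) best <- o
  }
  out <- rigid_transform(best$par[1:3], best$par[4:6], center)
  pen <- if (is.null(prior)) 0 else prior_weight * sum((best$par - prior)^2)
  attr(out, "ncc") <- -(best$value - pen)
  out
}

#' Register one slice to a volume
#'
#' Finds the rigid transform maximizing normalized cross-correlation between
#' the slice simulated from the volume and the observed slice, by
#' multi-start local (Nelder-Mead) optimization seeded at `init`.
#' Deterministic given `init` and `seed`.
#'
#' @param slice list with `values` (nx x ny matrix), `affine` (stack 4x4)
#'   and `k` (slice index)
#' @param volume a `voxel_volume`
#' @param init initial [rigid_transform()]
#' @param psf_fwhm PSF FWHM (mm): in-plane x, in-plane y, through-plane
#' @param min_support minimum finite, non-constant observed voxels
#' @param multi_start extra jittered starts
#' @param seed jitter seed
#' @return a `rigid_transform` with attributes `ncc` and `excluded`
#'   (TRUE when the slice has too little support to register)
#' @export
register_slice_to_volume <- function(slice, volume, init = rigid_transform(),
                                     psf_fwhm = c(3.75, 3.75, 3),
                                     min_support = 16, multi_start = 2,
                                     seed = 1L) {
  obs <- as.vector(slice$values)
  fin <- is.finite(obs)
  if (sum(fin) < min_support || stats::sd(obs[fin]) == 0) {
    out <- init
    attr(out, "ncc") <- NA_real_
    attr(out, "excluded") <- TRUE
    return(out)
  }
  axes <- sweep(slice$affine[1:3, 1:3], 2, voxel_spacing(slice$affine), "/")
  quad <- psf_quadrature(fwhm_to_sigma(psf_fwhm), axes, 3)
  out <- register_rigid_ncc(volume$values, volume$affine, slice$affine,
                            slice$k, matrix(obs, 1), init, quad,
                            nrow(slice$values), ncol(slice$values),
                            center = init$center, multi_start = multi_start,
                            seed = seed)
  attr(out, "excluded") <- FALSE
  out
}

# ---- deformable refinement -------------------------------------------------

#' Deformable displacement field on a control-point lattice
#' @param disp 4D array (nx, ny, nz, 3) of control-point displacements (mm)
#' @param affine 4x4 lattice voxel-to-world matrix
#' @param spacing control-point spacing in mm
#' @return an object of class `deformable_field`; a zero lattice is the
#'   identity warp
#' @export
deformable_field <- function(disp, affine, spacing) {
  stopifnot(length(dim(disp)) == 4, dim(disp)[4] == 3)
  structure(list(disp = disp, affine = affine, spacing = spacing),
            class = "deformable_field")
}

#' Evaluate a deformable field at world points
#' @param field a [deformable_field()]
#' @param pts N x 3 world coordinates (mm)
#' @return N x 3 displacements (mm); zero outside the lattice
#' @export
eval_deformable <- function(field, pts) {
  if (is.null(field)) return(matrix(0, nrow(pts), 3))
  vox <- apply_affine(solve(field$affine), pts)
  d <- dim(field$disp)[1:3]
  out <- matrix(0, nrow(pts), 3)
  for (c in 1:3) {
    v <- cpp_gather(field$disp[, , , c], d, vox, FALSE)
    v[!is.finite(v)] <- 0
    out[, c] <- v
  }
  out
}

# One block-matching pass between an observed stack and its resimulation.
# Returns scattered displacement observations: world positions (volume
# frame), displacements (mm, volume frame) and confidences.
block_match <- function(obs, resim, stack_affine, rigids_by_k, search,
                        block_half, step) {
  d <- dim(obs)
  ctr <- function(n, h, st) {
    if (n < 2 * h + 1) return(integer(0))
    unique(pmin(pmax(seq(h + 1, n - h, by = st), h + 1), n - h))
  }
  cx <- ctr(d[1], block_half[1], step[1])
  cy <- ctr(d[2], block_half[2], step[2])
  cz <- ctr(d[3], block_half[3], step[3])
  pos <- NULL; disp <- NULL; conf <- NULL
  shifts <- as.matrix(expand.grid(sx = -search:search, sy = -search:search,
                                  sz = -search:search))
  sp <- voxel_spacing(stack_affine)
  sd_ref <- stats::sd(obs[is.finite(obs) & obs > 0])
  if (!is.finite(sd_ref) || sd_ref == 0) sd_ref <- stats::sd(obs[is.finite(obs)])
  shift_pen <- 0.002  # NCC units per squared voxel: prefers the zero shift
  for (k in cz) for (j in cy) for (i in cx) {
    bo <- obs[(i - block_half[1]):(i + block_half[1]),
              (j - block_half[2]):(j + block_half[2]),
              (k - block_half[3]):(k + block_half[3])]
    # only blocks with genuine structure can be matched
    if (!all(is.finite(bo)) || stats::sd(bo) < 0.1 * sd_ref) next
    best <- -Inf; braw <- -Inf; bsh <- c(0, 0, 0)
    sc <- array(NA_real_, rep(2 * search + 1, 3))
    for (s in seq_len(nrow(shifts))) {
      sh <- shifts[s, ]
      x0 <- i + sh[1]; y0 <- j + sh[2]; z0 <- k + sh[3]
      if (x0 - block_half[1] < 1 || x0 + block_half[1] > d[1] ||
          y0 - block_half[2] < 1 || y0 + block_half[2] > d[2] ||
          z0 - block_half[3] < 1 || z0 + block_half[3] > d[3]) next
      br <- resim[(x0 - block_half[1]):(x0 + block_half[1]),
                  (y0 - block_half[2]):(y0 + block_half[2]),
                  (z0 - block_half[3]):(z0 + block_half[3])]
      if (!all(is.finite(br))) next
      v <- ncc(bo, br)
      sc[sh[1] + search + 1, sh[2] + search + 1, sh[3] + search + 1] <- v
      vp <- v - shift_pen * sum(sh^2)
      if (is.finite(vp) && vp > best) { best <- vp; braw <- v; bsh <- sh }
    }
    if (!is.finite(braw) || braw < 0.6) next
    # quadratic sub-voxel refinement along each axis
    fsh <- as.numeric(bsh)
    for (a in 1:3) {
      ii <- bsh + search + 1
      if (ii[a] > 1 && ii[a] < 2 * search + 1) {
        im <- ii; im[a] <- im[a] - 1
        ip <- ii; ip[a] <- ip[a] + 1
        ym <- sc[im[1], im[2], im[3]]; y0v <- sc[ii[1], ii[2], ii[3]]
        yp <- sc[ip[1], ip[2], ip[3]]
        if (is.finite(ym) && is.finite(yp)) {
          den <- ym - 2 * y0v + yp
          if (is.finite(den) && den < -1e-12)
            fsh[a] <- fsh[a] + 0.5 * (ym - yp) / den
        }
      }
    }
    m <- rigids_by_k[[k]]
    pw <- apply_affine(m, apply_affine(stack_affine,
                                       matrix(c(i, j, k) - 1, 1)))
    # stack affine columns carry the voxel spacing, so a voxel-space shift
    # maps to world mm through the linear parts directly
    u_world <- as.numeric(m[1:3, 1:3] %*% stack_affine[1:3, 1:3] %*% fsh)
    pos <- rbind(pos, pw)
    disp <- rbind(disp, u_world)
    conf <- rbind(conf, braw)
  }
  list(pos = pos, disp = disp, conf = as.numeric(conf))
}

# Drop blocks whose displacement deviates grossly from the per-dynamic
# consensus (median +/- 4 MAD, at least 2 mm): isolated mismatches in
# low-contrast regions, not deformation.
reject_outlier_blocks <- function(bm) {
  if (is.null(bm$pos) || nrow(bm$pos) < 5) return(bm)
  keep <- rep(TRUE, nrow(bm$pos))
  for (c in 1:3) {
    med <- stats::median(bm$disp[, c])
    tol <- max(2, 4 * stats::mad(bm$disp[, c]))
    keep <- keep & abs(bm$disp[, c] - med) <= tol
  }
  list(pos = bm$pos[keep, , drop = FALSE],
       disp = bm$disp[keep, , drop = FALSE],
       conf = bm$conf[keep])
}

# Normalized Gaussian scatter of displacement observations onto a lattice.
scatter_to_lattice <- function(pos, disp, conf, grid_affine, grid_dim,
                               spacing, cap) {
  lo <- apply_affine(grid_affine, matrix(c(0, 0, 0), 1))
  hi <- apply_affine(grid_affine, matrix(grid_dim - 1, 1))
  lo2 <- pmin(lo, hi); hi2 <- pmax(lo, hi)
  nl <- pmax(2, ceiling((hi2 - lo2) / spacing) + 1)
  laff <- make_affine(rep(spacing, 3), as.numeric(lo2))
  nodes <- grid_world_coords(laff, nl)
  acc <- matrix(0, nrow(nodes), 3)
  wacc <- numeric(nrow(nodes))
  if (!is.null(pos)) {
    s2 <- spacing^2
    for (b in seq_len(nrow(pos))) {
      d2 <- rowSums(sweep(nodes, 2, pos[b, ])^2)
      wb <- conf[b] * exp(-d2 / (2 * s2))
      acc <- acc + outer(wb, disp[b, ])
      wacc <- wacc + wb
    }
  }
  u <- acc / pmax(wacc, 1e-9)
  u[wacc < 0.5, ] <- 0  # nodes without real block support stay at identity
  nrm <- sqrt(rowSums(u^2))
  over <- nrm > cap
  if (any(over)) u[over, ] <- u[over, ] * (cap / nrm[over])
  disp4 <- array(0, c(nl, 3))
  for (c in 1:3) disp4[, , , c] <- array(u[, c], nl)
  deformable_field(disp4, laff, spacing)
}

#' Deformable refinement of a rigid reconstruction
#'
#' Coarse-to-fine estimation of a smooth per-dynamic deformation: at each
#' control-point level the observed stacks are compared with their
#' resimulation from the current volume by local block matching, and the
#' scattered displacements are smoothed onto the control-point lattice
#' (confidence-weighted normalized convolution). Rigid-only inputs yield
#' near-zero fields.
#'
#' @param volume a `voxel_volume` (current reconstruction)
#' @param stacks list (by dynamic index) of observed 3D arrays
#' @param models list of `slice_model`s (as in a `recon_result`)
#' @param stack_affine 4x4 affine of the observed stacks
#' @param cp_spacing control-point spacings in mm, coarse to fine
#' @param cap displacement cap in mm
#' @param quad PSF quadrature (as used by the reconstruction)
#' @return list of [deformable_field()] indexed by dynamic
#' @export
deformable_refine <- function(volume, stacks, models, stack_affine,
                              cp_spacing = c(12, 5), cap = 10, quad = NULL) {
  if (is.null(quad)) {
    sp <- voxel_spacing(stack_affine)
    quad <- psf_quadrature(fwhm_to_sigma(c(1.2 * sp[1], 1.2 * sp[2], sp[3])),
                           diag(3), 3)
  }
  dyn_ids <- sort(unique(vapply(models, function(m) m$dynamic, numeric(1))))
  grid_dim <- dim(volume$values)
  fields <- vector("list", max(dyn_ids))
  sp <- voxel_spacing(stack_affine)
  for (d in dyn_ids) {
    dm <- Filter(function(m) m$dynamic == d && !m$excluded, models)
    if (length(dm) == 0) next
    field <- NULL
    for (li in seq_along(cp_spacing)) {
      spc <- cp_spacing[li]
      df <- NULL
      if (!is.null(field)) {
        df <- vector("list", d)
        df[[d]] <- field
      }
      ss <- build_slice_set(volume$affine, grid_dim, stack_affine, dm, quad,
                            def_fields = df,
                            nx = dim(stacks[[d]])[1],
                            ny = dim(stacks[[d]])[2])
      pred <- ss_forward(ss, volume$values)
      resim <- array(NA_real_, dim(stacks[[d]]))
      for (s in seq_along(dm))
        resim[, , dm[[s]]$slice] <- matrix(pred[s, ], dim(resim)[1],
                                           dim(resim)[2])
      rigids_by_k <- vector("list", dim(stacks[[d]])[3])
      for (s in seq_along(dm))
        rigids_by_k[[dm[[s]]$slice]] <- rigid_matrix(dm[[s]]$rigid)
      for (k in seq_along(rigids_by_k))
        if (is.null(rigids_by_k[[k]])) rigids_by_k[[k]] <- diag(4)
      bh <- pmax(2, round(spc / 2 / sp))
      st <- pmax(1, round(spc / sp))
      srch <- if (li == 1) 2L else 1L
      bm <- block_match(stacks[[d]], resim, stack_affine, rigids_by_k,
                        srch, bh, st)
      bm <- reject_outlier_blocks(bm)
      inc <- scatter_to_lattice(bm$pos, bm$disp, bm$conf, volume$affine,
                                grid_dim, spc, cap)
      field <- if (is.null(field)) inc else add_fields(field, inc, cap)
    }
    # accept the field only if it actually reduces this dynamic's residual;
    # rigid-consistent dynamics keep the identity (zero) field
    resid_with <- function(f) {
      df <- NULL
      if (!is.null(f)) { df <- vector("list", d); df[[d]] <- f }
      ss <- build_slice_set(volume$affine, grid_dim, stack_affine, dm, quad,
                            def_fields = df, nx = dim(stacks[[d]])[1],
                            ny = dim(stacks[[d]])[2])
      pred <- ss_forward(ss, volume$values)
      obsm <- t(vapply(dm, function(m) as.vector(stacks[[d]][, , m$slice]),
                       numeric(dim(stacks[[d]])[1] * dim(stacks[[d]])[2])))
      ok <- is.finite(pred) & is.finite(obsm)
      sqrt(mean((pred[ok] - obsm[ok])^2))
    }
    if (resid_with(field) > 0.98 * resid_with(NULL)) {
      field$disp[] <- 0
    }
    fields[[d]] <- field
  }
  fields
}

# Combine two lattice fields: resample both on the finer lattice and add.
add_fields <- function(a, b, cap) {
  fine <- if (a$spacing <= b$spacing) a else b
  nodes <- grid_world_coords(fine$affine, dim(fine$disp)[1:3])
  u <- eval_deformable(a, nodes) + eval_deformable(b, nodes)
  nrm <- sqrt(rowSums(u^2))
  over <- nrm > cap
  if (any(over)) u[over, ] <- u[over, ] * (cap / nrm[over])
  disp <- array(0, dim(fine$disp))
  for (c in 1:3) disp[, , , c] <- array(u[, c], dim(fine$disp)[1:3])
  deformable_field(disp, fine$affine, fine$spacing)
}

# ---- robust slice statistics (off by default) ------------------------------

# EM over slice RMS residuals: two-component (inlier Gaussian around the
# median, uniform outlier) posterior inlier probabilities.
robust_slice_weights <- function(resid_rms) {
  r <- resid_rms
  ok <- is.finite(r)
  w <- rep(1, length(r))
  if (sum(ok) < 4) return(w)
  mu <- stats::median(r[ok]); s <- stats::mad(r[ok]) + 1e-9
  pi_in <- 0.9
  for (it in 1:20) {
    din <- stats::dnorm(r[ok], mu, s)
    dout <- 1 / (max(r[ok]) - min(r[ok]) + 1e-9)
    post <- pi_in * din / (pi_in * din + (1 - pi_in) * dout)
    mu <- sum(post * r[ok]) / sum(post)
    s <- sqrt(sum(post * (r[ok] - mu)^2) / sum(post)) + 1e-9
    pi_in <- mean(post)
  }
  w[ok] <- post
  w
}

# ---- orchestration ---------------------------------------------------------

#' Reconstruct a high-resolution volume from a dynamic series
#'
#' Orchestrates the slice-to-volume pipeline on one echo of the series:
#' target-grid initialization from the voxelwise median stack, interleaved
#' registration / super-resolution rounds (stack-level rigid first, then
#' per-slice), an optional deformable refinement, and a final
#' super-resolution solve at the final-iteration regularization weight.
#' Intensity matching and robust slice-outlier statistics are off by
#' default.
#'
#' @param series a `multi_echo_series`
#' @param echo echo index used for registration and reconstruction
#' @param params a [recon_config()]
#' @return an object of class `recon_result`: `volume` (1.2 mm
#'   `voxel_volume` with coverage mask), `slice_models`, `deformable`
#'   (per-dynamic fields), `convergence` (per-iteration data residuals),
#'   `excluded_slices`, plus the internals needed by [propagate_channel()]
#' @export
reconstruct <- function(series, echo = 2, params = recon_config()) {
  stopifnot(length(series$included) >= 1)
  echo <- min(echo, n_echoes(series))
  dyns <- series$included
  stack_affine <- series$stacks[[1]][[1]]$affine
  d3 <- dim(series$stacks[[1]][[1]]$values)
  nx <- d3[1]; ny <- d3[2]; nz <- d3[3]
  stacks <- lapply(seq_len(n_dynamics(series)), function(d)
    if (d %in% dyns) series$stacks[[d]][[echo]]$values else NULL)

  arrs <- vapply(dyns, function(d) stacks[[d]], stacks[[dyns[1]]])
  med <- if (length(dyns) > 1) apply(arrs, 1:3, stats::median) else
    arrs[, , , 1]

  # target grid: bounding box of the median-stack body mask, padded
  thr <- 0.1 * stats::quantile(med[med > 0], 0.99, names = FALSE)
  if (!is.finite(thr) || thr <= 0) thr <- 0
  bm <- med > thr
  if (!any(bm)) bm[] <- TRUE
  idx <- which(bm, arr.ind = TRUE)
  wc <- apply_affine(stack_affine, idx - 1)
  lo <- apply(wc, 2, min) - params$pad_mm
  hi <- apply(wc, 2, max) + params$pad_mm
  res <- params$resolution
  gdim <- pmax(8, ceiling((hi - lo) / res) + 1)
  gaff <- make_affine(rep(res, 3), lo)
  center <- as.numeric(lo + (gdim - 1) / 2 * res)

  sp <- voxel_spacing(stack_affine)
  psf_fwhm <- c(params$psf_inplane_factor * sp[1],
                params$psf_inplane_factor * sp[2],
                series$protocol$slice_thickness %||% sp[3])
  # super-resolution quadrature: the through-plane PSF carries the slice
  # profile; in-plane blur is at the sampling scale and is left to the
  # interpolation model
  axes <- sweep(stack_affine[1:3, 1:3], 2, sp, "/")
  quad <- psf_quadrature(fwhm_to_sigma(psf_fwhm), axes,
                         c(3, 3, params$quad_points))

  # registration uses a delta PSF on a decimated in-plane grid: the target
  # volume is already smooth, so the quadrature mainly costs time there
  reg_stride <- 2L
  ix <- seq(1, nx, by = reg_stride)
  iy <- seq(1, ny, by = reg_stride)
  dec_affine <- stack_affine %*% diag(c(reg_stride, reg_stride, 1, 1))
  quad1 <- list(offsets = matrix(0, 1, 3), weights = 1)

  # model only slices carrying anatomy (plus one margin slice each side);
  # background-only slices constrain nothing inside the body bounding box
  models <- list()
  for (d in dyns) {
    has_sig <- vapply(seq_len(nz), function(k)
      any(stacks[[d]][, , k] > thr), logical(1))
    keep <- has_sig | c(has_sig[-1], FALSE) | c(FALSE, has_sig[-nz])
    if (!any(keep)) keep[] <- TRUE
    for (k in which(keep)) {
      m <- slice_model(d, k, rigid_transform(center = center), psf_fwhm)
      models[[length(models) + 1]] <- m
    }
  }

  obs_values <- function(models) {
    t(vapply(models, function(m)
      as.vector(stacks[[m$dynamic]][, , m$slice]), numeric(nx * ny)))
  }
  weights_of <- function(models) {
    w <- matrix(1, length(models), nx * ny)
    ex <- vapply(models, function(m) m$excluded, logical(1))
    w[ex, ] <- 0
    w
  }

  # initial target: the reference dynamic alone (a single stack is
  # rigid-consistent, unlike a consensus of unaligned stacks), chosen as
  # the dynamic closest to the voxelwise median
  ref_scores <- vapply(dyns, function(d) ncc(stacks[[d]], med), numeric(1))
  ref_dyn <- dyns[which.max(ifelse(is.finite(ref_scores), ref_scores, -Inf))]
  vals <- obs_values(models)
  ref_models <- Filter(function(m) m$dynamic == ref_dyn, models)
  ss0 <- build_slice_set(gaff, gdim, stack_affine, ref_models, quad,
                         values = obs_values(ref_models),
                         nx = nx, ny = ny)
  sr <- sr_solve(ss0, params$lambda, 1, params$lambda, params$huber_delta,
                 params$cg_iters, mu = params$sr_damping)
  x <- sr$volume
  convergence <- sr$residuals
  def_fields <- NULL

  for (r in seq_len(params$rounds)) {
    vol <- voxel_volume(x, gaff)
    if (r == 1) {
      # stack-level rigid initialization per dynamic, body slices only
      for (d in dyns) {
        ks <- which(vapply(seq_len(nz), function(k)
          any(stacks[[d]][, , k] > thr), logical(1)))
        if (length(ks) == 0) ks <- seq_len(nz)
        obs <- t(vapply(ks, function(k)
          as.vector(stacks[[d]][ix, iy, k]), numeric(length(ix) * length(iy))))
        tf <- register_rigid_ncc(x, gaff, dec_affine, ks, obs,
                                 rigid_transform(center = center), quad1,
                                 length(ix), length(iy), center,
                                 multi_start = params$multi_start,
                                 maxit = 400,
                                 seed = derive_seed(params$seed, 10 + d))
        for (i in seq_along(models))
          if (models[[i]]$dynamic == d) {
            models[[i]]$rigid <- tf
            models[[i]]$ncc <- attr(tf, "ncc")
          }
      }
    } else if (r == 2) {
      # leave-one-out stack re-registration: each dynamic registers to the
      # volume rebuilt from the other dynamics only, removing the
      # self-consistency bias of registering to one's own data
      for (d in dyns) {
        others <- Filter(function(m) m$dynamic != d && !m$excluded, models)
        if (length(others) == 0) next
        sso <- build_slice_set(gaff, gdim, stack_affine, others, quad,
                               values = obs_values(others),
                               nx = nx, ny = ny)
        sro <- sr_solve(sso, params$lambda, 2, params$lambda,
                        params$huber_delta, params$cg_iters,
                        mu = params$sr_damping)
        ks <- which(vapply(seq_len(nz), function(k)
          any(stacks[[d]][, , k] > thr), logical(1)))
        if (length(ks) == 0) ks <- seq_len(nz)
        obs <- t(vapply(ks, function(k)
          as.vector(stacks[[d]][ix, iy, k]), numeric(length(ix) * length(iy))))
        init <- mean_rigid(Filter(function(m) m$dynamic == d, models))
        tf <- register_rigid_ncc(sro$volume, gaff, dec_affine, ks, obs,
                                 init, quad1, length(ix), length(iy), center,
                                 multi_start = 0, maxit = 400,
                                 seed = derive_seed(params$seed, 50 + d))
        for (i in seq_along(models))
          if (models[[i]]$dynamic == d) {
            models[[i]]$rigid <- tf
            models[[i]]$ncc <- attr(tf, "ncc")
          }
      }
    } else {
      # per-slice refinement, tethered to the dynamic's stack transform:
      # within-dynamic motion is (near-)rigid, so slices may deviate only
      # where the data supports it
      stack_tf <- lapply(seq_len(n_dynamics(series)), function(d) {
        dm <- Filter(function(m) m$dynamic == d, models)
        if (length(dm)) mean_rigid(dm) else NULL
      })
      for (i in seq_along(models)) {
        m <- models[[i]]
        obs <- stacks[[m$dynamic]][ix, iy, m$slice]
        fin <- is.finite(obs)
        if (sum(fin) < params$min_support ||
            stats::sd(obs[fin]) == 0 || max(obs[fin]) <= thr) {
          models[[i]]$ncc <- NA_real_
          next
        }
        st <- stack_tf[[m$dynamic]]
        tf <- register_rigid_ncc(x, gaff, dec_affine, m$slice,
                                 matrix(as.vector(obs), 1), quad1,
                                 init = m$rigid,
                                 nx = length(ix), ny = length(iy),
                                 center = center,
                                 multi_start = if (r == 3) 1 else 0,
                                 maxit = 120,
                                 seed = derive_seed(params$seed, 1000 + i),
                                 jitter = rep(1, 6),
                                 prior = c(st$rotation, st$translation),
                                 prior_weight = params$slice_prior,
                                 restarts = 1)
        models[[i]]$rigid <- tf
        models[[i]]$ncc <- attr(tf, "ncc")
      }
    }
    if (r == params$rounds) {
      # final exclusion by NCC, never emptying the slice set
      nccs <- vapply(models, function(m) m$ncc, numeric(1))
      bad <- is.finite(nccs) & nccs < params$exclude_ncc
      if (!all(bad[is.finite(nccs)]))
        for (i in which(bad)) models[[i]]$excluded <- TRUE
      if (params$deformable)
        def_fields <- deformable_refine(voxel_volume(x, gaff), stacks,
                                        models, stack_affine,
                                        params$cp_spacing, params$def_cap,
                                        quad)
    }
    w <- weights_of(models)
    svals <- vals
    if ((params$robust_stats || params$intensity_matching) && r > 1) {
      pred <- ss_forward(build_slice_set(gaff, gdim, stack_affine, models,
                                         quad, nx = nx, ny = ny), x)
      if (params$intensity_matching) {
        # per-slice multiplicative scale: obs ~ scale * simulated
        for (i in seq_along(models)) {
          num <- pred[i, ]; ob <- vals[i, ]
          keep <- is.finite(num) & is.finite(ob) & num > thr
          sc_i <- if (sum(keep) >= 8) stats::median(ob[keep] / num[keep]) else 1
          if (!is.finite(sc_i) || sc_i <= 0) sc_i <- 1
          models[[i]]$scale <- sc_i
        }
        svals <- vals / vapply(models, function(m) m$scale, numeric(1))
      }
      if (params$robust_stats) {
        rr <- vals - pred
        rms <- sqrt(rowMeans(rr^2, na.rm = TRUE))
        w <- w * robust_slice_weights(rms)
      }
    }
    ss <- build_slice_set(gaff, gdim, stack_affine, models, quad,
                          values = svals, weights = w,
                          def_fields = def_fields, nx = nx, ny = ny)
    last <- if (r == params$rounds) params$last_iter_lambda else params$lambda
    # The final solve is cold-started with the same iteration budget used by
    # propagate_channel: early-stopped CG is part of the regularization, and
    # a fixed budget makes channel propagation reproduce the registration
    # channel exactly.
    sr <- sr_solve(ss, params$lambda, params$sr_iters, last,
                   params$huber_delta, params$cg_iters,
                   x0 = if (r == params$rounds) NULL else x,
                   mu = params$sr_damping)
    x <- sr$volume
    convergence <- c(convergence, sr$residuals)
  }

  excluded <- which(vapply(models, function(m) m$excluded, logical(1)))
  structure(list(
    volume = voxel_volume(x, gaff, mask = sr$coverage),
    slice_models = models,
    deformable = def_fields,
    convergence = convergence,
    excluded_slices = excluded,
    grid = list(affine = gaff, dim = gdim),
    stack_affine = stack_affine,
    stack_dim = d3,
    quad = quad,
    echo = echo,
    included = dyns,
    params = params),
    class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf(
    "recon_result: %s voxels at %.2g mm, %d slices (%d excluded), final residual %.4g\n",
    paste(dim(x$volume$values), collapse = "x"),
    voxel_spacing(x$volume$affine)[1], length(x$slice_models),
    length(x$excluded_slices), utils::tail(x$convergence, 1)))
  invisible(x)
}

#' Propagate a channel through frozen reconstruction transforms
#'
#' Applies the slice transforms and deformable fields recovered by
#' [reconstruct()] to another channel of the same acquisition (e.g. the
#' per-dynamic T2* maps) and solves the same super-resolution inversion
#' without re-estimating any transform. Non-finite channel voxels (failed
#' T2* fits) are excluded from the data term; a dynamic whose channel is
#' entirely invalid drops out of the data term.
#'
#' @param recon a `recon_result`
#' @param channel_stacks list of `voxel_volume` (one per included dynamic,
#'   in the order of `recon$included`), geometrically identical to the
#'   reconstruction input stacks
#' @return a `voxel_volume` on the reconstruction grid (coverage mask set)
#' @export
propagate_channel <- function(recon, channel_stacks) {
  dyns <- recon$included
  if (length(channel_stacks) != length(dyns))
    stop(sprintf("expected %d channel stacks (one per included dynamic)",
                 length(dyns)))
  ch <- vector("list", max(dyns))
  for (i in seq_along(dyns)) {
    v <- channel_stacks[[i]]
    if (!all(dim(v$values) == recon$stack_dim) ||
        !affines_equal(v$affine, recon$stack_affine))
      stop(sprintf("geometry error: channel stack for dynamic %d does not match the reconstruction inputs", dyns[i]))
    ch[[dyns[i]]] <- v$values
  }
  models <- recon$slice_models
  nx <- recon$stack_dim[1]; ny <- recon$stack_dim[2]
  vals <- t(vapply(models, function(m)
    as.vector(ch[[m$dynamic]][, , m$slice]), numeric(nx * ny)))
  w <- matrix(1, length(models), nx * ny)
  w[!is.finite(vals)] <- 0
  ex <- vapply(models, function(m) m$excluded, logical(1))
  w[ex, ] <- 0
  ss <- build_slice_set(recon$grid$affine, recon$grid$dim,
                        recon$stack_affine, models, recon$quad,
                        values = vals, weights = w,
                        def_fields = recon$deformable, nx = nx, ny = ny)
  p <- recon$params
  sr <- sr_solve(ss, p$lambda, p$sr_iters, p$last_iter_lambda,
                 p$huber_delta, p$cg_iters, mu = p$sr_damping %||% 0)
  voxel_volume(sr$volume, recon$grid$affine, mask = sr$coverage)
}

#' Resample a volume onto a target grid
#'
#' @param vol a `voxel_volume`
#' @param target_affine 4x4 affine of the target grid
#' @param target_dim target grid dimensions
#' @param transform optional 4x4 world-space matrix mapping target world
#'   coordinates into the source volume's world (identity by default)
#' @param nearest nearest-neighbor instead of trilinear interpolation
#' @return a `voxel_volume` on the target grid (NA outside the source)
#' @export
resample_volume <- function(vol, target_affine, target_dim,
                            transform = diag(4), nearest = FALSE) {
  pts <- grid_world_coords(target_affine, target_dim)
  src <- apply_affine(solve(vol$affine) %*% transform, pts)
  v <- cpp_gather(vol$values, dim(vol$values), src, nearest)
  voxel_volume(array(v, target_dim), target_affine)
}
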