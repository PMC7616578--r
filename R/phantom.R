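#' Gestational-age model of organ T2*
#'
#' A per-organ linear model of mean T2* against gestational age (GA):
#' `T2*(ga) = intercept + slope * (ga - 17)` plus a subject-level Gaussian
#' deviation with standard deviation `noise_sd`. The default numbers are
#' configuration chosen for the low-field (0.55T) regime — lung T2* of the
#' order of 200-300 ms — with trend directions increasing over gestation in
#' the lungs and liver and decreasing in the kidney parenchyma and pelvis;
#' they are not fitted normative curves.
#'
#' @param table data.frame with columns `organ`, `intercept` (ms at GA 17),
#'   `slope` (ms/week), `noise_sd` (ms across subjects), `amplitude`
#'   (proton-density-weighted signal, arbitrary units)
#' @return an object of class `organ_t2s_model`
#' @export
organ_t2s_model <- function(table = default_organ_table()) {
  need <- c("organ", "intercept", "slope", "noise_sd", "amplitude")
  stopifnot(all(need %in% names(table)))
  stopifnot(setequal(table$organ, names(organ_labels())))
  dirs <- stats::setNames(table$slope, table$organ)
  if (!(dirs[["lungs"]] > 0 && dirs[["liver"]] > 0 &&
        dirs[["kidney_parenchyma"]] < 0 && dirs[["kidney_pelvis"]] < 0))
    stop("organ_t2s_model: slope signs must be positive for lungs/liver and negative for kidney parenchyma/pelvis")
  structure(list(table = table), class = "organ_t2s_model")
}

#' Default organ T2* growth table
#' @return data.frame used by [organ_t2s_model()]
#' @export
default_organ_table <- function() {
  data.frame(
    organ = c("lungs", "thymus", "gall_bladder", "kidney_pelvis",
              "kidney_parenchyma", "spleen", "adrenal_gland", "stomach",
              "bladder", "liver"),
    intercept = c(180, 150, 250, 260, 180, 140, 160, 220, 280, 120),
    slope     = c(5.0, 0.3, -2.0, -3.0, -2.5, 1.0, -1.0, -0.2, -0.2, 2.5),
    noise_sd  = c(15, 12, 20, 20, 10, 10, 12, 18, 20, 10),
    amplitude = c(95, 100, 110, 105, 100, 95, 100, 110, 115, 90),
    stringsAsFactors = FALSE)
}

# Organ geometry in body-normalized coordinates. Each organ is one or two
# ellipsoids (center, radii as fractions of the body semi-axes); organs are
# painted in this order and never overwrite an already-labeled voxel, so
# the final label map is disjoint by construction.
organ_geometry <- function() {
  g <- list(
    kidney_pelvis     = list(c( 0.18, -0.28, -0.22, 0.06, 0.06, 0.10),
                             c(-0.18, -0.28, -0.22, 0.06, 0.06, 0.10)),
    kidney_parenchyma = list(c( 0.28, -0.28, -0.22, 0.13, 0.12, 0.20),
                             c(-0.28, -0.28, -0.22, 0.13, 0.12, 0.20)),
    adrenal_gland     = list(c( 0.28, -0.28,  0.06, 0.08, 0.07, 0.06),
                             c(-0.28, -0.28,  0.06, 0.08, 0.07, 0.06)),
    gall_bladder      = list(c( 0.12,  0.25,  0.05, 0.08, 0.07, 0.11)),
    thymus            = list(c( 0.00,  0.15,  0.68, 0.13, 0.10, 0.09)),
    lungs             = list(c( 0.34,  0.00,  0.42, 0.26, 0.30, 0.27),
                             c(-0.34,  0.00,  0.42, 0.26, 0.30, 0.27)),
    stomach           = list(c(-0.30,  0.20,  0.02, 0.18, 0.16, 0.16)),
    spleen            = list(c(-0.45, -0.12,  0.12, 0.12, 0.10, 0.14)),
    bladder           = list(c( 0.00,  0.12, -0.62, 0.16, 0.14, 0.14)),
    liver             = list(c( 0.24,  0.06,  0.06, 0.34, 0.32, 0.26)))
  g
}

#' Digital fetus phantom
#'
#' Builds a piecewise-constant digital phantom: a uniform body envelope
#' containing ten non-overlapping ellipsoidal organs, with organ volumes
#' scaling monotonically with gestational age and organ T2* drawn from the
#' GA-linear model plus seeded subject-level noise. The phantom is exact
#' ground truth for fit- and reconstruction-recovery tests.
#'
#' @param ga gestational age in weeks (17-40)
#' @param model an [organ_t2s_model()]
#' @param seed integer seed for the subject-level T2* draws
#' @param grid_size voxels per axis of the (isotropic) phantom grid
#' @param voxel_mm phantom voxel size in mm
#' @param envelope_t2s,envelope_amplitude body-envelope tissue values
#' @return an object of class `digital_phantom` with fields `labels`
#'   (`label_map`), `t2star`, `amplitude` (`voxel_volume`, mask = body),
#'   `ga_weeks`, `organ_t2s` (named ms values actually used), `seed`
#' @export
make_phantom <- function(ga, model = organ_t2s_model(), seed = 1L,
                         grid_size = 64L, voxel_mm = 2,
                         envelope_t2s = 60, envelope_amplitude = 85) {
  if (!is.finite(ga) || ga < 17 || ga > 40)
    stop("domain error: ga must lie in [17, 40] weeks")
  tab <- model$table
  draws <- with_seed(derive_seed(seed, 1),
                     stats::rnorm(nrow(tab), 0, tab$noise_sd))
  t2s <- pmax(tab$intercept + tab$slope * (ga - 17) + draws, 10)
  names(t2s) <- tab$organ
  amp <- stats::setNames(tab$amplitude, tab$organ)

  n <- as.integer(grid_size)
  fov <- n * voxel_mm
  aff <- make_affine(rep(voxel_mm, 3), rep(-(n - 1) / 2 * voxel_mm, 3))
  cw <- (seq_len(n) - 1 - (n - 1) / 2) * voxel_mm  # world mm, centered

  # body semi-axes (mm): largest subject fills the grid with a margin
  scale_ga <- 0.55 + 0.45 * (ga - 17) / 23
  body <- c(0.375, 0.3125, 0.453125) * fov * scale_ga

  xn <- outer(cw / body[1], rep(1, n))
  x2 <- array(rep(xn^2, n), c(n, n, n))
  y2 <- array(rep(outer(rep(1, n), (cw / body[2])^2), n), c(n, n, n))
  z2 <- aperm(array(rep(outer(rep(1, n), (cw / body[3])^2), n), c(n, n, n)),
              c(1, 3, 2))
  inside_body <- (x2 + y2 + z2) <= 1

  labels <- array(0L, c(n, n, n))
  geom <- organ_geometry()
  ids <- organ_labels()
  for (organ in names(geom)) {
    for (ell in geom[[organ]]) {
      ctr <- ell[1:3] * body
      rad <- ell[4:6] * body
      ex <- outer(((cw - ctr[1]) / rad[1])^2, rep(1, n))
      ey <- outer(rep(1, n), ((cw - ctr[2]) / rad[2])^2)
      d2 <- array(rep(ex + ey, n), c(n, n, n)) +
        aperm(array(rep(outer(rep(1, n), ((cw - ctr[3]) / rad[3])^2), n),
                    c(n, n, n)), c(1, 3, 2))
      sel <- d2 <= 1 & inside_body & labels == 0L
      labels[sel] <- ids[[organ]]
    }
  }

  t2map <- array(0, c(n, n, n))
  ampmap <- array(0, c(n, n, n))
  t2map[inside_body] <- envelope_t2s
  ampmap[inside_body] <- envelope_amplitude
  for (organ in names(ids)) {
    sel <- labels == ids[[organ]]
    t2map[sel] <- t2s[[organ]]
    ampmap[sel] <- amp[[organ]]
  }

  structure(list(labels = label_map(labels, aff),
                 t2star = voxel_volume(t2map, aff, mask = inside_body),
                 amplitude = voxel_volume(ampmap, aff, mask = inside_body),
                 ga_weeks = ga,
                 organ_t2s = t2s,
                 organ_amplitude = amp,
                 seed = as.integer(seed)),
            class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  cat(sprintf("digital_phantom: GA %.1f weeks, %s grid, lung T2* %.1f ms\n",
              x$ga_weeks, paste(dim(x$labels$labels), collapse = "x"),
              x$organ_t2s[["lungs"]]))
  invisible(x)
}

#' Per-dynamic rigid motion trace
#'
#' @param rotations n x 3 matrix of rotations (degrees, extrinsic x-y-z
#'   Euler convention, see [rigid_transform()])
#' @param translations n x 3 matrix of translations (mm)
#' @param slice_jitter optional list (per dynamic) of per-slice
#'   `rigid_transform` perturbations
#' @return an object of class `motion_trace`
#' @export
motion_trace <- function(rotations, translations, slice_jitter = NULL) {
  rotations <- matrix(rotations, ncol = 3)
  translations <- matrix(translations, ncol = 3)
  stopifnot(nrow(rotations) == nrow(translations),
            all(is.finite(rotations)), all(is.finite(translations)))
  structure(list(rotations = rotations, translations = translations,
                 slice_jitter = slice_jitter),
            class = "motion_trace")
}

#' Identity motion trace
#' @param n_dynamics number of dynamics
#' @return a `motion_trace` with all parameters zero
#' @export
identity_trace <- function(n_dynamics) {
  motion_trace(matrix(0, n_dynamics, 3), matrix(0, n_dynamics, 3))
}

#' Smooth random-walk rigid motion trace
#'
#' A seeded random walk starting at the identity (the first dynamic is the
#' reference), rescaled so rotations stay within `max_rotation` degrees and
#' translations within `max_translation` mm.
#'
#' @param n_dynamics number of dynamics
#' @param max_rotation rotation cap in degrees
#' @param max_translation translation cap in mm
#' @param seed integer seed
#' @return a `motion_trace`
#' @export
random_motion_trace <- function(n_dynamics, max_rotation = 10,
                                max_translation = 10, seed = 1L) {
  stopifnot(n_dynamics >= 1)
  with_seed(derive_seed(seed, 2), {
    walk <- function(cap) {
      if (n_dynamics == 1) return(matrix(0, 1, 3))
      steps <- matrix(stats::rnorm((n_dynamics - 1) * 3), n_dynamics - 1, 3)
      w <- rbind(0, apply(steps, 2, cumsum))
      m <- max(abs(w))
      if (m > 0) w * (cap / m) * stats::runif(1, 0.6, 1) else w
    }
    motion_trace(walk(max_rotation), walk(max_translation))
  })
}

n_trace <- function(trace) nrow(trace$rotations)

trace_transform <- function(trace, d, center = c(0, 0, 0)) {
  rigid_transform(trace$rotations[d, ], trace$translations[d, ], center)
}

#' Simulate the multi-echo dynamic acquisition of a phantom
#'
#' The forward model: for each dynamic the phantom is rigidly moved by the
#' motion trace, the signal `S(x, TE) = amplitude(x) * exp(-TE / T2*(x))` is
#' integrated through an anisotropic Gaussian PSF (through-plane FWHM equal
#' to the slice thickness, in-plane FWHM 1.2x the in-plane voxel size),
#' sampled on the low-resolution grid, and Rician noise of scale
#' `noise_sigma` is applied. With `noise_sigma = 0` and an identity trace
#' this is the pure forward model.
#'
#' @param ph a `digital_phantom`
#' @param protocol an [acquisition_protocol()]
#' @param motion a `motion_trace` (NULL = identity for `protocol$n_dynamics`)
#' @param noise_sigma Rician noise scale, in amplitude units (>= 0)
#' @param seed integer seed for the noise
#' @param quad_points Gauss-Hermite nodes per PSF axis
#' @return a `multi_echo_series`; the simulated trace is kept in field
#'   `trace` for validation against ground truth
#' @export
simulate_acquisition <- function(ph, protocol = acquisition_protocol(),
                                 motion = NULL, noise_sigma = 0, seed = 1L,
                                 quad_points = 5) {
  stopifnot(noise_sigma >= 0)
  if (is.null(motion)) motion <- identity_trace(protocol$n_dynamics)
  nd <- n_trace(motion)
  tes <- protocol$echo_times

  # low-resolution grid covering the phantom field of view, centered
  pd <- dim(ph$t2star$values)
  pfov <- pd * voxel_spacing(ph$t2star$affine)
  res <- protocol$in_plane_resolution
  thick <- protocol$slice_thickness
  nx <- ceiling(pfov[1] / res); ny <- ceiling(pfov[2] / res)
  nz <- protocol$n_slices %||% ceiling(pfov[3] / thick)
  spacing <- c(res, res, thick)
  lr_aff <- make_affine(spacing, -(c(nx, ny, nz) - 1) / 2 * spacing)

  sigmas <- fwhm_to_sigma(c(1.2 * res, 1.2 * res, thick))
  quad <- psf_quadrature(sigmas, diag(3), quad_points)

  hr_aff <- ph$t2star$affine
  w2v <- solve(hr_aff)
  t2 <- ph$t2star$values
  signal <- lapply(tes, function(te) {
    s <- ph$amplitude$values * exp(-te / pmax(t2, 1e-6))
    s[t2 <= 0] <- 0
    s
  })

  stacks <- vector("list", nd)
  for (d in seq_len(nd)) {
    tf <- trace_transform(motion, d)
    rigid_inv <- solve(rigid_matrix(tf))  # sample the moved phantom
    slice_rigids <- lapply(seq_len(nz), function(k) {
      if (is.null(motion$slice_jitter)) return(rigid_inv)
      jit <- motion$slice_jitter[[d]][[k]]
      solve(rigid_matrix(jit) %*% rigid_matrix(tf))
    })
    geom <- slice_projection(w2v, lr_aff, seq_len(nz), slice_rigids, quad)
    stacks[[d]] <- lapply(seq_along(tes), function(e) {
      m <- cpp_psf_forward(signal[[e]], dim(t2), geom$base, geom$step1,
                           geom$step2, geom$quadvox, quad$weights,
                           nx, ny, NULL)
      a <- array(0, c(nx, ny, nz))
      for (k in seq_len(nz)) a[, , k] <- matrix(m[k, ], nx, ny)
      a[!is.finite(a)] <- 0
      a
    })
  }

  if (noise_sigma > 0) {
    stacks <- with_seed(derive_seed(seed, 3), {
      lapply(stacks, function(st) lapply(st, function(a) {
        sqrt((a + stats::rnorm(length(a), 0, noise_sigma))^2 +
               stats::rnorm(length(a), 0, noise_sigma)^2)
      }))
    })
  }

  stacks <- lapply(stacks, function(st)
    lapply(st, function(a) voxel_volume(a, lr_aff)))
  proto <- protocol
  proto$n_dynamics <- nd
  proto$n_slices <- nz
  out <- multi_echo_series(stacks, proto)
  out$trace <- motion
  out
}

#' Simulate a cohort of phantoms across gestation
#'
#' @param n_subjects number of subjects (>= 2)
#' @param ga_range GA interval in weeks (non-degenerate, within 17-40)
#' @param model an [organ_t2s_model()]
#' @param seed integer seed (GAs and subject draws are reproducible)
#' @param ... further arguments to [make_phantom()] (e.g. `grid_size`)
#' @return list of `digital_phantom`
#' @export
make_cohort <- function(n_subjects, ga_range = c(17, 40),
                        model = organ_t2s_model(), seed = 1L, ...) {
  stopifnot(n_subjects >= 2)
  if (!(length(ga_range) == 2) || ga_range[2] <= ga_range[1])
    stop("domain error: ga_range must be a non-degenerate interval")
  gas <- with_seed(derive_seed(seed, 4),
                   stats::runif(n_subjects, ga_range[1], ga_range[2]))
  lapply(seq_len(n_subjects), function(i)
    make_phantom(gas[i], model = model, seed = derive_seed(seed, 100 + i),
                 ...))
}

#' Write a synthetic subject to disk
#'
#' Emits the NIfTI stacks (one 4D file per echo), ground-truth maps, the
#' label map, and a JSON manifest (GA, seed, motion trace).
#'
#' @param ph a `digital_phantom`
#' @param series the simulated `multi_echo_series` for the phantom
#' @param dir output directory (created if missing)
#' @return the manifest path, invisibly
#' @export
write_phantom_fixture <- function(ph, series, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- write_series(series, dir, "stack")
  write_volume(ph$t2star, file.path(dir, "truth_t2star.nii.gz"))
  write_volume(ph$amplitude, file.path(dir, "truth_amplitude.nii.gz"))
  write_nifti_array(ph$labels$labels, ph$labels$affine,
                    file.path(dir, "labels.nii.gz"), datatype = "int16")
  manifest <- list(ga_weeks = ph$ga_weeks, seed = ph$seed,
                   organ_t2s = as.list(ph$organ_t2s),
                   echo_times = series$protocol$echo_times,
                   stacks = basename(paths),
                   rotations = series$trace$rotations,
                   translations = series$trace$translations)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}
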