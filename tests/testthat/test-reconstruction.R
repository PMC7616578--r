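make_affine2 <- function(spacing, origin) {
  m <- diag(4); diag(m)[1:3] <- spacing; m[1:3, 4] <- origin; m
}

# a small moving-phantom reconstruction shared by several tests
fx_small_recon <- function() fx_get("small_recon", function() {
  ph <- fx_phantom()
  proto <- acquisition_protocol(n_dynamics = 3)
  trace <- random_motion_trace(3, max_rotation = 5, max_translation = 5,
                               seed = 5)
  ser <- simulate_acquisition(ph, proto, trace, noise_sigma = 0, seed = 1)
  cfg <- recon_config(rounds = 1, deformable = FALSE, multi_start = 2)
  rec <- reconstruct(ser, echo = 2, params = cfg)
  list(ph = ph, ser = ser, trace = trace, rec = rec)
})

test_that("simulate_slice is PSF-normalized, linear, and matches a brute-force oracle", {
  aff <- make_affine2(c(2, 2, 2), c(0, 0, 0))   # 12^3 volume, world 0..22 mm
  nvox <- 12
  grid <- list(affine = make_affine2(c(2, 2, 3), c(4, 4, 5)),
               nx = 7, ny = 7)
  sm <- slice_model(1, 2, rigid_transform(c(3, -4, 2), c(1, -1.5, 0.5),
                                          center = c(11, 11, 11)))

  # constant volume -> constant slice inside support
  const <- voxel_volume(array(7, c(nvox, nvox, nvox)), aff)
  s <- simulate_slice(const, sm, grid)
  expect_equal(unique(round(s[is.finite(s)], 10)), 7)

  # linearity in the volume
  set.seed(9)
  v1 <- voxel_volume(array(rnorm(nvox^3), rep(nvox, 3)), aff)
  v2 <- voxel_volume(array(rnorm(nvox^3), rep(nvox, 3)), aff)
  comb <- voxel_volume(2 * v1$values - 3 * v2$values, aff)
  lhs <- simulate_slice(comb, sm, grid)
  rhs <- 2 * simulate_slice(v1, sm, grid) - 3 * simulate_slice(v2, sm, grid)
  expect_equal(lhs[is.finite(lhs)], rhs[is.finite(rhs)], tolerance = 1e-10)

  # brute-force oracle: plain-R gather over every sample and quadrature
  # point of the same acquisition definition
  got <- simulate_slice(v1, sm, grid)
  quad <- fetalt2star:::psf_quadrature(
    fetalt2star:::fwhm_to_sigma(sm$psf_fwhm), diag(3), 3)
  w2v <- solve(aff)
  tm <- rigid_matrix(sm$rigid)
  tri <- function(vol, p) {
    if (any(p < 0) || any(p > nvox - 1)) return(NA_real_)
    f <- floor(pmin(p, nvox - 2)); r <- p - f
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, r, 1 - r))
      acc <- acc + w * vol[f[1] + dx + 1, f[2] + dy + 1, f[3] + dz + 1]
    }
    acc
  }
  oracle <- matrix(NA_real_, grid$nx, grid$ny)
  for (i in 0:(grid$nx - 1)) for (j in 0:(grid$ny - 1)) {
    p <- grid$affine %*% c(i, j, sm$slice - 1, 1)
    acc <- 0; wsum <- 0
    for (q in seq_along(quad$weights)) {
      pw <- tm %*% c(p[1:3] + quad$offsets[q, ], 1)
      val <- tri(v1$values, (w2v %*% pw)[1:3])
      if (!is.na(val)) {
        acc <- acc + quad$weights[q] * val
        wsum <- wsum + quad$weights[q]
      }
    }
    oracle[i + 1, j + 1] <- if (wsum >= 0.5) acc / wsum else NA_real_
  }
  keep <- is.finite(got) & is.finite(oracle)
  expect_gt(sum(keep), 10)
  expect_lt(max(abs(got[keep] - oracle[keep])), 1e-10)
  expect_equal(is.finite(got), is.finite(oracle))
})

test_that("single-slice registration recovers a known transform", {
  z <- fx_small_recon()
  ph <- z$ph
  sig <- ph$amplitude$values * exp(-120 / pmax(ph$t2star$values, 1e-6))
  sig[ph$t2star$values <= 0] <- 0
  vol <- voxel_volume(sig, ph$t2star$affine)
  st <- get_stack(z$ser, 1, 2)
  k <- round(dim(st$values)[3] / 2)
  true_tf <- rigid_transform(c(3, -2, 4), c(2.5, -3, 1.5))
  obs <- simulate_slice(vol, slice_model(1, k, true_tf),
                        list(affine = st$affine, nx = dim(st$values)[1],
                             ny = dim(st$values)[2]))
  got <- register_slice_to_volume(list(values = obs, affine = st$affine,
                                       k = k), vol)
  err <- rigid_matrix(got) %*% solve(rigid_matrix(true_tf))
  rot_err <- rotation_distance(rigid_from_matrix(err), rigid_transform())
  trans_err <- sqrt(sum((err %*% c(0, 0, 0, 1))[1:3]^2))
  expect_lt(rot_err, 0.5)
  expect_lt(trans_err, 0.5)
  expect_false(attr(got, "excluded"))

  # identity transform recovers approximately the identity
  obs0 <- simulate_slice(vol, slice_model(1, k, rigid_transform()),
                         list(affine = st$affine, nx = dim(st$values)[1],
                              ny = dim(st$values)[2]))
  got0 <- register_slice_to_volume(list(values = obs0, affine = st$affine,
                                        k = k), vol)
  expect_lt(rotation_distance(got0, rigid_transform()), 0.5)
  expect_lt(sqrt(sum(got0$translation^2)), 0.5)
})

test_that("a pure-noise slice is never a silent registration success", {
  z <- fx_small_recon()
  ph <- z$ph
  vol <- ph$amplitude
  st <- get_stack(z$ser, 1, 2)
  set.seed(14)
  noise <- matrix(rnorm(prod(dim(st$values)[1:2]), 50, 15),
                  dim(st$values)[1], dim(st$values)[2])
  got <- register_slice_to_volume(list(values = noise, affine = st$affine,
                                       k = 5), vol)
  expect_true(isTRUE(attr(got, "excluded")) || attr(got, "ncc") < 0.5)

  # too-few-voxels slice is flagged excluded
  tiny <- matrix(NA_real_, dim(st$values)[1], dim(st$values)[2])
  tiny[1:3, 1] <- 1
  got2 <- register_slice_to_volume(list(values = tiny, affine = st$affine,
                                        k = 5), vol)
  expect_true(attr(got2, "excluded"))
})

test_that("super-resolution of a single identity stack resimulates the input", {
  ser <- fx_series_clean()
  cfg <- recon_config(rounds = 1, deformable = FALSE, multi_start = 0)
  one <- multi_echo_series(ser$stacks[1], ser$protocol)
  rec <- reconstruct(one, echo = 2, params = cfg)
  # resimulate the stack from the reconstruction; in-organ agreement < 1%
  st <- get_stack(one, 1, 2)
  dm <- rec$slice_models
  ss <- fetalt2star:::build_slice_set(rec$grid$affine, rec$grid$dim,
                                      rec$stack_affine, dm, rec$quad,
                                      nx = dim(st$values)[1],
                                      ny = dim(st$values)[2])
  pred <- fetalt2star:::ss_forward(ss, rec$volume$values)
  obs <- t(vapply(dm, function(m) as.vector(st$values[, , m$slice]),
                  numeric(prod(dim(st$values)[1:2]))))
  lab <- fx_lr_labels(one)
  organ_lr <- lab$labels > 0
  keep <- matrix(FALSE, nrow(obs), ncol(obs))
  for (s in seq_along(dm))
    keep[s, ] <- as.vector(fetalt2star:::erode_mask(organ_lr, 1)[, , dm[[s]]$slice])
  keep <- keep & is.finite(pred) & is.finite(obs)
  relerr <- abs(pred[keep] - obs[keep]) / mean(obs[keep])
  expect_lt(median(relerr), 0.01)
})

test_that("stronger regularization yields smoother solutions on a fixed problem", {
  ser <- fx_series_clean()
  one <- multi_echo_series(ser$stacks[1], ser$protocol)
  rec <- reconstruct(one, 2, recon_config(rounds = 1, deformable = FALSE,
                                          multi_start = 0))
  st <- get_stack(one, 1, 2)
  dm <- rec$slice_models
  vals <- t(vapply(dm, function(m) as.vector(st$values[, , m$slice]),
                   numeric(prod(dim(st$values)[1:2]))))
  ss <- fetalt2star:::build_slice_set(rec$grid$affine, rec$grid$dim,
                                      rec$stack_affine, dm, rec$quad,
                                      values = vals,
                                      nx = dim(st$values)[1],
                                      ny = dim(st$values)[2])
  vars <- vapply(c(0.02, 1, 20), function(lam) {
    sr <- fetalt2star:::sr_solve(ss, lam, 3, lam, 0.05, 8)
    var(sr$volume[sr$coverage])
  }, numeric(1))
  expect_true(all(diff(vars) < 0))
})

test_that("super-resolution with the true transforms recovers the phantom", {
  z <- fx_small_recon()
  ph <- z$ph; ser <- z$ser; trace <- z$trace
  rec <- z$rec
  # replace recovered transforms by the true ones (no registration error)
  models <- rec$slice_models
  for (i in seq_along(models)) {
    d <- models[[i]]$dynamic
    tm <- solve(rigid_matrix(fetalt2star:::trace_transform(trace, d)))
    models[[i]]$rigid <- rigid_from_matrix(tm, models[[i]]$rigid$center)
  }
  st_dim <- dim(get_stack(ser, 1, 2)$values)
  vals <- t(vapply(models, function(m)
    as.vector(get_stack(ser, m$dynamic, 2)$values[, , m$slice]),
    numeric(prod(st_dim[1:2]))))
  ss <- fetalt2star:::build_slice_set(rec$grid$affine, rec$grid$dim,
                                      rec$stack_affine, models, rec$quad,
                                      values = vals,
                                      nx = st_dim[1], ny = st_dim[2])
  sr <- fetalt2star:::sr_solve(ss, 0.02, 3, 0.015, 0.05, 8)
  expect_true(all(diff(sr$residuals) < 1e-6))  # non-increasing residuals
  # in-organ RMSE against the phantom signal truth (identity gauge: the
  # true transforms are expressed in the phantom frame)
  sig <- ph$amplitude$values * exp(-120 / pmax(ph$t2star$values, 1e-6))
  sig[ph$t2star$values <= 0] <- 0
  truth <- resample_volume(voxel_volume(sig, ph$t2star$affine),
                           rec$grid$affine, rec$grid$dim)
  lab <- resample_volume(voxel_volume(ph$labels$labels + 0,
                                      ph$labels$affine),
                         rec$grid$affine, rec$grid$dim, nearest = TRUE)
  lv <- lab$values; lv[!is.finite(lv)] <- 0
  rmse <- fx_inorgan_relrmse(sr$volume, truth$values, lv, erode = 3)
  expect_lt(rmse, 3)
})

test_that("reconstruction defaults mirror the intended pipeline settings", {
  cfg <- recon_config()
  expect_false(cfg$intensity_matching)
  expect_false(cfg$robust_stats)
  expect_equal(cfg$resolution, 1.2)
  expect_equal(cfg$cp_spacing, c(12, 5))
  expect_equal(cfg$last_iter_lambda, 0.015)
  z <- fx_small_recon()
  expect_equal(unname(fetalt2star:::voxel_spacing(z$rec$volume$affine)),
               rep(1.2, 3), tolerance = 1e-12)
  expect_true(all(vapply(z$rec$slice_models, function(m) m$scale,
                         numeric(1)) == 1))
})

test_that("deformable refinement is identity on rigid data and fixes true bending", {
  z <- fx_small_recon()
  rec <- z$rec; ser <- z$ser
  nd <- 3
  stacks <- lapply(seq_len(nd), function(d) get_stack(ser, d, 2)$values)
  def0 <- deformable_refine(rec$volume, stacks, rec$slice_models,
                            rec$stack_affine, quad = rec$quad)
  for (d in seq_len(nd)) {
    expect_equal(dim(def0[[d]]$disp)[4], 3)
    expect_lt(mean(sqrt(apply(def0[[d]]$disp^2, 1:3, sum))), 0.5)
  }

  # seeded smooth bending applied in the forward model to dynamics 2 and 3
  gd <- rec$grid$dim
  lo <- fetalt2star:::apply_affine(rec$grid$affine, matrix(0, 1, 3))
  nl <- pmax(2, ceiling((gd - 1) * 1.2 / 12) + 1)
  laff <- fetalt2star:::make_affine(rep(12, 3), as.numeric(lo))
  nodes <- fetalt2star:::grid_world_coords(laff, nl)
  disp <- array(0, c(nl, 3))
  disp[, , , 1] <- array(3 * sin(pi * nodes[, 3] / 40), nl)
  fld <- deformable_field(disp, laff, 12)
  bent <- lapply(seq_len(nd), function(d) {
    dm <- Filter(function(m) m$dynamic == d & !m$excluded, rec$slice_models)
    df <- NULL
    if (d >= 2) { df <- vector("list", nd); df[[d]] <- fld }
    ss <- fetalt2star:::build_slice_set(rec$grid$affine, gd,
                                        rec$stack_affine, dm, rec$quad,
                                        def_fields = df,
                                        nx = dim(stacks[[d]])[1],
                                        ny = dim(stacks[[d]])[2])
    pred <- fetalt2star:::ss_forward(ss, rec$volume$values)
    a <- array(NA_real_, dim(stacks[[d]]))
    for (s in seq_along(dm))
      a[, , dm[[s]]$slice] <- matrix(pred[s, ], dim(a)[1], dim(a)[2])
    a
  })
  resid <- function(def) {
    tot <- 0; n <- 0
    for (d in seq_len(nd)) {
      dm <- Filter(function(m) m$dynamic == d & !m$excluded,
                   rec$slice_models)
      ss <- fetalt2star:::build_slice_set(rec$grid$affine, gd,
                                          rec$stack_affine, dm, rec$quad,
                                          def_fields = def,
                                          nx = dim(stacks[[d]])[1],
                                          ny = dim(stacks[[d]])[2])
      pred <- fetalt2star:::ss_forward(ss, rec$volume$values)
      obs <- t(vapply(dm, function(m) as.vector(bent[[d]][, , m$slice]),
                      numeric(prod(dim(bent[[d]])[1:2]))))
      ok <- is.finite(pred) & is.finite(obs)
      tot <- tot + sum((pred[ok] - obs[ok])^2); n <- n + sum(ok)
    }
    sqrt(tot / n)
  }
  def <- deformable_refine(rec$volume, bent, rec$slice_models,
                           rec$stack_affine, quad = rec$quad)
  expect_lt(resid(def), resid(NULL))
  # fields appear only where the bending was applied
  expect_equal(max(abs(def[[1]]$disp)), 0)
  expect_gt(mean(sqrt(apply(def[[3]]$disp^2, 1:3, sum))), 0.5)
  # two pyramid levels from the default control-point spacings
  expect_equal(recon_config()$cp_spacing, c(12, 5))
  expect_equal(def[[3]]$spacing, 5)
})

test_that("channel propagation validates geometry and tolerates failed dynamics", {
  z <- fx_small_recon()
  rec <- z$rec; ser <- z$ser
  ch <- lapply(1:3, function(d) get_stack(ser, d, 2))
  expect_error(propagate_channel(rec, ch[1:2]), "one per included dynamic")
  wrong <- ch
  wrong[[2]] <- voxel_volume(ch[[2]]$values, diag(4))
  expect_error(propagate_channel(rec, wrong), "dynamic 2")

  # one dynamic entirely invalid: excluded from the data term, output intact
  holed <- ch
  holed[[2]] <- voxel_volume(array(NA_real_, dim(ch[[2]]$values)),
                             ch[[2]]$affine)
  out <- propagate_channel(rec, holed)
  expect_true(any(is.finite(out$values)))
  full <- propagate_channel(rec, ch)
  m <- out$mask & full$mask
  expect_gt(cor(out$values[m], full$values[m]), 0.98)
})

test_that("a single identity dynamic reconstructs end to end", {
  ser <- fx_series_clean()
  one <- multi_echo_series(ser$stacks[1], ser$protocol)
  rec <- reconstruct(one, 2, recon_config(rounds = 1, deformable = FALSE,
                                          multi_start = 0))
  expect_s3_class(rec, "recon_result")
  up <- resample_volume(get_stack(one, 1, 2), rec$grid$affine, rec$grid$dim)
  m <- rec$volume$mask & is.finite(up$values) & up$values > 1
  expect_gt(cor(rec$volume$values[m], up$values[m]), 0.95)
})
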