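mini_labels <- function(arr, affine = diag(4)) label_map(arr, affine)

test_that("organ statistics exclude failed voxels and flag missing organs", {
  d <- c(6, 6, 6)
  lab <- array(0L, d)
  lab[1:3, 1, 1] <- 1L                      # lungs: three voxels
  lab[5, 5, 5] <- 8L                        # stomach: one voxel
  t2 <- array(NA_real_, d)
  t2[1:3, 1, 1] <- c(100, 200, 300)
  t2[5, 5, 5] <- 200
  failed <- array(TRUE, d)
  failed[1:3, 1, 1] <- c(FALSE, TRUE, FALSE)  # middle lung voxel failed
  failed[5, 5, 5] <- FALSE
  st <- organ_stats(voxel_volume(t2, diag(4)), mini_labels(lab),
                    failure_mask = failed)
  lungs <- st[st$organ == "lungs", ]
  expect_equal(lungs$mean_t2s, 200)          # (100 + 300) / 2
  expect_equal(lungs$valid_voxels, 2)
  expect_equal(lungs$organ_voxels, 3)
  stomach <- st[st$organ == "stomach", ]
  expect_equal(stomach$mean_t2s, 200)
  expect_equal(stomach$sd_t2s, 0)
  liver <- st[st$organ == "liver", ]
  expect_true(liver$missing)
  expect_true(is.na(liver$mean_t2s))
  expect_equal(st$volume_mm3[st$organ == "lungs"], 3)
})

test_that("uniform organs give mean = median and zero SD", {
  d <- c(5, 5, 5)
  lab <- array(0L, d); lab[2:4, 2:4, 2:4] <- 10L
  t2 <- array(200, d)
  st <- organ_stats(voxel_volume(t2, diag(4), mask = array(TRUE, d)),
                    mini_labels(lab))
  liver <- st[st$organ == "liver", ]
  expect_equal(liver$mean_t2s, 200)
  expect_equal(liver$median_t2s, 200)
  expect_equal(liver$sd_t2s, 0)
})

test_that("labels on a different grid are resampled by nearest neighbor", {
  ph <- fx_phantom()
  # truth map on the phantom grid, labels downsampled to a coarser grid
  coarse_aff <- fetalt2star:::make_affine(c(4, 4, 4), c(-47, -47, -47))
  lab_c <- resample_volume(voxel_volume(ph$labels$labels + 0,
                                        ph$labels$affine),
                           coarse_aff, c(24, 24, 24), nearest = TRUE)
  lv <- lab_c$values; lv[!is.finite(lv)] <- 0
  st <- organ_stats(ph$t2star, label_map(lv, coarse_aff))
  lungs <- st[st$organ == "lungs", ]
  # the median is immune to the minority of boundary voxels whose coarse
  # nearest-neighbor label disagrees with the fine grid
  expect_equal(lungs$median_t2s, unname(ph$organ_t2s[["lungs"]]),
               tolerance = 1e-12)
  expect_true(all(st$label == unname(organ_labels())))
})

test_that("the organ means of a noiseless phantom match ground truth", {
  ph <- fx_phantom()
  st <- organ_stats(ph$t2star, ph$labels)
  for (og in names(organ_labels())) {
    row <- st[st$organ == og, ]
    expect_false(row$missing)
    expect_equal(row$mean_t2s, unname(ph$organ_t2s[[og]]), tolerance = 1e-12)
  }
})

test_that("the two-sigma equivalence check reproduces its defining arithmetic", {
  eq <- equivalence_check(c(190, 192, 194, 196, 198), 195)
  expect_equal(eq$pooled_mean, 194)
  expect_equal(eq$sigma, sd(c(190, 192, 194, 196, 198)))
  expect_equal(eq$interval, 194 + c(-2, 2) * eq$sigma)
  expect_true(eq$pass)
  # the reconstruction value equal to the pooled mean passes for any sigma
  expect_true(equivalence_check(c(200, 200, 200), 200)$pass)
  # scale invariance
  eq2 <- equivalence_check(10 * c(190, 192, 194, 196, 198), 10 * 195)
  expect_equal(eq2$pass, eq$pass)
  eq3 <- equivalence_check(c(190, 192, 194, 196, 198), 240)
  expect_false(eq3$pass)
  expect_error(equivalence_check(194, 195), "2 finite")
  # n-denominator option shrinks sigma
  eqn <- equivalence_check(c(190, 200), 195, sd_denominator = "n")
  expect_lt(eqn$sigma, equivalence_check(c(190, 200), 195)$sigma)
})

test_that("dice behaves as an overlap coefficient", {
  d <- c(4, 4, 2)
  a <- array(0L, d); b <- array(0L, d)
  a[1:4, 1, 1] <- 1L                 # |A| = 4
  b[3:4, 1, 1] <- 1L; b[1:2, 2, 1] <- 1L  # |B| = 4, overlap 2
  la <- mini_labels(a); lb <- mini_labels(b)
  expect_equal(dice(la, lb, 1), 0.5)
  expect_equal(dice(lb, la, 1), 0.5)          # symmetric
  expect_equal(dice(la, la, 1), 1)
  empty <- mini_labels(array(0L, d))
  expect_equal(dice(la, empty, 1), 0)          # disjoint
  expect_equal(dice(empty, empty, 1), 1)       # both empty
  expect_error(dice(la, mini_labels(array(0L, c(5, 5, 5))), 1),
               "geometry error")
  # monotone in the overlap at fixed |A| + |B|
  b2 <- array(0L, d); b2[2:4, 1, 1] <- 1L; b2[1, 2, 1] <- 1L  # overlap 3
  expect_gt(dice(la, mini_labels(b2), 1), dice(la, lb, 1))
})

test_that("growth curves fit exact lines with signed R-squared", {
  f <- growth_curve(c(20, 25, 30, 35), c(300, 280, 260, 240))
  expect_equal(f$slope, -4, tolerance = 1e-12)
  expect_equal(f$signed_r2, -1, tolerance = 1e-12)
  up <- growth_curve(c(20, 25, 30), c(100, 120, 140))
  expect_equal(up$signed_r2, 1, tolerance = 1e-12)
  flat <- growth_curve(c(20, 25, 30, 35), c(200, 200, 200, 200))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$signed_r2, 0)
  expect_error(growth_curve(c(20, 25), c(1, 2)), "3 subjects")
  expect_error(growth_curve(c(20, 20, 20), c(1, 2, 3)), "not all")
})

test_that("cohort curves recover generative slopes and report unfittable organs", {
  mod <- organ_t2s_model()
  coh <- make_cohort(30, c(17, 40), mod, seed = 5, grid_size = 16)
  df <- do.call(rbind, lapply(seq_along(coh), function(i)
    data.frame(subject = i, ga = coh[[i]]$ga_weeks,
               organ = names(coh[[i]]$organ_t2s),
               mean_t2s = as.numeric(coh[[i]]$organ_t2s))))
  fits <- cohort_curves(df)
  gen <- stats::setNames(mod$table$slope, mod$table$organ)
  lungs <- fits[fits$organ == "lungs", ]
  expect_true(abs(lungs$slope - gen[["lungs"]]) < 2 * lungs$slope_se)
  expect_gt(fits$slope[fits$organ == "liver"], 0)
  expect_lt(fits$slope[fits$organ == "kidney_parenchyma"], 0)

  # zero subject noise: exact linear truth, |signed R2| = 1
  mod0 <- mod; mod0$table$noise_sd[] <- 0
  coh0 <- make_cohort(10, c(17, 40), mod0, seed = 5, grid_size = 16)
  df0 <- do.call(rbind, lapply(seq_along(coh0), function(i)
    data.frame(subject = i, ga = coh0[[i]]$ga_weeks,
               organ = names(coh0[[i]]$organ_t2s),
               mean_t2s = as.numeric(coh0[[i]]$organ_t2s))))
  fits0 <- cohort_curves(df0)
  expect_true(all(abs(abs(fits0$signed_r2) - 1) < 1e-8))

  # an organ absent everywhere is reported not fittable, the run completes
  df_miss <- df
  df_miss$mean_t2s[df_miss$organ == "thymus"] <- NA_real_
  fits_m <- cohort_curves(df_miss)
  expect_false(fits_m$fittable[fits_m$organ == "thymus"])
  expect_true(all(fits_m$fittable[fits_m$organ != "thymus"]))

  # CSV and figure outputs
  dir <- withr::local_tempdir()
  cohort_curves(df, csv = file.path(dir, "curves.csv"),
                figure = file.path(dir, "curves.png"))
  expect_true(file.exists(file.path(dir, "curves.csv")))
  expect_true(file.exists(file.path(dir, "curves.png")))
})
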