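test_that("phantom generation is deterministic and respects the GA domain", {
  a <- make_phantom(25, seed = 7, grid_size = 32)
  b <- make_phantom(25, seed = 7, grid_size = 32)
  expect_identical(a$labels$labels, b$labels$labels)
  expect_identical(a$organ_t2s, b$organ_t2s)
  expect_error(make_phantom(16.5), "domain error")
  expect_error(make_phantom(41), "domain error")
})

test_that("organ T2* trends and volumes follow gestational age", {
  mod <- organ_t2s_model()
  mod$table$noise_sd[] <- 0
  young <- make_phantom(17, mod, seed = 1, grid_size = 48)
  old <- make_phantom(40, mod, seed = 1, grid_size = 48)
  expect_gt(old$organ_t2s[["lungs"]], young$organ_t2s[["lungs"]])
  expect_gt(old$organ_t2s[["liver"]], young$organ_t2s[["liver"]])
  expect_lt(old$organ_t2s[["kidney_parenchyma"]],
            young$organ_t2s[["kidney_parenchyma"]])
  mid <- make_phantom(20, seed = 1, grid_size = 48)
  big <- make_phantom(30, seed = 1, grid_size = 48)
  # every organ grows (ties possible only from voxelization of the smallest)
  for (id in organ_labels())
    expect_gte(sum(big$labels$labels == id), sum(mid$labels$labels == id))
  for (og in c("lungs", "liver", "stomach", "bladder"))
    expect_gt(sum(big$labels$labels == organ_labels()[[og]]),
              sum(mid$labels$labels == organ_labels()[[og]]))
  expect_gt(sum(big$labels$labels > 0), sum(mid$labels$labels > 0))
  # all ten organs present and piecewise constant
  expect_setequal(unique(as.vector(big$labels$labels)), c(0L, organ_labels()))
  for (og in names(organ_labels())) {
    v <- big$t2star$values[big$labels$labels == organ_labels()[[og]]]
    expect_equal(stats::sd(v), 0)
    expect_equal(v[1], unname(big$organ_t2s[[og]]))
  }
})

test_that("trend-direction constraints on the organ model are enforced", {
  tab <- default_organ_table()
  tab$slope[tab$organ == "lungs"] <- -1
  expect_error(organ_t2s_model(tab), "slope signs")
})

test_that("noiseless forward model shows the analytic echo decay in organ plateaus", {
  ph <- fx_phantom()
  ser <- fx_series_clean()
  lab <- fx_lr_labels(ser)
  tes <- ser$protocol$echo_times
  for (og in c("lungs", "liver")) {
    msk <- fetalt2star:::erode_mask(lab$labels == organ_labels()[[og]], 1)
    expect_gt(sum(msk), 4)
    r21 <- get_stack(ser, 1, 2)$values[msk] / get_stack(ser, 1, 1)$values[msk]
    expected <- exp(-(tes[2] - tes[1]) / ph$organ_t2s[[og]])
    expect_equal(median(r21), expected, tolerance = 0.01)
  }
})

test_that("a pure translation shifts the simulated stack (forward-model equivariance)", {
  ph <- fx_phantom()
  proto <- acquisition_protocol(n_dynamics = 2)
  trace <- motion_trace(rbind(c(0, 0, 0), c(0, 0, 0)),
                        rbind(c(0, 0, 0), c(6.25, 0, 0)))  # 2 in-plane voxels
  ser <- simulate_acquisition(ph, proto, trace, noise_sigma = 0, seed = 1)
  a <- get_stack(ser, 1, 2)$values
  b <- get_stack(ser, 2, 2)$values
  # the moved phantom appears shifted by +2 voxels along x
  interior <- 8:(dim(a)[1] - 8)
  shifted <- a[interior - 2, , ]
  moved <- b[interior, , ]
  keep <- shifted > 1 & moved > 1
  expect_gt(cor(shifted[keep], moved[keep]), 0.995)
})

test_that("zero-signal background follows the Rayleigh law under Rician noise", {
  ph <- fx_phantom()
  proto <- acquisition_protocol(n_dynamics = 1)
  ser <- simulate_acquisition(ph, proto, noise_sigma = 5, seed = 3)
  s <- get_stack(ser, 1, 1)$values
  bg <- s[1:6, 1:6, 1:6]  # far corner: outside the body
  expect_equal(mean(bg), 5 * sqrt(pi / 2), tolerance = 0.1)
})

test_that("noiseless fitting recovers phantom T2* inside organs to < 1%", {
  # full-scale phantom: organ interiors must clear the PSF support
  z <- fx_get("fit64", function() {
    ph <- make_phantom(30, seed = 2, grid_size = 64)
    ser <- simulate_acquisition(ph, acquisition_protocol(n_dynamics = 1),
                                noise_sigma = 0, seed = 1)
    st <- get_stack(ser, 1, 1)
    lab <- fetalt2star:::labels_at_dynamic(ph, st$affine, dim(st$values),
                                           identity_trace(1), 1)
    list(ph = ph, map = fit_t2star_map(ser, 1), lab = lab)
  })
  # lungs and liver: the organs whose interiors clearly outsize the PSF
  for (og in c("lungs", "liver")) {
    msk <- fetalt2star:::erode_mask(z$lab$labels == organ_labels()[[og]], 2)
    expect_gt(sum(msk), 4)
    v <- z$map$t2star$values[msk & !z$map$failure_mask]
    err <- median(abs(v - z$ph$organ_t2s[[og]]) / z$ph$organ_t2s[[og]])
    expect_lt(err, 0.01)
  }
})

test_that("simulation is reproducible and seeded noise differs across seeds", {
  ph <- make_phantom(22, seed = 4, grid_size = 32)
  proto <- acquisition_protocol(n_dynamics = 2)
  a <- simulate_acquisition(ph, proto, noise_sigma = 3, seed = 9)
  b <- simulate_acquisition(ph, proto, noise_sigma = 3, seed = 9)
  c2 <- simulate_acquisition(ph, proto, noise_sigma = 3, seed = 10)
  expect_identical(get_stack(a, 1, 1)$values, get_stack(b, 1, 1)$values)
  expect_false(identical(get_stack(a, 1, 1)$values,
                         get_stack(c2, 1, 1)$values))
})

test_that("cohorts are reproducible, reject degenerate intervals, and recover the slope", {
  coh <- make_cohort(30, c(17, 40), seed = 3, grid_size = 16)
  coh2 <- make_cohort(30, c(17, 40), seed = 3, grid_size = 16)
  expect_equal(vapply(coh, `[[`, numeric(1), "ga_weeks"),
               vapply(coh2, `[[`, numeric(1), "ga_weeks"))
  expect_error(make_cohort(2, c(20, 20)), "domain error")
  expect_error(make_cohort(1, c(17, 40)))
  # OLS on the generated truth recovers the lung slope within its CI
  ga <- vapply(coh, `[[`, numeric(1), "ga_weeks")
  lung <- vapply(coh, function(p) p$organ_t2s[["lungs"]], numeric(1))
  fit <- lm(lung ~ ga)
  ci <- confint(fit)["ga", ]
  gen <- organ_t2s_model()$table
  expect_true(ci[1] <= gen$slope[gen$organ == "lungs"] &&
                gen$slope[gen$organ == "lungs"] <= ci[2])
})

test_that("phantom fixtures round-trip through the on-disk layout", {
  dir <- withr::local_tempdir()
  ph <- make_phantom(24, seed = 6, grid_size = 24)
  ser <- simulate_acquisition(ph, acquisition_protocol(n_dynamics = 2),
                              noise_sigma = 2, seed = 6)
  write_phantom_fixture(ph, ser, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$ga_weeks, 24)
  back <- read_series(file.path(dir, man$stacks), man$echo_times)
  expect_equal(get_stack(back, 1, 1)$values, get_stack(ser, 1, 1)$values,
               tolerance = 1e-12)
})
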