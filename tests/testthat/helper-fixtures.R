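# Shared fixtures, built once per test run and memoized. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# small phantom at GA 30 (the default study subject for unit tests)
fx_phantom <- function() fx_get("phantom", function() {
  make_phantom(30, seed = 2, grid_size = 48)
})

# noiseless 3-dynamic series with identity motion
fx_series_clean <- function() fx_get("series_clean", function() {
  simulate_acquisition(fx_phantom(), acquisition_protocol(n_dynamics = 3),
                       noise_sigma = 0, seed = 1)
})

# noisy 3-dynamic series (identity motion)
fx_series_noisy <- function() fx_get("series_noisy", function() {
  simulate_acquisition(fx_phantom(), acquisition_protocol(n_dynamics = 3),
                       noise_sigma = 6, seed = 5)
})

# lung mask on the acquisition grid of a series (identity motion), eroded
fx_lr_labels <- function(series) {
  st <- get_stack(series, 1, 1)
  fetalt2star:::labels_at_dynamic(fx_phantom(), st$affine, dim(st$values),
                                  identity_trace(n_dynamics(series)), 1)
}

# The full-scale moving-phantom reconstruction experiment shared by the
# reconstruction-oracle and propagation acceptance checks (computed once).
fx_recon_experiment <- function(seed = 5) fx_get("recon_exp", function() {
  ph <- make_phantom(30, seed = 2, grid_size = 64)
  nd <- 8
  proto <- acquisition_protocol(n_dynamics = nd)
  trace <- random_motion_trace(nd, max_rotation = 10, max_translation = 10,
                               seed = seed)
  ser <- simulate_acquisition(ph, proto, trace, noise_sigma = 0, seed = 1)
  cfg <- recon_config(rounds = 2, deformable = FALSE, multi_start = 2)
  rec <- reconstruct(ser, echo = 2, params = cfg)
  # mean gauge over dynamics: G_d = T_d^-1 M_d^-1
  gd <- lapply(seq_len(nd), function(d) {
    md <- Filter(function(m) m$dynamic == d & is.finite(m$ncc),
                 rec$slice_models)
    rigid_from_matrix(solve(
      rigid_matrix(fetalt2star:::trace_transform(trace, d)) %*%
        rigid_matrix(fetalt2star:::mean_rigid(md))))
  })
  gm <- rigid_matrix(rigid_transform(
    colMeans(t(vapply(gd, `[[`, numeric(3), "rotation"))),
    colMeans(t(vapply(gd, `[[`, numeric(3), "translation")))))
  list(ph = ph, nd = nd, trace = trace, ser = ser, rec = rec,
       gauges = gd, gauge = gm)
})

# Relative residuals pooled over eroded organ interiors on the recon grid.
fx_inorgan_relrmse <- function(values, truth_vol, labels_arr, erode = 3) {
  rr <- c()
  for (id in organ_labels()) {
    m <- fetalt2star:::erode_mask(labels_arr == id, erode)
    if (sum(m) < 20) next
    t <- truth_vol[m]
    r <- values[m]
    ok <- is.finite(t) & is.finite(r)
    rr <- c(rr, (r[ok] - t[ok]) / mean(t[ok]))
  }
  sqrt(mean(rr^2)) * 100
}
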