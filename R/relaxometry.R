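#' Voxel-wise mono-exponential T2* fitting
#'
#' Fits `S(TE) = S0 * exp(-TE / T2*)` per voxel: a log-linear least-squares
#' fit weighted by the squared signal (the standard variance stabilization
#' for log-transformed magnitude data) provides the initial estimate, which
#' is refined by damped Gauss-Newton on the exponential model. A fit is
#' classified failed when any input signal is non-positive (code 1), when
#' the fitted T2* lies outside `(0, cap]` (code 2), or when the refinement
#' does not converge (code 3). With exactly two echoes the fit is the closed
#' form and `fit_r2` is defined as 1.
#'
#' @name relaxometry
NULL

# Vectorized fit over a voxels x echoes signal matrix. Returns amplitude,
# t2star (NA where failed), fit_r2 and an integer failure code per voxel.
fit_t2star_signals <- function(S, tes, cap = 1000, max_iter = 50,
                               tol = 1e-12) {
  S <- matrix(S, ncol = length(tes))
  nv <- nrow(S); ne <- ncol(S)
  code <- integer(nv)
  amplitude <- rep(NA_real_, nv)
  t2star <- rep(NA_real_, nv)
  fit_r2 <- rep(NA_real_, nv)

  bad <- rowSums(!is.finite(S) | S <= 0) > 0
  code[bad] <- 1L
  ok <- which(!bad)
  if (length(ok) == 0)
    return(list(amplitude = amplitude, t2star = t2star, fit_r2 = fit_r2,
                code = code))

  Sv <- S[ok, , drop = FALSE]
  y <- log(Sv)
  w <- Sv^2
  sw <- rowSums(w)
  xw <- (w %*% tes) / sw
  yw <- rowSums(w * y) / sw
  xc <- matrix(tes, length(ok), ne, byrow = TRUE) - as.numeric(xw)
  slope <- rowSums(w * xc * (y - as.numeric(yw))) / rowSums(w * xc^2)
  a <- as.numeric(yw) - slope * as.numeric(xw)       # log amplitude
  r2rate <- pmax(-slope, 1e-8)                       # decay rate 1/ms

  if (ne == 2) {
    conv <- rep(TRUE, length(ok))
  } else {
    # damped Gauss-Newton on (a, r2rate); all voxels in lockstep
    tem <- matrix(tes, length(ok), ne, byrow = TRUE)
    sse <- function(a, r) rowSums((Sv - exp(a - r * tem))^2)
    cur <- sse(a, r2rate)
    conv <- rep(FALSE, length(ok))
    for (it in seq_len(max_iter)) {
      sh <- exp(a - r2rate * tem)
      res <- Sv - sh
      j11 <- rowSums(sh * sh)
      j12 <- rowSums(-tem * sh * sh)
      j22 <- rowSums(tem^2 * sh * sh)
      g1 <- rowSums(sh * res)
      g2 <- rowSums(-tem * sh * res)
      det <- j11 * j22 - j12^2
      det[abs(det) < 1e-300] <- 1e-300
      da <- (j22 * g1 - j12 * g2) / det
      dr <- (j11 * g2 - j12 * g1) / det
      step <- rep(1, length(ok))
      for (h in 1:8) {
        nsse <- sse(a + step * da, r2rate + step * dr)
        worse <- !is.finite(nsse) | nsse > cur
        if (!any(worse)) break
        step[worse] <- step[worse] / 2
      }
      a2 <- a + step * da
      r2n <- r2rate + step * dr
      nsse <- sse(a2, r2n)
      accept <- is.finite(nsse) & nsse <= cur
      a[accept] <- a2[accept]
      r2rate[accept] <- r2n[accept]
      cur[accept] <- nsse[accept]
      done <- abs(da) < tol * pmax(abs(a), 1) &
        abs(dr) < tol * pmax(abs(r2rate), 1e-6)
      conv <- conv | done | !accept
      if (all(conv)) break
    }
    conv <- conv | cur <= 1e-20 * rowSums(Sv^2)
  }

  t2 <- 1 / r2rate
  s0 <- exp(a)
  okrange <- is.finite(t2) & t2 > 0 & t2 <= cap & is.finite(s0) & s0 > 0
  vc <- integer(length(ok))
  vc[!conv & okrange] <- 3L
  vc[!okrange] <- 2L

  sh <- exp(outer(a, rep(1, ne)) - r2rate * matrix(tes, length(ok), ne,
                                                   byrow = TRUE))
  sse_f <- rowSums((Sv - sh)^2)
  sst <- rowSums((Sv - rowMeans(Sv))^2)
  r2fit <- ifelse(sst > 0, pmax(0, pmin(1, 1 - sse_f / sst)),
                  as.numeric(sse_f <= 1e-12 * rowSums(Sv^2)))
  if (ne == 2) r2fit <- rep(1, length(ok))

  good <- vc == 0L
  idx <- ok[good]
  amplitude[idx] <- s0[good]
  t2star[idx] <- t2[good]
  fit_r2[ok] <- r2fit
  code[ok] <- vc
  list(amplitude = amplitude, t2star = t2star, fit_r2 = fit_r2, code = code)
}

#' Fit one voxel's T2* decay
#'
#' @param signals measured intensities, one per echo
#' @param tes echo times in ms, strictly increasing, same length as `signals`
#' @param cap upper bound (ms) beyond which a fit is classified failed
#' @return list with `amplitude` (signal at TE 0), `t2star` (ms), `fit_r2`,
#'   `failed` flag and the integer failure `code` (0 = ok, 1 = non-positive
#'   signal, 2 = estimate out of range, 3 = non-convergence)
#' @export
fit_t2star_voxel <- function(signals, tes, cap = 1000) {
  if (length(signals) != length(tes))
    stop("precondition error: signals and tes must have equal length")
  if (length(tes) < 2 || any(diff(tes) <= 0))
    stop("precondition error: tes must be strictly increasing, length >= 2")
  f <- fit_t2star_signals(matrix(signals, 1), tes, cap)
  list(amplitude = f$amplitude[1], t2star = f$t2star[1],
       fit_r2 = f$fit_r2[1], failed = f$code[1] > 0L, code = f$code[1])
}

#' Fit a T2* map for one dynamic of a series
#'
#' @param series a `multi_echo_series`
#' @param dynamic index of the dynamic to fit (must be included)
#' @param mask 3D logical fit mask; default: voxels finite in every echo
#' @param cap upper T2* bound in ms (fits above are classified failed)
#' @return an object of class `t2star_map` with fields `t2star`, `amplitude`
#'   (`voxel_volume`, NA where failed), `failure_mask`, `failure_code`
#'   (0 ok, 1 non-positive signal, 2 out of range, 3 non-convergence,
#'   4 outside mask) and `fit_r2`
#' @export
fit_t2star_map <- function(series, dynamic, mask = NULL, cap = 1000) {
  if (!(dynamic %in% series$included))
    stop("precondition error: dynamic is not in included_dynamics")
  tes <- series$protocol$echo_times
  st <- series$stacks[[dynamic]]
  d3 <- dim(st[[1]]$values)
  aff <- st[[1]]$affine
  S <- vapply(st, function(v) as.vector(v$values),
              numeric(prod(d3)))
  if (is.null(mask)) mask <- array(rowSums(!is.finite(S)) == 0, d3)
  if (!any(mask)) stop("precondition error: empty fit mask")
  sel <- which(as.vector(mask))
  f <- fit_t2star_signals(S[sel, , drop = FALSE], tes, cap)
  mk <- function(vals, fill = NA_real_) {
    a <- array(fill, d3); a[sel] <- vals; a
  }
  code <- array(4L, d3)
  code[sel] <- f$code
  structure(list(
    t2star = voxel_volume(mk(f$t2star), aff),
    amplitude = voxel_volume(mk(f$amplitude), aff),
    failure_mask = code != 0L,
    failure_code = code,
    fit_r2 = mk(f$fit_r2)),
    class = "t2star_map")
}

#' Write a T2* map and its companions as NIfTI
#' @param map a `t2star_map`
#' @param path output path of the T2* map; amplitude, failure-code and
#'   fit-r2 companions are written alongside
#' @return the path, invisibly
#' @export
write_t2star_map <- function(map, path) {
  write_volume(map$t2star, path)
  stem <- sub("(\\.nii(\\.gz)?)$", "", path)
  ext <- sub(sprintf("^%s", gsub("([.\\\\])", "\\\\\\1", stem)), "", path)
  write_volume(map$amplitude, paste0(stem, "_amplitude", ext))
  write_nifti_array(map$failure_code, map$t2star$affine,
                    paste0(stem, "_failcode", ext), datatype = "int16")
  write_nifti_array(map$fit_r2, map$t2star$affine,
                    paste0(stem, "_fitr2", ext))
  invisible(path)
}
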