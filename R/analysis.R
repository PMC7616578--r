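#' Organ-wise T2* statistics
#'
#' Per-organ mean, median and SD of T2* over valid voxels only (voxels
#' where the fit failed, or that are non-finite, are excluded), plus valid
#' voxel counts and organ volumes. Labels on a different grid are resampled
#' to the T2* grid by nearest neighbor (label ids are never interpolated).
#' An organ with zero valid voxels is flagged missing, never reported as 0.
#'
#' @param t2s a `t2star_map`, or a `voxel_volume` of T2* values (e.g. a
#'   propagated reconstruction; its mask, if any, marks valid voxels)
#' @param labels a `label_map`
#' @param failure_mask optional 3D logical (TRUE = invalid voxel),
#'   overriding the mask carried by `t2s`
#' @param erode morphological erosion steps applied to each organ mask
#'   before sampling (interior sampling, limiting partial-volume
#'   contamination at organ boundaries); 0 = use every labeled voxel.
#'   Organ voxel counts and volumes always refer to the uneroded organ.
#' @return data.frame of class `organ_stats` with one row per organ:
#'   `organ`, `label`, `mean_t2s`, `median_t2s`, `sd_t2s`, `valid_voxels`,
#'   `organ_voxels`, `volume_mm3`, `missing`
#' @export
organ_stats <- function(t2s, labels, failure_mask = NULL, erode = 0) {
  if (inherits(t2s, "t2star_map")) {
    vol <- t2s$t2star
    invalid <- t2s$failure_mask
  } else if (inherits(t2s, "voxel_volume")) {
    vol <- t2s
    invalid <- !volume_mask(t2s)
  } else stop("t2s must be a t2star_map or voxel_volume")
  if (!is.null(failure_mask)) invalid <- failure_mask
  invalid <- invalid | !is.finite(vol$values)

  lab <- labels$labels
  if (!all(dim(lab) == dim(vol$values)) ||
      !affines_equal(labels$affine, vol$affine)) {
    lv <- resample_volume(voxel_volume(labels$labels + 0, labels$affine),
                          vol$affine, dim(vol$values), nearest = TRUE)
    lab <- array(as.integer(ifelse(is.na(lv$values), 0L, lv$values)),
                 dim(vol$values))
  }
  vvol <- prod(voxel_spacing(vol$affine))
  dict <- labels$dictionary
  rows <- lapply(names(dict), function(organ) {
    id <- dict[[organ]]
    inorgan <- lab == id
    sample_mask <- if (erode > 0) erode_mask(inorgan, erode) else inorgan
    if (!any(sample_mask)) sample_mask <- inorgan  # never lose a small organ
    vals <- vol$values[sample_mask & !invalid]
    n <- length(vals)
    data.frame(organ = organ, label = id,
               mean_t2s = if (n > 0) mean(vals) else NA_real_,
               median_t2s = if (n > 0) stats::median(vals) else NA_real_,
               sd_t2s = if (n > 1) stats::sd(vals) else
                 if (n == 1) 0 else NA_real_,
               valid_voxels = n,
               organ_voxels = sum(inorgan),
               volume_mm3 = sum(inorgan) * vvol,
               missing = n == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("organ_stats", "data.frame")
  out
}

#' Two-standard-deviation reconstruction equivalence check
#'
#' The reconstruction-derived mean is considered equal to the per-dynamic
#' means when it lies within two standard deviations of them: the interval
#' is `pooled_mean +/- 2 * sigma` with `sigma` the SD of the dynamic means
#' (sample SD, n-1 denominator, by default) and the check uses the closed
#' interval. Scale-invariant: rescaling all inputs preserves the outcome.
#'
#' @param dynamic_means mean T2* of the organ in each dynamic (ms), >= 2
#' @param recon_value mean T2* of the organ in the reconstructed volume (ms)
#' @param sd_denominator `"n-1"` (sample SD, default) or `"n"`
#' @return list of class `equivalence_result`: `dynamic_means`,
#'   `pooled_mean`, `sigma`, `interval` (lower, upper), `recon_value`,
#'   `pass`
#' @export
equivalence_check <- function(dynamic_means, recon_value,
                              sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  dynamic_means <- as.numeric(dynamic_means)
  if (length(dynamic_means) < 2 || !all(is.finite(dynamic_means)))
    stop("precondition error: need >= 2 finite dynamic means")
  if (!is.finite(recon_value))
    stop("precondition error: recon_value must be finite")
  m <- mean(dynamic_means)
  s <- stats::sd(dynamic_means)
  if (sd_denominator == "n") {
    n <- length(dynamic_means)
    s <- s * sqrt((n - 1) / n)
  }
  interval <- c(m - 2 * s, m + 2 * s)
  structure(list(dynamic_means = dynamic_means, pooled_mean = m, sigma = s,
                 interval = interval, recon_value = recon_value,
                 pass = recon_value >= interval[1] &
                   recon_value <= interval[2]),
            class = "equivalence_result")
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf("mean %.2f, 2-sigma range %.1f - %.1f, reconstruction %.2f: %s\n",
              x$pooled_mean, x$interval[1], x$interval[2], x$recon_value,
              if (x$pass) "equal (within 2 SD)" else "NOT equal"))
  invisible(x)
}

#' Dice similarity coefficient for one label
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty. Symmetric in its arguments.
#'
#' @param a,b `label_map`s on the same grid
#' @param label label id to compare
#' @return Dice coefficient in `[0, 1]`
#' @export
dice <- function(a, b, label) {
  if (!all(dim(a$labels) == dim(b$labels)) ||
      !affines_equal(a$affine, b$affine))
    stop("geometry error: label maps must share a grid")
  ma <- a$labels == label
  mb <- b$labels == label
  denom <- sum(ma) + sum(mb)
  if (denom == 0) return(1)
  2 * sum(ma & mb) / denom
}

#' Linear T2*-against-GA growth curve for one organ
#'
#' Ordinary least squares of organ T2* on gestational age, summarized by
#' the slope, intercept and the signed coefficient of determination
#' `sign(slope) * R^2` (so decreasing organs carry a negative value).
#'
#' @param ga gestational ages in weeks (n >= 3, not all equal)
#' @param values organ mean T2* in ms, same length
#' @param organ optional organ name carried into the result
#' @return list of class `growth_curve_fit`: `organ`, `slope` (ms/week),
#'   `intercept` (ms at GA 0), `signed_r2`, `slope_se`, `n_subjects`
#' @export
growth_curve <- function(ga, values, organ = NA_character_) {
  keep <- is.finite(ga) & is.finite(values)
  ga <- ga[keep]; values <- values[keep]
  if (length(ga) < 3)
    stop("precondition error: need >= 3 subjects with finite values")
  if (stats::sd(ga) == 0)
    stop("precondition error: gestational ages must not all be equal")
  if (stats::sd(values) == 0) {
    return(structure(list(organ = organ, slope = 0, intercept = values[1],
                          signed_r2 = 0, slope_se = 0,
                          n_subjects = length(ga)),
                     class = "growth_curve_fit"))
  }
  fit <- stats::lm(values ~ ga)
  slope <- unname(stats::coef(fit)[2])
  sm <- suppressWarnings(summary(fit))  # exact fits are expected here
  r2 <- sm$r.squared
  se <- sm$coefficients[2, 2]
  structure(list(organ = organ, slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 signed_r2 = sign(slope) * r2,
                 slope_se = se,
                 n_subjects = length(ga)),
            class = "growth_curve_fit")
}

#' @export
print.growth_curve_fit <- function(x, ...) {
  cat(sprintf("%s: slope %.3f ms/week, signed R^2 %.2f (n = %d)\n",
              x$organ %||% "organ", x$slope, x$signed_r2, x$n_subjects))
  invisible(x)
}

#' Growth curves for a cohort of subjects
#'
#' One linear fit per organ of mean T2* against GA. Subjects missing an
#' organ are skipped (and counted); an organ with fewer than 3 valid
#' subjects is reported as not fittable rather than failing the run.
#'
#' @param cohort data.frame with columns `subject`, `ga`, `organ`,
#'   `mean_t2s` (e.g. rows of [organ_stats()] augmented with GA)
#' @param organs organ names to fit (default: all present)
#' @param csv optional path: write the fit table as CSV
#' @param figure optional path: write a panel figure (PNG) of the curves
#' @return data.frame with one row per organ: `organ`, `slope`,
#'   `intercept`, `signed_r2`, `slope_se`, `n_subjects`, `fittable`
#' @export
cohort_curves <- function(cohort, organs = NULL, csv = NULL, figure = NULL) {
  stopifnot(all(c("subject", "ga", "organ", "mean_t2s") %in% names(cohort)))
  organs <- organs %||% unique(cohort$organ)
  rows <- lapply(organs, function(og) {
    sub <- cohort[cohort$organ == og & is.finite(cohort$mean_t2s), ]
    if (nrow(sub) < 3 || stats::sd(sub$ga) == 0)
      return(data.frame(organ = og, slope = NA_real_, intercept = NA_real_,
                        signed_r2 = NA_real_, slope_se = NA_real_,
                        n_subjects = nrow(sub), fittable = FALSE,
                        stringsAsFactors = FALSE))
    f <- growth_curve(sub$ga, sub$mean_t2s, og)
    data.frame(organ = og, slope = f$slope, intercept = f$intercept,
               signed_r2 = f$signed_r2, slope_se = f$slope_se,
               n_subjects = f$n_subjects, fittable = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(csv))
    utils::write.csv(out, csv, row.names = FALSE)
  if (!is.null(figure)) {
    grDevices::png(figure, width = 1500, height = 600 *
                     ceiling(length(organs) / 5), res = 120)
    old <- graphics::par(mfrow = c(ceiling(length(organs) / 5), 5),
                         mar = c(4, 4, 2, 1))
    on.exit({ graphics::par(old); grDevices::dev.off() }, add = TRUE)
    for (og in organs) {
      sub <- cohort[cohort$organ == og & is.finite(cohort$mean_t2s), ]
      fit <- out[out$organ == og, ]
      graphics::plot(sub$ga, sub$mean_t2s, pch = 19, col = "steelblue",
                     xlab = "GA (weeks)", ylab = "mean T2* (ms)",
                     main = sprintf("%s (signed R2: %.2f)", og,
                                    fit$signed_r2))
      if (isTRUE(fit$fittable))
        graphics::abline(fit$intercept, fit$slope, col = "firebrick")
    }
  }
  out
}
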