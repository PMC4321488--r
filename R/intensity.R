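# Pseudo-Wilson statistics on raw partial intensities.
#
# For each frame we regress ln(I_partial) on (sin theta / lambda)^2 by
# ordinary least squares. The gradient equals -2B (B: pseudo-Wilson
# temperature factor, A^2) and the intercept is ln G (G: per-frame scale).
# "Pseudo" because the intensities are partial and unnormalized: no
# multiplicity/epsilon normalization and no partiality correction is
# applied. Natural logarithms throughout; non-positive intensities are
# dropped (and counted), not offset-shifted.

#' Squared scattering vector (sin theta / lambda)^2 of reflections
#'
#' Computed from the reciprocal metric: 1/d^2 = h' G^{-1} h with G the
#' real-space metric tensor, and s^2 = 1/(4 d^2).
#'
#' @param cell A unit cell.
#' @param hkl Matrix or data frame with columns `h`, `k`, `l` (integers, not
#'   all zero per row).
#' @return Numeric vector of s^2 values in 1/A^2.
#' @examples
#' reflection_s2(unit_cell(10, 10, 10), data.frame(h = 1, k = 0, l = 0))
#' @export
reflection_s2 <- function(cell, hkl) {
  if (is.data.frame(hkl)) hkl <- as.matrix(hkl[, c("h", "k", "l")])
  hkl <- matrix(as.numeric(hkl), ncol = 3)
  if (any(rowSums(hkl != 0) == 0)) abort("(0,0,0) is not a valid reflection")
  G <- metric_tensor(cell)
  Gstar <- tryCatch(solve(G), error = function(e) abort("invalid unit cell: singular metric tensor"))
  inv_d2 <- rowSums((hkl %*% Gstar) * hkl)
  inv_d2 / 4
}

#' Pseudo-Wilson fit for one set of reflections
#'
#' Ordinary least squares of ln(I) on s^2. Reflections with non-positive
#' intensity are dropped and counted. If fewer than `min_reflections`
#' positive intensities remain, or s^2 has zero variance, the fit is refused
#' (`ok = FALSE`, estimates `NA`) rather than raising an error, so refused
#' frames can be excluded and logged at the aggregate level.
#'
#' @param s2 Squared scattering vectors (1/A^2).
#' @param intensity Raw partial intensities (same length).
#' @param min_reflections Minimum number of positive intensities (default 10).
#' @return One-row tibble: `n_used`, `n_dropped_nonpositive`, `slope`,
#'   `intercept`, `se_slope`, `se_intercept`, `b` (= -slope/2), `g`
#'   (= exp(intercept)), `ok`.
#' @export
wilson_fit <- function(s2, intensity, min_reflections = 10) {
  stopifnot(length(s2) == length(intensity))
  keep <- is.finite(intensity) & intensity > 0 & is.finite(s2)
  n_dropped <- sum(is.finite(intensity) & intensity <= 0)
  x <- s2[keep]; y <- log(intensity[keep])
  refused <- tibble(
    n_used = length(x), n_dropped_nonpositive = n_dropped,
    slope = NA_real_, intercept = NA_real_,
    se_slope = NA_real_, se_intercept = NA_real_,
    b = NA_real_, g = NA_real_, ok = FALSE
  )
  if (length(x) < min_reflections) return(refused)
  if (var(x) == 0) return(refused)
  fit <- lm(y ~ x)
  # summary.lm warns on exactly log-linear (noiseless) input; that case is
  # legitimate here and the zero standard errors are the right answer
  cf <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  tibble(
    n_used = length(x), n_dropped_nonpositive = n_dropped,
    slope = cf["x", "Estimate"], intercept = cf["(Intercept)", "Estimate"],
    se_slope = cf["x", "Std. Error"], se_intercept = cf["(Intercept)", "Std. Error"],
    b = -cf["x", "Estimate"] / 2, g = exp(cf["(Intercept)", "Estimate"]),
    ok = TRUE
  )
}

#' Per-frame pseudo-Wilson fits
#'
#' Applies [wilson_fit()] to every frame with a reflection table, computing
#' s^2 from the frame's own (reported) unit cell. Frames without reflections
#' or with a refused fit are kept in the output with `ok = FALSE`.
#'
#' @param frames A frames tibble (see [frames_tbl()]).
#' @param min_reflections Minimum positive reflections per fit.
#' @return Tibble with one row per frame: `frame_id` plus the [wilson_fit()]
#'   columns.
#' @export
wilson_fits <- function(frames, min_reflections = 10) {
  stopifnot(is.data.frame(frames), "reflections" %in% names(frames))
  purrr::map_dfr(seq_len(nrow(frames)), function(i) {
    refl <- frames$reflections[[i]]
    if (is.null(refl) || nrow(refl) == 0) {
      fit <- wilson_fit(numeric(0), numeric(0), min_reflections)
    } else {
      s2 <- reflection_s2(unlist(frames[i, CELL_PARS]), refl)
      fit <- wilson_fit(s2, refl$i_partial, min_reflections)
    }
    dplyr::bind_cols(tibble(frame_id = frames$frame_id[i]), fit)
  })
}

#' Rolling average of a pseudo-Wilson point cloud
#'
#' Sorts points by s^2 and computes the moving mean of both coordinates over
#' a sliding window of `window` consecutive points; the result has
#' `n - window + 1` rows. With `window = 1` the (sorted) input is returned
#' unchanged.
#'
#' @param data Data frame with columns `s2` and `log_i`.
#' @param window Window size in points (default 50; must not exceed `n`).
#' @return Tibble with smoothed `s2`, `log_i`.
#' @export
rolling_average <- function(data, window = 50) {
  stopifnot(all(c("s2", "log_i") %in% names(data)))
  n <- nrow(data)
  if (window < 1 || window > n) abort("window must be between 1 and the number of points")
  data <- dplyr::arrange(as_tibble(data), .data$s2)
  roll <- function(v) {
    cs <- cumsum(c(0, v))
    (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  }
  tibble(s2 = roll(data$s2), log_i = roll(data$log_i))
}

#' Aggregate intensity statistics over all frames
#'
#' Per-frame pseudo-Wilson fits, the pooled (s^2, ln I) point cloud over all
#' frames, a pooled OLS line, and robust outlier flags on the per-frame
#' gradient/intercept. The pooled slope sign summarizes the overall trend
#' (well-behaved data decreases with scattering angle).
#'
#' @inheritParams wilson_fits
#' @param robust_z Robust z threshold for [flag_outlier_frames()].
#' @param window Default rolling-average window used by the plot method.
#' @return An `intensity_stats` object: list with `fits` (flagged), `pooled`
#'   (tibble `frame_id`, `s2`, `log_i`), `pooled_fit`, `trend`, `window`.
#' @export
aggregate_intensity <- function(frames, min_reflections = 10, robust_z = 3.5,
                                window = 50) {
  fits <- wilson_fits(frames, min_reflections = min_reflections)
  if (!any(fits$ok)) abort("no frame yielded an eligible pseudo-Wilson fit")
  if (sum(fits$ok) >= 5) {
    fits <- flag_outlier_frames(fits, robust_z = robust_z)
  } else {
    fits$flag_slope <- fits$flag_intercept <- fits$flagged <- NA
  }
  pooled <- purrr::map_dfr(seq_len(nrow(frames)), function(i) {
    refl <- frames$reflections[[i]]
    if (is.null(refl) || nrow(refl) == 0) return(NULL)
    keep <- is.finite(refl$i_partial) & refl$i_partial > 0
    if (!any(keep)) return(NULL)
    s2 <- reflection_s2(unlist(frames[i, CELL_PARS]), refl[keep, ])
    tibble(frame_id = frames$frame_id[i], s2 = s2, log_i = log(refl$i_partial[keep]))
  })
  pf <- wilson_fit(pooled$s2, pooled$log_i |> exp(), min_reflections = 2)
  structure(
    list(fits = fits, pooled = pooled, pooled_fit = pf,
         trend = sign(pf$slope), window = window),
    class = "intensity_stats"
  )
}

#' @export
print.intensity_stats <- function(x, ...) {
  cat(sprintf("Pseudo-Wilson intensity statistics: %d/%d frames fit, %d flagged\n",
              sum(x$fits$ok), nrow(x$fits), sum(x$fits$flagged, na.rm = TRUE)))
  cat(sprintf("  pooled slope %.4g (trend %s), pooled intercept %.4g\n",
              x$pooled_fit$slope, if (x$trend < 0) "decreasing" else "increasing",
              x$pooled_fit$intercept))
  invisible(x)
}

#' @describeIn aggregate_intensity Per-frame fit table (the `fits` element).
#' @param x An `intensity_stats` object.
#' @param ... Unused.
#' @export
tidy.intensity_stats <- function(x, ...) x$fits

#' @describeIn aggregate_intensity One-row overview: counts, pooled slope and
#'   intercept, median B and G across fitted frames.
#' @export
glance.intensity_stats <- function(x, ...) {
  okfits <- dplyr::filter(x$fits, .data$ok)
  tibble(
    n_frames = nrow(x$fits),
    n_fit = nrow(okfits),
    n_flagged = sum(x$fits$flagged, na.rm = TRUE),
    pooled_slope = x$pooled_fit$slope,
    pooled_intercept = x$pooled_fit$intercept,
    median_b = median(okfits$b),
    median_g = median(okfits$g)
  )
}

#' Flag frames with aberrant pseudo-Wilson fits
#'
#' A frame is flagged when the robust z score of its gradient *or* its
#' intercept exceeds the threshold: |x - median| / (1.4826 MAD) > robust_z.
#' Extreme values of either are the signature of mis-indexing. If the MAD of
#' a statistic is zero while values differ, the filter falls back to
#' exact-match comparison against the median (and says so).
#'
#' @param fits Tibble from [wilson_fits()] (needs >= 5 successful fits).
#' @param robust_z Threshold (default 3.5).
#' @return `fits` with logical columns `flag_slope`, `flag_intercept`,
#'   `flagged` added; the surviving subset is available as attribute
#'   `survivors`.
#' @export
flag_outlier_frames <- function(fits, robust_z = 3.5) {
  ok <- fits$ok
  if (sum(ok) < 5L) abort("need at least 5 successful fits to flag outliers")
  robust_flag <- function(x) {
    med <- median(x)
    s <- mad(x)              # 1.4826 * median absolute deviation
    if (s == 0) {
      if (any(x != med)) {
        inform("flag_outlier_frames: zero MAD with non-identical values; falling back to exact-match filtering")
        return(x != med)
      }
      return(rep(FALSE, length(x)))
    }
    abs(x - med) / s > robust_z
  }
  fs <- fi <- rep(NA, nrow(fits))
  fs[ok] <- robust_flag(fits$slope[ok])
  fi[ok] <- robust_flag(fits$intercept[ok])
  fits$flag_slope <- fs
  fits$flag_intercept <- fi
  fits$flagged <- ifelse(ok, fs | fi, NA)
  attr(fits, "survivors") <- fits[which(ok & !(fs | fi)), , drop = FALSE]
  fits
}

#' @describeIn aggregate_intensity Super-plot of all partial log intensities
#'   against s^2 with rolling average and pooled fit line.
#' @param object An `intensity_stats` object.
#' @export
autoplot.intensity_stats <- function(object, ...) {
  win <- min(object$window, nrow(object$pooled))
  ra <- rolling_average(object$pooled, window = win)
  ggplot2::ggplot(object$pooled, ggplot2::aes(x = .data$s2, y = .data$log_i)) +
    ggplot2::geom_point(size = 0.2, alpha = 0.15) +
    ggplot2::geom_line(data = ra, color = "orange", linewidth = 0.8) +
    ggplot2::geom_abline(intercept = object$pooled_fit$intercept,
                         slope = object$pooled_fit$slope, color = "red") +
    ggplot2::labs(x = expression((sin~theta/lambda)^2 ~ ("Å"^-2)),
                  y = expression(ln~I[partial]),
                  title = "Pooled pseudo-Wilson plot") +
    ggplot2::theme_minimal()
}

#' Pseudo-Wilson plot for a single frame
#'
#' log intensity against s^2 for one frame, with the rolling average and the
#' per-frame OLS line.
#'
#' @param frame One-row frames tibble (or a row index into `frames`).
#' @param min_reflections,window As elsewhere.
#' @return A ggplot object.
#' @export
plot_frame_intensity <- function(frame, min_reflections = 10, window = 50) {
  stopifnot(is.data.frame(frame), nrow(frame) == 1L)
  refl <- frame$reflections[[1]]
  if (is.null(refl) || nrow(refl) == 0) abort("frame has no reflections")
  keep <- refl$i_partial > 0
  pts <- tibble(s2 = reflection_s2(unlist(frame[1, CELL_PARS]), refl[keep, ]),
                log_i = log(refl$i_partial[keep]))
  fit <- wilson_fit(pts$s2, exp(pts$log_i), min_reflections)
  win <- min(window, nrow(pts))
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$s2, y = .data$log_i)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::geom_line(data = rolling_average(pts, win), color = "orange") +
    ggplot2::labs(x = expression((sin~theta/lambda)^2 ~ ("Å"^-2)),
                  y = expression(ln~I[partial]),
                  title = sprintf("Frame %s pseudo-Wilson plot", frame$frame_id)) +
    ggplot2::theme_minimal()
  if (isTRUE(fit$ok)) {
    p <- p + ggplot2::geom_abline(intercept = fit$intercept, slope = fit$slope,
                                  color = "red") +
      ggplot2::labs(subtitle = sprintf("B = %.2f Å², G = %.3g", fit$b, fit$g))
  }
  p
}

#' Histograms of per-frame gradients and standard errors
#'
#' @param fits Tibble from [wilson_fits()].
#' @return A ggplot object (faceted histograms of slope, intercept and their
#'   standard errors).
#' @export
plot_fit_histograms <- function(fits) {
  okfits <- dplyr::filter(fits, .data$ok)
  long <- okfits |>
    dplyr::select("slope", "intercept", "se_slope", "se_intercept") |>
    tidyr::pivot_longer(dplyr::everything())
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::facet_wrap(~ name, scales = "free") +
    ggplot2::labs(x = NULL, y = "frames",
                  title = "Per-frame pseudo-Wilson fit statistics") +
    ggplot2::theme_minimal()
}
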