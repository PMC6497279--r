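# How many frames are enough? Two lines of evidence, mirroring standard
# practice for subsample-size selection:
#   1. LOWESS-smooth diversity against log10 sample size and find where the
#      smoothed curve levels off (slope below a tolerance per decade);
#   2. regress the replicate coefficient of variation on log10 sample size
#      and find the smallest size whose predicted CV falls below a
#      threshold (default 25%).
# The recommendation takes the more conservative of the two.

#' LOWESS fit of diversity against log10 sample size
#'
#' Locally weighted scatterplot smoothing: local linear fits with tricube
#' weights over the `span` nearest neighbours, with optional robustness
#' reweighting iterations. Wraps [stats::lowess()] with `delta = 0` so a
#' fitted value is produced at every observed x.
#'
#' @param x,y Numeric vectors (at least 3 points).
#' @param span Fraction of points in each local window, in (0, 1];
#'   default 2/3.
#' @param n_robust_iters Robustness iterations (default 0).
#' @return A `lowess_fit` list with sorted `x`, `fitted`, and the
#'   parameters used.
#' @export
lowess_fit <- function(x, y, span = 2/3, n_robust_iters = 0) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("lowess_fit needs at least 3 finite points",
                          call. = FALSE)
  if (span <= 0 || span > 1) stop("span must be in (0, 1]", call. = FALSE)
  if (ceiling(span * length(x)) < 2) {
    stop("local window has fewer than 2 points; increase span",
         call. = FALSE)
  }
  fit <- stats::lowess(x, y, f = span, iter = n_robust_iters, delta = 0)
  structure(list(x = fit$x, fitted = fit$y, span = span,
                 n_robust_iters = n_robust_iters),
            class = "lowess_fit")
}

#' Detect the plateau of a smoothed diversity curve
#'
#' Returns `n* = 10^x0` for the smallest observed `x0` such that every
#' subsequent segment of the smoothed curve has slope below `slope_tol`
#' (diversity units per decade of sample size). `NA` when the curve never
#' levels off.
#'
#' @param fit A [lowess_fit()] on (log10 n, diversity) points.
#' @param slope_tol Plateau slope tolerance; default 0.05 per decade.
#' @return Plateau sample size in frames (integer), or `NA`.
#' @export
detect_plateau <- function(fit, slope_tol = 0.05) {
  stopifnot(inherits(fit, "lowess_fit"))
  x <- fit$x; y <- fit$fitted
  keep <- !duplicated(x)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("plateau detection needs >= 3 distinct x",
                          call. = FALSE)
  slopes <- diff(y) / diff(x)
  flat <- slopes < slope_tol
  # smallest x whose suffix of slopes is entirely flat
  ok_from <- rev(cumprod(rev(flat))) > 0
  if (!any(ok_from)) return(NA_integer_)
  as.integer(round(10^x[which(ok_from)[1]]))
}

#' Replicate coefficient of variation by sample size
#'
#' @param curve A `diversity_curve` from [run_design()].
#' @param index Which index to summarize, `"N2"` (default) or `"H"`.
#' @return Tibble with columns n (mean realized frames), mean, sd,
#'   cv (= sd/mean, `NA` when the mean is 0). Replicates are grouped by
#'   nominal size for random designs and by interval for systematic
#'   designs (random starts shift the realized size by one frame).
#' @export
cv_by_size <- function(curve, index = c("N2", "H")) {
  index <- match.arg(index)
  vals <- curve[[index]]
  key <- if (all(curve$kind == "systematic")) curve$interval else curve$n_frames
  sizes <- sort(unique(key))
  out <- lapply(sizes, function(s) {
    sel <- key == s
    v <- vals[sel]
    if (length(v) < 2) {
      stop("need >= 2 replicates per size to compute a CV (size ", s, ")",
           call. = FALSE)
    }
    m <- mean(v, na.rm = TRUE)
    s2 <- sd(v, na.rm = TRUE)
    tibble::tibble(n = mean(curve$n_frames[sel]), mean = m, sd = s2,
                   cv = if (isTRUE(m == 0)) NA_real_ else s2 / m)
  })
  out <- dplyr::bind_rows(out)
  out[order(out$n), ]
}

#' Linear CV model on log10 sample size
#'
#' Ordinary least squares of CV on log10(n), one point per size, and the
#' smallest integer size whose predicted CV falls at or below the
#' threshold.
#'
#' @param cv_table Output of [cv_by_size()].
#' @param threshold Acceptable CV; default 0.25 (25%).
#' @return List with slope, intercept, r_squared, threshold and `n_cv`
#'   (`NA` when the fitted line never reaches the threshold).
#' @export
fit_cv_model <- function(cv_table, threshold = 0.25) {
  tab <- cv_table[is.finite(cv_table$cv), ]
  if (nrow(tab) < 3) stop("need >= 3 sizes with a defined CV", call. = FALSE)
  lx <- log10(tab$n)
  if (length(unique(lx)) < 2) stop("degenerate sizes: all equal", call. = FALSE)
  fit <- stats::lm(tab$cv ~ lx)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  ss_tot <- sum((tab$cv - mean(tab$cv))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  n_min <- min(tab$n)
  pred_min <- intercept + slope * log10(n_min)
  n_cv <- if (pred_min <= threshold) {
    as.integer(round(n_min))
  } else if (slope < 0) {
    as.integer(ceiling(10^((threshold - intercept) / slope)))
  } else {
    NA_integer_
  }
  list(slope = slope, intercept = intercept, r_squared = r2,
       threshold = threshold, n_cv = n_cv)
}

#' Sampling-sufficiency report
#'
#' Combines LOWESS plateau detection on replicate (log10 n, diversity)
#' points with the CV-threshold rule, and converts the more conservative
#' recommended size into a frame interval for production annotation.
#'
#' @param curve A `diversity_curve` from [run_design()].
#' @param n_total Total frames in the full sequence the curve subsampled.
#' @param index `"N2"` (default) or `"H"`.
#' @param span,n_robust_iters LOWESS parameters (see [lowess_fit()]).
#' @param slope_tol Plateau slope tolerance per decade (default 0.05).
#' @param cv_threshold Acceptable CV (default 0.25).
#' @return A `sufficiency_report` list: n_star, cv fit, n_cv,
#'   n_recommended = max(n_star, n_cv), recommended_interval =
#'   floor(n_total / n_recommended), plus the smoothed curve and CV table.
#' @export
sufficiency_report <- function(curve, n_total, index = c("N2", "H"),
                               span = 2/3, n_robust_iters = 0,
                               slope_tol = 0.05, cv_threshold = 0.25) {
  index <- match.arg(index)
  vals <- curve[[index]]
  ok <- is.finite(vals) & curve$n_frames > 0
  fit <- lowess_fit(log10(curve$n_frames[ok]), vals[ok],
                    span = span, n_robust_iters = n_robust_iters)
  n_star <- detect_plateau(fit, slope_tol)
  cvt <- cv_by_size(curve, index)
  cvm <- fit_cv_model(cvt, cv_threshold)
  n_rec <- suppressWarnings(max(c(n_star, cvm$n_cv), na.rm = TRUE))
  if (!is.finite(n_rec)) n_rec <- NA_integer_
  interval <- if (is.na(n_rec)) NA_integer_ else
    max(1L, as.integer(floor(n_total / n_rec)))
  structure(list(
    index = index, n_total = n_total,
    n_star = n_star, slope_tol = slope_tol,
    cv_fit = cvm[c("slope", "intercept", "r_squared")],
    cv_threshold = cv_threshold, n_cv = cvm$n_cv,
    n_recommended = as.integer(n_rec),
    recommended_interval = interval,
    smoothed = tibble::tibble(log10_n = fit$x, fitted = fit$fitted),
    cv_table = cvt
  ), class = "sufficiency_report")
}

#' @export
print.sufficiency_report <- function(x, ...) {
  cat("Sampling-sufficiency report (", x$index, ")\n", sep = "")
  cat("  full sequence:        ", x$n_total, " frames\n", sep = "")
  cat("  LOWESS plateau n*:    ", x$n_star, " frames (slope tol ",
      x$slope_tol, "/decade)\n", sep = "")
  cat("  CV model:             cv = ", signif(x$cv_fit$intercept, 4), " + ",
      signif(x$cv_fit$slope, 4), " * log10(n),  R^2 = ",
      signif(x$cv_fit$r_squared, 3), "\n", sep = "")
  cat("  CV <= ", 100 * x$cv_threshold, "% at n_cv: ", x$n_cv,
      " frames\n", sep = "")
  cat("  recommended:          n >= ", x$n_recommended,
      " frames, i.e. every ", x$recommended_interval, "th frame\n", sep = "")
  invisible(x)
}

#' Serialize a sufficiency report to JSON
#'
#' @param report A `sufficiency_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sufficiency_report <- function(report, path) {
  x <- unclass(report)
  x$smoothed <- NULL
  x$cv_table <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
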