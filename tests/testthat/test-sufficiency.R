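test_that("LOWESS reproduces lines exactly and agrees with a direct-summation oracle", {
  x <- seq(0, 4, length.out = 40)
  y <- 2 + 0.5 * x
  fit <- lowess_fit(x, y, span = 0.5)
  expect_equal(fit$fitted, 2 + 0.5 * fit$x, tolerance = 1e-9)

  yc <- rep(3.2, 40)
  expect_equal(lowess_fit(x, yc)$fitted, rep(3.2, 40), tolerance = 1e-9)

  # noisy logistic-shaped curve against an independently coded tricube
  # local-linear smoother; agreement within the noise envelope
  withr::local_seed(5)
  x2 <- sort(runif(50, 0, 4))
  truth <- 2 / (1 + exp(-3 * (x2 - 2)))
  y2 <- truth + rnorm(50, sd = 0.08)
  fit2 <- lowess_fit(x2, y2, span = 0.5)
  oracle <- oracle_tricube_smooth(x2, y2, 0.5)
  expect_equal(fit2$fitted, oracle, tolerance = 0.02)
  expect_lt(max(abs(fit2$fitted - truth)), 0.25)

  # permutation invariance of fitted values at matching x
  p <- sample(50)
  fit3 <- lowess_fit(x2[p], y2[p], span = 0.5)
  expect_equal(fit3$fitted, fit2$fitted)

  expect_error(lowess_fit(1:2, 1:2), "at least 3")
  expect_error(lowess_fit(1:10, 1:10, span = 0.05), "span")
})

test_that("plateau detection finds constructed level-off points", {
  # piecewise curve rising to flat at x = 2.5
  x <- seq(1, 4, by = 0.1)
  y <- pmin(x, 2.5)
  fit <- structure(list(x = x, fitted = y, span = NA, n_robust_iters = 0),
                   class = "lowess_fit")
  expect_equal(detect_plateau(fit, 0.05), as.integer(round(10^2.5)))
  # strictly rising line steeper than the tolerance: no plateau
  fit2 <- structure(list(x = x, fitted = 0.2 * x, span = NA, n_robust_iters = 0),
                    class = "lowess_fit")
  expect_true(is.na(detect_plateau(fit2, 0.05)))
  expect_equal(detect_plateau(fit2, 0.3), as.integer(round(10^x[1])))
  # monotone in the tolerance: larger tol never gives larger n*
  withr::local_seed(8)
  xs <- seq(1, 3.5, length.out = 30)
  ys <- cumsum(abs(rnorm(30, 0.05, 0.05)))
  fit3 <- structure(list(x = xs, fitted = ys, span = NA, n_robust_iters = 0),
                    class = "lowess_fit")
  tols <- c(0.02, 0.05, 0.1, 0.3, 0.8)
  ns <- vapply(tols, function(t) {
    n <- detect_plateau(fit3, t)
    if (is.na(n)) Inf else as.numeric(n)
  }, numeric(1))
  expect_true(all(ns[-1] <= ns[-length(ns)]))
})

test_that("replicate CV tables match hand and two-pass computations", {
  curve <- tibble::tibble(
    kind = "random",
    interval = NA_real_,
    n_frames = rep(c(10L, 20L, 40L), each = 3),
    size_nominal = n_frames,
    rep = rep(1:3, 3),
    N2 = c(1, 2, 3, 2, 2, 2, 4, 5, 6),
    H = N2
  )
  cvt <- cv_by_size(curve)
  expect_equal(cvt$mean, c(2, 2, 5))
  expect_equal(cvt$sd, c(1, 0, 1))
  expect_equal(cvt$cv, c(0.5, 0, 0.2))

  # generated curve vs independent two-pass mean/sd
  withr::local_seed(21)
  cfg <- sim_config(500, composition = c(A = 2, B = 1, C = 1),
                    organism_rate = 1, persistence_range = c(1, 1), seed = 21)
  st <- generate_frame_stream(cfg)
  curve2 <- run_design(st$records,
                       subsample_design("random", sizes = c(30, 100, 300),
                                        n_reps = 10))
  cvt2 <- cv_by_size(curve2)
  for (i in seq_len(nrow(cvt2))) {
    v <- curve2$N2[curve2$n_frames == cvt2$n[i]]
    m <- sum(v) / length(v)
    s <- sqrt(sum((v - m)^2) / (length(v) - 1))
    expect_equal(cvt2$mean[i], m)
    expect_equal(cvt2$sd[i], s)
  }
  # single replicate is an error
  expect_error(cv_by_size(curve[curve$rep == 1, ]), ">= 2 replicates")
})

test_that("the CV model inverts to the threshold crossing in closed form", {
  # exactly linear CV: R^2 = 1 and exact coefficients
  n <- c(31, 100, 316, 1000)
  cvt <- tibble::tibble(n = n, mean = 2, sd = 2 * (0.8 - 0.22 * log10(n)),
                        cv = 0.8 - 0.22 * log10(n))
  fit <- fit_cv_model(cvt, threshold = 0.25)
  expect_equal(fit$slope, -0.22)
  expect_equal(fit$intercept, 0.8)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n_cv, as.integer(ceiling(10^(0.55 / 0.22))))
  expect_equal(fit$n_cv, 317L)
  # threshold above all CVs: the smallest observed size
  fit2 <- fit_cv_model(cvt, threshold = 0.9)
  expect_equal(fit2$n_cv, 31L)
  # degenerate x
  expect_error(fit_cv_model(tibble::tibble(n = c(10, 10, 10), mean = 1,
                                           sd = 1, cv = c(0.1, 0.2, 0.3))),
               "degenerate")
})

test_that("CV decreases with sample size in expectation on synthetic streams", {
  withr::local_seed(31)
  cfg <- sim_config(2000, composition = c(A = 5, B = 3, C = 1, D = 1),
                    organism_rate = 0.7, theta = 0.5,
                    persistence_range = c(1, 1), seed = 31)
  st <- generate_frame_stream(cfg)
  curve <- run_design(st$records,
                      subsample_design("random",
                                       sizes = c(30, 60, 125, 250, 500, 1000),
                                       n_reps = 12))
  cvt <- cv_by_size(curve)
  # one-sided trend test at generous alpha
  ct <- suppressWarnings(cor.test(log10(cvt$n), cvt$cv, method = "kendall",
                                  alternative = "less"))
  expect_lt(ct$p.value, 0.1)
})

test_that("the full sufficiency report recovers the plateau of a calibrated stream", {
  # stream emulating the consecutive-frame camera test set: organism total
  # and composition from the published test-set column, transect-calibrated
  # patchiness, 3-5 frame persistence
  base <- calibrate(3035, 4393, 1463/4393)
  n_stars <- vapply(1:4, function(s) {
    cfg <- sim_config(9155, organism_rate = 339 / 9155, theta = base$theta,
                      persistence_range = c(3, 5), seed = s)
    st <- generate_frame_stream(cfg)
    withr::with_seed(s, {
      curve <- run_design(st$records, subsample_design("random", n_reps = 10))
    })
    rep <- suppressWarnings(sufficiency_report(curve, n_total = 9155))
    expect_s3_class(rep, "sufficiency_report")
    expect_true(rep$recommended_interval >= 1)
    as.numeric(rep$n_star)
  }, numeric(1))
  # seed envelope established by repeated runs of this generator and frozen
  expect_true(all(n_stars >= 100 & n_stars <= 700))
})

test_that("smoothed plateau diversity recovers the generator's true N2", {
  base <- calibrate(3035, 4393, 1463/4393, seed = 2,
                    persistence_range = c(1, 1))
  cfg <- sim_config(9155, organism_rate = base$organism_rate,
                    theta = base$theta, persistence_range = c(1, 1), seed = 2)
  st <- generate_frame_stream(cfg)
  withr::with_seed(2, {
    curve <- run_design(st$records, subsample_design("random", n_reps = 10))
  })
  rep <- sufficiency_report(curve, n_total = 9155)
  plateau_level <- utils::tail(rep$smoothed$fitted, 1)
  expect_equal(plateau_level, st$truth$N2, tolerance = 0.1)
})
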