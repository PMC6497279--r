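test_that("stream generation honors rates, composition and seeds", {
  # zero arrival rate: every frame empty
  cfg0 <- sim_config(100, composition = c(A = 1), organism_rate = 0,
                     seed = 1)
  st0 <- generate_frame_stream(cfg0)
  expect_equal(sum(as_abundance(st0$records)), 0)
  expect_equal(nrow(st0$records), 100)

  # identical configs give identical streams
  cfg <- sim_config(500, composition = c(A = 3, B = 1), organism_rate = 0.4,
                    theta = 0.7, seed = 9)
  s1 <- generate_frame_stream(cfg)
  s2 <- generate_frame_stream(cfg)
  expect_identical(s1$records, s2$records)

  # invalid compositions are rejected
  expect_error(sim_config(10, composition = c(A = -1, B = 1)), "non-negative")
  expect_error(sim_config(10, composition = c(A = 0, B = 0)), "not all zero")

  # truth carries the analytic diversity of the composition
  expect_equal(s1$truth$N2, 1 / sum(c(0.75, 0.25)^2))
  expect_equal(s1$truth$H, -sum(c(0.75, 0.25) * log(c(0.75, 0.25))))
})

test_that("the Poisson limit reproduces the closed-form occupancy", {
  lambda <- 0.35
  cfg <- sim_config(50000, composition = c(A = 1), organism_rate = lambda,
                    theta = Inf, persistence_range = c(1, 1), seed = 101)
  st <- generate_frame_stream(cfg)
  occ <- mean(st$records$A > 0)
  # Monte-Carlo tolerance: ~4 binomial SDs at n = 50000
  se <- sqrt((1 - exp(-lambda)) * exp(-lambda) / 50000)
  expect_equal(occ, 1 - exp(-lambda), tolerance = 4 * se / (1 - exp(-lambda)))
})

test_that("organism-level composition follows the law of large numbers", {
  cfg <- sim_config(30000, composition = c(A = 3, B = 1), organism_rate = 0.5,
                    persistence_range = c(1, 1), seed = 7)
  st <- generate_frame_stream(cfg)
  tab <- table(st$truth$organisms$taxon)
  p <- as.numeric(tab / sum(tab))
  expect_equal(p, c(0.75, 0.25), tolerance = 0.02)
})

test_that("pooled frame counts converge to composition diversity under persistence", {
  # taxon-independent persistence leaves pooled proportions unbiased, so
  # diversity from pooled frame counts converges to the composition's
  cfg <- sim_config(50000, composition = c(A = 6, B = 2, C = 1, D = 1),
                    organism_rate = 0.3, theta = 0.6,
                    persistence_range = c(3, 5), seed = 13)
  st <- generate_frame_stream(cfg)
  v <- as_abundance(st$records)
  expect_equal(hills_n2(v), st$truth$N2, tolerance = 0.02)
  expect_equal(shannon(v), st$truth$H, tolerance = 0.02)
})

test_that("calibration solves the negative-binomial zero probability", {
  cfg <- calibrate(3035, 4393, 1463 / 4393, persistence_range = c(1, 1),
                   seed = 3)
  cal <- attr(cfg, "calibration")
  expect_equal(cfg$organism_rate, 3035 / 4393)
  expect_lt(abs(cal$p0_achieved - cal$p0_target), 1e-6)
  expect_true(is.finite(cfg$theta))

  # generated streams reproduce the target occupancy within Monte-Carlo error
  occ <- vapply(1:20, function(s) {
    cc <- calibrate(3035, 4393, 1463 / 4393, persistence_range = c(1, 1),
                    seed = s)
    st <- generate_frame_stream(cc)
    cols <- taxon_columns(st$records)
    mean(rowSums(st$records[cols]) > 0)
  }, numeric(1))
  expect_equal(mean(occ), 1463 / 4393, tolerance = 0.02)

  # exact Poisson boundary reports the Poisson limit
  mu <- 0.5
  cfgp <- calibrate(500, 1000, 1 - exp(-mu), composition = c(A = 1))
  expect_false(is.finite(cfgp$theta))
  expect_true(attr(cfgp, "calibration")$poisson_limit)

  # occupancy above the Poisson bound is infeasible for a mixed process
  expect_error(calibrate(339, 9155, 0.27), "Poisson bound")
})

test_that("synthetic trawl catches follow the composition with optional jackpots", {
  comp <- c(dollar = 5, hermit = 3, star = 2)
  z <- generate_trawl_catches(comp, n_stations = 3, effort = 0, seed = 1)
  expect_true(all(z$count == 0))

  big <- generate_trawl_catches(comp, n_stations = 10, effort = 5000, seed = 2)
  pooled <- as_abundance(big)
  expect_equal(unname(pooled / sum(pooled)), unname(comp[names(pooled)] / sum(comp)),
               tolerance = 0.02)

  jp <- generate_trawl_catches(comp, n_stations = 10, effort = 200,
                               jackpot = list(station = 4, taxon = "dollar",
                                              multiplier = 50), seed = 3)
  div <- diversity_by_group(jp, rank = "taxon")
  n2 <- div$N2[div$group != "All"]
  names(n2) <- div$group[div$group != "All"]
  expect_equal(unname(which.min(n2[paste0("BT", 1:10)])), 4)
  expect_lt(n2[["BT4"]], 1.2)
})

test_that("end-to-end recovery: full-set and interval-30 N2 track the truth", {
  base <- calibrate(3035, 4393, 1463 / 4393)
  res <- vapply(1:10, function(s) {
    cfg <- sim_config(9155, organism_rate = base$organism_rate,
                      theta = base$theta, persistence_range = c(1, 1),
                      seed = s)
    st <- generate_frame_stream(cfg)
    full <- hills_n2(as_abundance(st$records))
    sub <- withr::with_seed(s + 1000, {
      idx <- systematic_select(9155, 30, sample.int(30, 1))
      x <- st$records[idx, ]
      class(x) <- class(st$records)
      x
    })
    est <- hills_n2(as_abundance(sub))
    c(full_ok = abs(full - st$truth$N2) / st$truth$N2 <= 0.05,
      sub_ok = abs(est - full) / full <= 0.10)
  }, numeric(2))
  expect_true(all(res["full_ok", ] == 1))
  expect_gte(mean(res["sub_ok", ]), 0.9)
})
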