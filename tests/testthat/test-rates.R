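test_that("an exact linear series is fitted perfectly on any grid", {
  for (grid in list(seq(0, 20, 2), c(0, 1, 3, 7.5, 12, 19), seq(0, 5, 0.5))) {
    ts <- time_series(grid, 10 - 0.22 * grid, "fumarate", "ref")
    fit <- fit_rate(ts)
    expect_equal(fit$rate, 0.22, tolerance = 1e-12)
    expect_equal(fit$intercept, 10, tolerance = 1e-12)
    expect_equal(fit$r_squared, 1)
  }
})

test_that("the default window stops before depletion", {
  t <- seq(0, 60, 4)
  conc <- pmax(0, 10 - 0.25 * t)   # depleted at 40 h
  fit <- fit_rate(time_series(t, conc))
  expect_equal(fit$rate, 0.25, tolerance = 1e-12)
  expect_lt(fit$window[2], 40)
  # including the flat tail would bias the rate low; the window must not
  expect_equal(fit$n_points, sum(t < 40))
})

test_that("degenerate series are handled with warnings or errors", {
  t <- seq(0, 10, 2)
  expect_warning(f <- fit_rate(time_series(t, rep(5, length(t)))),
                 "constant")
  expect_equal(f$rate, 0)
  expect_equal(f$r_squared, 0)
  expect_warning(g <- fit_rate(time_series(t, 1 + 0.1 * t)), "positive")
  expect_equal(g$rate, 0)
  expect_error(fit_rate(time_series(t, 10 - t), window = c(0, 1)),
               "fewer than 2")
  expect_error(time_series(c(0, 0, 1), c(1, 1, 1)), "strictly increasing")
})

test_that("segmented fits recover a two-regime curve exactly", {
  t <- seq(0, 40, 2)
  truth <- consumption_truth("fumarate", c0 = 10, true_rate = 0.16,
                             times = t, breakpoint = 22, rate_after = 0.057)
  ts <- simulate_consumption_series(truth, seed = 1)
  seg <- segmented_rates(ts, 22)
  expect_equal(seg$before$rate, 0.16, tolerance = 1e-12)
  expect_equal(seg$after$rate, 0.057, tolerance = 1e-12)
  # a globally linear series yields the same rate on both sides
  lin <- time_series(t, 12 - 0.2 * t)
  seg2 <- segmented_rates(lin, 22)
  expect_equal(seg2$before$rate, seg2$after$rate)
  expect_error(segmented_rates(lin, 45), "outside")
  expect_error(segmented_rates(time_series(c(0, 30, 35, 40), c(9, 5, 4.5, 4)),
                               22),
               "before the breakpoint")
})

test_that("rate ratios round half away from zero at significant figures", {
  expect_equal(rate_ratio(0.24, 0.22, 2)$ratio_rounded, 1.1)
  expect_equal(rate_ratio(0.27, 0.24, 3)$ratio_rounded, 1.13)
  expect_equal(rate_ratio(0.18, 0.19, 2)$ratio_rounded, 0.95)
  expect_equal(rate_ratio(0.2, 0.2, 2)$ratio_rounded, 1)
  expect_equal(rate_ratio(0.27, 0.24, 3)$ratio, 0.27 / 0.24)
  expect_error(rate_ratio(0.1, 0), "positive")
})

test_that("the strain-by-substrate table reproduces per-cell ratios", {
  t <- seq(0, 30, 3)
  mk <- function(strain, substrate, rate) {
    fit_rate(time_series(t, 10 - rate * t, substrate, strain))
  }
  fits <- list(mk("ref", "fumarate", 0.22), mk("ref", "malate", 0.24),
               mk("mutA", "fumarate", 0.24), mk("mutA", "malate", 0.27),
               mk("mutB", "fumarate", 0.16), mk("mutB", "malate", 0.12))
  tab <- rate_table(fits, "ref")
  expect_equal(tab$fumarate_ratio[tab$strain == "ref"], 1)
  expect_equal(tab$malate_ratio[tab$strain == "ref"], 1)
  for (st in c("mutA", "mutB")) for (su in c("fumarate", "malate")) {
    f <- Filter(function(x) x$strain == st && x$substrate == su, fits)[[1]]
    r <- Filter(function(x) x$strain == "ref" && x$substrate == su, fits)[[1]]
    expect_equal(tab[[paste0(su, "_ratio")]][tab$strain == st],
                 rate_ratio(f, r, 2)$ratio_rounded)
  }
  expect_error(rate_table(fits[-1], "ref"), "missing reference")
  flat <- suppressWarnings(mk("ref", "citrate", 0))
  expect_error(rate_table(c(fits, list(flat)), "ref"), "zero")
})

test_that("noisy-series rate estimates are unbiased with honest intervals", {
  set.seed(55)
  n_sim <- 200L
  t <- seq(0, 40, length.out = 12)
  errs <- numeric(n_sim)
  covered <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    rate <- stats::runif(1, 0.05, 0.3)
    ts <- simulate_consumption_series(
      consumption_truth("s", c0 = 15, true_rate = rate, times = t,
                        noise_sd = 0.05), seed = 7000L + i)
    fit <- fit_rate(ts)
    errs[i] <- fit$rate - rate
    # OLS slope standard error
    keep <- ts$time >= fit$window[1] & ts$time <= fit$window[2]
    res <- (ts$concentration - (fit$intercept - fit$rate * ts$time))[keep]
    se <- sqrt(sum(res^2) / (sum(keep) - 2) /
                 sum((ts$time[keep] - mean(ts$time[keep]))^2))
    covered[i] <- abs(errs[i]) <= 2 * se
  }
  expect_lt(stats::median(abs(errs)), 0.01)
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})
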