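rhu <- pamdensity:::round_half_up

test_that("click-counting estimator reproduces the printed site rows", {
  # cleanly recomputing rows at 2 dp
  expect_equal(rhu(click_density(0.00377, 1, 0.073, 0.492, 0.043)$density_per_1000km2), 3.29)
  expect_equal(rhu(click_density(0.00105, 1, 0.060, 0.493, 0.070)$density_per_1000km2), 0.57)
  expect_equal(rhu(click_density(0.00057, 1, 0.056, 0.470, 0.069)$density_per_1000km2), 0.33)
  # rows carried with unrounded intermediates in the source land within 0.01
  expect_equal(rhu(click_density(0.00385, 1, 0.064, 0.484, 0.043)$density_per_1000km2),
    3.45,
    tolerance = 0.011
  )
  expect_equal(rhu(click_density(0.01431, 1, 0.049, 0.488, 0.044)$density_per_1000km2),
    12.60,
    tolerance = 0.011
  )
  expect_equal(rhu(click_density(0.02744, 1, 0.055, 0.457, 0.070)$density_per_1000km2),
    16.12,
    tolerance = 0.011
  )
  # zero cues give zero density
  expect_equal(click_density(0, 1000, 0.06, 0.49, 0.07)$density_per_1000km2, 0)
  expect_error(click_density(10, 100, 0.05, 0, 0.07), "positive")
})

test_that("group-counting estimator reproduces the printed site rows", {
  expect_equal(rhu(group_density(0.00655, 1, 0.003, 2.06, 0.254, 0.281)$density_per_1000km2), 3.75)
  expect_equal(rhu(group_density(0.02670, 1, 0.005, 2.80, 0.254, 0.278)$density_per_1000km2), 20.96)
  expect_equal(rhu(group_density(0.00335, 1, 0.013, 2.10, 0.471, 0.359)$density_per_1000km2), 0.82)
  expect_equal(rhu(group_density(0.00189, 1, 0.008, 1.69, 0.471, 0.360)$density_per_1000km2), 0.37)
  expect_equal(rhu(group_density(0.05440, 1, 0.003, 1.98, 0.471, 0.358)$density_per_1000km2), 12.67)
  expect_equal(rhu(group_density(0.00677, 1, 0.007, 2.18, 0.254, 0.281)$density_per_1000km2),
    4.09,
    tolerance = 0.011
  )
  expect_equal(group_density(0, 100, 0.003, 2, 0.47, 0.36)$density_per_1000km2, 0)
})

test_that("both estimators are exactly linear in the count", {
  set.seed(14)
  for (i in 1:5) {
    n <- runif(1, 10, 5000)
    t <- runif(1, 1e5, 1e6)
    d1 <- click_density(n, t, 0.06, 0.49, 0.07)$density_per_1000km2
    d2 <- click_density(2 * n, t, 0.06, 0.49, 0.07)$density_per_1000km2
    expect_equal(d2, 2 * d1)
    g1 <- group_density(n, t, 0.005, 2.1, 0.47, 0.36)$density_per_1000km2
    g2 <- group_density(2 * n, t, 0.005, 2.1, 0.47, 0.36)$density_per_1000km2
    expect_equal(g2, 2 * g1)
  }
})

test_that("delta-method CV is the root of summed squares", {
  expect_equal(round(delta_cv(c(0.08, 0.03)), 2), 0.09)
  expect_equal(round(delta_cv(c(0.171, 0.03)), 2), 0.17)
  expect_equal(delta_cv(0.25), 0.25)
  # permutation-invariant and at least the largest component
  set.seed(2)
  for (i in 1:5) {
    cvs <- runif(4, 0, 0.5)
    expect_equal(delta_cv(cvs), delta_cv(rev(cvs)))
    expect_gte(delta_cv(cvs), max(cvs))
  }
  expect_error(delta_cv(c(0.1, -0.2)), "non-negative")
})

test_that("lognormal intervals are log-symmetric and widen with CV", {
  ci0 <- lognormal_ci(3.2, 0)
  expect_equal(ci0$low, 3.2)
  expect_equal(ci0$high, 3.2)
  expect_equal(lognormal_ci(0, 0.5), tibble::tibble(low = 0, high = 0))

  # low * high = D^2 for any cv
  for (cv in c(0.1, 0.5, 1.2)) {
    ci <- lognormal_ci(2.5, cv)
    expect_equal(ci$low * ci$high, 2.5^2)
  }

  # Monte Carlo lognormal-quantile oracle at 1e6 draws, D = 1, cv = 0.5
  set.seed(99)
  sigma <- sqrt(log(1 + 0.5^2))
  draws <- exp(rnorm(1e6, 0, sigma))
  q <- unname(quantile(draws, c(0.025, 0.975)))
  ci <- lognormal_ci(1, 0.5)
  expect_equal(ci$low, q[1], tolerance = 0.01)
  expect_equal(ci$high, q[2], tolerance = 0.01)

  # width is monotone in cv at fixed D
  widths <- vapply(seq(0.05, 1, by = 0.05), function(cv) {
    ci <- lognormal_ci(4, cv)
    ci$high - ci$low
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("weekly series joins multipliers, propagates CVs and flags gaps", {
  wk <- tibble::tibble(
    week_start = as.Date("2011-01-02") + 7 * (0:3),
    site = "MC", species = "Zc",
    n_clicks = c(1000, 1000, 1000, 1000),
    n_bins_detected = c(40, 40, 40, 40),
    t_seconds = 604800, t_bins = 2016
  )
  m <- multiplier_set("Zc", "MC",
    false_rate = 0.06, false_rate_cv = 0.04,
    click_rate = 0.493, click_rate_cv = 0.088,
    group_size = 2.10, group_size_cv = 0.09,
    p_v = 0.471, p_v_cv = 0.09, p_k = 0.07, p_k_cv = 0.16
  )
  sc <- weekly_series(wk, m, "click")
  # constant counts give a constant series
  expect_equal(length(unique(sc$density_per_1000km2)), 1)
  expect_equal(sc$cv, rep(delta_cv(c(0.04, 0.088, 0.16)), 4))
  expect_true(all(sc$ci_low <= sc$density_per_1000km2 & sc$density_per_1000km2 <= sc$ci_high))

  sg <- weekly_series(wk, m, "group")
  expect_equal(
    sg$density_per_1000km2[1],
    group_density(40, 2016, 0.06, 2.10, 0.471, 0.07)$density_per_1000km2
  )

  # missing multiplier errors by name
  m_bad <- m
  m_bad$click_rate <- NA_real_
  expect_error(weekly_series(wk, m_bad, "click"), "click_rate")
  expect_error(weekly_series(dplyr::mutate(wk, site = "DT"), m, "click"), "DT")

  # averaging equals pooling under equal effort
  avg <- average_density(sc)
  expect_equal(
    avg$density_per_1000km2,
    click_density(sum(wk$n_clicks), sum(wk$t_seconds), 0.06, 0.493, 0.07)$density_per_1000km2
  )
})

test_that("bootstrap count CV responds to within-week dispersion", {
  set.seed(77)
  wk <- tibble::tibble(
    week_start = as.Date("2011-01-02"), site = "MC", species = "Zc",
    n_clicks = 600L, n_bins_detected = 30L, t_seconds = 604800, t_bins = 2016
  )
  m <- multiplier_set("Zc", "MC",
    false_rate = 0.06, click_rate = 0.493, p_k = 0.07
  )
  # clumped clicks: all in a handful of bins
  bins_clumped <- tibble::tibble(
    site = "MC", species = "Zc",
    bin_start = as.POSIXct("2011-01-02", tz = "UTC") + 300 * (0:2015),
    n_clicks = c(rep(200L, 3), rep(0L, 2013)),
    detected = n_clicks >= 5
  )
  s1 <- weekly_series(wk, m, "click", bins = bins_clumped, n_boot = 200, seed = 1)
  s0 <- weekly_series(wk, m, "click", seed = 1)
  expect_gt(s1$cv, s0$cv)
})

test_that("multiplier tables round-trip through the long CSV form", {
  m <- multiplier_set("Zc", "MC",
    false_rate = 0.06, false_rate_cv = 0.04,
    click_rate = 0.493, click_rate_cv = 0.088,
    group_size = 2.10, group_size_cv = 0.09,
    p_v = 0.471, p_v_cv = 0.09, p_k = 0.07, p_k_cv = 0.16, w_km = 4
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_multipliers(m, path)
  back <- read_multipliers(path)
  expect_equal(back$click_rate, 0.493)
  expect_equal(back$p_v_cv, 0.09)
  expect_equal(back$w_km, 4)
})
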