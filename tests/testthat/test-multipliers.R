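test_that("weekly ICI mode finds the dominant peak and honours the count floor", {
  # degenerate: all mass at one value
  m <- ici_weekly_mode(rep(0.29, 200))
  expect_equal(m$mode, 0.29, tolerance = 0.002)

  # mixture with missed-click doubles near 1 s; mode stays at the primary peak
  set.seed(41)
  x <- c(rnorm(800, 0.50, 0.01), rnorm(200, 1.00, 0.02))
  m2 <- ici_weekly_mode(x)
  expect_equal(m2$mode, oracle_hist_mode(x), tolerance = 0.005)
  expect_equal(m2$mode, 0.50, tolerance = 0.01)

  # weeks under the 100-value floor yield no mode; values >= 1 s don't count
  wk <- c(rep(1, 150), rep(2, 50))
  x3 <- c(rnorm(150, 0.29, 0.005), rnorm(50, 0.29, 0.005))
  m3 <- ici_weekly_mode(x3, wk)
  expect_equal(m3$week, 1)
  expect_equal(nrow(ici_weekly_mode(runif(300, 1.0, 2.0))), 0)
})

test_that("pooled click rate is the weighted mean of inverse modes with Cochran CV", {
  eq <- pooled_click_rate(c(0.5, 0.5), c(1, 1))
  expect_equal(eq$rate, 2)
  expect_equal(eq$cv, 0)

  # hand-computed: (1*2 + 3*4) / 4 = 3.5
  ww <- pooled_click_rate(c(0.5, 0.25), c(1, 3))
  expect_equal(ww$rate, 3.5)

  # equal weights reduce to the simple mean and the classical SE
  set.seed(8)
  modes <- runif(12, 0.45, 0.55)
  p <- pooled_click_rate(modes, rep(2, 12))
  x <- 1 / modes
  expect_equal(p$rate, mean(x))
  expect_equal(p$cv, sd(x) / sqrt(12) / mean(x))

  expect_warning(one <- pooled_click_rate(0.5, 1), "single")
  expect_equal(one$cv, 0)

  # Cuvier's-like modes give about 2 clicks/s
  cz <- pooled_click_rate(c(0.50, 0.52, 0.53), c(1, 1, 1))
  expect_gt(cz$rate, 1.88)
  expect_lt(cz$rate, 2.01)
})

test_that("proportion of clicking seconds is the duration-weighted mean", {
  tag <- tibble::tibble(
    cycle_id = 0:2,
    duration_s = c(1000, 3600, 1800),
    cps = list(0:9, 0:899, 0:179)
  )
  p <- proportion_clicking_seconds(tag) # first cycle excluded
  expect_equal(p$proportion, (900 + 180) / (3600 + 1800))

  # all-positive tag gives exactly 1
  full <- tibble::tibble(
    cycle_id = 1:2, duration_s = c(600, 600),
    cps = list(0:599, 0:599)
  )
  expect_equal(proportion_clicking_seconds(full)$proportion, 1)

  expect_error(
    proportion_clicking_seconds(full[1, ]),
    "at least two"
  )
})

test_that("randomized-start bin proportion matches the exhaustive-start oracle", {
  # one 600-s cycle, positives in [0, 60)
  tag <- tibble::tibble(
    cycle_id = 1:2, duration_s = c(600, 600),
    cps = list(0:599, 0:59)
  )
  want <- oracle_bin_proportion(0:59, 600)
  got <- proportion_clicking_bins(tag, exhaustive = TRUE, exclude_first = FALSE)
  # weighted over the two cycles: cycle 1 is fully positive
  expect_equal(got$proportion, (1 * 600 + want * 600) / 1200)
  # with the first cycle excluded only the sparse cycle remains
  got1 <- proportion_clicking_bins(tag, exhaustive = TRUE)
  expect_equal(got1$proportion, want)

  # sampling converges to the same value
  got_s <- proportion_clicking_bins(tag,
    n_starts = 400, seed = 5,
    exclude_first = FALSE
  )
  expect_equal(got_s$proportion, got$proportion, tolerance = 0.02)

  # all-positive cycles give 1 for any start
  full <- tibble::tibble(
    cycle_id = 1:2, duration_s = c(900, 900),
    cps = list(0:899, 0:899)
  )
  expect_equal(proportion_clicking_bins(full, seed = 1)$proportion, 1)

  # binning can only inflate occupancy relative to the per-second proportion
  set.seed(9)
  for (i in 1:4) {
    tg <- generate_tag_records(6, proportion = runif(1, 0.1, 0.5), seed = 100 + i)
    ps <- proportion_clicking_seconds(tg)$proportion
    pb <- proportion_clicking_bins(tg, n_starts = 40, seed = i)$proportion
    expect_gte(pb, ps - 1e-9)
  }
})

test_that("cue rate is proportion times inverse ICI with root-sum-square CV", {
  r <- click_rate(0.5, 2.0)
  expect_equal(r$rate, 1.0)
  r2 <- click_rate(0.243, 1 / 0.51, proportion_cv = 0.171, ici_cv = 0.03)
  expect_equal(r2$rate, 0.476, tolerance = 0.001)
  expect_equal(r2$cv, sqrt(0.171^2 + 0.03^2))
  expect_error(click_rate(0, 2), "positive")
})

test_that("synchrony overlap is interval arithmetic over tracked animals", {
  # identical intervals overlap fully
  b1 <- tibble::tibble(
    encounter_id = 1, animal_id = c("A", "B"),
    start_s = c(0, 0), end_s = c(100, 100)
  )
  expect_equal(synchrony_overlap(b1)$overlap, 1)

  # disjoint intervals do not overlap
  b0 <- tibble::tibble(
    encounter_id = 1, animal_id = c("A", "B"),
    start_s = c(0, 200), end_s = c(100, 300)
  )
  expect_equal(synchrony_overlap(b0)$overlap, 0)

  # A = [0,100], B = [50,150]: 50 / 100
  bh <- tibble::tibble(
    encounter_id = 1, animal_id = c("A", "B"),
    start_s = c(0, 50), end_s = c(100, 150)
  )
  expect_equal(synchrony_overlap(bh)$overlap, 0.5)

  # single-animal encounters are dropped; all-single errors
  expect_warning(
    res <- synchrony_overlap(dplyr::bind_rows(
      bh,
      tibble::tibble(encounter_id = 2, animal_id = "A", start_s = 0, end_s = 10)
    )),
    "single animal"
  )
  expect_equal(res$n_encounters, 1)
  expect_error(
    suppressWarnings(synchrony_overlap(
      tibble::tibble(encounter_id = 1, animal_id = "A", start_s = 0, end_s = 10)
    )),
    "two or more"
  )
})

test_that("group vocal probability follows p_r(2 - o) with a unity cap", {
  expect_equal(group_vocal_probability(0.354, 0.67)$p_v, 0.471, tolerance = 5e-4)
  expect_equal(group_vocal_probability(0.191, 0.67)$p_v, 0.254, tolerance = 5e-4)
  expect_equal(group_vocal_probability(0.6, 0)$p_v, 1)
  expect_error(group_vocal_probability(0.3, 0.5, group_size = 3), "two-animal")

  # bounds and monotonicity over a grid
  for (p_r in seq(0.05, 0.95, by = 0.15)) {
    pv <- vapply(
      seq(0, 1, by = 0.1),
      function(o) group_vocal_probability(p_r, o)$p_v, numeric(1)
    )
    expect_true(all(diff(pv) <= 1e-12))
    expect_true(all(pv >= p_r - 1e-12 & pv <= min(1, 2 * p_r) + 1e-12))
    expect_equal(pv[1], min(1, 2 * p_r))
    expect_equal(pv[11], p_r)
  }
})

test_that("group-size summary gives mean, SE-based CV and histogram", {
  g <- group_size_stats(c(2, 2, 2))
  expect_equal(g$mean, 2)
  expect_equal(g$cv, 0)

  g2 <- group_size_stats(c(1, 2, 3))
  expect_equal(g2$mean, 2)
  expect_equal(g2$cv, sd(c(1, 2, 3)) / sqrt(3) / 2)
  expect_equal(g2$histogram$count, c(1L, 1L, 1L))
})
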