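test_that("encounter assembly matches the brute-force gap scan", {
  # worked cases first: burst, short gap, long gap
  t1 <- c(seq(0, 80, by = 0.5), seq(1880, 1960, by = 0.5))
  enc <- assemble_encounters(sim_click_tbl(t1))
  expect_equal(nrow(enc), 1)
  expect_equal(as.numeric(enc$start), 0)
  expect_equal(as.numeric(enc$end), 1960)

  t2 <- c(seq(0, 80, by = 0.5), seq(0, 80, by = 0.5) + 80 + 7200)
  enc2 <- assemble_encounters(sim_click_tbl(t2))
  expect_equal(nrow(enc2), 2)

  # a lone click spans 0 s and is discarded
  expect_equal(nrow(assemble_encounters(sim_click_tbl(42))), 0)

  # randomized property check against the independent O(n) scan
  set.seed(71)
  for (rep in 1:5) {
    n_burst <- sample(20:60, 1)
    starts <- cumsum(runif(n_burst, 0, 3 * 3600))
    times <- sort(unlist(lapply(starts, function(s) {
      s + cumsum(runif(sample(1:400, 1), 0.3, 0.9))
    })))
    got <- assemble_encounters(sim_click_tbl(times))
    want <- oracle_encounters(times)
    expect_equal(nrow(got), nrow(want))
    expect_equal(as.numeric(got$start), want$start)
    expect_equal(as.numeric(got$end), want$end)
    expect_equal(got$n_clicks, want$n)
  }

  # assembly is idempotent on its own spans and rejects unsorted input
  expect_error(assemble_encounters(sim_click_tbl(c(5, 1))), "sorted")
  expect_equal(nrow(assemble_encounters(sim_click_tbl(numeric(0)))), 0)
})

test_that("5-min binning zero-fills effort and applies the 5-click rule", {
  eff <- sim_effort_tbl(SUNDAY, SUNDAY + 3600)
  empty <- sim_click_tbl(numeric(0))
  b0 <- bin_clicks(empty, eff)
  expect_equal(nrow(b0), 12)
  expect_false(any(b0$detected))

  # 4 clicks miss the threshold, 5 meet it
  b4 <- bin_clicks(sim_click_tbl(SUNDAY + c(1, 2, 3, 4)), eff)
  expect_false(b4$detected[1])
  expect_equal(b4$n_clicks[1], 4L)
  b5 <- bin_clicks(sim_click_tbl(SUNDAY + c(1, 2, 3, 4, 5)), eff)
  expect_true(b5$detected[1])

  # random log against the histogram oracle
  set.seed(12)
  times <- sort(runif(2000, SUNDAY, SUNDAY + 3600))
  bb <- bin_clicks(sim_click_tbl(times), eff)
  expect_equal(
    bb$n_clicks,
    oracle_bin_counts(times, as.numeric(bb$bin_start))
  )

  # clicks outside effort are excluded with a warning
  expect_warning(
    out <- bin_clicks(sim_click_tbl(c(SUNDAY - 100, SUNDAY + 10)), eff),
    "outside effort"
  )
  expect_equal(sum(out$n_clicks), 1L)
})

test_that("weekly aggregation yields 2016 bins for a full week and merges short edges", {
  eff <- sim_effort_tbl(SUNDAY, SUNDAY + 604800)
  clicks <- sim_click_tbl(SUNDAY + seq(1, 604000, by = 97))
  bins <- bin_clicks(clicks, eff)
  wk <- weekly_aggregate(bins, clicks, eff)
  expect_equal(nrow(wk), 1)
  expect_equal(wk$t_bins, 2016L)
  expect_equal(wk$t_seconds, 604800)
  expect_equal(format(wk$week_start, "%u"), "7") # ISO day 7 = Sunday
  expect_equal(wk$n_clicks, nrow(clicks))

  # no effort -> no row
  expect_equal(nrow(weekly_aggregate(
    bin_clicks(sim_click_tbl(numeric(0)), eff), sim_click_tbl(numeric(0)), eff
  )), 1) # the single full effort week is still a row
  # (weeks without any effort are simply absent: 2-week span check below)

  # Friday start (2 days of effort) stands alone
  fri <- SUNDAY - 2 * 86400
  eff_f <- sim_effort_tbl(fri, SUNDAY + 604800)
  cl_f <- sim_click_tbl(fri + seq(1, 9 * 86400 - 100, by = 301))
  wk_f <- weekly_aggregate(bin_clicks(cl_f, eff_f), cl_f, eff_f)
  expect_equal(nrow(wk_f), 2)
  expect_equal(wk_f$t_seconds[1], 2 * 86400)

  # Saturday start (1 day) merges into the following week
  sat <- SUNDAY - 86400
  eff_s <- sim_effort_tbl(sat, SUNDAY + 604800)
  cl_s <- sim_click_tbl(sat + seq(1, 8 * 86400 - 100, by = 301))
  wk_s <- weekly_aggregate(bin_clicks(cl_s, eff_s), cl_s, eff_s)
  expect_equal(nrow(wk_s), 1)
  expect_equal(wk_s$t_seconds, 8 * 86400)
  expect_equal(wk_s$t_bins, 2016L + 288L)
})

test_that("weekly accounting conserves clicks, bins and effort seconds", {
  # gapped 3.5-week deployment; every effort second lands in exactly one row
  eff <- sim_effort_tbl(
    c(SUNDAY, SUNDAY + 10 * 86400),
    c(SUNDAY + 8 * 86400, SUNDAY + 24.5 * 86400)
  )
  set.seed(31)
  times <- sort(c(
    runif(5000, SUNDAY, SUNDAY + 8 * 86400),
    runif(5000, SUNDAY + 10 * 86400, SUNDAY + 24.5 * 86400)
  ))
  clicks <- sim_click_tbl(times)
  bins <- bin_clicks(clicks, eff)
  wk <- weekly_aggregate(bins, clicks, eff)
  expect_equal(sum(wk$t_seconds), sum(as.numeric(eff$end) - as.numeric(eff$start)))
  expect_equal(sum(wk$t_bins), nrow(bins))
  expect_equal(sum(wk$n_clicks), nrow(clicks))
  # per-bin counts summed over a week equal that week's pre-filter click count
  # (effort here is bin-aligned except the final half day)
  expect_equal(sum(wk$n_bins_detected), sum(bins$detected))
})

test_that("false-detection proportion and CV follow the binomial rule", {
  r <- estimate_false_rate(c(rep(TRUE, 59), rep(FALSE, 941)))
  expect_equal(r$proportion, 0.059)
  expect_equal(r$cv, sqrt(0.059 * 0.941 / 1000) / 0.059)

  expect_warning(r0 <- estimate_false_rate(rep(FALSE, 100)), "undefined")
  expect_equal(r0$proportion, 0)
  expect_equal(r0$cv, 0)

  rb <- estimate_false_rate(c(rep(TRUE, 30), rep(FALSE, 5970)))
  expect_equal(rb$proportion, 0.005)
})
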