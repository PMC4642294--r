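#' Weekly modal inter-click interval
#'
#' Detected inter-click intervals mix true single-animal intervals with
#' doubled intervals (a missed click) and intervals across animals, so the
#' mode of the distribution is the robust summary of the true ICI. Values are
#' restricted to (0, `upper`) seconds; weeks with fewer than `min_count`
#' eligible values yield no mode. The mode is the argmax of a Gaussian kernel
#' density (Silverman's rule-of-thumb bandwidth) evaluated on a 1-ms grid,
#' ties broken towards the smaller ICI.
#'
#' @param ici Numeric vector of inter-click intervals, seconds.
#' @param week Vector parallel to `ici` giving the week of each value (any
#'   type usable as a grouping key; typically the `week_start` Date).
#' @param min_count Minimum eligible values for a weekly mode (default 100).
#' @param upper Upper ICI limit in seconds (default 1).
#' @return Tibble `week`, `mode` (seconds), `n` (eligible values), one row
#'   per week that reached `min_count`.
#' @export
ici_weekly_mode <- function(ici, week = rep(1L, length(ici)), min_count = 100,
                            upper = 1) {
  if (any(ici <= 0, na.rm = TRUE)) abort("ICI values must be positive")
  keep <- !is.na(ici) & ici < upper
  tibble(ici = ici[keep], week = week[keep]) %>%
    group_by(.data$week) %>%
    summarise(
      mode = if (dplyr::n() >= min_count) kde_mode(.data$ici, upper) else NA_real_,
      n = dplyr::n(), .groups = "drop"
    ) %>%
    filter(!is.na(.data$mode))
}

kde_mode <- function(x, upper = 1) {
  grid_n <- round(upper / 0.001) - 1
  d <- stats::density(x,
    bw = "nrd0", kernel = "gaussian",
    from = 0.001, to = upper - 0.001, n = grid_n
  )
  # ties towards the smaller ICI
  d$x[which.max(d$y)]
}

#' Pooled click-spacing rate from weekly modal ICIs
#'
#' Converts weekly modal ICIs to click rates (1/mode) and pools them as a
#' weighted mean with the weekly recording-time as weight. The CV comes from
#' Cochran's ratio-estimator variance for a weighted mean.
#'
#' @param modes Numeric vector of weekly modal ICIs, seconds.
#' @param weights Positive weights (weekly bin lengths, seconds). Default
#'   equal weights.
#' @return One-row tibble `rate` (clicks/s), `cv`, `n_weeks`. A single week
#'   gives cv = 0 with a warning.
#' @export
pooled_click_rate <- function(modes, weights = rep(1, length(modes))) {
  keep <- !is.na(modes)
  modes <- modes[keep]
  weights <- weights[keep]
  if (length(modes) < 1) abort("need at least one weekly mode")
  if (any(modes <= 0) || any(weights <= 0)) abort("modes and weights must be positive")
  x <- 1 / modes
  rate <- sum(weights * x) / sum(weights)
  n <- length(x)
  if (n == 1) {
    warn("single weekly mode: CV reported as 0")
    cv <- 0
  } else {
    v <- cochran_ratio_var(x, weights)
    cv <- sqrt(v) / rate
  }
  tibble(rate = rate, cv = cv, n_weeks = n)
}

# Cochran's variance of a weighted ratio mean R = sum(w x)/sum(w)
cochran_ratio_var <- function(x, w) {
  n <- length(x)
  r <- sum(w * x) / sum(w)
  n / ((n - 1) * sum(w)^2) * sum((w * x - r * w)^2)
}

validate_tag <- function(tag) {
  stopifnot(is.data.frame(tag), all(c("cycle_id", "duration_s", "cps") %in% names(tag)))
  bad <- purrr::map2_lgl(tag$cps, tag$duration_s, function(s, d) {
    length(s) > 0 && (min(s) < 0 || max(s) >= d)
  })
  if (any(bad)) abort("click-positive second indices must lie in [0, duration)")
  invisible(tag)
}

#' Read dive-cycle tag records
#'
#' Accepts either the wide CSV form `cycle_id,duration_s,click_positive_seconds`
#' (with second indices separated by `;`) or the long form
#' `cycle_id,duration_s,second_index` (one row per click-positive second).
#'
#' @param path Path to a CSV file.
#' @return Tibble `cycle_id`, `duration_s`, `cps` (list column of integer
#'   second indices), ordered by cycle.
#' @export
read_tag_records <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("click_positive_seconds" %in% names(raw)) {
    out <- tibble(
      cycle_id = raw$cycle_id,
      duration_s = as.numeric(raw$duration_s),
      cps = purrr::map(raw$click_positive_seconds, function(s) {
        if (is.na(s) || !nzchar(s)) integer(0) else as.integer(strsplit(s, ";")[[1]])
      })
    )
  } else {
    out <- as_tibble(raw) %>%
      group_by(.data$cycle_id, .data$duration_s) %>%
      summarise(cps = list(sort(unique(as.integer(.data$second_index)))), .groups = "drop")
  }
  out <- arrange(out, .data$cycle_id)
  validate_tag(out)
  out
}

#' Proportion of dive-cycle seconds spent clicking
#'
#' Weighted mean (by dive-cycle duration) of the per-cycle proportion of
#' click-positive seconds. The first dive cycle of a tag record is excluded
#' by default because of an apparent tagging effect (depressed clicking).
#' The CV is the Cochran weighted-ratio standard error over cycles divided
#' by the mean.
#'
#' @param tag Tag tibble (`cycle_id`, `duration_s`, `cps` list column), as
#'   from [read_tag_records()] or [generate_tag_records()].
#' @param exclude_first Drop the first cycle (default TRUE).
#' @return One-row tibble `proportion`, `cv`, `n_cycles`.
#' @export
proportion_clicking_seconds <- function(tag, exclude_first = TRUE) {
  validate_tag(tag)
  if (exclude_first) {
    if (nrow(tag) < 2) abort("need at least two dive cycles when excluding the first")
    tag <- tag[-1, ]
  }
  if (nrow(tag) == 0) abort("no dive cycles left to analyse")
  p <- purrr::map2_dbl(tag$cps, tag$duration_s, function(s, d) length(s) / d)
  w <- tag$duration_s
  prop <- sum(w * p) / sum(w) # equals total positive seconds / total seconds
  cv <- if (nrow(tag) > 1) sqrt(cochran_ratio_var(p, w)) / prop else 0
  tibble(proportion = prop, cv = cv, n_cycles = nrow(tag))
}

# bins touched by the click-positive seconds of one cycle for one cyclic start
cycle_bin_prop <- function(cps, dur, start, bin_s) {
  n_bins <- floor(dur / bin_s)
  shifted <- (cps - start) %% dur
  bins <- unique(shifted[shifted < n_bins * bin_s] %/% bin_s)
  length(bins) / n_bins
}

#' Proportion of 5-min bins with clicking, randomized cyclic start
#'
#' Splits each dive cycle into 5-min bins from a random start point, treating
#' the cycle as cyclical and dropping the last incomplete bin, and reports
#' the duration-weighted mean proportion of bins that contain at least one
#' click-positive second. Randomizing the start removes the arbitrary-anchor
#' effect; results are averaged over `n_starts` random integer-second starts
#' (or all starts when `exhaustive = TRUE`).
#'
#' @inheritParams proportion_clicking_seconds
#' @param bin_s Bin length, seconds (default 300).
#' @param n_starts Number of random start points per cycle (default 100).
#' @param exhaustive Enumerate every integer start instead of sampling.
#' @param seed Optional integer seed for the random starts.
#' @return One-row tibble `proportion`, `cv`, `n_cycles`. Cycles shorter than
#'   one bin are skipped with a warning.
#' @export
proportion_clicking_bins <- function(tag, bin_s = BIN_SECONDS, n_starts = 100,
                                     exclude_first = TRUE, exhaustive = FALSE,
                                     seed = NULL) {
  validate_tag(tag)
  if (exclude_first) {
    if (nrow(tag) < 2) abort("need at least two dive cycles when excluding the first")
    tag <- tag[-1, ]
  }
  short <- tag$duration_s < bin_s
  if (any(short)) {
    warn(sprintf("%d cycle(s) shorter than one bin were skipped", sum(short)))
    tag <- tag[!short, ]
  }
  if (nrow(tag) == 0) abort("no dive cycles left to analyse")
  p <- with_seed_if(seed, purrr::map2_dbl(tag$cps, tag$duration_s, function(s, d) {
    starts <- if (exhaustive) 0:(d - 1) else sample.int(d, n_starts, replace = TRUE) - 1
    mean(purrr::map_dbl(starts, function(st) cycle_bin_prop(s, d, st, bin_s)))
  }))
  w <- tag$duration_s
  prop <- sum(w * p) / sum(w)
  cv <- if (nrow(tag) > 1) sqrt(cochran_ratio_var(p, w)) / prop else 0
  tibble(proportion = prop, cv = cv, n_cycles = nrow(tag))
}

#' Cue production rate
#'
#' The mean click production rate over a dive cycle: the proportion of time
#' spent clicking times the instantaneous click rate (the inverse modal ICI).
#' CVs combine by the delta method (root of summed squares).
#'
#' @param proportion Proportion of dive-cycle seconds spent clicking.
#' @param ici_rate Instantaneous click rate while clicking, clicks/s (the
#'   pooled inverse modal ICI).
#' @param proportion_cv,ici_cv Component CVs (default 0).
#' @return One-row tibble `rate` (clicks/s), `cv`.
#' @export
click_rate <- function(proportion, ici_rate, proportion_cv = 0, ici_cv = 0) {
  if (proportion <= 0 || ici_rate <= 0) abort("proportion and ici_rate must be positive")
  tibble(rate = proportion * ici_rate, cv = delta_cv(c(proportion_cv, ici_cv)))
}

#' Vocal-bout synchrony overlap between tracked animals
#'
#' For each encounter with two or more tracked animals, the overlap is the
#' total time during which at least two animals are vocalizing divided by the
#' mean per-animal vocalization time. The estimate is the mean over
#' encounters (each encounter's bout set is one sample unit) with
#' CV = SE/mean.
#'
#' @param bouts Tibble `encounter_id`, `animal_id`, `start_s`, `end_s`, one
#'   row per vocal interval.
#' @return List with `overlap`, `cv`, `n_encounters` and the per-encounter
#'   tibble `encounters`. Encounters with a single animal are dropped with a
#'   warning; if none remain an error is raised.
#' @export
synchrony_overlap <- function(bouts) {
  stopifnot(all(c("encounter_id", "animal_id", "start_s", "end_s") %in% names(bouts)))
  if (any(bouts$end_s <= bouts$start_s)) abort("bout intervals must have start < end")
  per_enc <- bouts %>%
    group_by(.data$encounter_id) %>%
    dplyr::group_modify(function(df, key) {
      if (dplyr::n_distinct(df$animal_id) < 2) {
        return(tibble(overlap = NA_real_))
      }
      tibble(overlap = encounter_overlap(df))
    }) %>%
    ungroup()
  dropped <- sum(is.na(per_enc$overlap))
  if (dropped > 0) {
    warn(sprintf("%d encounter(s) with a single animal were dropped", dropped))
  }
  per_enc <- filter(per_enc, !is.na(.data$overlap))
  if (nrow(per_enc) == 0) abort("no encounters with two or more tracked animals")
  o <- mean(per_enc$overlap)
  cv <- if (nrow(per_enc) > 1 && o > 0) {
    sd(per_enc$overlap) / sqrt(nrow(per_enc)) / o
  } else {
    0
  }
  list(overlap = o, cv = cv, n_encounters = nrow(per_enc), encounters = per_enc)
}

# time with >= 2 animals vocal, over mean per-animal vocal time (one encounter)
encounter_overlap <- function(df) {
  per_animal <- df %>%
    group_by(.data$animal_id) %>%
    summarise(t = sum(union_length(.data$start_s, .data$end_s)), .groups = "drop")
  ev <- tibble(
    t = c(df$start_s, df$end_s),
    d = c(rep(1L, nrow(df)), rep(-1L, nrow(df)))
  ) %>% arrange(.data$t, dplyr::desc(.data$d))
  depth <- cumsum(ev$d)
  seg <- diff(ev$t)
  t_ge2 <- sum(seg[depth[-length(depth)] >= 2])
  t_ge2 / mean(per_animal$t)
}

union_length <- function(start, end) {
  o <- order(start)
  start <- start[o]
  end <- end[o]
  tot <- 0
  cur_s <- start[1]
  cur_e <- end[1]
  if (length(start) > 1) {
    for (i in 2:length(start)) {
      if (start[i] > cur_e) {
        tot <- tot + (cur_e - cur_s)
        cur_s <- start[i]
        cur_e <- end[i]
      } else {
        cur_e <- max(cur_e, end[i])
      }
    }
  }
  tot + (cur_e - cur_s)
}

#' Group vocal-activity probability for a two-animal group
#'
#' Asynchrony between the vocal bouts of group members inflates the chance
#' that at least one animal is clicking in a 5-min window. For a group of
#' two, `P_v = min(1, p_r * (2 - o))`, where `p_r` is the individual per-bin
#' clicking probability and `o` the bout overlap; `o = 1` (full synchrony)
#' gives `p_r`, `o = 0` gives `2 p_r`, capped at unity. CVs combine as the
#' root of summed squares.
#'
#' @param p_r Individual probability of clicking in a 5-min bin, in `[0, 1]`.
#' @param o Bout overlap, in `[0, 1]`.
#' @param p_r_cv,o_cv Component CVs (default 0).
#' @param group_size Only the two-animal relation is supported.
#' @return One-row tibble `p_v`, `cv`.
#' @export
group_vocal_probability <- function(p_r, o, p_r_cv = 0, o_cv = 0, group_size = 2) {
  if (group_size != 2) abort("only the two-animal synchrony relation is supported")
  if (p_r < 0 || p_r > 1 || o < 0 || o > 1) abort("p_r and o must lie in [0, 1]")
  tibble(p_v = min(1, p_r * (2 - o)), cv = delta_cv(c(p_r_cv, o_cv)))
}

#' Group-size summary from encounter counts
#'
#' Mean group size across acoustic encounters, with CV = SE/mean and the
#' count histogram.
#'
#' @param sizes Integer vector of per-encounter group sizes (each >= 1).
#' @return List with `mean`, `cv`, `n`, and `histogram` (tibble
#'   `size`, `count`).
#' @export
group_size_stats <- function(sizes) {
  if (length(sizes) < 1 || any(sizes < 1)) abort("need group sizes >= 1")
  m <- mean(sizes)
  cv <- if (length(sizes) > 1) sd(sizes) / sqrt(length(sizes)) / m else 0
  hist <- tibble(size = as.integer(sizes)) %>%
    count(.data$size, name = "count")
  list(mean = m, cv = cv, n = length(sizes), histogram = hist)
}
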