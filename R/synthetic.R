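#' Ground-truth scenario for the synthetic data generator
#'
#' Defines the state of nature behind a synthetic monitoring record: the true
#' animal density, group-size distribution, the vocal behaviour (modal ICI
#' with jitter, proportion of dive-cycle seconds spent clicking, bout
#' overlap), the dive-cycle length distribution, the false-click load, the
#' acoustic scenario used for received levels and the group orientation
#' behaviour. The derived quantities the estimators consume (`click_rate`,
#' `p_v`, `mean_group_size`) are computed from these and stored alongside.
#'
#' @param true_density True animal density, animals per 1000 km^2.
#' @param group_size_probs Named probability vector over group sizes
#'   (names "1".."5").
#' @param modal_ici_s Modal inter-click interval, seconds.
#' @param ici_jitter_cv Click-to-click ICI jitter CV (default 0.05).
#' @param proportion_clicking Proportion of dive-cycle seconds an individual
#'   spends clicking (default 0.243).
#' @param p_bin_single Individual probability of clicking within a 5-min bin
#'   (default 0.354); with `bout_overlap` this sets the group vocal-activity
#'   probability `p_v = min(1, p_bin_single * (2 - bout_overlap))`.
#' @param bout_overlap Vocal-bout overlap between group members
#'   (default 0.67).
#' @param dive_cycle_mean_s,dive_cycle_cv Lognormal dive-cycle length,
#'   seconds (defaults 7200 s, CV 0.2).
#' @param false_click_rate Proportion of emitted detections that are false
#'   (default 0.059).
#' @param false_clicks_per_hour Additional absolute false-click load,
#'   clicks/h (default 0; lets a zero-density scenario still carry noise).
#' @param acoustic An [acoustic_scenario()] (default Cuvier's Gulf of Mexico
#'   set).
#' @param behavior A [group_behavior()].
#' @param weeks Length of the monitoring record, weeks (default 26).
#' @return An object of class `truth_scenario`.
#' @export
truth_scenario <- function(true_density = 5,
                           group_size_probs = c(
                             "1" = 0.35, "2" = 0.45, "3" = 0.15, "4" = 0.05
                           ),
                           modal_ici_s = 0.51,
                           ici_jitter_cv = 0.05,
                           proportion_clicking = 0.243,
                           p_bin_single = 0.354,
                           bout_overlap = 0.67,
                           dive_cycle_mean_s = 7200,
                           dive_cycle_cv = 0.2,
                           false_click_rate = 0.059,
                           false_clicks_per_hour = 0,
                           acoustic = scenario_cuviers_gom(),
                           behavior = group_behavior(),
                           weeks = 26) {
  if (abs(sum(group_size_probs) - 1) > 1e-8) abort("group-size probabilities must sum to 1")
  rates <- c(
    ici_jitter_cv, proportion_clicking, p_bin_single, bout_overlap,
    false_click_rate
  )
  if (any(rates < 0) || any(c(
    proportion_clicking, p_bin_single, bout_overlap, false_click_rate
  ) > 1)) {
    abort("rates must lie in [0, 1]")
  }
  sizes <- as.integer(names(group_size_probs))
  structure(
    list(
      true_density = true_density,
      group_size_probs = group_size_probs,
      sizes = sizes,
      mean_group_size = sum(sizes * group_size_probs),
      modal_ici_s = modal_ici_s,
      ici_jitter_cv = ici_jitter_cv,
      proportion_clicking = proportion_clicking,
      p_bin_single = p_bin_single,
      bout_overlap = bout_overlap,
      p_v = min(1, p_bin_single * (2 - bout_overlap)),
      click_rate = proportion_clicking / modal_ici_s,
      dive_cycle_mean_s = dive_cycle_mean_s,
      dive_cycle_cv = dive_cycle_cv,
      false_click_rate = false_click_rate,
      false_clicks_per_hour = false_clicks_per_hour,
      acoustic = acoustic,
      behavior = behavior,
      weeks = weeks
    ),
    class = "truth_scenario"
  )
}

#' Generate a recording-effort table
#'
#' Continuous effort of the requested number of weeks starting on a Sunday
#' 00:00 UTC, with optional gaps cut out.
#'
#' @param weeks Number of weeks (>= 1; fractional allowed).
#' @param gaps Optional tibble `offset_s`, `duration_s`: gaps relative to the
#'   deployment start.
#' @param start Deployment start (default the Sunday `"2011-01-02 00:00:00"`
#'   UTC).
#' @param site Site label (default `"SIM"`).
#' @return Effort tibble `site`, `start`, `end`.
#' @export
generate_effort <- function(weeks, gaps = NULL, start = "2011-01-02 00:00:00",
                            site = "SIM") {
  s0 <- as.numeric(as_utc_time(start))
  e0 <- s0 + weeks * WEEK_SECONDS
  starts <- s0
  ends <- e0
  if (!is.null(gaps) && nrow(gaps) > 0) {
    gaps <- arrange(gaps, .data$offset_s)
    for (i in seq_len(nrow(gaps))) {
      gs <- s0 + gaps$offset_s[i]
      ge <- gs + gaps$duration_s[i]
      k <- length(ends)
      if (gs <= starts[k] || ge >= ends[k]) abort("gaps must nest inside the effort span")
      ends <- c(ends[-k], gs, ends[k])
      starts <- c(starts, ge)
    }
  }
  tibble(site = site, start = as_utc_time(starts), end = as_utc_time(sort(ends)))
}

rlnorm_mean_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
}

#' Generate a synthetic click-detection log with known truth
#'
#' Simulates the full observation chain for one site: groups arrive as a
#' Poisson process with the rate implied by the true density, sit at a
#' uniform position in the monitoring disc for one dive cycle, and produce
#' vocal bouts whose bin-level group occupancy matches the scenario's `p_v`
#' and whose per-animal click budget matches the scenario's cue rate
#' (`proportion_clicking / modal ICI`). Clicks take received levels from the
#' sonar-equation propagation model with the piston beam pattern; within
#' each 5-min window the group heading sweeps an azimuth window (as in the
#' group detection model) while pitch varies normally about zero (as in the
#' click detection model). Clicks below the detection threshold are dropped;
#' false clicks are injected at the configured rates.
#'
#' @param truth A [truth_scenario()].
#' @param effort Effort tibble (one site), e.g. from [generate_effort()].
#' @param seed Optional integer seed.
#' @return List: `clicks` (tibble `time`, `received_level`, `species`,
#'   `site`, `group_id`; `group_id` is `NA` for false clicks), `groups`
#'   (ground-truth ledger: one row per group dive cycle with arrival time,
#'   cycle length, size, position), `n_false`.
#' @export
generate_click_log <- function(truth, effort, seed = NULL) {
  stopifnot(inherits(truth, "truth_scenario"))
  validate_effort(effort)
  site <- unique(effort$site)
  if (length(site) != 1) abort("generate_click_log() expects a single site")
  species <- truth$acoustic$label
  sc <- truth$acoustic
  es <- as.numeric(as_utc_time(effort$start))
  ee <- as.numeric(as_utc_time(effort$end))
  t0 <- min(es)
  t1 <- max(ee)
  effort_s <- sum(ee - es)

  with_seed_if(seed, {
    w_km <- sc$monitoring_radius_km
    disc_km2 <- pi * w_km^2
    group_density_km2 <- truth$true_density / 1000 / truth$mean_group_size
    arrival_rate <- group_density_km2 * disc_km2 / truth$dive_cycle_mean_s
    span <- (t1 - t0) + 4 * truth$dive_cycle_mean_s
    n_groups <- rpois(1, arrival_rate * span)

    groups <- tibble(
      cycle_id = seq_len(n_groups),
      arrival = runif(n_groups, t0 - 4 * truth$dive_cycle_mean_s, t1),
      cycle_s = rlnorm_mean_cv(n_groups, truth$dive_cycle_mean_s, truth$dive_cycle_cv),
      size = if (n_groups > 0) {
        sample(truth$sizes, n_groups, replace = TRUE, prob = truth$group_size_probs)
      } else {
        integer(0)
      },
      range_m = w_km * 1000 * sqrt(runif(n_groups)),
      altitude_m = runif(
        n_groups, sc$animal_altitude_range_m[1],
        sc$animal_altitude_range_m[2]
      ),
      pitch_sd = runif(n_groups, sc$pitch_sd_range_deg[1], sc$pitch_sd_range_deg[2]),
      di = runif(
        n_groups, sc$directivity_index_range[1],
        sc$directivity_index_range[2]
      )
    )

    clicks <- generate_group_clicks(truth, groups)

    # clip to effort and apply the detection threshold
    if (nrow(clicks) > 0) {
      on_eff <- purrr::reduce(
        purrr::map2(es, ee, function(s, e) clicks$t >= s & clicks$t < e),
        `|`
      )
      clicks <- clicks[on_eff & clicks$rl >= sc$detection_threshold, ]
    }

    n_false <- rpois(
      1,
      nrow(clicks) * truth$false_click_rate / (1 - truth$false_click_rate) +
        truth$false_clicks_per_hour / 3600 * effort_s
    )
    false_t <- sample_effort_times(n_false, es, ee)
    false_rl <- if (nrow(clicks) >= 10) {
      sample(clicks$rl, n_false, replace = TRUE)
    } else {
      sc$detection_threshold + stats::rexp(n_false, 1 / 5)
    }

    out <- tibble(
      time = c(clicks$t, false_t),
      received_level = c(clicks$rl, false_rl),
      species = species, site = site,
      group_id = c(clicks$cycle_id, rep(NA_integer_, n_false))
    ) %>% arrange(.data$time)
    out$time <- as_utc_time(out$time)

    list(
      clicks = out,
      groups = groups %>% mutate(arrival = as_utc_time(.data$arrival)),
      n_false = n_false
    )
  })
}

sample_effort_times <- function(n, es, ee) {
  if (n == 0) return(numeric(0))
  len <- ee - es
  idx <- sample.int(length(es), n, replace = TRUE, prob = len)
  es[idx] + runif(n) * len[idx]
}

# click times, orientations and received levels for every group dive cycle
generate_group_clicks <- function(truth, groups) {
  sc <- truth$acoustic
  deg <- pi / 180
  res <- purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    cyc <- g$cycle_s
    # vocal union sized so that expected 5-min-bin occupancy matches p_v
    u_len <- max(0, min(cyc, truth$p_v * cyc - BIN_SECONDS))
    if (u_len <= 0) return(NULL)
    v0 <- g$arrival + runif(1, 0, cyc - u_len)
    duty <- min(1, truth$proportion_clicking * cyc / u_len)
    n_clicks_per_animal <- floor(duty * u_len / truth$modal_ici_s)
    if (n_clicks_per_animal < 1) return(NULL)
    block_s <- 60
    on_s <- duty * block_s
    purrr::map_dfr(seq_len(g$size), function(a) {
      phase <- runif(1, 0, block_s)
      u <- (seq_len(n_clicks_per_animal) - 1) * truth$modal_ici_s
      t <- v0 + phase + floor(u / on_s) * block_s + u %% on_s
      t <- t + rnorm(length(t), 0, truth$modal_ici_s * truth$ici_jitter_cv)
      tibble(cycle_id = g$cycle_id, t = t)
    }) %>% mutate(
      range_m = g$range_m,
      dz = g$altitude_m - sc$receiver_altitude_m,
      pitch_sd = g$pitch_sd, di = g$di
    )
  })
  if (is.null(res) || nrow(res) == 0) {
    return(tibble(
      cycle_id = integer(), t = numeric(), rl = numeric()
    ))
  }

  # per-(group, 5-min bin) azimuth sweep window, uniform centre
  bin_abs <- floor(res$t / BIN_SECONDS)
  key <- bin_abs * 1e6 + res$cycle_id
  uk <- match(key, unique(key))
  n_u <- max(uk)
  bw <- truth$behavior$azimuth_sweep_range_deg
  centre <- runif(n_u, -pi, pi)[uk]
  width <- (runif(n_u, bw[1], bw[2]) * deg)[uk]
  frac <- (res$t %% BIN_SECONDS) / BIN_SECONDS
  dphi <- centre + width * (frac - 0.5)

  slant <- sqrt(res$range_m^2 + res$dz^2)
  sin_eps <- -res$dz / slant
  cos_eps <- res$range_m / slant
  pitch <- rnorm(nrow(res), 0, res$pitch_sd) * deg
  cos_th <- cos(pitch) * cos_eps * cos(dphi) + sin(pitch) * sin_eps
  theta <- acos(pmin(pmax(cos_th, -1), 1)) / deg
  sl <- rnorm(nrow(res), sc$source_level_mean, sc$source_level_sd)
  loss <- beam_loss(theta, res$di, sc$beam_floor_db)
  rl <- sl - transmission_loss(sc, slant) - loss
  tibble(cycle_id = res$cycle_id, t = res$t, rl = rl)
}

#' Generate synthetic dive-cycle tag records
#'
#' Tag records whose expected per-cycle proportion of click-positive seconds
#' equals the requested value; between-cycle variation follows a beta
#' distribution, and click-positive seconds form one contiguous vocal phase
#' per cycle. With `tagging_effect = TRUE` the first cycle's proportion is
#' halved, emulating a post-tagging suppression of clicking.
#'
#' @param n_cycles Number of dive cycles (>= 2).
#' @param proportion Expected proportion of click-positive seconds
#'   (default 0.243).
#' @param between_cycle_cv Between-cycle CV of the proportion (default 0.3).
#' @param duration_mean_s,duration_cv Lognormal cycle length (defaults
#'   7200 s, CV 0.2).
#' @param tagging_effect Bias the first cycle low (default FALSE).
#' @param seed Optional integer seed.
#' @return Tag tibble `cycle_id`, `duration_s`, `cps`.
#' @export
generate_tag_records <- function(n_cycles, proportion = 0.243,
                                 between_cycle_cv = 0.3,
                                 duration_mean_s = 7200, duration_cv = 0.2,
                                 tagging_effect = FALSE, seed = NULL) {
  if (n_cycles < 2) abort("need at least two dive cycles")
  with_seed_if(seed, {
    dur <- round(rlnorm_mean_cv(n_cycles, duration_mean_s, duration_cv))
    p <- if (between_cycle_cv > 0 && proportion < 1) {
      v <- (proportion * between_cycle_cv)^2
      k <- max(proportion * (1 - proportion) / v - 1, 1e-3)
      stats::rbeta(n_cycles, proportion * k, (1 - proportion) * k)
    } else {
      rep(proportion, n_cycles)
    }
    if (tagging_effect) p[1] <- p[1] / 2
    cps <- purrr::map2(p, dur, function(pp, d) {
      len <- round(pp * d)
      if (len == 0) return(integer(0))
      s0 <- sample.int(d - len + 1, 1) - 1
      seq.int(s0, s0 + len - 1)
    })
    tibble(cycle_id = seq_len(n_cycles), duration_s = dur, cps = cps)
  })
}

#' Generate two-animal vocal-bout tables with a target overlap
#'
#' Each encounter holds two animals with equal-length bouts offset so the
#' overlap statistic equals the target (optionally jittered between
#' encounters).
#'
#' @param o_target Target overlap, in `[0, 1]`.
#' @param n_encounters Number of encounters.
#' @param bout_length_s Bout length, seconds (default 600).
#' @param jitter_sd Between-encounter jitter on the overlap (default 0).
#' @param seed Optional integer seed.
#' @return Bout tibble `encounter_id`, `animal_id`, `start_s`, `end_s`.
#' @export
generate_synchrony_bouts <- function(o_target, n_encounters, bout_length_s = 600,
                                     jitter_sd = 0, seed = NULL) {
  if (o_target < 0 || o_target > 1) abort("o_target must lie in [0, 1]")
  with_seed_if(seed, {
    o <- pmin(1, pmax(0, o_target + rnorm(n_encounters, 0, jitter_sd)))
    purrr::map_dfr(seq_len(n_encounters), function(i) {
      s <- (1 - o[i]) * bout_length_s
      tibble(
        encounter_id = i,
        animal_id = c("A", "B"),
        start_s = c(0, s),
        end_s = c(bout_length_s, s + bout_length_s)
      )
    })
  })
}

#' Generate group-size samples
#'
#' @param n Number of encounters.
#' @param probs Named probability vector over sizes (default the
#'   [truth_scenario()] default).
#' @param seed Optional integer seed.
#' @return Integer vector of group sizes.
#' @export
generate_group_sizes <- function(n, probs = c(
                                   "1" = 0.35, "2" = 0.45, "3" = 0.15,
                                   "4" = 0.05
                                 ), seed = NULL) {
  with_seed_if(seed, {
    sample(as.integer(names(probs)), n, replace = TRUE, prob = probs)
  })
}
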