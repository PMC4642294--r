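#' Delta-method CV combination
#'
#' First-order variance propagation for a product/quotient of independent
#' estimates: the combined CV is the root of the sum of squared component
#' CVs.
#'
#' @param cvs Numeric vector of component CVs (all >= 0).
#' @return The combined CV.
#' @export
delta_cv <- function(cvs) {
  if (any(cvs < 0)) abort("CVs must be non-negative")
  sqrt(sum(cvs^2))
}

#' Lognormal confidence interval for a density estimate
#'
#' Interval bounds assuming the density estimate is lognormally distributed
#' (precluding negative densities): `C = exp(z * sqrt(log(1 + cv^2)))` and
#' the interval is `(D / C, D * C)`, log-symmetric about the estimate.
#'
#' @param density Point estimate (>= 0). Vectorized.
#' @param cv Coefficient of variation (>= 0).
#' @param level Confidence level (default 0.95).
#' @return Tibble `low`, `high`. A zero density gives `(0, 0)`.
#' @export
lognormal_ci <- function(density, cv, level = 0.95) {
  if (any(density < 0) || any(cv < 0)) abort("density and cv must be non-negative")
  z <- qnorm(1 - (1 - level) / 2)
  c_mult <- exp(z * sqrt(log(1 + cv^2)))
  tibble(
    low = ifelse(density > 0, density / c_mult, 0),
    high = ifelse(density > 0, density * c_mult, 0)
  )
}

density_result <- function(d_1000km2, cvs, level) {
  cv <- purrr::map_dbl(purrr::transpose(cvs), function(row) delta_cv(unlist(row)))
  ci <- lognormal_ci(d_1000km2, cv, level)
  tibble(
    density_per_1000km2 = d_1000km2,
    cv = cv,
    sd = d_1000km2 * cv,
    ci_low = ci$low,
    ci_high = ci$high
  )
}

#' Cue-count (click counting) density estimate
#'
#' Density from the number of detected echolocation clicks:
#' `D = (n/T) (1 - c) / (r P_k pi w^2)`, converted to animals per 1000 km^2.
#' `n/T` is the detected click rate at the site, `c` the false-detection
#' proportion, `r` the per-animal cue production rate, `P_k` the probability
#' of detecting a click produced within the monitoring radius `w`. The CV
#' combines the component CVs (count, false rate, click rate, detection
#' probability) by the delta method and the interval is lognormal.
#'
#' @param n_clicks Detected clicks in the period. Vectorized over rows.
#' @param t_seconds Effort seconds in the period.
#' @param false_rate False-detection proportion for clicks, in `[0, 1)`.
#' @param click_rate Cue production rate `r`, clicks/s.
#' @param p_k Click detection probability within `w`.
#' @param w_km Monitoring radius, km (default 4).
#' @param false_rate_cv,click_rate_cv,p_k_cv,count_cv Component CVs
#'   (default 0).
#' @param ci_level Confidence level for the lognormal interval.
#' @return Tibble `density_per_1000km2`, `cv`, `sd`, `ci_low`, `ci_high`.
#' @export
click_density <- function(n_clicks, t_seconds, false_rate, click_rate, p_k,
                          w_km = 4, false_rate_cv = 0, click_rate_cv = 0,
                          p_k_cv = 0, count_cv = 0, ci_level = 0.95) {
  if (any(t_seconds <= 0)) abort("effort must be positive")
  if (any(click_rate <= 0) || any(p_k <= 0)) {
    abort("click rate and detection probability must be positive")
  }
  d <- (n_clicks / t_seconds) * (1 - false_rate) /
    (click_rate * p_k * pi * w_km^2) * 1000
  n <- length(d)
  density_result(
    d,
    list(
      count = rep_len(count_cv, n), false_rate = rep_len(false_rate_cv, n),
      rate = rep_len(click_rate_cv, n), p_k = rep_len(p_k_cv, n)
    ),
    ci_level
  )
}

#' Group-count density estimate
#'
#' Density from the number of 5-min bins with a detected group:
#' `D = (n/T) (1 - c) S / (P_k P_v pi w^2)`, converted to animals per
#' 1000 km^2. `n/T` is the proportion of effort bins with a detection, `S`
#' the expected group size, `P_v` the probability that a group is vocally
#' active in a bin and `P_k` the group detection probability within `w`.
#'
#' @param n_bins_detected Bins with a detected group. Vectorized over rows.
#' @param t_bins Effort bins in the period.
#' @param false_rate False-detection proportion for whole bins.
#' @param group_size Expected group size `S`.
#' @param p_v Group vocal-activity probability per bin.
#' @param p_k Group detection probability within `w`.
#' @param w_km Monitoring radius, km (default 4).
#' @param false_rate_cv,group_size_cv,p_v_cv,p_k_cv,count_cv Component CVs.
#' @param ci_level Confidence level for the lognormal interval.
#' @return Tibble `density_per_1000km2`, `cv`, `sd`, `ci_low`, `ci_high`.
#' @export
group_density <- function(n_bins_detected, t_bins, false_rate, group_size, p_v,
                          p_k, w_km = 4, false_rate_cv = 0, group_size_cv = 0,
                          p_v_cv = 0, p_k_cv = 0, count_cv = 0,
                          ci_level = 0.95) {
  if (any(t_bins <= 0)) abort("effort must be positive")
  if (any(p_v <= 0) || any(p_k <= 0)) {
    abort("vocal-activity and detection probabilities must be positive")
  }
  d <- (n_bins_detected / t_bins) * (1 - false_rate) * group_size /
    (p_k * p_v * pi * w_km^2) * 1000
  n <- length(d)
  density_result(
    d,
    list(
      count = rep_len(count_cv, n), false_rate = rep_len(false_rate_cv, n),
      size = rep_len(group_size_cv, n), p_v = rep_len(p_v_cv, n),
      p_k = rep_len(p_k_cv, n)
    ),
    ci_level
  )
}

#' Multiplier set for one species at one site
#'
#' Collects the multipliers either counting mode needs, each with a CV:
#' the false-detection proportion, the cue production rate (click mode), the
#' group size and group vocal-activity probability (group mode), and the
#' detection probability with the monitoring radius.
#'
#' @param species,site Labels.
#' @param false_rate,false_rate_cv False-detection proportion and CV.
#' @param click_rate,click_rate_cv Cue rate `r` (click mode).
#' @param group_size,group_size_cv Expected group size `S` (group mode).
#' @param p_v,p_v_cv Group vocal-activity probability (group mode).
#' @param p_k,p_k_cv Detection probability within `w`.
#' @param w_km Monitoring radius, km.
#' @return A one-row tibble of class `pam_multipliers`.
#' @export
multiplier_set <- function(species, site, false_rate, false_rate_cv = 0,
                           click_rate = NA_real_, click_rate_cv = 0,
                           group_size = NA_real_, group_size_cv = 0,
                           p_v = NA_real_, p_v_cv = 0,
                           p_k, p_k_cv = 0, w_km = 4) {
  out <- tibble(
    species = species, site = site,
    false_rate = false_rate, false_rate_cv = false_rate_cv,
    click_rate = click_rate, click_rate_cv = click_rate_cv,
    group_size = group_size, group_size_cv = group_size_cv,
    p_v = p_v, p_v_cv = p_v_cv, p_k = p_k, p_k_cv = p_k_cv, w_km = w_km
  )
  class(out) <- c("pam_multipliers", class(out))
  out
}

check_multipliers <- function(m, method) {
  need <- if (method == "click") {
    c("false_rate", "click_rate", "p_k")
  } else {
    c("false_rate", "group_size", "p_v", "p_k")
  }
  for (q in need) {
    if (!q %in% names(m) || anyNA(m[[q]])) {
      abort(sprintf("multiplier '%s' is missing for method '%s'", q, method))
    }
  }
  invisible(m)
}

# bootstrap CV of the weekly count from its per-bin counts
bootstrap_count_cv <- function(bin_counts, statistic = sum, n_boot = 500) {
  obs <- statistic(bin_counts)
  if (obs == 0 || length(bin_counts) < 2) return(0)
  nb <- length(bin_counts)
  reps <- purrr::map_dbl(seq_len(n_boot), function(i) {
    statistic(bin_counts[sample.int(nb, nb, replace = TRUE)])
  })
  sd(reps) / obs
}

#' Weekly density series
#'
#' Applies the cue-count or group-count estimator to each weekly row,
#' combining the count-level CV (nonparametric bootstrap over the week's
#' 5-min bins, when the bin series is supplied) with the multiplier CVs by
#' the delta method, and attaching lognormal intervals.
#'
#' @param weekly Weekly counts from [weekly_aggregate()].
#' @param multipliers A [multiplier_set()] (or tibble of them, one row per
#'   species x site).
#' @param method `"click"` or `"group"`.
#' @param bins Optional bin series from [bin_clicks()] used to bootstrap the
#'   weekly count CV; without it the count CV is 0.
#' @param n_boot Bootstrap resamples per week (default 500).
#' @param ci_level Confidence level.
#' @param seed Optional integer seed for the bootstrap.
#' @return Tibble `week_start`, `site`, `species`, `method`,
#'   `density_per_1000km2`, `cv`, `sd`, `ci_low`, `ci_high`.
#' @export
weekly_series <- function(weekly, multipliers, method = c("click", "group"),
                          bins = NULL, n_boot = 500, ci_level = 0.95,
                          seed = NULL) {
  method <- match.arg(method)
  with_seed_if(seed, {
    rows <- weekly %>%
      left_join(as_tibble(multipliers), by = c("species", "site"))
    if (anyNA(rows$p_k)) {
      miss <- rows %>%
        filter(is.na(.data$p_k)) %>%
        dplyr::distinct(.data$species, .data$site)
      abort(sprintf(
        "no multipliers for: %s",
        paste(miss$species, miss$site, sep = "/", collapse = ", ")
      ))
    }
    check_multipliers(rows, method)

    count_cv <- rep(0, nrow(rows))
    if (!is.null(bins)) {
      bw <- bins %>%
        mutate(week = week_floor(as.numeric(as_utc_time(.data$bin_start))))
      stat <- if (method == "click") {
        function(x) sum(x)
      } else {
        function(x) sum(x >= 5)
      }
      count_cv <- purrr::map_dbl(seq_len(nrow(rows)), function(i) {
        wk <- as.numeric(as_utc_time(as.POSIXct(rows$week_start[i], tz = "UTC")))
        cnts <- bw$n_clicks[bw$week == wk]
        if (length(cnts) == 0) 0 else bootstrap_count_cv(cnts, stat, n_boot)
      })
    }

    est <- if (method == "click") {
      click_density(
        rows$n_clicks, rows$t_seconds, rows$false_rate, rows$click_rate,
        rows$p_k,
        w_km = rows$w_km, false_rate_cv = rows$false_rate_cv,
        click_rate_cv = rows$click_rate_cv, p_k_cv = rows$p_k_cv,
        count_cv = count_cv, ci_level = ci_level
      )
    } else {
      group_density(
        rows$n_bins_detected, rows$t_bins, rows$false_rate, rows$group_size,
        rows$p_v, rows$p_k,
        w_km = rows$w_km, false_rate_cv = rows$false_rate_cv,
        group_size_cv = rows$group_size_cv, p_v_cv = rows$p_v_cv,
        p_k_cv = rows$p_k_cv, count_cv = count_cv, ci_level = ci_level
      )
    }
    dplyr::bind_cols(
      rows %>% select("week_start", "site", "species"),
      tibble(method = method),
      est
    )
  })
}

#' Average density over a weekly series
#'
#' Multi-week average: the mean of the weekly point estimates, with the
#' count-level CV taken as the empirical standard error of the weekly
#' estimates about their mean, combined with the (shared) multiplier CVs by
#' the delta method.
#'
#' @param series Output of [weekly_series()].
#' @param multiplier_cv Combined CV of the shared multipliers (e.g.
#'   `delta_cv(c(...))` over false rate, rate or size/vocal terms, and
#'   `p_k`). Default 0.
#' @param ci_level Confidence level.
#' @return One-row tibble `density_per_1000km2`, `cv`, `sd`, `ci_low`,
#'   `ci_high`, `n_weeks`.
#' @export
average_density <- function(series, multiplier_cv = 0, ci_level = 0.95) {
  d <- series$density_per_1000km2
  m <- mean(d)
  se_cv <- if (length(d) > 1 && m > 0) sd(d) / sqrt(length(d)) / m else 0
  cv <- delta_cv(c(se_cv, multiplier_cv))
  ci <- lognormal_ci(m, cv, ci_level)
  tibble(
    density_per_1000km2 = m, cv = cv, sd = m * cv,
    ci_low = ci$low, ci_high = ci$high, n_weeks = length(d)
  )
}
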