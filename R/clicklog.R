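#' Read a click-detection log
#'
#' Reads a CSV click log with columns `time_iso8601`, `received_level_dbpp`,
#' `species`, `site` into the tibble format used throughout the package
#' (`time` as POSIXct UTC, `received_level`, `species`, `site`).
#'
#' @param path Path to a CSV file.
#' @return A tibble sorted by time.
#' @export
read_click_log <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble(
    time = as_utc_time(raw$time_iso8601),
    received_level = as.numeric(raw$received_level_dbpp),
    species = as.character(raw$species),
    site = as.character(raw$site)
  ) %>% arrange(.data$time)
}

#' Read a recording-effort table
#'
#' CSV columns `site`, `start_iso8601`, `end_iso8601`; on-effort periods must
#' be non-overlapping within a site.
#'
#' @param path Path to a CSV file.
#' @return A tibble with `site`, `start`, `end` (POSIXct UTC).
#' @export
read_effort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- tibble(
    site = as.character(raw$site),
    start = as_utc_time(raw$start_iso8601),
    end = as_utc_time(raw$end_iso8601)
  )
  validate_effort(out)
  out
}

validate_effort <- function(effort) {
  if (any(effort$end <= effort$start)) {
    abort("effort periods must have start < end")
  }
  overlap <- effort %>%
    group_by(.data$site) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    summarise(bad = any(.data$start[-1] < .data$end[-dplyr::n()]), .groups = "drop")
  if (any(overlap$bad)) abort("effort periods overlap within a site")
  invisible(effort)
}

#' Assemble click encounters
#'
#' Groups a time-sorted click log (one species, one site) into encounters:
#' runs of clicks with no inter-click gap longer than `max_gap` seconds.
#' Encounters whose clicking span (first click to last click) is not longer
#' than `min_duration` seconds are discarded, the rule used to screen out
#' isolated false detections.
#'
#' @param clicks Tibble with at least a `time` column (POSIXct or numeric
#'   seconds), sorted by time. `species` and `site` columns, if present, are
#'   carried through and must be single-valued.
#' @param max_gap Maximum within-encounter gap between successive clicks,
#'   seconds (default one hour).
#' @param min_duration Minimum clicking span for a retained encounter,
#'   seconds; spans less than or equal to this are dropped (default 75 s).
#' @return Tibble with `species`, `site`, `start`, `end`, `n_clicks`, one row
#'   per retained encounter. Empty input gives an empty tibble.
#' @export
assemble_encounters <- function(clicks, max_gap = 3600, min_duration = 75) {
  species <- if ("species" %in% names(clicks)) unique(clicks$species) else NA_character_
  site <- if ("site" %in% names(clicks)) unique(clicks$site) else NA_character_
  if (length(species) > 1 || length(site) > 1) {
    abort("assemble_encounters() expects a single species and site; split first")
  }
  empty <- tibble(
    species = character(), site = character(),
    start = as_utc_time(numeric()), end = as_utc_time(numeric()),
    n_clicks = integer()
  )
  if (nrow(clicks) == 0) return(empty)
  t <- as.numeric(as_utc_time(clicks$time))
  if (is.unsorted(t)) abort("click log must be sorted by time")
  enc_id <- cumsum(c(1, as.integer(diff(t) > max_gap)))
  out <- tibble(t = t, enc = enc_id) %>%
    group_by(.data$enc) %>%
    summarise(
      start = min(.data$t), end = max(.data$t),
      n_clicks = dplyr::n(), .groups = "drop"
    ) %>%
    filter(.data$end - .data$start > min_duration, .data$n_clicks >= 2) %>%
    mutate(
      species = species, site = site,
      start = as_utc_time(.data$start), end = as_utc_time(.data$end)
    ) %>%
    select("species", "site", "start", "end", "n_clicks")
  out
}

# full 5-min bins wholly inside one effort period, on the global UTC grid
effort_bins <- function(start_s, end_s, bin_length = BIN_SECONDS) {
  b0 <- ceiling(start_s / bin_length) * bin_length
  b1 <- floor(end_s / bin_length) * bin_length
  if (b1 <= b0) return(numeric(0))
  seq(b0, b1 - bin_length, by = bin_length)
}

#' Bin clicks into 5-minute detection bins
#'
#' Lays a fixed 5-minute grid (anchored at the UTC epoch, so Sunday 00:00 UTC
#' week boundaries coincide with bin boundaries) over the on-effort periods
#' and counts clicks per bin. Only bins lying wholly inside an effort period
#' are produced. A bin is flagged `detected` when it holds at least
#' `min_clicks` clicks, the rule used to screen false detections from the
#' group-counting data stream.
#'
#' @param clicks Click tibble (`time`, optionally `species`, `site`); a single
#'   species and site.
#' @param effort Effort tibble (`site`, `start`, `end`).
#' @param bin_length Bin length in seconds (default 300).
#' @param min_clicks Detection threshold per bin (default 5 clicks).
#' @return Tibble `site`, `species`, `bin_start` (POSIXct), `n_clicks`,
#'   `detected`, one row per effort bin (zero-filled). Clicks falling outside
#'   all effort bins are excluded with a warning giving the count.
#' @export
bin_clicks <- function(clicks, effort, bin_length = BIN_SECONDS, min_clicks = 5) {
  species <- if ("species" %in% names(clicks) && nrow(clicks) > 0) {
    unique(clicks$species)
  } else {
    NA_character_
  }
  if (length(species) > 1) abort("bin_clicks() expects a single species; split first")
  validate_effort(effort)
  site <- unique(effort$site)
  if (length(site) != 1) abort("bin_clicks() expects effort for a single site")

  bins <- purrr::map2(
    as.numeric(as_utc_time(effort$start)), as.numeric(as_utc_time(effort$end)),
    effort_bins, bin_length = bin_length
  )
  bin_start <- sort(unique(unlist(bins)))
  out <- tibble(
    site = site, species = species,
    bin_start = bin_start, n_clicks = 0L
  )
  if (nrow(clicks) > 0) {
    t <- as.numeric(as_utc_time(clicks$time))
    b <- floor(t / bin_length) * bin_length
    inside <- b %in% bin_start
    if (any(!inside)) {
      warn(sprintf("%d click(s) outside effort bins were excluded", sum(!inside)))
    }
    cnt <- table(b[inside])
    idx <- match(as.numeric(names(cnt)), out$bin_start)
    out$n_clicks[idx] <- as.integer(cnt)
  }
  out %>%
    mutate(
      detected = .data$n_clicks >= min_clicks,
      bin_start = as_utc_time(.data$bin_start)
    )
}

week_floor <- function(t_seconds) {
  # Sunday 00:00 UTC; the first Sunday after the epoch (a Thursday) is day 3
  floor((t_seconds - 3 * 86400) / WEEK_SECONDS) * WEEK_SECONDS + 3 * 86400
}

# effort seconds per Sunday-aligned week for one site
weekly_effort <- function(effort) {
  purrr::map2_dfr(
    as.numeric(as_utc_time(effort$start)), as.numeric(as_utc_time(effort$end)),
    function(s, e) {
      ws <- week_floor(s)
      brks <- unique(c(s, seq(ws + WEEK_SECONDS, week_floor(e - 0.5) + WEEK_SECONDS,
        by = WEEK_SECONDS
      ), e))
      brks <- sort(brks[brks >= s & brks <= e])
      if (length(brks) < 2) brks <- c(s, e)
      tibble(
        week = week_floor(brks[-length(brks)]),
        seconds = diff(brks)
      )
    }
  ) %>%
    group_by(.data$week) %>%
    summarise(t_seconds = sum(.data$seconds), .groups = "drop")
}

#' Aggregate clicks and bins into weekly counts
#'
#' Aggregates a 5-minute bin series, the underlying click log and the effort
#' table into weekly counts for both counting modes: `n_clicks` (all detected
#' clicks on effort, the cue-count stream, counted before the per-bin
#' threshold) and `n_bins_detected` (bins with at least 5 clicks, the
#' group-count stream). Weeks run Sunday through Saturday (UTC). Partial weeks
#' at the start or end of a deployment with less than `edge_min_days` of
#' cumulative effort are merged into the adjacent week, which then carries
#' the combined effort.
#'
#' @param bins Output of [bin_clicks()].
#' @param clicks The click tibble that produced `bins`.
#' @param effort Effort tibble for the same site.
#' @param edge_min_days Minimum days of effort for a standalone edge week
#'   (default 2; interpreted as 48 h of cumulative effort).
#' @return Tibble `week_start` (Date, a Sunday), `site`, `species`,
#'   `n_clicks`, `n_bins_detected`, `t_seconds`, `t_bins`. Weeks without
#'   effort yield no row. A merged edge week can push `t_bins` above the 2016
#'   bins of a single full week.
#' @export
weekly_aggregate <- function(bins, clicks, effort, edge_min_days = 2) {
  species <- unique(bins$species)
  site <- unique(bins$site)
  if (length(species) != 1 || length(site) != 1) {
    abort("weekly_aggregate() expects one species and one site")
  }
  eff <- weekly_effort(effort)
  if (nrow(eff) == 0) {
    return(tibble(
      week_start = as.Date(character()), site = character(), species = character(),
      n_clicks = integer(), n_bins_detected = integer(),
      t_seconds = numeric(), t_bins = integer()
    ))
  }

  bs <- as.numeric(as_utc_time(bins$bin_start))
  bin_week <- week_floor(bs)
  bint <- tibble(week = bin_week, n = bins$n_clicks, det = bins$detected) %>%
    group_by(.data$week) %>%
    summarise(
      n_bins_detected = sum(.data$det), t_bins = dplyr::n(),
      .groups = "drop"
    )

  # clicks counted over all effort (clicks inside any effort period)
  clk <- tibble(week = numeric(0), n_clicks = integer(0))
  if (nrow(clicks) > 0) {
    t <- as.numeric(as_utc_time(clicks$time))
    es <- as.numeric(as_utc_time(effort$start))
    ee <- as.numeric(as_utc_time(effort$end))
    on_eff <- purrr::map_lgl(t, function(x) any(x >= es & x < ee))
    clk <- tibble(week = week_floor(t[on_eff])) %>%
      count(.data$week, name = "n_clicks")
  }

  wk <- eff %>%
    left_join(bint, by = "week") %>%
    left_join(clk, by = "week") %>%
    mutate(
      n_bins_detected = dplyr::coalesce(.data$n_bins_detected, 0L),
      t_bins = dplyr::coalesce(.data$t_bins, 0L),
      n_clicks = dplyr::coalesce(.data$n_clicks, 0L)
    ) %>%
    arrange(.data$week)

  # merge under-effort edge weeks into the adjacent week
  edge_s <- edge_min_days * 86400
  if (nrow(wk) > 1 && wk$t_seconds[1] < edge_s) {
    wk$week[1] <- wk$week[2]
  }
  nr <- nrow(wk)
  if (nr > 1 && wk$t_seconds[nr] < edge_s) {
    wk$week[nr] <- wk$week[nr - 1]
  }
  wk %>%
    group_by(.data$week) %>%
    summarise(
      n_clicks = sum(.data$n_clicks),
      n_bins_detected = sum(.data$n_bins_detected),
      t_seconds = sum(.data$t_seconds),
      t_bins = sum(.data$t_bins),
      .groups = "drop"
    ) %>%
    mutate(
      week_start = as.Date(as_utc_time(.data$week)),
      site = site, species = species
    ) %>%
    select(
      "week_start", "site", "species", "n_clicks", "n_bins_detected",
      "t_seconds", "t_bins"
    )
}

#' Estimate the false-detection proportion from a labelled subsample
#'
#' Proportion of manually labelled detections (clicks or whole 5-min bins)
#' that are false, with a binomial CV.
#'
#' @param is_false Logical vector: TRUE for a false detection. A data frame
#'   with an `is_false` column is also accepted.
#' @return One-row tibble `proportion`, `cv`, `n`. With zero false detections
#'   the CV is undefined and is reported as 0 with a warning.
#' @export
estimate_false_rate <- function(is_false) {
  if (is.data.frame(is_false)) is_false <- is_false$is_false
  is_false <- as.logical(is_false)
  n <- length(is_false)
  if (n < 1) abort("need at least one labelled detection")
  p <- mean(is_false)
  if (p == 0) {
    warn("no false detections in sample; CV undefined, reported as 0")
    cv <- 0
  } else {
    cv <- sqrt(p * (1 - p) / n) / p
  }
  tibble(proportion = p, cv = cv, n = n)
}
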