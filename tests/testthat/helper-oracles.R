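# Independent oracles used to freeze expected values. These deliberately use
# naive algorithms, separate from the package's implementations.

# brute-force encounter scan: walk the sorted times, split on gaps, filter
oracle_encounters <- function(times, max_gap = 3600, min_duration = 75) {
  if (length(times) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0), n = integer(0)))
  }
  out <- list()
  cur <- times[1]
  for (t in times[-1]) {
    last <- cur[length(cur)]
    if (t - last > max_gap) {
      out[[length(out) + 1]] <- cur
      cur <- t
    } else {
      cur <- c(cur, t)
    }
  }
  out[[length(out) + 1]] <- cur
  res <- do.call(rbind, lapply(out, function(x) {
    data.frame(start = min(x), end = max(x), n = length(x))
  }))
  res[res$end - res$start > min_duration & res$n >= 2, , drop = FALSE]
}

# histogram oracle for 5-min bin counts on a fixed grid
oracle_bin_counts <- function(times, bin_starts, bin_length = 300) {
  vapply(
    bin_starts,
    function(b) sum(times >= b & times < b + bin_length),
    integer(1)
  )
}

# histogram-argmax mode at 5-ms resolution
oracle_hist_mode <- function(x, width = 0.005) {
  brks <- seq(0, 1, by = width)
  h <- hist(x[x > 0 & x < 1], breaks = brks, plot = FALSE)
  h$mids[which.max(h$counts)]
}

# exhaustive-start expected proportion of occupied 5-min bins for one cycle
oracle_bin_proportion <- function(cps, dur, bin_s = 300) {
  n_bins <- floor(dur / bin_s)
  mean(vapply(0:(dur - 1), function(st) {
    shifted <- (cps - st) %% dur
    length(unique(shifted[shifted < n_bins * bin_s] %/% bin_s)) / n_bins
  }, numeric(1)))
}

# directivity index recomputed by quadrature from a beam-loss curve
oracle_di_from_pattern <- function(di, floor_db = 60) {
  f <- function(th_deg) {
    b <- 10^(-pamdensity::beam_loss(th_deg, di, floor_db = floor_db) / 20)
    b^2 * sin(th_deg * pi / 180) * pi / 180
  }
  integral <- stats::integrate(f, 0, 90, subdivisions = 500, rel.tol = 1e-7)$value
  10 * log10(2 / integral)
}

sim_click_tbl <- function(times, species = "Zc", site = "MC") {
  tibble::tibble(
    time = as.POSIXct(times, origin = "1970-01-01", tz = "UTC"),
    received_level = 130,
    species = species, site = site
  )
}

sim_effort_tbl <- function(start, end, site = "MC") {
  tibble::tibble(
    site = site,
    start = as.POSIXct(start, origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(end, origin = "1970-01-01", tz = "UTC")
  )
}

# a Sunday 00:00 UTC anchor used across tests
SUNDAY <- as.numeric(as.POSIXct("2011-01-02 00:00:00", tz = "UTC"))
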