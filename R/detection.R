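#' Acoustic scenario for the detection simulation
#'
#' Bundles the sound-production and geometry parameters of one species/site:
#' click source level (mean and spread), peak frequency and the matching
#' seawater absorption, click directivity, the detection threshold of the
#' recorder, the vertical geometry (animal altitude band and receiver height
#' above the seafloor) and the monitoring radius.
#'
#' @param source_level_mean Mean click source level, dB pp re 1 uPa at 1 m.
#' @param source_level_sd Click-to-click source-level spread, dB (default 3).
#' @param peak_frequency_khz Click peak frequency, kHz.
#' @param directivity_index_range Two-element range of directivity index, dB.
#' @param detection_threshold Detection threshold, dB pp re 1 uPa
#'   (default 121).
#' @param absorption_db_km Absorption at the peak frequency, dB/km. `NULL`
#'   computes it from `peak_frequency_khz` via [absorption_coefficient()]
#'   with the default deep-water properties.
#' @param receiver_altitude_m Receiver height above the seafloor, m
#'   (default 10).
#' @param animal_altitude_range_m Two-element band of animal altitude above
#'   the seafloor during vocal phases, m (default `c(175, 225)`).
#' @param monitoring_radius_km Monitoring radius `w`, km (default 4).
#' @param pitch_sd_range_deg Range of the per-animal pitch standard
#'   deviation, degrees (default `c(5, 15)`; mean body angle is 0).
#' @param beam_floor_db Far-off-axis beam-loss floor, dB (default 40).
#' @param label Free-text label for printing.
#' @return An object of class `acoustic_scenario`.
#' @export
acoustic_scenario <- function(source_level_mean,
                              source_level_sd = 3,
                              peak_frequency_khz,
                              directivity_index_range = c(24, 28),
                              detection_threshold = 121,
                              absorption_db_km = NULL,
                              receiver_altitude_m = 10,
                              animal_altitude_range_m = c(175, 225),
                              monitoring_radius_km = 4,
                              pitch_sd_range_deg = c(5, 15),
                              beam_floor_db = 40,
                              label = "scenario") {
  if (is.null(absorption_db_km)) {
    absorption_db_km <- absorption_coefficient(peak_frequency_khz)
  }
  if (source_level_mean <= detection_threshold) {
    warn("source level does not exceed the detection threshold; nothing will be detectable")
  }
  if (monitoring_radius_km <= 0) abort("monitoring radius must be positive")
  stopifnot(
    diff(directivity_index_range) >= 0,
    diff(animal_altitude_range_m) >= 0,
    diff(pitch_sd_range_deg) >= 0
  )
  structure(
    list(
      source_level_mean = source_level_mean,
      source_level_sd = source_level_sd,
      peak_frequency_khz = peak_frequency_khz,
      directivity_index_range = directivity_index_range,
      detection_threshold = detection_threshold,
      absorption_db_km = absorption_db_km,
      receiver_altitude_m = receiver_altitude_m,
      animal_altitude_range_m = animal_altitude_range_m,
      monitoring_radius_km = monitoring_radius_km,
      pitch_sd_range_deg = pitch_sd_range_deg,
      beam_floor_db = beam_floor_db,
      label = label
    ),
    class = "acoustic_scenario"
  )
}

#' Gulf of Mexico default scenarios
#'
#' The shipped parameter sets for Cuvier's and Gervais' beaked whales:
#' source level 225 +/- 3 (Cuvier's) and 220 +/- 3 dB pp (Gervais'),
#' directivity 24-28 dB, detection threshold 121 dB pp, absorption 10.05 and
#' 11.30 dB/km at peak frequencies 40.2 and 43.8 kHz, dive altitudes
#' 175-225 m, receiver 10 m above the seafloor, monitoring radius 4 km.
#'
#' @return An `acoustic_scenario`.
#' @export
scenario_cuviers_gom <- function() {
  read_scenario(system.file("extdata", "cuviers_gom.yaml", package = "pamdensity"))
}

#' @rdname scenario_cuviers_gom
#' @export
scenario_gervais_gom <- function() {
  read_scenario(system.file("extdata", "gervais_gom.yaml", package = "pamdensity"))
}

#' Read an acoustic scenario from a YAML config
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [acoustic_scenario()].
#' @return An `acoustic_scenario`.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(acoustic_scenario, cfg)
}

#' @export
print.acoustic_scenario <- function(x, ...) {
  cat(sprintf(
    "<acoustic_scenario> %s\n  SL %g +/- %g dB pp, DI %g-%g dB, threshold %g dB pp\n  absorption %.2f dB/km @ %.1f kHz, w = %g km\n",
    x$label, x$source_level_mean, x$source_level_sd,
    x$directivity_index_range[1], x$directivity_index_range[2],
    x$detection_threshold, x$absorption_db_km, x$peak_frequency_khz,
    x$monitoring_radius_km
  ))
  invisible(x)
}

#' Group orientation behaviour over a 5-min window
#'
#' Extent of heading change of a foraging group within a 5-min time bin:
#' azimuthal rotation and elevation rotation (wider while foraging, narrow
#' while descending).
#'
#' @param azimuth_sweep_range_deg Range of total azimuthal rotation, degrees
#'   (default `c(140, 160)`).
#' @param elevation_sweep_foraging_deg Elevation rotation while foraging
#'   (default `c(55, 65)`).
#' @param elevation_sweep_descent_deg Elevation rotation while descending
#'   (default `c(10, 15)`).
#' @param descent_fraction Fraction of groups in the descent phase
#'   (default 0, all foraging).
#' @return An object of class `group_behavior`.
#' @export
group_behavior <- function(azimuth_sweep_range_deg = c(140, 160),
                           elevation_sweep_foraging_deg = c(55, 65),
                           elevation_sweep_descent_deg = c(10, 15),
                           descent_fraction = 0) {
  stopifnot(
    all(azimuth_sweep_range_deg >= 0), all(azimuth_sweep_range_deg <= 360),
    descent_fraction >= 0, descent_fraction <= 1
  )
  structure(
    list(
      azimuth_sweep_range_deg = azimuth_sweep_range_deg,
      elevation_sweep_foraging_deg = elevation_sweep_foraging_deg,
      elevation_sweep_descent_deg = elevation_sweep_descent_deg,
      descent_fraction = descent_fraction
    ),
    class = "group_behavior"
  )
}

#' Monte Carlo simulation settings
#'
#' @param iterations Number of model iterations (default 500).
#' @param n_per_iteration Animals or groups placed per iteration
#'   (default 10000).
#' @param range_bin_m Width of the range bins for the detection function, m
#'   (default 100).
#' @param seed Optional integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(iterations = 500, n_per_iteration = 10000,
                       range_bin_m = 100, seed = NULL) {
  stopifnot(iterations >= 1, n_per_iteration >= 1, range_bin_m > 0)
  structure(
    list(
      iterations = iterations, n_per_iteration = n_per_iteration,
      range_bin_m = range_bin_m, seed = seed
    ),
    class = "sim_config"
  )
}

# uniform placement over the monitoring disc plus vertical geometry
place_animals <- function(scenario, n) {
  w_m <- scenario$monitoring_radius_km * 1000
  rh <- w_m * sqrt(runif(n))
  alt <- runif(
    n, scenario$animal_altitude_range_m[1],
    scenario$animal_altitude_range_m[2]
  )
  dz <- alt - scenario$receiver_altitude_m
  slant <- sqrt(rh^2 + dz^2)
  list(
    rh = rh, dz = dz, slant = slant,
    sin_eps = -dz / slant, cos_eps = rh / slant
  )
}

transmission_loss <- function(scenario, slant) {
  20 * log10(slant) + scenario$absorption_db_km * slant / 1000
}

detfun_result <- function(det_rh, det_flag, p_iter, sim, scenario, mode) {
  n_bins <- ceiling(scenario$monitoring_radius_km * 1000 / sim$range_bin_m)
  centers <- (seq_len(n_bins) - 0.5) * sim$range_bin_m
  bin_of <- pmin(floor(det_rh / sim$range_bin_m), n_bins - 1) + 1
  per_iter <- matrix(0, nrow = length(p_iter), ncol = n_bins)
  # det_rh/det_flag come concatenated with an iteration index attribute
  it <- attr(det_rh, "iteration")
  for (b in seq_len(n_bins)) {
    sel <- bin_of == b
    tab_n <- tabulate(it[sel], nbins = length(p_iter))
    tab_d <- tabulate(it[sel][det_flag[sel]], nbins = length(p_iter))
    per_iter[, b] <- ifelse(tab_n > 0, tab_d / tab_n, NA_real_)
  }
  bins <- tibble(
    range_m = centers,
    prob = apply(per_iter, 2, mean, na.rm = TRUE),
    sd = apply(per_iter, 2, sd, na.rm = TRUE)
  )
  max_r <- if (any(det_flag)) max(det_rh[det_flag]) else NA_real_
  p_k <- mean(p_iter)
  structure(
    list(
      bins = bins,
      p_k = p_k,
      cv = if (p_k > 0) sd(p_iter) / p_k else NA_real_,
      max_detection_range_m = max_r,
      mode = mode,
      n_iterations = sim$iterations,
      n_per_iteration = sim$n_per_iteration,
      scenario = scenario
    ),
    class = "pam_detection_function"
  )
}

#' Simulate single-click detection probability versus range
#'
#' Monte Carlo model of the probability that one echolocation click is
#' received above the detection threshold, as a function of horizontal range.
#' Each iteration places animals uniformly over the monitoring disc with
#' altitude uniform in the configured band, heading uniform on the circle,
#' and pitch normal about 0 with a per-animal standard deviation drawn from
#' the configured range. Each animal emits one click with source level drawn
#' from the normal source-level distribution and a piston beam pattern whose
#' directivity index is drawn from the configured range. A click is detected
#' when the received level, after spherical spreading, absorption along the
#' slant path and off-axis beam loss, is at or above the threshold.
#'
#' @param scenario An [acoustic_scenario()].
#' @param sim A [sim_config()].
#' @return A `pam_detection_function`: range-binned detection probabilities
#'   (mean and between-iteration sd), the disc-averaged probability `p_k`
#'   with its between-iteration CV, and the maximum detection range.
#' @export
simulate_click_detection <- function(scenario, sim = sim_config()) {
  stopifnot(inherits(scenario, "acoustic_scenario"), inherits(sim, "sim_config"))
  with_seed_if(sim$seed, {
    n <- sim$n_per_iteration
    rh_all <- numeric(n * sim$iterations)
    det_all <- logical(n * sim$iterations)
    it_all <- rep(seq_len(sim$iterations), each = n)
    p_iter <- numeric(sim$iterations)
    for (i in seq_len(sim$iterations)) {
      slot <- (i - 1) * n + seq_len(n)
      g <- place_animals(scenario, n)
      pitch_sd <- runif(n, scenario$pitch_sd_range_deg[1], scenario$pitch_sd_range_deg[2])
      pitch <- rnorm(n, 0, pitch_sd) * pi / 180
      dphi <- runif(n, -pi, pi)
      cos_th <- cos(pitch) * g$cos_eps * cos(dphi) + sin(pitch) * g$sin_eps
      theta <- acos(pmin(pmax(cos_th, -1), 1)) * 180 / pi
      di <- runif(n, scenario$directivity_index_range[1], scenario$directivity_index_range[2])
      sl <- rnorm(n, scenario$source_level_mean, scenario$source_level_sd)
      loss <- beam_loss(theta, di, scenario$beam_floor_db)
      rl <- sl - transmission_loss(scenario, g$slant) - loss
      det <- rl >= scenario$detection_threshold
      p_iter[i] <- mean(det)
      rh_all[slot] <- g$rh
      det_all[slot] <- det
    }
    attr(rh_all, "iteration") <- it_all
    detfun_result(rh_all, det_all, p_iter, sim, scenario, mode = "click")
  })
}

# smallest/largest off-axis angle achievable within an azimuth x elevation
# sweep window centred on the group heading; receiver at relative azimuth
# dphi and elevation eps
cone_theta_limits <- function(dphi, sin_eps, cos_eps, az_half, el_half) {
  # residual azimuth offset after steering to the nearest window edge
  delta_near <- pmax(abs(dphi) - az_half, 0)
  a <- cos_eps * cos(delta_near)
  b <- sin_eps
  rr <- sqrt(a^2 + b^2)
  beta <- atan2(b, a)
  el_c <- pmin(pmax(beta, -el_half), el_half)
  theta_min <- acos(pmin(pmax(rr * cos(el_c - beta), -1), 1))
  # farthest corner: far azimuth endpoint, worse elevation endpoint
  delta_far <- pmin(abs(dphi) + az_half, pi)
  a2 <- cos_eps * cos(delta_far)
  rr2 <- sqrt(a2^2 + b^2)
  beta2 <- atan2(b, a2)
  cos_lo <- rr2 * cos(-el_half - beta2)
  cos_hi <- rr2 * cos(el_half - beta2)
  theta_max <- acos(pmin(pmax(pmin(cos_lo, cos_hi), -1), 1))
  list(theta_min = theta_min, theta_max = pmax(theta_max, theta_min))
}

# minimum piston loss over theta in [th_min, th_max] on an angular grid
min_loss_over_interval <- function(th_min, th_max, ka, floor_db, n_grid = 128) {
  m <- length(th_min)
  tt <- seq(0, 1, length.out = n_grid)
  th <- rep(th_min, each = n_grid) + rep(th_max - th_min, each = n_grid) * tt
  loss <- -20 * log10(piston_amplitude(rep(ka, each = n_grid) * sin(th)))
  loss[th > pi / 2] <- floor_db
  loss <- pmin(pmax(loss, 0), floor_db)
  do.call(pmin, asplit(matrix(loss, nrow = n_grid), 1))
}

#' Simulate 5-min group detection probability versus range
#'
#' Monte Carlo model of the probability that a group of echolocating animals
#' is detected at least once during a 5-min time bin. The group is treated as
#' a point source at its centre; over the bin its heading sweeps an azimuth
#' window (width drawn from the configured range, centred on a uniform random
#' heading) and an elevation window (foraging or descent width). The group is
#' detected when any orientation within the swept cone puts the received
#' level at or above the threshold; the minimum beam loss over the cone is
#' found in closed form on the main lobe and on a fine angular grid (about
#' 1.5 degrees) beyond it.
#'
#' @param scenario An [acoustic_scenario()].
#' @param behavior A [group_behavior()].
#' @param sim A [sim_config()].
#' @return A `pam_detection_function` (as for [simulate_click_detection()]),
#'   with `mode = "group"`.
#' @export
simulate_group_detection <- function(scenario, behavior = group_behavior(),
                                     sim = sim_config()) {
  stopifnot(
    inherits(scenario, "acoustic_scenario"),
    inherits(behavior, "group_behavior"), inherits(sim, "sim_config")
  )
  deg <- pi / 180
  with_seed_if(sim$seed, {
    n <- sim$n_per_iteration
    rh_all <- numeric(n * sim$iterations)
    det_all <- logical(n * sim$iterations)
    it_all <- rep(seq_len(sim$iterations), each = n)
    p_iter <- numeric(sim$iterations)
    for (i in seq_len(sim$iterations)) {
      slot <- (i - 1) * n + seq_len(n)
      g <- place_animals(scenario, n)
      az_half <- runif(
        n, behavior$azimuth_sweep_range_deg[1],
        behavior$azimuth_sweep_range_deg[2]
      ) / 2 * deg
      descending <- runif(n) < behavior$descent_fraction
      el_rng <- ifelse(descending,
        runif(n, behavior$elevation_sweep_descent_deg[1], behavior$elevation_sweep_descent_deg[2]),
        runif(n, behavior$elevation_sweep_foraging_deg[1], behavior$elevation_sweep_foraging_deg[2])
      )
      el_half <- el_rng / 2 * deg
      dphi <- runif(n, -pi, pi)
      di <- runif(n, scenario$directivity_index_range[1], scenario$directivity_index_range[2])
      ka <- ka_from_di(di)
      sl <- rnorm(n, scenario$source_level_mean, scenario$source_level_sd)
      margin <- sl - transmission_loss(scenario, g$slant) - scenario$detection_threshold

      lim <- cone_theta_limits(dphi, g$sin_eps, g$cos_eps, az_half, el_half)
      loss_near <- beam_loss(
        pmin(lim$theta_min / deg, 180), di,
        scenario$beam_floor_db
      )
      det <- margin >= scenario$beam_floor_db |
        (margin >= 0 & loss_near <= margin)
      # unresolved: theta_min beyond the first null, moderate margin
      th_null <- asin(pmin(1, 3.8317 / ka))
      open <- !det & margin >= 0 & lim$theta_min > th_null
      if (any(open)) {
        ml <- min_loss_over_interval(
          lim$theta_min[open], lim$theta_max[open], ka[open],
          scenario$beam_floor_db
        )
        det[open] <- ml <= margin[open]
      }
      p_iter[i] <- mean(det)
      rh_all[slot] <- g$rh
      det_all[slot] <- det
    }
    attr(rh_all, "iteration") <- it_all
    detfun_result(rh_all, det_all, p_iter, sim, scenario, mode = "group")
  })
}

#' @export
print.pam_detection_function <- function(x, ...) {
  cat(sprintf(
    "<pam_detection_function> %s mode, %s\n  p_k = %.4f (CV %.3f), max detection range %.0f m\n  %d iterations x %d placements\n",
    x$mode, x$scenario$label, x$p_k, x$cv, x$max_detection_range_m,
    x$n_iterations, x$n_per_iteration
  ))
  invisible(x)
}

#' @describeIn simulate_click_detection Tidy the range-binned detection
#'   function into a tibble (`range_m`, `prob`, `sd`).
#' @param x A `pam_detection_function`.
#' @param ... Unused.
#' @export
tidy.pam_detection_function <- function(x, ...) {
  x$bins
}

#' @describeIn simulate_click_detection One-row summary: `p_k`, `cv`,
#'   `max_detection_range_m`, `mode`.
#' @export
glance.pam_detection_function <- function(x, ...) {
  tibble(
    mode = x$mode, p_k = x$p_k, cv = x$cv,
    max_detection_range_m = x$max_detection_range_m,
    n_iterations = x$n_iterations, n_per_iteration = x$n_per_iteration
  )
}

#' Write a detection function to CSV
#'
#' Writes the range-binned detection function (`range_m,prob,sd`) and
#' returns the summary row invisibly.
#'
#' @param x A `pam_detection_function`.
#' @param path Output CSV path.
#' @return `glance(x)`, invisibly.
#' @export
write_detection_function <- function(x, path) {
  utils::write.csv(tidy(x), path, row.names = FALSE)
  invisible(glance(x))
}
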