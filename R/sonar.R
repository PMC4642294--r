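#' Received level under spherical spreading and seawater absorption
#'
#' Sonar-equation transmission: `RL = SL - 20 log10(range) - alpha * range/1000
#' - off_axis_loss`, i.e. spherical spreading plus frequency-dependent
#' absorption, with an optional beam-pattern loss for off-axis reception.
#' Slant (3-D) range should be supplied when the source and receiver differ
#' in depth.
#'
#' @param source_level Source level, dB pp re 1 uPa at 1 m. Vectorized.
#' @param range_m Range in metres (> 0).
#' @param absorption_db_km Absorption coefficient, dB/km.
#' @param off_axis_loss_db Beam-pattern loss, dB (default 0, on-axis).
#' @return Received level, dB pp re 1 uPa.
#' @export
received_level <- function(source_level, range_m, absorption_db_km,
                           off_axis_loss_db = 0) {
  if (any(range_m <= 0)) abort("range must be positive")
  source_level - 20 * log10(range_m) - absorption_db_km * range_m / 1000 -
    off_axis_loss_db
}

#' Seawater absorption coefficient
#'
#' Ainslie & McColm's (1998) simplification of the Francois-Garrison model:
#' boric-acid and magnesium-sulphate relaxation terms plus pure-water
#' viscosity, as a function of frequency and water properties.
#'
#' @param frequency_khz Frequency in kHz (> 0). Vectorized.
#' @param salinity Salinity, ppt (default 35).
#' @param temperature Temperature, degrees C (default 6).
#' @param ph Acidity (default 8).
#' @param depth_km Depth in km (default 0.98).
#' @return Absorption in dB/km.
#' @export
absorption_coefficient <- function(frequency_khz, salinity = 35, temperature = 6,
                                   ph = 8, depth_km = 0.98) {
  if (any(frequency_khz <= 0)) abort("frequency must be positive")
  f <- frequency_khz
  f1 <- 0.78 * sqrt(salinity / 35) * exp(temperature / 26)
  f2 <- 42 * exp(temperature / 17)
  boric <- 0.106 * (f1 * f^2 / (f1^2 + f^2)) * exp((ph - 8) / 0.56)
  mgso4 <- 0.52 * (1 + temperature / 43) * (salinity / 35) *
    (f2 * f^2 / (f2^2 + f^2)) * exp(-depth_km / 6)
  water <- 0.00049 * f^2 * exp(-(temperature / 27 + depth_km / 17))
  boric + mgso4 + water
}

# --- circular-piston beam pattern -------------------------------------------

# |2 J1(x)/x| with the on-axis limit
piston_amplitude <- function(x) {
  out <- rep(1, length(x))
  nz <- x != 0
  out[nz] <- abs(2 * besselJ(x[nz], 1) / x[nz])
  out
}

# directivity index (dB) of a piston of given ka, radiating into the forward
# hemisphere: DI = 10 log10(2 / int_0^{pi/2} b^2(theta) sin(theta) dtheta)
piston_di <- function(ka) {
  purrr::map_dbl(ka, function(k) {
    th <- seq(0, pi / 2, length.out = 4001)
    b2 <- piston_amplitude(k * sin(th))^2
    integral <- sum((b2 * sin(th))[-1] + (b2 * sin(th))[-length(th)]) / 2 *
      diff(th[1:2])
    10 * log10(2 / integral)
  })
}

# cached monotone interpolator DI -> ka
the <- new.env(parent = emptyenv())
ka_from_di <- function(di) {
  if (is.null(the$ka_interp)) {
    ka_grid <- exp(seq(log(1.5), log(130), length.out = 400))
    the$ka_interp <- stats::approxfun(piston_di(ka_grid), ka_grid, rule = 2)
  }
  the$ka_interp(di)
}

#' Off-axis beam-pattern loss for a piston-type source
#'
#' Attenuation relative to the acoustic axis for a radially symmetric
#' circular-piston beam pattern whose integrated directivity index equals the
#' supplied DI (the piston `ka` is solved numerically from the DI). Loss is 0
#' on-axis and is bounded by a far-off-axis floor, since clicks far off-axis
#' are never detectable at relevant ranges; angles behind the source plane
#' (> 90 degrees) take the floor value.
#'
#' @param angle_deg Off-axis angle in degrees, in `[0, 180]`. Vectorized.
#' @param directivity_index Directivity index in dB, in `[10, 40]`. Scalar or
#'   vector parallel to `angle_deg`.
#' @param floor_db Maximum loss, dB (default 40).
#' @return Loss in dB (>= 0, <= `floor_db`).
#' @export
beam_loss <- function(angle_deg, directivity_index, floor_db = 40) {
  if (any(angle_deg < 0 | angle_deg > 180)) abort("angle must lie in [0, 180] degrees")
  if (any(directivity_index < 10 | directivity_index > 40)) {
    abort("directivity index outside [10, 40] dB")
  }
  ka <- ka_from_di(directivity_index)
  th <- angle_deg * pi / 180
  loss <- -20 * log10(piston_amplitude(ka * sin(th)))
  loss[angle_deg > 90] <- floor_db
  pmin(pmax(loss, 0), floor_db)
}
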