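# Deterrent acoustics: six continuous-emission subarrays at fixed ultrasonic
# frequencies, grouped into three treatments. Received level follows
# spherical spreading from the 1 m reference plus linear atmospheric
# absorption, which is faster at higher frequencies.

ud_subarray_freqs <- list(
  low = c(20, 26, 32),
  high = c(38, 44, 50),
  combined = c(20, 26, 32, 38, 44, 50),
  off = numeric(0)
)

# order-of-magnitude atmospheric absorption, dB per meter, by frequency (kHz)
default_atten_db_per_m <- c(`20` = 0.3, `26` = 0.5, `32` = 0.7,
                            `38` = 0.9, `44` = 1.1, `50` = 1.3)

#' Ultrasonic deterrent emission field
#'
#' One deterrent treatment: which subarrays emit (`low` = 20/26/32 kHz,
#' `high` = 38/44/50 kHz, `combined` = all six, `off` = none), the source
#' level at the 1 m reference distance, per-frequency atmospheric
#' attenuation, and the strength of the repulsive drift the field exerts on a
#' simulated bat (see [simulate_flight()]).
#'
#' @param treatment `"combined"`, `"high"`, `"low"` or `"off"`.
#' @param source_level_db Source level in dB SPL at 1 m (default 125).
#' @param atten_db_per_m Named vector of attenuation coefficients (dB/m) for
#'   the six subarray frequencies.
#' @param repulsion_coeff Strength (m^2/s^2 per unit relative pressure
#'   gradient) of the drift pushing a simulated bat away from the source;
#'   forced to 0 when `treatment = "off"`.
#' @return An object of class `deterrent_field`.
#' @export
#' @examples
#' deterrent_field("combined")
deterrent_field <- function(treatment = c("combined", "high", "low", "off"),
                            source_level_db = 125,
                            atten_db_per_m = default_atten_db_per_m,
                            repulsion_coeff = 60) {
  treatment <- match.arg(treatment)
  freqs <- ud_subarray_freqs[[treatment]]
  if (treatment == "off") repulsion_coeff <- 0
  missing_f <- setdiff(as.character(freqs), names(atten_db_per_m))
  if (length(missing_f)) {
    abort(paste0("atten_db_per_m lacks coefficients for ",
                 paste(missing_f, collapse = ", "), " kHz"))
  }
  structure(
    list(treatment = treatment, subarray_freqs_khz = freqs,
         source_level_db = source_level_db,
         atten_db_per_m = atten_db_per_m,
         repulsion_coeff = repulsion_coeff),
    class = "deterrent_field"
  )
}

#' @export
print.deterrent_field <- function(x, ...) {
  cat(sprintf("<deterrent_field> %s (%s kHz), %g dB at 1 m, repulsion %g\n",
              x$treatment, paste(x$subarray_freqs_khz, collapse = "/"),
              x$source_level_db, x$repulsion_coeff))
  invisible(x)
}

#' All four emission fields with shared parameters
#'
#' @inheritParams deterrent_field
#' @return Named list of [deterrent_field()] objects
#'   (`off`, `combined`, `high`, `low`).
#' @export
deterrent_fields <- function(source_level_db = 125,
                             atten_db_per_m = default_atten_db_per_m,
                             repulsion_coeff = 60) {
  trts <- c("off", "combined", "high", "low")
  setNames(lapply(trts, deterrent_field, source_level_db = source_level_db,
                  atten_db_per_m = atten_db_per_m,
                  repulsion_coeff = repulsion_coeff), trts)
}

#' Received level of one subarray at distance
#'
#' Spherical-spreading plus linear-absorption model:
#' `SL - 20 log10(d) - alpha(f) (d - 1)` dB SPL, valid for `d >= 1` m.
#'
#' @param distance_m Distance(s) from the source in meters, all `>= 1`.
#' @param field A [deterrent_field()].
#' @param freq_khz Subarray frequency; must belong to the field's active
#'   treatment.
#' @return Received level(s) in dB SPL.
#' @export
#' @examples
#' deterrent_intensity(1, deterrent_field("combined"), 26)  # 125 dB
deterrent_intensity <- function(distance_m, field, freq_khz) {
  if (!freq_khz %in% field$subarray_freqs_khz) {
    abort(sprintf("frequency %g kHz is not emitted under treatment '%s'",
                  freq_khz, field$treatment), class = "batcage_invalid_freq")
  }
  if (any(distance_m < 1)) {
    abort("deterrent_intensity() is defined for distances >= 1 m")
  }
  a <- field$atten_db_per_m[[as.character(freq_khz)]]
  field$source_level_db - 20 * log10(distance_m) - a * (distance_m - 1)
}

# Summed pressure amplitude over the active subarrays, relative to one
# subarray at the 1 m reference; clamped below 1 m.
pressure_rel <- function(r, field) {
  r <- pmax(r, 1)
  out <- numeric(length(r))
  for (f in field$subarray_freqs_khz) {
    a <- field$atten_db_per_m[[as.character(f)]]
    out <- out + (1 / r) * 10^(-a * (r - 1) / 20)
  }
  out
}

# Repulsive acceleration profile: drift proportional to the negative radial
# gradient of summed relative pressure, sampled on a regular grid of distance
# from the source and capped at max_accel. Constant below the 1 m reference.
drift_profile <- function(field, cage, grid_dx = 0.05, max_accel = 20) {
  r <- seq(0, cage$length_m, by = grid_dx)
  rc <- pmax(r, 1)
  g <- numeric(length(r))
  for (f in field$subarray_freqs_khz) {
    a <- field$atten_db_per_m[[as.character(f)]]
    p <- (1 / rc) * 10^(-a * (rc - 1) / 20)
    # -dp/dr = p * (1/r + a ln10 / 20)  (>= 0)
    g <- g + p * (1 / rc + a * log(10) / 20)
  }
  pmin(field$repulsion_coeff * g, max_accel)
}
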