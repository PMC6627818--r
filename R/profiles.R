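#' Describe a simulated fish
#'
#' Ground-truth parameters for one simulated animal: its reference standard
#' metabolic rate, thermal sensitivity, handling-stress dynamics, spontaneous
#' activity and aerobic ceiling. These are the quantities the downstream
#' estimators try to recover.
#'
#' @param fish_id Character identifier.
#' @param origin Population label (e.g. `"northern"`, `"southern"`).
#' @param body_weight Body mass, kg. Must be positive.
#' @param smr_ref True mass-specific standard metabolic rate at `t_ref`,
#'   mg O2 kg^-1 h^-1.
#' @param t_ref Reference temperature for `smr_ref`, degrees C.
#' @param q10_true True Q10 governing how SMR scales with temperature.
#' @param stress_amplitude Initial proportional elevation of MO2 above SMR due
#'   to handling (0 = no stress response).
#' @param stress_tau Exponential decay time of the handling-stress response,
#'   hours.
#' @param activity_rate Expected spontaneous-activity excursions per hour.
#' @param activity_magnitude Mean additive excursion size as a multiple of SMR.
#' @param mmr_multiplier True maximum metabolic rate as a multiple of SMR at
#'   the same temperature; instantaneous MO2 is capped here. Must exceed 1.
#' @return An object of class `fish_profile`.
#' @examples
#' fish_profile("f1", "northern", body_weight = 0.25, smr_ref = 72,
#'              q10_true = 2.1)
#' @export
fish_profile <- function(fish_id, origin = "unknown", body_weight = 0.34,
                         smr_ref = 60, t_ref = 15, q10_true = 2,
                         stress_amplitude = 1, stress_tau = 3,
                         activity_rate = 1.5, activity_magnitude = 1,
                         mmr_multiplier = 3) {
  stopifnot(is.character(fish_id), length(fish_id) == 1L)
  if (body_weight <= 0) stop("body_weight must be positive")
  if (smr_ref <= 0) stop("smr_ref must be positive")
  if (q10_true <= 0) stop("q10_true must be positive")
  if (stress_tau <= 0) stop("stress_tau must be positive")
  if (stress_amplitude < 0) stop("stress_amplitude must be >= 0")
  if (activity_rate < 0 || activity_magnitude < 0)
    stop("activity parameters must be >= 0")
  if (mmr_multiplier <= 1) stop("mmr_multiplier must exceed 1")
  structure(list(
    fish_id = fish_id, origin = origin, body_weight = body_weight,
    smr_ref = smr_ref, t_ref = t_ref, q10_true = q10_true,
    stress_amplitude = stress_amplitude, stress_tau = stress_tau,
    activity_rate = activity_rate, activity_magnitude = activity_magnitude,
    mmr_multiplier = mmr_multiplier), class = "fish_profile")
}

#' @export
print.fish_profile <- function(x, ...) {
  cat(sprintf("<fish_profile> %s (%s): %.0f g, SMR %.1f mg O2/kg/h @ %g C, Q10 %.2f\n",
              x$fish_id, x$origin, 1000 * x$body_weight, x$smr_ref, x$t_ref,
              x$q10_true))
  invisible(x)
}

#' True SMR of a fish at a temperature
#'
#' Applies the Q10 law generatively: SMR(T) = smr_ref * q10^((T - t_ref)/10).
#'
#' @param fish A [fish_profile()].
#' @param temp Temperature, degrees C (vectorized).
#' @return True SMR, mg O2 kg^-1 h^-1.
#' @examples
#' f <- fish_profile("f1", smr_ref = 50, t_ref = 15, q10_true = 2)
#' true_smr_at(f, c(5, 15, 25))  # 25, 50, 100
#' @export
true_smr_at <- function(fish, temp) {
  stopifnot(inherits(fish, "fish_profile"), all(is.finite(temp)))
  fish$smr_ref * fish$q10_true^((temp - fish$t_ref) / 10)
}

#' Instantaneous metabolic rate during a trial
#'
#' SMR at the current temperature, elevated by an exponentially decaying
#' handling-stress term and, optionally, an additive spontaneous-activity
#' excursion; the total is capped at the fish's true MMR
#' (`mmr_multiplier * SMR`).
#'
#' @inheritParams true_smr_at
#' @param elapsed Time since the fish entered the chamber, hours.
#' @param activity_excursion Additive excursion in units of SMR (0 = quiescent).
#'   The simulator draws this per cycle; see [simulate_trial()].
#' @return MO2, mg O2 kg^-1 h^-1.
#' @export
instantaneous_mo2 <- function(fish, temp, elapsed, activity_excursion = 0) {
  stopifnot(all(elapsed >= 0), all(activity_excursion >= 0))
  smr <- true_smr_at(fish, temp)
  mo2 <- smr * (1 + fish$stress_amplitude * exp(-elapsed / fish$stress_tau)) +
    activity_excursion * smr
  pmin(mo2, fish$mmr_multiplier * smr)
}

#' Intermittent-flow protocol description
#'
#' A thermal-challenge protocol: an ordered set of temperature holds connected
#' by linear ramps, plus the flush/wait/measure cycle timing at each nominal
#' temperature. Defaults give a 180 s flush and 60 s wait with
#' temperature-dependent measurement periods (longer when the water is cold and
#' the fish consumes oxygen slowly): 1200 s at 5 C, 600 s at 10 C, 300 s at
#' 15 C, 240 s at 20 and 25 C, 180 s at 30 C.
#'
#' @param steps List of `c(temperature_C, hold_hours)` pairs, in order.
#' @param ramp_rate Absolute rate of temperature change between holds,
#'   degrees C per hour.
#' @param flush_s,wait_s Flush and wait durations, seconds.
#' @param measure_s Named numeric vector mapping nominal temperature (degrees C,
#'   as names) to measurement-phase duration in seconds.
#' @param salinity Water salinity, ppt.
#' @return An object of class `protocol_spec`.
#' @examples
#' cold_arm_protocol()   # 15 C (20 h) -> 10 C (5 h) -> 5 C (18 h)
#' heat_arm_protocol()   # 20 C (20 h) -> 25 C (5 h) -> 30 C (18 h)
#' @export
protocol_spec <- function(steps, ramp_rate = 2.5, flush_s = 180, wait_s = 60,
                          measure_s = c(`5` = 1200, `10` = 600, `15` = 300,
                                        `20` = 240, `25` = 240, `30` = 180),
                          salinity = 18) {
  stopifnot(is.list(steps), length(steps) >= 1L)
  for (s in steps) {
    if (length(s) != 2L || !is.finite(s[1]))
      stop("each step must be c(temperature_C, hold_hours)")
    if (!is.finite(s[2]) || s[2] <= 0)
      stop("hold duration must be positive")
  }
  if (ramp_rate <= 0) stop("ramp_rate must be positive")
  if (flush_s <= 0 || wait_s <= 0 || any(measure_s <= 0))
    stop("phase durations must be positive")
  if (is.null(names(measure_s)))
    stop("measure_s must be a named vector keyed by temperature")
  structure(list(steps = steps, ramp_rate = ramp_rate, flush_s = flush_s,
                 wait_s = wait_s, measure_s = measure_s, salinity = salinity),
            class = "protocol_spec")
}

#' @rdname protocol_spec
#' @param hold_hours Hold durations for the three steps, hours.
#' @param ... Passed on to [protocol_spec()].
#' @export
cold_arm_protocol <- function(hold_hours = c(20, 5, 18), ...) {
  protocol_spec(steps = list(c(15, hold_hours[1]), c(10, hold_hours[2]),
                             c(5, hold_hours[3])), ...)
}

#' @rdname protocol_spec
#' @export
heat_arm_protocol <- function(hold_hours = c(20, 5, 18), ...) {
  protocol_spec(steps = list(c(20, hold_hours[1]), c(25, hold_hours[2]),
                             c(30, hold_hours[3])), ...)
}

#' @export
print.protocol_spec <- function(x, ...) {
  holds <- vapply(x$steps, function(s) sprintf("%g C (%g h)", s[1], s[2]), "")
  cat("<protocol_spec>", paste(holds, collapse = " -> "),
      sprintf("| ramp %g C/h | flush %gs wait %gs\n", x$ramp_rate, x$flush_s,
              x$wait_s))
  invisible(x)
}

#' Respirometry chamber description
#'
#' @param volume Chamber volume, L (cylindrical respirometers of 4 or 7 L are
#'   typical for fish of a few hundred grams).
#' @param background_rate Whole-chamber microbial (background) respiration,
#'   mg O2 h^-1. Default 0: background measured in blank runs is typically
#'   under 1% of the fish's rate and ignored.
#' @param noise_sd Additive Gaussian sensor noise on PO2 readings, mm Hg.
#' @param saturation_po2 PO2 restored by each flush, mm Hg (~air saturation).
#' @return An object of class `respirometer_spec`.
#' @export
respirometer_spec <- function(volume = 7, background_rate = 0, noise_sd = 0.25,
                              saturation_po2 = 155) {
  if (volume <= 0) stop("volume must be positive")
  if (background_rate < 0) stop("background_rate must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (saturation_po2 <= 0) stop("saturation_po2 must be positive")
  structure(list(volume = volume, background_rate = background_rate,
                 noise_sd = noise_sd, saturation_po2 = saturation_po2),
            class = "respirometer_spec")
}

#' Pick a respirometer sized to the fish
#'
#' Chamber volume is matched to fish size (4 L below the mass cutoff, 7 L
#' above), keeping the per-cycle PO2 decline deep enough relative to sensor
#' noise for reliable slope regressions.
#'
#' @param fish A [fish_profile()].
#' @param small_volume,large_volume Chamber volumes, L.
#' @param cutoff_kg Body-mass cutoff between the two chambers.
#' @param ... Passed to [respirometer_spec()].
#' @return A [respirometer_spec()].
#' @export
assign_chamber <- function(fish, small_volume = 4, large_volume = 7,
                           cutoff_kg = 0.3, ...) {
  stopifnot(inherits(fish, "fish_profile"))
  respirometer_spec(volume = if (fish$body_weight < cutoff_kg) small_volume
                    else large_volume, ...)
}

#' @export
print.respirometer_spec <- function(x, ...) {
  cat(sprintf("<respirometer_spec> %g L, background %g mg O2/h, noise sd %g mmHg\n",
              x$volume, x$background_rate, x$noise_sd))
  invisible(x)
}
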