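#' Quality-control policy for MO2 extraction
#'
#' @param r2_min Minimum r-squared for a per-cycle regression to pass QC.
#'   Cycles below this are excluded from all downstream estimation.
#' @param min_points Minimum samples required to fit a slope.
#' @param background_rate Whole-chamber background (microbial) respiration to
#'   subtract, mg O2 h^-1. Default 0: blank-run background is typically below
#'   1% of the fish's rate and ignored.
#' @param background_negligibility_threshold Fraction of the fish's rate below
#'   which background is reported as negligible.
#' @return An object of class `qc_policy`.
#' @export
qc_policy <- function(r2_min = 0.95, min_points = 3, background_rate = 0,
                      background_negligibility_threshold = 0.01) {
  if (r2_min <= 0 || r2_min > 1) stop("r2_min must be in (0, 1]")
  if (min_points < 3) stop("min_points must be >= 3")
  if (background_rate < 0) stop("background_rate must be >= 0")
  structure(list(r2_min = r2_min, min_points = min_points,
                 background_rate = background_rate,
                 background_negligibility_threshold =
                   background_negligibility_threshold),
            class = "qc_policy")
}

#' Split a trace into per-cycle measurement windows
#'
#' Extracts the sealed measurement-phase samples of every respirometry cycle
#' and annotates each window with its nominal hold temperature. A cycle whose
#' measurement phase is not at a stable hold temperature (i.e. it overlaps a
#' thermal ramp) is flagged with `is_ramp = TRUE` and is excluded from
#' temperature-binned statistics downstream.
#'
#' @param trace A `raw_trace` (from [simulate_trial()] or [read_trace_csv()]).
#' @param hold_temps Numeric vector of nominal hold temperatures. Defaults to
#'   the protocol carried by the trace.
#' @param temp_tol Maximum deviation (degrees C) of any measurement-phase
#'   sample from a hold temperature for the cycle to count as on-hold.
#' @return A list of per-cycle data frames (columns of `trace` for the
#'   measurement phase), each with attributes `cycle_index`, `nominal_temp`
#'   (NA when on a ramp) and `is_ramp`.
#' @export
segment_cycles <- function(trace, hold_temps = NULL, temp_tol = 0.25) {
  if (is.null(hold_temps)) {
    prot <- attr(trace, "protocol")
    if (is.null(prot))
      stop("hold_temps must be given when the trace carries no protocol")
    hold_temps <- vapply(prot$steps, function(s) as.numeric(s[1]), numeric(1))
  }
  meas <- trace[trace$phase == "measure", , drop = FALSE]
  if (nrow(meas) == 0) stop("trace contains no measurement-phase samples")
  lapply(split(meas, meas$cycle_index), function(w) {
    dev <- vapply(hold_temps, function(h) max(abs(w$temp_C - h)), numeric(1))
    on_hold <- any(dev <= temp_tol)
    attr(w, "cycle_index") <- w$cycle_index[1]
    attr(w, "nominal_temp") <- if (on_hold) hold_temps[which.min(dev)] else NA_real_
    attr(w, "is_ramp") <- !on_hold
    w
  })
}

#' Least-squares PO2 slope of one measurement window
#'
#' Ordinary least-squares regression of PO2 on time (time in hours), returning
#' the slope in mm Hg h^-1 and the squared Pearson correlation. A window with
#' constant PO2 gets slope 0 and, by convention, r-squared 0 (it fails QC).
#'
#' @param time_s Sample times, seconds.
#' @param po2 PO2 readings, mm Hg.
#' @return List with `slope` (mm Hg h^-1) and `r_squared`.
#' @examples
#' t <- 0:299
#' fit_slope(t, 150 - 10 * t / 3600)  # slope -10, r2 1
#' @export
fit_slope <- function(time_s, po2) {
  n <- length(time_s)
  stopifnot(n == length(po2))
  if (n < 3) stop("need at least 3 samples to fit a slope")
  th <- time_s / 3600
  vt <- stats::var(th)
  if (vt == 0) stop("degenerate window: no time variation")
  vp <- stats::var(po2)
  slope <- stats::cov(th, po2) / vt
  r2 <- if (vp == 0) 0 else stats::cor(th, po2)^2
  list(slope = slope, r_squared = r2)
}

#' Convert a PO2 slope into an oxygen consumption rate
#'
#' Implements MO2 = V * |dPO2/dt| * beta for a sealed respirometer, with V the
#' chamber volume corrected for fish volume (1 kg = 1 L) and beta the oxygen
#' solubility. Background respiration (whole-chamber, mg O2 h^-1) is
#' subtracted from the whole-animal rate before division by body mass; the
#' result is clipped at zero. A non-negative slope (PO2 not declining) yields
#' a record flagged `valid_slope = FALSE` rather than an error.
#'
#' @param slope PO2 slope, mm Hg h^-1 (negative when the fish consumes O2).
#' @param chamber A [respirometer_spec()].
#' @param body_weight Fish mass, kg.
#' @param temp Water temperature, degrees C.
#' @param salinity Salinity, ppt.
#' @param background_rate Whole-chamber background respiration, mg O2 h^-1.
#' @return List with `mo2_whole` (mg O2 h^-1), `mo2_mass_specific`
#'   (mg O2 kg^-1 h^-1) and `valid_slope`.
#' @export
compute_mo2 <- function(slope, chamber, body_weight, temp, salinity,
                        background_rate = 0) {
  v_eff <- chamber$volume - body_weight
  if (v_eff <= 0) stop("effective volume must be positive")
  beta <- o2_solubility(temp, salinity)
  whole <- max(0, v_eff * abs(slope) * beta - background_rate)
  list(mo2_whole = whole, mo2_mass_specific = whole / body_weight,
       valid_slope = slope < 0)
}

#' Standardize a mass-specific metabolic rate to a common body mass
#'
#' Allometric correction MO2_std = MO2_obs * (BW / std_weight)^(1 - b). With
#' the teleost average exponents, b = 0.948 standardizes SMR-bound rates and
#' b = 0.937 MMR-bound rates; the default standard mass is 0.34 kg. At
#' BW = std_weight, or with b = 1 (isometric scaling), the rate is unchanged.
#'
#' @param mo2 Observed mass-specific MO2, mg O2 kg^-1 h^-1.
#' @param body_weight Fish mass, kg.
#' @param b Allometric mass exponent, in (0, 2).
#' @param std_weight Standard mass, kg.
#' @return Mass-standardized MO2, mg O2 kg^-1 h^-1.
#' @examples
#' mass_correct(100, 0.68, b = 0.948)  # 100 * 2^0.052
#' @export
mass_correct <- function(mo2, body_weight, b, std_weight = 0.34) {
  if (any(body_weight <= 0)) stop("body_weight must be positive")
  if (any(b <= 0) || any(b >= 2)) stop("b must be in (0, 2)")
  mo2 * (body_weight / std_weight)^(1 - b)
}

#' Background-respiration negligibility check
#'
#' Compares the chamber background respiration with a typical whole-animal
#' rate. When the ratio is below the threshold (default 1%), the pipeline
#' default of ignoring background is appropriate.
#'
#' @param background_rate Background respiration, mg O2 h^-1.
#' @param typical_fish_rate Typical whole-animal MO2, mg O2 h^-1 (positive).
#' @param threshold Negligibility threshold as a fraction of the fish rate.
#' @return List with `ratio` and logical `negligible`.
#' @export
check_background <- function(background_rate, typical_fish_rate,
                             threshold = 0.01) {
  if (typical_fish_rate <= 0) stop("typical_fish_rate must be positive")
  if (background_rate < 0) stop("background_rate must be >= 0")
  ratio <- background_rate / typical_fish_rate
  list(ratio = ratio, negligible = ratio < threshold)
}

#' Extract quality-filtered MO2 records from a raw trace
#'
#' Runs the full per-cycle extraction: segment the measurement windows, fit
#' the OLS slope of PO2 on time, convert to whole-animal and mass-specific
#' MO2, and standardize to the reference mass with both the SMR exponent
#' (b = 0.948) and the MMR exponent (b = 0.937). A record passes QC when its
#' regression r-squared meets `policy$r2_min`, its slope is negative, and it
#' lies on a temperature hold.
#'
#' @param trace A `raw_trace`.
#' @param chamber A [respirometer_spec()]; defaults to the one carried by the
#'   trace.
#' @param body_weight Fish mass, kg; defaults to the profile carried by the
#'   trace.
#' @param salinity Water salinity, ppt; defaults to the trace protocol's.
#' @param policy A [qc_policy()].
#' @param b_smr,b_mmr Allometric exponents for SMR- and MMR-bound
#'   standardization.
#' @param std_weight Standard mass, kg.
#' @return Data frame of MO2 records: `trial_id`, `cycle_index`, `mid_time_s`,
#'   `temperature_bin` (NA on ramps), `slope`, `r_squared`, `mo2_whole`,
#'   `mo2_mass_specific`, `mo2_std_smr`, `mo2_std_mmr`, `is_ramp`,
#'   `passed_qc`. The number of QC-excluded cycles is stored in attribute
#'   `n_excluded`.
#' @export
process_trace <- function(trace, chamber = attr(trace, "chamber"),
                          body_weight = attr(trace, "fish")$body_weight,
                          salinity = attr(trace, "protocol")$salinity,
                          policy = qc_policy(), b_smr = 0.948, b_mmr = 0.937,
                          std_weight = 0.34) {
  if (is.null(chamber)) stop("no chamber metadata: supply `chamber`")
  if (is.null(body_weight)) stop("no fish metadata: supply `body_weight`")
  if (is.null(salinity)) salinity <- 18
  windows <- segment_cycles(trace)
  recs <- lapply(windows, function(w) {
    if (nrow(w) < policy$min_points) return(NULL)
    fit <- fit_slope(w$time_s, w$po2_mmHg)
    temp <- attr(w, "nominal_temp")
    is_ramp <- attr(w, "is_ramp")
    mo2 <- compute_mo2(fit$slope, chamber, body_weight,
                       if (is_ramp) mean(w$temp_C) else temp, salinity,
                       policy$background_rate)
    data.frame(
      trial_id = attr(trace, "trial_id") %||% NA_character_,
      cycle_index = attr(w, "cycle_index"),
      mid_time_s = mean(range(w$time_s)),
      temperature_bin = temp,
      slope = fit$slope, r_squared = fit$r_squared,
      mo2_whole = mo2$mo2_whole,
      mo2_mass_specific = mo2$mo2_mass_specific,
      mo2_std_smr = mass_correct(mo2$mo2_mass_specific, body_weight, b_smr,
                                 std_weight),
      mo2_std_mmr = mass_correct(mo2$mo2_mass_specific, body_weight, b_mmr,
                                 std_weight),
      is_ramp = is_ramp,
      passed_qc = fit$r_squared >= policy$r2_min && mo2$valid_slope && !is_ramp)
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) stop("no cycle had enough samples to fit a slope")
  out <- out[order(out$cycle_index), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!out$passed_qc)
  attr(out, "body_weight") <- body_weight
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
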