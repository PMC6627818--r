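#' Simulate one intermittent-flow respirometry trial
#'
#' Generates the full PO2 time series of a thermal-challenge trial. Each
#' respirometry cycle consists of a flush (chamber PO2 held at saturation), a
#' wait, and a sealed measurement phase; from the end of the flush the chamber
#' is sealed and PO2 declines linearly at
#' \deqn{-(MO2 \cdot BW + background) / (V_{eff} \, \beta(T, S))}
#' in mm Hg h^-1, where the effective volume \eqn{V_{eff}} is the chamber
#' volume minus the fish volume (1 kg = 1 L) and \eqn{\beta} is the oxygen
#' solubility from [o2_solubility()]. The fish's instantaneous MO2 for a cycle
#' is evaluated at the midpoint of its measurement phase via
#' [instantaneous_mo2()]: SMR scaled by the Q10 law, an exponentially decaying
#' handling-stress elevation, and per-cycle Bernoulli activity excursions with
#' lognormally jittered magnitude, capped at the fish's true MMR. Gaussian
#' sensor noise is added to every sample. Temperature moves between holds at
#' the protocol ramp rate; cycle timing follows the nominal temperature
#' nearest the cycle start.
#'
#' Identical `(fish, protocol, chamber, seed)` give a byte-identical trace; the
#' caller's RNG state is left untouched.
#'
#' @param fish A [fish_profile()].
#' @param protocol A [protocol_spec()].
#' @param chamber A [respirometer_spec()]. Effective volume
#'   (`volume - body_weight`) must be positive.
#' @param seed Integer seed controlling sensor noise and activity events.
#' @param sample_interval Sensor sampling interval, seconds. The measurement
#'   phase must contain at least 3 samples at this interval.
#' @param trial_id Identifier stored in the trace; defaults to the fish id.
#' @return A data frame of class `raw_trace` with columns `time_s`,
#'   `po2_mmHg`, `temp_C`, `phase` (`flush`/`wait`/`measure`) and
#'   `cycle_index`, carrying attributes `fish`, `protocol`, `chamber`,
#'   `trial_id` and `truth`. `truth` holds the per-hold true SMR/MMR, the true
#'   Q10, and a per-cycle table of the generative MO2 (`cycles`).
#' @examples
#' f <- fish_profile("f1", smr_ref = 60, q10_true = 2)
#' tr <- simulate_trial(f, cold_arm_protocol(hold_hours = c(1, 1, 1)),
#'                      respirometer_spec(), seed = 1, sample_interval = 5)
#' head(tr)
#' @export
simulate_trial <- function(fish, protocol, chamber, seed,
                           sample_interval = 1, trial_id = fish$fish_id) {
  stopifnot(inherits(fish, "fish_profile"),
            inherits(protocol, "protocol_spec"),
            inherits(chamber, "respirometer_spec"))
  v_eff <- chamber$volume - fish$body_weight
  if (v_eff <= 0)
    stop("chamber volume must exceed fish volume (1 kg = 1 L)")
  if (min(protocol$measure_s) / sample_interval < 3)
    stop("measurement phase must span at least 3 samples at the configured ",
         "sampling interval")

  traj <- temperature_trajectory(protocol)
  total_s <- traj$total_s
  temp_at <- function(t) stats::approx(traj$time_s, traj$temp_C, t,
                                       rule = 2)$y
  nominal_temps <- as.numeric(names(protocol$measure_s))

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)

  cyc <- list(); samp <- list()
  cursor <- 0; idx <- 0L
  repeat {
    t_nom <- nominal_temps[which.min(abs(nominal_temps - temp_at(cursor)))]
    measure_s <- unname(protocol$measure_s[as.character(t_nom)])
    cycle_s <- protocol$flush_s + protocol$wait_s + measure_s
    if (cursor + cycle_s > total_s) break
    idx <- idx + 1L

    t_seal <- cursor + protocol$flush_s
    t_mid <- t_seal + protocol$wait_s + measure_s / 2
    temp_mid <- temp_at(t_mid)

    spike <- 0
    p_spike <- min(1, fish$activity_rate * cycle_s / 3600)
    if (stats::runif(1) < p_spike)
      spike <- fish$activity_magnitude * stats::rlnorm(1, -0.125, 0.5)
    mo2 <- instantaneous_mo2(fish, temp_mid, t_mid / 3600, spike)

    beta <- o2_solubility(temp_mid, protocol$salinity)
    rate_s <- (mo2 * fish$body_weight + chamber$background_rate) /
      (v_eff * beta) / 3600           # mm Hg per second

    tt <- seq(cursor, cursor + cycle_s - sample_interval, by = sample_interval)
    rel <- tt - t_seal
    po2 <- ifelse(rel < 0, chamber$saturation_po2,
                  chamber$saturation_po2 - rate_s * rel)
    phase <- ifelse(rel < 0, "flush",
                    ifelse(rel < protocol$wait_s, "wait", "measure"))
    samp[[idx]] <- data.frame(
      time_s = tt, po2_mmHg = po2, temp_C = temp_at(tt), phase = phase,
      cycle_index = idx)
    cyc[[idx]] <- data.frame(
      cycle_index = idx, nominal_temp = t_nom, mid_time_s = t_mid,
      temp_mid = temp_mid, mo2_true = mo2,
      is_hold = isTRUE(all.equal(temp_mid, t_nom, tolerance = 1e-6)))
    cursor <- cursor + cycle_s
  }
  if (idx == 0L) stop("protocol too short to contain a single cycle")

  out <- do.call(rbind, samp)
  if (chamber$noise_sd > 0)
    out$po2_mmHg <- out$po2_mmHg +
      stats::rnorm(nrow(out), 0, chamber$noise_sd)
  rownames(out) <- NULL

  hold_temps <- vapply(protocol$steps, `[`, numeric(1), 1)
  truth <- list(
    smr = stats::setNames(true_smr_at(fish, hold_temps),
                          as.character(hold_temps)),
    mmr = stats::setNames(fish$mmr_multiplier * true_smr_at(fish, hold_temps),
                          as.character(hold_temps)),
    q10 = fish$q10_true,
    cycles = do.call(rbind, cyc))
  structure(out, class = c("raw_trace", "data.frame"), trial_id = trial_id,
            fish = fish, protocol = protocol, chamber = chamber,
            truth = truth, sample_interval = sample_interval)
}

# Piecewise-linear temperature profile: holds joined by ramps at ramp_rate.
temperature_trajectory <- function(protocol) {
  times <- 0; temps <- protocol$steps[[1]][1]
  cursor <- 0
  for (i in seq_along(protocol$steps)) {
    s <- protocol$steps[[i]]
    cursor <- cursor + s[2] * 3600
    times <- c(times, cursor); temps <- c(temps, s[1])
    if (i < length(protocol$steps)) {
      nxt <- protocol$steps[[i + 1]][1]
      ramp_s <- abs(nxt - s[1]) / protocol$ramp_rate * 3600
      cursor <- cursor + ramp_s
      times <- c(times, cursor); temps <- c(temps, nxt)
    }
  }
  list(time_s = times, temp_C = temps, total_s = cursor)
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old_seed, envir = globalenv())
}

#' @export
print.raw_trace <- function(x, ...) {
  tr <- attr(x, "truth")
  cat(sprintf("<raw_trace> trial %s: %d samples, %d cycles, %.1f h\n",
              attr(x, "trial_id"), nrow(x), max(x$cycle_index),
              max(x$time_s) / 3600))
  cat("  true SMR (mg O2/kg/h):",
      paste(sprintf("%s C: %.1f", names(tr$smr), tr$smr), collapse = ", "),
      sprintf("| true Q10 %.2f\n", tr$q10))
  invisible(x)
}

#' Plot a simulated or imported PO2 trace
#'
#' @param x A `raw_trace`.
#' @param ... Passed to [plot()].
#' @export
plot.raw_trace <- function(x, ...) {
  plot(x$time_s / 3600, x$po2_mmHg, type = "l", xlab = "time (h)",
       ylab = expression(PO[2] ~ (mm ~ Hg)),
       main = attr(x, "trial_id"), ...)
  invisible(x)
}

#' Generate a study cohort of fish profiles
#'
#' Draws per-fish simulator parameters for a two-population thermal-challenge
#' cohort. Defaults mirror a cold-challenge design with 10 northern and 11
#' southern fish (heat arm: 10 and 5), body masses spanning each population's
#' observed range, population-level SMR at the starting temperature with
#' realistic between-fish dispersion, and population-specific Q10 spans
#' (northern 1.9-2.4; southern 1.4-3.4).
#'
#' @param arm `"cold"` (holds at 15, 10, 5 C) or `"heat"` (20, 25, 30 C).
#' @param n Named integer vector: fish per origin,
#'   e.g. `c(northern = 10, southern = 11)`.
#' @param smr_mean Named vector of population mean SMR at the starting
#'   temperature (mg O2 kg^-1 h^-1).
#' @param smr_cv Between-fish coefficient of variation of SMR.
#' @param weight_range Named list of body-mass ranges in kg per origin.
#' @param q10_range Named list of Q10 ranges per origin.
#' @param seed Integer seed.
#' @return List of [fish_profile()] objects.
#' @export
make_cohort <- function(arm = c("cold", "heat"),
                        n = NULL, smr_mean = NULL, smr_cv = 0.14,
                        weight_range = NULL, q10_range = NULL, seed = 1) {
  arm <- match.arg(arm)
  if (is.null(n))
    n <- if (arm == "cold") c(northern = 10, southern = 11)
         else c(northern = 10, southern = 5)
  if (is.null(smr_mean))
    smr_mean <- if (arm == "cold") c(northern = 72.5, southern = 53.8)
                else c(northern = 100.2, southern = 86.6)
  if (is.null(weight_range))
    weight_range <- if (arm == "cold")
      list(northern = c(0.140, 0.252), southern = c(0.235, 0.838))
    else list(northern = c(0.122, 0.439), southern = c(0.368, 0.508))
  if (is.null(q10_range))
    q10_range <- list(northern = c(1.9, 2.4), southern = c(1.4, 3.4))
  t_ref <- if (arm == "cold") 15 else 20

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)

  fishes <- list()
  for (origin in names(n)) {
    for (i in seq_len(n[[origin]])) {
      sdlog <- sqrt(log(1 + smr_cv^2))
      fishes[[length(fishes) + 1L]] <- fish_profile(
        fish_id = sprintf("%s_%02d", origin, i), origin = origin,
        body_weight = stats::runif(1, weight_range[[origin]][1],
                                   weight_range[[origin]][2]),
        smr_ref = stats::rlnorm(1, log(smr_mean[[origin]]) - sdlog^2 / 2,
                                sdlog),
        t_ref = t_ref,
        q10_true = stats::runif(1, q10_range[[origin]][1],
                                q10_range[[origin]][2]),
        stress_amplitude = stats::runif(1, 0.5, 1.5),
        stress_tau = stats::runif(1, 2, 4),
        activity_rate = stats::runif(1, 1, 2),
        activity_magnitude = stats::runif(1, 0.8, 1.5),
        mmr_multiplier = stats::runif(1, 2.5, 3.5))
    }
  }
  fishes
}

#' Write / read a trace as CSV with a JSON truth sidecar
#'
#' The CSV holds the sample table (`trial_id, time_s, po2_mmHg, temp_C, phase,
#' cycle_index`); simulation ground truth and trial metadata go to
#' `<path>.truth.json` so that processed results can be checked against the
#' generative values.
#'
#' @param trace A `raw_trace`.
#' @param path Output CSV path.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a `raw_trace` (with truth and metadata when the sidecar exists).
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "raw_trace"))
  df <- cbind(trial_id = attr(trace, "trial_id"), as.data.frame(trace))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(
    trial_id = attr(trace, "trial_id"),
    fish = unclass(attr(trace, "fish")),
    chamber = unclass(attr(trace, "chamber")),
    protocol = unclass(attr(trace, "protocol")),
    sample_interval = attr(trace, "sample_interval"),
    truth = list(smr = as.list(attr(trace, "truth")$smr),
                 mmr = as.list(attr(trace, "truth")$mmr),
                 q10 = attr(trace, "truth")$q10))
  jsonlite::write_json(meta, paste0(path, ".truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param path Path of a CSV written by [write_trace_csv()] (or any CSV with
#'   the same columns).
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "po2_mmHg", "temp_C", "phase", "cycle_index")
  if (!all(need %in% names(df)))
    stop("trace CSV must contain columns: ", paste(need, collapse = ", "))
  trial_id <- if ("trial_id" %in% names(df)) df$trial_id[1] else basename(path)
  out <- df[need]
  attr(out, "trial_id") <- trial_id
  side <- paste0(path, ".truth.json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(out, "fish") <- structure(as.list(meta$fish), class = "fish_profile")
    ch <- as.list(meta$chamber)
    attr(out, "chamber") <- structure(ch, class = "respirometer_spec")
    pr <- as.list(meta$protocol)
    pr$steps <- lapply(seq_len(nrow(meta$protocol$steps)),
                       function(i) unlist(meta$protocol$steps[i, ]))
    attr(out, "protocol") <- structure(pr, class = "protocol_spec")
    attr(out, "truth") <- list(smr = unlist(meta$truth$smr),
                               mmr = unlist(meta$truth$mmr),
                               q10 = meta$truth$q10)
    attr(out, "sample_interval") <- meta$sample_interval
  }
  class(out) <- c("raw_trace", "data.frame")
  out
}
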