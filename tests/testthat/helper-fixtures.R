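# Shared builders for small, fast simulation fixtures.

# A fish with no stress response and no activity: MO2 is exactly SMR.
quiet_fish <- function(id = "quiet", smr_ref = 60, q10 = 2, bw = 0.34,
                       t_ref = 15) {
  fish_profile(id, origin = "test", body_weight = bw, smr_ref = smr_ref,
               t_ref = t_ref, q10_true = q10, stress_amplitude = 0,
               activity_rate = 0)
}

# Noise-free chamber: deterministic PO2 physics.
clean_chamber <- function(volume = 7, background = 0) {
  respirometer_spec(volume = volume, background_rate = background,
                    noise_sd = 0)
}

# Short three-hold cold protocol for fast trials.
short_cold <- function(hold_hours = c(2, 1, 2)) {
  cold_arm_protocol(hold_hours = hold_hours)
}

# One null-calibration replicate: does the origin LRT reject at 0.05?
null_lrt_rejects <- function(n_fish = c(30, 30)) {
  fit <- fit_smr_lmm(simulate_null_smr(n_fish))
  fit$lrt$p_value[fit$lrt$effect == "origin"] <= 0.05
}

# Hand-built trace: `cycles` measurement windows with known linear PO2 decline
# (slope in mm Hg/h), constant temperature, 1 Hz sampling.
handmade_trace <- function(slopes, temp = 15, flush_s = 30, wait_s = 10,
                           measure_s = 60, po2_top = 150) {
  rows <- list(); t0 <- 0
  for (i in seq_along(slopes)) {
    tt <- seq(t0, t0 + flush_s + wait_s + measure_s - 1)
    rel <- tt - (t0 + flush_s)
    po2 <- ifelse(rel < 0, po2_top, po2_top + slopes[i] * rel / 3600)
    phase <- ifelse(rel < 0, "flush",
                    ifelse(rel < wait_s, "wait", "measure"))
    rows[[i]] <- data.frame(time_s = tt, po2_mmHg = po2, temp_C = temp,
                            phase = phase, cycle_index = i)
    t0 <- t0 + flush_s + wait_s + measure_s
  }
  out <- do.call(rbind, rows)
  attr(out, "trial_id") <- "handmade"
  class(out) <- c("raw_trace", "data.frame")
  out
}
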