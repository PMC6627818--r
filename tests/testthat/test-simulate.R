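test_that("true SMR follows the Q10 law", {
  f <- fish_profile("f", smr_ref = 50, t_ref = 15, q10_true = 2)
  expect_equal(true_smr_at(f, 15), 50)
  expect_equal(true_smr_at(f, 25), 100)
  f2 <- fish_profile("f", smr_ref = 50, t_ref = 15, q10_true = 2.5)
  expect_equal(true_smr_at(f2, 5), 20)
})

test_that("instantaneous MO2: stress decay, activity and the MMR cap", {
  quiet <- quiet_fish()
  expect_equal(instantaneous_mo2(quiet, 15, elapsed = 0), 60)
  expect_equal(instantaneous_mo2(quiet, 15, elapsed = 100), 60)

  f <- fish_profile("f", smr_ref = 50, q10_true = 2, stress_amplitude = 1,
                    stress_tau = 3, activity_rate = 0)
  expect_equal(instantaneous_mo2(f, 15, elapsed = 3), 50 * (1 + exp(-1)))
  # converges to SMR within 1% after 5 time constants
  expect_lt(abs(instantaneous_mo2(f, 15, 5 * 3) - 50) / 50, 0.01)
  # cap at true MMR
  expect_equal(instantaneous_mo2(f, 15, 0, activity_excursion = 50),
               f$mmr_multiplier * 50)
})

test_that("profile invariants are enforced", {
  expect_error(fish_profile("f", body_weight = 0), "body_weight")
  expect_error(fish_profile("f", q10_true = -1), "q10")
  expect_error(fish_profile("f", mmr_multiplier = 1), "mmr_multiplier")
  expect_error(protocol_spec(list(c(15, 0))), "hold|positive")
  expect_error(respirometer_spec(noise_sd = -1), "noise_sd")
})

test_that("identical seeds give byte-identical traces; seeds differ traces", {
  f <- quiet_fish()
  ch <- respirometer_spec(noise_sd = 0.3)
  pr <- short_cold()
  a <- simulate_trial(f, pr, ch, seed = 7, sample_interval = 5)
  b <- simulate_trial(f, pr, ch, seed = 7, sample_interval = 5)
  expect_identical(a, b)
  c <- simulate_trial(f, pr, ch, seed = 8, sample_interval = 5)
  expect_false(identical(a$po2_mmHg, c$po2_mmHg))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  r1 <- runif(1)
  set.seed(123)
  invisible(simulate_trial(quiet_fish(), short_cold(), clean_chamber(),
                           seed = 1, sample_interval = 10))
  expect_identical(runif(1), r1)
})

test_that("trace structure: phases ordered, time increasing, holds covered", {
  tr <- simulate_trial(quiet_fish(), short_cold(), clean_chamber(), seed = 1,
                       sample_interval = 5)
  expect_true(all(diff(tr$time_s) > 0))
  expect_setequal(unique(tr$phase), c("flush", "wait", "measure"))
  for (cyc in split(tr, tr$cycle_index)) {
    ph <- rle(cyc$phase)$values
    expect_identical(ph, c("flush", "wait", "measure"))
  }
  # cold arm visits all three holds
  expect_true(all(c(15, 10, 5) %in% round(tr$temp_C, 6)))
  # total span: holds plus two 2-hour ramps at 2.5 C/h
  expect_equal(max(tr$time_s) / 3600, 2 + 2 + 1 + 2 + 2, tolerance = 0.1)
})

test_that("temperature never changes faster than the ramp rate", {
  tr <- simulate_trial(quiet_fish(), short_cold(), clean_chamber(), seed = 1,
                       sample_interval = 5)
  rate <- abs(diff(tr$temp_C)) / diff(tr$time_s) * 3600
  expect_lte(max(rate), 2.5 + 1e-9)
})

test_that("embedded truth satisfies the Q10 law exactly", {
  f <- quiet_fish(smr_ref = 55, q10 = 2.3)
  tr <- simulate_trial(f, short_cold(), clean_chamber(), seed = 1,
                       sample_interval = 10)
  truth <- attr(tr, "truth")
  expect_equal(q10(truth$smr[["5"]], truth$smr[["15"]], 5, 15), 2.3)
  expect_equal(unname(truth$mmr / truth$smr),
               rep(f$mmr_multiplier, 3))
})

test_that("noise-free measure-phase declines equal the generative physics", {
  f <- quiet_fish(smr_ref = 60, bw = 0.3)
  ch <- clean_chamber(volume = 7)
  tr <- simulate_trial(f, short_cold(), ch, seed = 1, sample_interval = 5)
  truth <- attr(tr, "truth")$cycles
  hold <- truth[truth$is_hold, ]
  set.seed(4)
  for (i in sample(nrow(hold), 5)) {
    cyc <- tr[tr$cycle_index == hold$cycle_index[i] & tr$phase == "measure", ]
    expected <- -(hold$mo2_true[i] * 0.3) /
      ((7 - 0.3) * o2_solubility(hold$nominal_temp[i], 18))
    fit <- fit_slope(cyc$time_s, cyc$po2_mmHg)
    expect_equal(fit$slope, expected, tolerance = 1e-9)
    expect_equal(fit$r_squared, 1)
  }
})

test_that("invalid simulation requests are rejected", {
  heavy <- quiet_fish(bw = 5)
  expect_error(simulate_trial(heavy, short_cold(), respirometer_spec(4),
                              seed = 1), "volume")
  expect_error(
    simulate_trial(quiet_fish(), short_cold(), clean_chamber(), seed = 1,
                   sample_interval = 200),
    "at least 3 samples")
})

test_that("trace CSV + truth sidecar round-trip preserves data and truth", {
  f <- quiet_fish()
  tr <- simulate_trial(f, short_cold(), clean_chamber(), seed = 2,
                       sample_interval = 10)
  path <- file.path(tempdir(), "trace.csv")
  write_trace_csv(tr, path)
  back <- read_trace_csv(path)
  expect_equal(back$po2_mmHg, tr$po2_mmHg, tolerance = 1e-12)
  expect_equal(attr(back, "truth")$smr, attr(tr, "truth")$smr)
  expect_equal(attr(back, "fish")$smr_ref, f$smr_ref)
  # processable after the round trip
  rec <- process_trace(back)
  expect_gt(sum(rec$passed_qc), 0)
  unlink(c(path, paste0(path, ".truth.json")))
})

test_that("cohort generator reproduces study-style groups deterministically", {
  co <- make_cohort("cold", seed = 5)
  expect_length(co, 21)
  expect_equal(sum(vapply(co, function(f) f$origin, "") == "northern"), 10)
  q10s <- vapply(co, function(f) f$q10_true, 1)
  expect_true(all(q10s >= 1.4 & q10s <= 3.4))
  co2 <- make_cohort("cold", seed = 5)
  expect_identical(co, co2)
  heat <- make_cohort("heat", seed = 5)
  expect_length(heat, 15)
  expect_equal(heat[[1]]$t_ref, 20)
})
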