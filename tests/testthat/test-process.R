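test_that("segment_cycles returns one measure window per cycle", {
  tr <- handmade_trace(slopes = c(-40, -50, -60))
  w <- segment_cycles(tr, hold_temps = 15)
  expect_length(w, 3)
  expect_true(all(vapply(w, function(x) all(x$phase == "measure"), TRUE)))
  expect_equal(vapply(w, nrow, 1L), c(`1` = 60, `2` = 60, `3` = 60))
  expect_equal(vapply(w, attr, 1, "nominal_temp"), c(`1` = 15, `2` = 15,
                                                     `3` = 15))
  one <- handmade_trace(slopes = -40)
  expect_length(segment_cycles(one, hold_temps = 15), 1)
})

test_that("cycles overlapping a thermal ramp are flagged", {
  tr <- simulate_trial(quiet_fish(), short_cold(), clean_chamber(), seed = 1,
                       sample_interval = 5)
  w <- segment_cycles(tr)
  ramps <- vapply(w, attr, TRUE, "is_ramp")
  temps <- vapply(w, attr, 1, "nominal_temp")
  expect_true(any(ramps))
  expect_true(all(is.na(temps[ramps])))
  expect_true(all(temps[!ramps] %in% c(15, 10, 5)))
  # every flagged window has samples off all hold temperatures; every
  # unflagged window sits within tolerance of its nominal hold
  for (k in which(ramps))
    expect_gt(min(vapply(c(15, 10, 5), function(h)
      max(abs(w[[k]]$temp_C - h)), numeric(1))), 0.25)
  for (k in which(!ramps)[1:3])
    expect_lte(max(abs(w[[k]]$temp_C - temps[k])), 0.25)
})

test_that("traces without measurement phases are rejected", {
  tr <- handmade_trace(slopes = -40)
  tr2 <- tr[tr$phase != "measure", ]
  expect_error(segment_cycles(tr2, hold_temps = 15), "no measurement")
})

test_that("fit_slope recovers exact lines and matches lm on noisy windows", {
  t <- 0:299
  fit <- fit_slope(t, 150 - 10 * t / 3600)
  expect_equal(fit$slope, -10)
  expect_equal(fit$r_squared, 1)

  const <- fit_slope(t, rep(120, 300))
  expect_equal(const$slope, 0)
  expect_equal(const$r_squared, 0)

  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    tt <- sort(runif(n, 0, 600))
    po2 <- 150 + runif(1, -30, 0) * tt / 3600 + rnorm(n, 0, runif(1, 0, 2))
    ours <- fit_slope(tt, po2)
    ref <- lm(po2 ~ I(tt / 3600))
    expect_equal(ours$slope, unname(coef(ref)[2]), tolerance = 1e-10)
    expect_equal(ours$r_squared, summary(ref)$r.squared, tolerance = 1e-10)
  }
  expect_error(fit_slope(c(1, 1, 1), c(5, 6, 7)), "time")
  expect_error(fit_slope(1:2, 1:2), "3 samples")
})

test_that("compute_mo2 implements V * |slope| * beta with background", {
  ch <- respirometer_spec(volume = 10.5)
  # V_eff 10 L, slope -5, beta forced via salinity/temp: use arithmetic check
  beta <- o2_solubility(15, 18)
  res <- compute_mo2(-5, ch, body_weight = 0.5, temp = 15, salinity = 18)
  expect_equal(res$mo2_whole, 10 * 5 * beta)
  expect_equal(res$mo2_mass_specific, res$mo2_whole / 0.5)
  expect_true(res$valid_slope)

  zero <- compute_mo2(0, ch, 0.5, 15, 18)
  expect_equal(zero$mo2_whole, 0)
  expect_false(zero$valid_slope)

  bg <- compute_mo2(-5, ch, 0.5, 15, 18, background_rate = 1)
  expect_equal(bg$mo2_whole, 10 * 5 * beta - 1)
  huge_bg <- compute_mo2(-0.001, ch, 0.5, 15, 18, background_rate = 10)
  expect_equal(huge_bg$mo2_whole, 0)  # clipped, never negative
})

test_that("mass correction: standard-weight and isometric identities, and
           the documented direction for b < 1", {
  expect_equal(mass_correct(123.4, 0.34, b = 0.948), 123.4)
  expect_equal(mass_correct(123.4, 0.34, b = 0.937), 123.4)
  expect_equal(mass_correct(77, 0.9, b = 1), 77)
  expect_equal(mass_correct(100, 0.68, b = 0.948), 100 * 2^0.052)
  # b < 1: larger-than-standard fish adjusted upward, smaller downward
  expect_gt(mass_correct(100, 0.68, 0.948), 100)
  expect_lt(mass_correct(100, 0.17, 0.948), 100)
  # b > 1 reverses the direction
  expect_lt(mass_correct(100, 0.68, 1.2), 100)
  expect_error(mass_correct(100, -1, 0.948), "body_weight")
  expect_error(mass_correct(100, 0.3, 2.5), "b must")
})

test_that("background negligibility report matches the 1% convention", {
  expect_equal(check_background(0, 50)$ratio, 0)
  expect_true(check_background(0, 50)$negligible)
  expect_true(check_background(0.25, 50)$negligible)     # 0.5%
  expect_false(check_background(1, 50)$negligible)       # 2%
  expect_error(check_background(1, 0), "positive")
})

test_that("QC excludes exactly the low-r2, rising and ramp cycles", {
  tr <- simulate_trial(quiet_fish(), short_cold(), clean_chamber(), seed = 3,
                       sample_interval = 5)
  # inject noise into 4 chosen measure windows to destroy their linearity
  bad <- c(3, 6, 9, 12)   # all inside the first 15 C hold
  set.seed(1)
  for (b in bad) {
    sel <- tr$cycle_index == b & tr$phase == "measure"
    tr$po2_mmHg[sel] <- tr$po2_mmHg[sel] + rnorm(sum(sel), 0, 25)
  }
  rec <- process_trace(tr)
  expect_true(all(rec$r_squared >= 0 & rec$r_squared <= 1))
  low_r2 <- rec$cycle_index[rec$r_squared < 0.95 & !rec$is_ramp]
  expect_setequal(low_r2, bad)
  expect_setequal(rec$cycle_index[!rec$passed_qc & !rec$is_ramp], bad)
  expect_equal(attr(rec, "n_excluded"), sum(!rec$passed_qc))
  # every other on-hold cycle passes (noise-free simulation)
  expect_true(all(rec$passed_qc[!rec$is_ramp & !rec$cycle_index %in% bad]))
})

test_that("processing closes the loop on noise-free simulations", {
  f <- quiet_fish(smr_ref = 45, q10 = 2.2, bw = 0.4)
  tr <- simulate_trial(f, short_cold(), clean_chamber(), seed = 5,
                       sample_interval = 5)
  rec <- process_trace(tr)
  truth <- attr(tr, "truth")$cycles
  m <- merge(rec[rec$passed_qc, ], truth, by = "cycle_index")
  m <- m[m$is_hold, ]   # boundary cycles are computed at the nominal temp
  expect_gt(nrow(m), 10)
  expect_lt(max(abs(m$mo2_mass_specific - m$mo2_true) / m$mo2_true), 1e-6)
})

test_that("standardized columns apply the two exponents to the same rate", {
  tr <- simulate_trial(quiet_fish(bw = 0.5), short_cold(), clean_chamber(),
                       seed = 2, sample_interval = 10)
  rec <- process_trace(tr)
  expect_equal(rec$mo2_std_smr,
               mass_correct(rec$mo2_mass_specific, 0.5, 0.948))
  expect_equal(rec$mo2_std_mmr,
               mass_correct(rec$mo2_mass_specific, 0.5, 0.937))
})
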