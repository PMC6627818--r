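test_that("pooled t-test matches the closed-form oracle", {
  # textbook pooled-variance formula, written out independently
  oracle <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    list(t = t, df = n1 + n2 - 2, p = 2 * pt(-abs(t), n1 + n2 - 2))
  }
  set.seed(31)
  for (i in 1:25) {
    a <- rnorm(sample(2:15, 1), 50, 5)
    b <- rnorm(sample(2:15, 1), 55, 8)
    ours <- t_test_pooled(a, b)
    ref <- oracle(a, b)
    expect_equal(ours$t_statistic, ref$t, tolerance = 1e-10)
    expect_equal(ours$df, ref$df)
    expect_equal(ours$p_value, ref$p, tolerance = 1e-10)
  }
})

test_that("pooled t-test df bookkeeping and symmetry", {
  set.seed(5)
  a <- rnorm(11, 40, 4); b <- rnorm(10, 46, 4)
  res <- t_test_pooled(a, b)
  expect_equal(res$df, 19L)   # n1 + n2 - 2
  rev <- t_test_pooled(b, a)
  expect_equal(rev$t_statistic, -res$t_statistic)
  expect_equal(rev$p_value, res$p_value)
})

test_that("degenerate pooled t-tests are explicit", {
  same <- t_test_pooled(c(5, 5, 5), c(5, 5))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$degenerate)

  ident <- t_test_pooled(c(3, 4, 5), c(3, 4, 5))
  expect_equal(ident$t_statistic, 0)
  expect_equal(ident$p_value, 1)

  apart <- t_test_pooled(c(5, 5, 5), c(7, 7))
  expect_true(apart$degenerate)
  expect_error(t_test_pooled(1, c(2, 3)), "at least 2")
})

test_that("percent difference", {
  expect_equal(round(percent_difference(185.6, 135.1)), 37)
  expect_equal(round(percent_difference(34.0, 28.6)), 19)
  expect_equal(percent_difference(50, 50), 0)
  expect_error(percent_difference(10, 0), "positive")
})

make_lmm_data <- function(n_per_origin = c(8, 8), delta = 0, sd_fish = 5,
                          sd_res = 4, temps = c(5, 10, 15),
                          cellmean = c(30, 42, 60)) {
  n <- sum(n_per_origin)
  fish <- sprintf("f%02d", seq_len(n))
  origin <- rep(c("north", "south"), n_per_origin)
  b <- rnorm(n, 0, sd_fish)
  d <- expand.grid(fish_id = fish, temperature = temps,
                   KEEP.OUT.ATTRS = FALSE)
  i <- match(d$fish_id, fish)
  d$origin <- origin[i]
  d$smr <- cellmean[match(d$temperature, temps)] + b[i] +
    delta * (d$origin == "north") + rnorm(nrow(d), 0, sd_res)
  d
}

test_that("with zero between-fish variance and balance, predictions equal
           cell means", {
  set.seed(2)
  d <- make_lmm_data(sd_fish = 0, sd_res = 3)
  fit <- fit_smr_lmm(d)
  pred <- predict(fit)
  cellmeans <- aggregate(smr ~ origin + temperature, d, mean)
  m <- merge(pred, cellmeans, by = c("origin", "temperature"))
  expect_equal(m$fit, m$smr, tolerance = 1e-6)
})

test_that("LRT df bookkeeping matches the model structure", {
  set.seed(3)
  d <- make_lmm_data()
  fit <- fit_smr_lmm(d)
  tab <- fit$lrt
  expect_equal(tab$df[tab$effect == "origin"], 1L)
  expect_equal(tab$df[tab$effect == "temperature"], 2L)
  expect_equal(tab$df[tab$effect == "origin:temperature"], 2L)
  expect_true(all(tab$chisq >= 0))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
})

test_that("LRT of a model against itself is the null result", {
  set.seed(8)
  d <- make_lmm_data(delta = 6)
  fit <- fit_smr_lmm(d)
  self <- lrt(fit$nested$additive, fit$nested$additive)
  expect_equal(self$chisq, 0)
  expect_equal(self$p_value, 1)
})

test_that("LRT chi-squared matches an independent nlme refit", {
  set.seed(8)
  d <- make_lmm_data(delta = 6)
  fit <- fit_smr_lmm(d)
  ours <- lrt(fit$nested$additive, fit$nested$temperature)

  d$temperature <- factor(d$temperature)
  m1 <- nlme::lme(smr ~ origin + temperature, random = ~ 1 | fish_id,
                  data = d, method = "ML")
  m0 <- nlme::lme(smr ~ temperature, random = ~ 1 | fish_id, data = d,
                  method = "ML")
  ref <- 2 * (as.numeric(logLik(m1)) - as.numeric(logLik(m0)))
  expect_equal(ours$chisq, ref, tolerance = 1e-6)
  expect_equal(ours$df, 1L)

  # non-nested pair rejected
  expect_error(lrt(fit$nested$temperature, fit$model), "nested")
})

test_that("mixed model recovers a known origin effect", {
  set.seed(14)
  hits <- 0; nrep <- 60; delta <- 8
  for (r in seq_len(nrep)) {
    d <- make_lmm_data(n_per_origin = c(10, 10), delta = delta)
    fit <- fit_smr_lmm(d)
    est <- coef(fit)[["originsouth"]]   # south - north contrast at baseline
    se <- sqrt(as.matrix(vcov(fit$model))["originsouth", "originsouth"])
    if (abs(-est - delta) <= 2 * se) hits <- hits + 1
  }
  expect_gte(hits / nrep, 0.9)
})

test_that("empty origin-by-temperature cells are reported, not silently fit", {
  set.seed(4)
  d <- make_lmm_data()
  d <- d[!(d$origin == "south" & d$temperature == 10), ]
  expect_error(fit_smr_lmm(d), "singular design")
})

test_that("predicted-SMR table carries n, fit, sd, se, ci per cell", {
  set.seed(6)
  d <- make_lmm_data(n_per_origin = c(10, 11), delta = 5)
  fit <- fit_smr_lmm(d)
  pred <- predict(fit)
  expect_named(pred, c("origin", "temperature", "n", "fit", "sd", "se", "ci"))
  expect_equal(nrow(pred), 6)
  expect_equal(sort(unique(pred$n)), c(10, 11))
  expect_equal(pred$sd, pred$se * sqrt(pred$n))
  expect_equal(pred$ci, qt(0.975, pred$n - 1) * pred$se)
  expect_true(all(pred$se > 0))
})

test_that("compare_populations builds the per-temperature contrast table", {
  set.seed(9)
  phenos <- list()
  for (i in 1:6) {
    f <- quiet_fish(sprintf("n%02d", i), smr_ref = 60 + rnorm(1, 0, 3))
    f$origin <- "north"
    tr <- simulate_trial(f, short_cold(), clean_chamber(), seed = 100 + i,
                         sample_interval = 10)
    phenos[[length(phenos) + 1]] <-
      estimate_phenotypes(process_trace(tr), origin = "north", min_obs = 5)
  }
  for (i in 1:6) {
    f <- quiet_fish(sprintf("s%02d", i), smr_ref = 45 + rnorm(1, 0, 3))
    tr <- simulate_trial(f, short_cold(), clean_chamber(), seed = 200 + i,
                         sample_interval = 10)
    phenos[[length(phenos) + 1]] <-
      estimate_phenotypes(process_trace(tr), origin = "south", min_obs = 5)
  }
  tab <- compare_populations(phenos)
  smr15 <- tab[tab$metric == "SMR" & tab$temperature == "15", ]
  expect_equal(smr15$df, 10L)
  expect_true(smr15$significant)   # 60 vs 45 with sd 3 is unmissable
  expect_true(all(c("SMR", "MMR", "AAS", "FAS", "Q10") %in% tab$metric))
  holm <- compare_populations(phenos, adjust = "holm")
  expect_true(all(holm$p_value >= tab$p_value))
})
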