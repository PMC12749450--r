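long_rows <- function(id, sex, ages, heights) {
  data.frame(sample_id = id, sex = sex, age = ages, height = heights,
             stringsAsFactors = FALSE)
}

test_that("annualized change is the height difference over the elapsed years", {
  long <- rbind(long_rows("a", "female", c(60, 65), c(170, 169)),
                long_rows("b", "male", c(50, 55), c(180, 180)),
                long_rows("c", "male", c(55, 55), c(175, 174)),   # zero interval
                long_rows("d", "female", 58, 166))                # single row
  expect_message(ch <- annualized_change(long), "rejected 2")
  expect_equal(nrow(ch), 2)
  expect_equal(ch$delta[ch$sample_id == "a"], -0.2)
  expect_equal(ch$age_mid[ch$sample_id == "a"], 62.5)
  expect_equal(ch$delta[ch$sample_id == "b"], 0)
})

test_that("onset is recovered from a simulated cohort with short intervals", {
  set.seed(40)
  n <- 50000
  cfg <- sim_config(n_samples = n, height_meas_sd = 0.05,
                    heightloss_onset = c(female = 55, male = 55),
                    followup_interval = c(1.5, 2), age_range = c(40, 75))
  pheno <- data.frame(sample_id = sprintf("S%05d", 1:n),
                      sex = sample(c("female", "male"), n, TRUE),
                      age = runif(n, 40, 75), height = 170,
                      stringsAsFactors = FALSE)
  long <- simulate_longitudinal_heights(cfg, pheno)
  ch <- annualized_change(long, verbose = FALSE)
  onset <- estimate_onset(ch, verbose = FALSE)
  expect_true(all(abs(onset - 55) <= 1))
})

test_that("onset estimation errors when no loss exists and handles boundaries", {
  set.seed(41)
  n <- 3000
  ch <- data.frame(sample_id = as.character(1:n),
                   sex = sample(c("female", "male"), n, TRUE),
                   delta = rnorm(n, 0, 0.05),
                   age_mid = runif(n, 45, 75), stringsAsFactors = FALSE)
  expect_error(estimate_onset(ch, verbose = FALSE), "no onset")
  # loss from the youngest observed age onward: onset is that age
  ch2 <- ch
  ch2$delta <- -0.3 + rnorm(n, 0, 0.01)
  onset2 <- estimate_onset(ch2, verbose = FALSE)
  expect_true(all(onset2 == 45))
  expect_error(estimate_onset(ch[ch$age_mid < 50, ], min_bins = 10,
                              verbose = FALSE),
               "bins")
})

test_that("percentile curves degenerate correctly under a constant loss rate", {
  set.seed(42)
  n <- 2000
  ch <- data.frame(sample_id = as.character(1:n),
                   sex = rep(c("female", "male"), n / 2),
                   delta = -0.25, age_mid = runif(n, 56, 75),
                   stringsAsFactors = FALSE)
  m <- fit_loss_percentiles(ch, c(female = 55, male = 55),
                            percentiles = c(10, 50, 90))
  for (a in c(60, 70))
    expect_equal(loss_quantiles_at_age(m, "female", a), rep(0.25, 3),
                 tolerance = 1e-6)
})

test_that("percentile curves are ordered and clamped non-negative", {
  set.seed(43)
  n <- 4000
  age <- runif(n, 56, 75)
  loss <- 0.02 * (age - 55) * rexp(n)  # age-increasing spread
  ch <- data.frame(sample_id = as.character(1:n),
                   sex = rep(c("female", "male"), n / 2),
                   delta = -loss, age_mid = age, stringsAsFactors = FALSE)
  m <- fit_loss_percentiles(ch, c(female = 55, male = 55))
  for (a in c(60, 68, 74)) {
    q <- loss_quantiles_at_age(m, "female", a)
    expect_true(all(diff(q) >= 0))   # monotone in percentile
    expect_true(all(q >= 0))
    expect_gt(q[95], q[50])
  }
  expect_error(fit_loss_percentiles(ch[1:100, ],
                                    c(female = 55, male = 55)),
               "minimum is 200")
})

flat_loss_model <- function(median_rate, spread = 0, percentiles = 1:99) {
  # loss model with constant-in-age percentile curves, built directly
  rates <- median_rate + spread * (percentiles - 50) / 100
  structure(list(onset = c(female = 55, male = 55),
                 percentiles = percentiles,
                 coefs = list(
                   female = cbind(rates, 0),
                   male = cbind(rates, 0))),
            class = "heightloss_model")
}

gap_table_for <- function(gap, height = 170) {
  out <- data.frame(sample_id = as.character(seq_along(gap)),
                    stratum = "s", measured_height = height + gap,
                    predicted_height = height, gap = gap,
                    stringsAsFactors = FALSE)
  attr(out, "gap_sd") <- sd(gap)
  attr(out, "heightloss_corrected") <- FALSE
  class(out) <- c("height_gap_table", "data.frame")
  out
}

test_that("median correction integrates the median curve from onset", {
  m <- flat_loss_model(0.1)
  gt <- gap_table_for(c(-2, 0, 2))
  ages <- c(50, 65, 58.5)
  sex <- rep("female", 3)
  out <- correct_median(gt, ages, sex, m)
  expect_equal(out$gap[1], -2)          # below onset: identity
  expect_equal(out$gap[2], 0 + 0.1 * 10)  # flat 0.1 cm/yr for 10 years
  expect_equal(out$gap[3], 2 + 0.1 * 3.5) # fractional years accumulate
  expect_equal(out$measured_height - gt$measured_height,
               out$gap - gt$gap)        # predicted height unchanged
})

test_that("an all-zero loss model makes both corrections the identity", {
  m <- flat_loss_model(0)
  gt <- gap_table_for(rnorm(50))
  ages <- runif(50, 50, 75)
  sex <- rep(c("female", "male"), 25)
  expect_equal(correct_median(gt, ages, sex, m)$gap, gt$gap)
  expect_equal(correct_worstcase(gt, ages, sex, m, verbose = FALSE)$gap,
               gt$gap)
})

test_that("worst-case at a median-only grid equals the median correction", {
  m50 <- flat_loss_model(0.15, percentiles = 50)
  set.seed(44)
  gt <- gap_table_for(rnorm(80))
  ages <- runif(80, 50, 75)
  sex <- rep(c("female", "male"), 40)
  med <- correct_median(gt, ages, sex, m50)
  wc <- correct_worstcase(gt, ages, sex, m50, verbose = FALSE)
  expect_identical(med$gap, wc$gap)
})

test_that("worst-case assigns larger corrections to larger deficits and keeps order", {
  m <- flat_loss_model(0.1, spread = 0.05)
  gap <- seq(-10, 10, length.out = 99)  # uniform GaP, spread >> correction
  gt <- gap_table_for(gap)
  ages <- rep(65, 99)
  sex <- rep("female", 99)
  out <- correct_worstcase(gt, ages, sex, m, verbose = FALSE)
  incr <- out$gap - gt$gap
  expect_true(all(diff(incr) <= 1e-12))  # deficit rank gets larger correction
  expect_true(all(diff(out$gap) > 0))    # monotone map preserves ordering
  # the mid-rank participant receives exactly the median correction
  mid <- which(rank(-gap) == 50)
  expect_equal(incr[mid], 0.1 * 10)
})

test_that("a second correction is rejected by the idempotence guard", {
  m <- flat_loss_model(0.1)
  gt <- gap_table_for(rnorm(10))
  out <- correct_median(gt, rep(60, 10), rep("female", 10), m)
  expect_error(correct_median(out, rep(60, 10), rep("female", 10), m),
               "twice")
  expect_error(correct_worstcase(out, rep(60, 10), rep("female", 10), m),
               "twice")
})

test_that("refitting after a zero-loss correction reproduces the hazard ratio", {
  co <- toy_gap_cohort(3000, hr_per_sd = 1.3, seed = 46)
  gt <- gap_table_for(co$gap)
  m <- flat_loss_model(0)
  corr <- correct_median(gt, co$age, co$sex, m)
  res <- refit_after_correction(gt, corr, co$surv)
  expect_equal(res$corrected$hr, res$uncorrected$hr, tolerance = 1e-10)
  expect_equal(res$attenuation, 1, tolerance = 1e-10)
})

test_that("loss uncorrelated with GaP leaves the association essentially intact", {
  co <- toy_gap_cohort(4000, hr_per_sd = 1.4, seed = 47)
  gt <- gap_table_for(co$gap)
  m <- flat_loss_model(0.15, spread = 0.1)
  corr <- correct_median(gt, co$age, co$sex, m)
  res <- refit_after_correction(gt, corr, co$surv)
  expect_equal(log(res$corrected$hr), log(res$uncorrected$hr),
               tolerance = 0.15)
})
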