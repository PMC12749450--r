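test_that("per-SD deficit standardization has the stated sign and scale", {
  gap <- c(-5.2, 0, 5.2)
  z <- -gap / sd(gap)
  expect_equal(per_sd_deficit(gap), z)
  expect_equal(per_sd_deficit(c(gap, gap))[1], 5.2 / sd(c(gap, gap)))
  expect_error(per_sd_deficit(rep(1, 10)), "zero SD")
})

test_that("sex-specific quartiles label deficits as Q1 and resist shifts", {
  g <- c(-3, -1, 1, 3)
  q <- sex_quartiles(g, rep("female", 4))
  expect_equal(as.character(q), c("Q1", "Q2", "Q3", "Q4"))
  # shift one sex: membership must be computed within sex
  set.seed(20)
  g2 <- rnorm(400)
  sex <- rep(c("female", "male"), each = 200)
  g_shift <- g2 + ifelse(sex == "male", 10, 0)
  expect_equal(as.character(sex_quartiles(g2, sex)),
               as.character(sex_quartiles(g_shift, sex)))
  # near-equal quartile sizes for continuous data
  expect_true(all(abs(table(sex_quartiles(g2, sex)) - 100) <= 2))
  expect_error(sex_quartiles(c(1, 2), c("f", "f")), "fewer than 4")
})

test_that("ties at a cut point fall into the lower quartile", {
  g <- c(1, 1, 1, 2, 3, 4, 5, 6)  # 25th percentile is 1
  q <- sex_quartiles(g, rep("f", 8))
  expect_true(all(q[g == 1] == "Q1"))
})

test_that("Cox per-SD fits satisfy exact reparameterization identities", {
  co <- toy_gap_cohort(3000, hr_per_sd = 1.3, seed = 21)
  z <- per_sd_deficit(co$gap)
  fit_pos <- fit_cox(co$surv, z)
  fit_neg <- fit_cox(co$surv, -z)
  expect_equal(fit_pos$hr, 1 / fit_neg$hr, tolerance = 1e-10)
  expect_equal(fit_pos$ci_low, 1 / fit_neg$ci_high, tolerance = 1e-10)
  # time-scale invariance: years -> half-years
  recs2 <- co$surv
  recs2$time <- recs2$time * 2
  expect_equal(fit_cox(recs2, z)$hr, fit_pos$hr, tolerance = 1e-10)
})

test_that("cause-specific fits censor other-cause deaths", {
  co <- toy_gap_cohort(4000, hr_per_sd = 1.4, seed = 22)
  z <- per_sd_deficit(co$gap)
  fit_ascvd <- fit_cox(co$surv, z, cause = c("chd", "stroke"))
  expect_lt(fit_ascvd$n_events, sum(co$surv$event))
  expect_equal(fit_ascvd$n_events,
               sum(co$surv$event == 1 &
                     co$surv$cause_label %in% c("chd", "stroke")))
  expect_error(fit_cox(co$surv, z, min_events = 1e6), "minimum")
})

test_that("adding an orthogonal predicted-height column barely moves the GaP coefficient", {
  # the Cox partial likelihood is non-collapsible, so exact invariance
  # holds only in linear models; here the shift must be pure risk-set
  # noise: an order of magnitude below the effect and centred on zero
  shifts <- vapply(1:10, function(r) {
    co <- toy_gap_cohort(5000, hr_per_sd = 1.3, seed = 230 + r)
    z <- per_sd_deficit(co$gap)
    set.seed(330 + r)
    pred <- rnorm(5000, 171, 4)          # independent of GaP by construction
    pred <- pred - sum(pred * z) / sum(z * z) * z  # exact orthogonalization
    b1 <- log(fit_cox(co$surv, z)$hr)
    b2 <- log(fit_cox(co$surv, z, data.frame(predicted_height = pred))$hr)
    b2 - b1
  }, numeric(1))
  expect_lt(mean(abs(shifts)), 0.05)  # about 5x below log(1.3) = 0.26
  expect_lt(abs(mean(shifts)), 0.03)                        # no systematic bias
})

test_that("quartile contrasts use the least-deficit reference and invert on swap", {
  co <- toy_gap_cohort(4000, hr_per_sd = 1.4, seed = 24)
  q <- sex_quartiles(co$gap, co$sex)
  res <- quartile_contrast(co$surv, q)
  expect_equal(res$term, paste0("quartileQ", 1:3))
  expect_gt(res$hr[1], 1)  # largest deficit quartile is harmful
  # reference swap: refit with Q1 as reference and compare reciprocals
  df <- data.frame(time = co$surv$time, event = co$surv$event,
                   quartile = relevel(q, ref = "Q1"))
  fit_swapped <- survival::coxph(survival::Surv(time, event) ~ quartile,
                                 data = df, ties = "efron")
  expect_equal(unname(exp(coef(fit_swapped)["quartileQ4"])),
               1 / res$hr[1], tolerance = 1e-10)
  expect_error(quartile_contrast(co$surv, factor(rep("Q1", 4000),
                                                 levels = paste0("Q", 1:4))),
               "empty quartile")
})

test_that("null-effect quartile CIs cover 1 at the nominal rate", {
  covered <- vapply(1:40, function(s) {
    co <- toy_gap_cohort(800, hr_per_sd = 1.0, seed = 400 + s,
                         baseline_hazard = 0.02)
    q <- sex_quartiles(co$gap, co$sex)
    res <- quartile_contrast(co$surv, q, min_events = 20)
    res$ci_low[1] <= 1 && 1 <= res$ci_high[1]
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("Kaplan-Meier output matches the product-limit estimate by hand", {
  recs <- data.frame(time = c(1, 2, 3, 4, 5, 6, 7, 8),
                     event = c(0, 0, 0, 0, 1, 0, 0, 0))
  labels <- factor(rep(c("Q1", "Q2"), each = 4), levels = paste0("Q", 1:4))
  km <- km_by_quartile(recs, labels)
  q2 <- km$curves[km$curves$quartile == "Q2", ]
  # single event at t=5 with all 4 still at risk: survival steps to 3/4
  expect_equal(min(q2$survival), 3 / 4)
  q1 <- km$curves[km$curves$quartile == "Q1", ]
  expect_true(all(q1$survival == 1))  # no events
  expect_true(all(c("time", "quartile", "at_risk") %in% names(km$at_risk)))
})

test_that("a strong deficit effect orders the KM curves", {
  co <- toy_gap_cohort(6000, hr_per_sd = 1.8, seed = 25,
                       baseline_hazard = 0.02)
  q <- sex_quartiles(co$gap, co$sex)
  km <- km_by_quartile(co$surv, q, times = c(0, 15))
  end <- km$at_risk[km$at_risk$time == 15, ]
  s_end <- setNames(end$survival, end$quartile)
  expect_true(s_end["Q1"] < s_end["Q2"] && s_end["Q2"] < s_end["Q3"] &&
                s_end["Q3"] < s_end["Q4"])
})

test_that("interaction tests detect sex-specific hazards and reject single levels", {
  set.seed(26)
  n <- 8000
  gap <- rnorm(n, 0, 5)
  sex <- sample(c("female", "male"), n, TRUE)
  z <- per_sd_deficit(gap)
  gamma <- ifelse(sex == "female", log(1.5), 0)
  u <- runif(n)
  t_event <- -log(u) / (0.02 * exp(gamma * z))
  recs <- data.frame(time = pmin(t_event, 15),
                     event = as.integer(t_event <= 15))
  p <- interaction_tests(recs, z, sex)
  expect_lt(p, 0.05)
  expect_error(interaction_tests(recs, z, rep("female", n)),
               "single level")
  # PCs dropped on request for race-ethnicity models
  covs <- data.frame(PC1 = rnorm(n), PC2 = rnorm(n), age = runif(n, 40, 70))
  p2 <- interaction_tests(recs, z, sex, covariates = covs, drop_pcs = TRUE)
  expect_true(is.finite(p2))
})
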