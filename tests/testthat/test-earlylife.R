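make_gap_data <- function(n, seed = 1, slope_bw = 0, u_shape = 0,
                          sex_slopes = NULL) {
  set.seed(seed)
  sex <- sample(c("female", "male"), n, TRUE)
  bw <- rnorm(n, 3.4, 0.5)
  eff <- if (is.null(sex_slopes)) slope_bw * (bw - 3.4) else
    ifelse(sex == "female", sex_slopes[1], sex_slopes[2]) * (bw - 3.4)
  gap <- eff + u_shape * (bw - 3.4)^2 + rnorm(n, 0, 5)
  data.frame(gap = gap, birthweight_kg = bw, sex = sex,
             age = runif(n, 20, 30),
             predicted_height = rnorm(n, 171, 4),
             stringsAsFactors = FALSE)
}

test_that("AIC pairing selects linear under a linear truth and spline under curvature", {
  d_lin <- make_gap_data(5000, seed = 2, slope_bw = -2)
  sp <- exposure_spec("birthweight_kg", "continuous", "per_unit_decrement")
  f_lin <- fit_exposure_models(d_lin, sp)
  expect_equal(f_lin$chosen, "linear")
  expect_lt(f_lin$aic_linear, f_lin$aic_spline)
  d_u <- make_gap_data(5000, seed = 3, u_shape = -3)
  f_u <- fit_exposure_models(d_u, sp)
  expect_equal(f_u$chosen, "spline")
})

test_that("forcing the spline basis to the raw exposure reproduces the linear AIC", {
  d <- make_gap_data(800, seed = 4, slope_bw = -1)
  sp <- exposure_spec("birthweight_kg", "continuous", "per_unit_decrement")
  f <- fit_exposure_models(d, sp, spline_df = 1)
  expect_equal(f$aic_linear, f$aic_spline)
})

test_that("constant exposures and undersized samples are hard errors", {
  d <- make_gap_data(200, seed = 5)
  d$birthweight_kg <- 3.4
  sp <- exposure_spec("birthweight_kg", "continuous", "per_unit_decrement")
  expect_error(fit_exposure_models(d, sp), "constant")
  d2 <- make_gap_data(40, seed = 6)
  expect_error(fit_exposure_models(d2, sp), "10 x parameters")
})

test_that("contrasts rescale correctly and flip sign for decrements", {
  set.seed(7)
  n <- 4000
  x <- rnorm(n, 0, 2)
  d <- data.frame(gap = 1 * x + rnorm(n, 0, 1), birthweight_kg = x,
                  sex = sample(c("female", "male"), n, TRUE),
                  age = runif(n, 20, 30), predicted_height = rnorm(n, 171, 4))
  sp_sd <- exposure_spec("birthweight_kg", "continuous", "per_1sd_decrement")
  res <- report_contrast(fit_exposure_models(d, sp_sd, adjusted = FALSE))
  # slope 1 per unit, SD 2 => per-1-SD decrement contrast -2 cm
  expect_equal(res$estimate, -1 * sd(x), tolerance = 0.05)
  expect_true(res$ci_low <= res$estimate && res$estimate <= res$ci_high)
})

test_that("an ordinal deprivation trend is recovered on the quantile scale", {
  set.seed(8)
  n <- 20000
  q <- sample(1:5, n, TRUE)
  d <- data.frame(gap = -0.2 * q + rnorm(n, 0, 5), deprivation_quintile = q,
                  sex = sample(c("female", "male"), n, TRUE),
                  age = runif(n, 20, 30), predicted_height = rnorm(n, 171, 4))
  sp <- exposure_spec("deprivation_quintile", "ordinal", "quantile")
  res <- report_contrast(fit_exposure_models(d, sp))
  expect_equal(res$estimate, -0.2, tolerance = 0.05 / 0.2)
  expect_equal(res$chosen, "linear")
})

test_that("category contrasts honour the stated reference and comparison", {
  set.seed(9)
  n <- 12000
  lev <- c("0", "<3", "3-6", "6+")
  x <- factor(sample(lev, n, TRUE), levels = lev)
  eff <- c(-1.0, -0.6, -0.3, 0)[as.integer(x)]
  d <- data.frame(gap = eff + rnorm(n, 0, 2), breastfeeding_months = x,
                  sex = sample(c("female", "male"), n, TRUE),
                  age = runif(n, 20, 30), predicted_height = rnorm(n, 171, 4))
  sp <- exposure_spec("breastfeeding_months", "categorical",
                      "category_vs_reference", reference = "6+",
                      comparison = "0")
  res <- report_contrast(fit_exposure_models(d, sp))
  expect_equal(res$estimate, -1.0, tolerance = 0.15)
  sp_bad <- exposure_spec("breastfeeding_months", "categorical",
                          "category_vs_reference", reference = "9+",
                          comparison = "0")
  expect_error(report_contrast(fit_exposure_models(d, sp_bad)),
               "reference")
})

test_that("null exposures give approximately uniform p-values", {
  ps <- vapply(1:300, function(s) {
    d <- make_gap_data(200, seed = 1000 + s)
    sp <- exposure_spec("birthweight_kg", "continuous",
                        "per_unit_decrement")
    report_contrast(fit_exposure_models(d, sp, adjusted = FALSE))$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("estimated marginal means collapse to raw means in simple designs", {
  set.seed(10)
  n <- 400
  x <- factor(rep(c("a", "b"), each = n / 2))
  y <- c(rnorm(n / 2, -1, 1), rnorm(n / 2, 1, 1))
  d <- data.frame(gap = y, grp = x)
  fit <- lm(gap ~ grp, data = d)
  emm <- estimated_marginal_means(fit, d, "grp", levels = c("a", "b"))
  expect_equal(emm$emm, c(mean(y[x == "a"]), mean(y[x == "b"])),
               tolerance = 1e-10)
  # intercept-only model: EMM equals the sample mean at every level
  fit0 <- lm(gap ~ 1, data = d)
  emm0 <- estimated_marginal_means(fit0, d, "grp", levels = c("a", "b"))
  expect_equal(emm0$emm, rep(mean(y), 2), tolerance = 1e-10)
})

test_that("EMMs agree with the emmeans package on an adjusted model", {
  skip_if_not_installed("emmeans")
  d <- make_gap_data(1000, seed = 11, slope_bw = -1.5)
  d$grp <- factor(sample(c("low", "mid", "high"), 1000, TRUE))
  fit <- lm(gap ~ grp + age + sex, data = d)
  ours <- estimated_marginal_means(fit, d, "grp",
                                   levels = levels(d$grp))
  ref <- as.data.frame(emmeans::emmeans(fit, "grp",
                                        weights = "proportional"))
  expect_equal(ours$emm, ref$emmean[match(ours$level, as.character(ref$grp))],
               tolerance = 1e-6)
})

test_that("EMMs warn when forced levels extrapolate", {
  d <- make_gap_data(500, seed = 12)
  fit <- lm(gap ~ birthweight_kg, data = d)
  expect_warning(
    estimated_marginal_means(fit, d, "birthweight_kg", levels = c(99)),
    "extrapolation")
})

test_that("sex-interaction test is powered under sex-specific slopes and errors on one sex", {
  hits <- vapply(1:20, function(s) {
    d <- make_gap_data(10000, seed = 2000 + s, sex_slopes = c(-2, 0))
    sp <- exposure_spec("birthweight_kg", "continuous",
                        "per_unit_decrement")
    sex_interaction(d, sp) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  d1 <- make_gap_data(500, seed = 13)
  d1$sex <- "female"
  sp <- exposure_spec("birthweight_kg", "continuous", "per_unit_decrement")
  expect_error(sex_interaction(d1, sp), "both sexes")
})

test_that("interaction p-values print with the reporting floor", {
  expect_equal(format_p_interaction(0.45), "p-interaction>=0.200")
  expect_equal(format_p_interaction(0.03), "p-interaction=0.030")
  expect_equal(format_p_interaction(NA), NA_character_)
})

test_that("Bonferroni thresholds round to the printed 3-decimal values", {
  expect_equal(bonferroni_threshold(0.050, 5), 0.010)
  expect_equal(bonferroni_threshold(0.050, 3), 0.017)
  expect_equal(bonferroni_threshold(0.050, 1), 0.050)
  expect_error(bonferroni_threshold(0.05, 0), "count")
  expect_error(bonferroni_threshold(1.2, 3), "alpha")
})

test_that("multivariable R^2 recovers the generating share of variance", {
  set.seed(14)
  n <- 5000
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  b <- sqrt(0.12 / 3 / (1 - 0.12))  # three equal slopes explaining 12%
  g <- b * (x1 + x2 + x3) + rnorm(n, 0, 1)
  d <- data.frame(gap = g, x1 = x1, x2 = x2, x3 = x3)
  res <- multivariable_r2(d, c("x1", "x2", "x3"), n_boot = 200)
  expect_equal(res$r_squared, 0.12, tolerance = 0.02 / 0.12)
  expect_true(res$ci[1] < res$r_squared && res$r_squared < res$ci[2])
})

test_that("a duplicated exposure column leaves R^2 unchanged", {
  set.seed(15)
  d <- data.frame(gap = rnorm(300), x1 = rnorm(300))
  d$x2 <- d$x1
  r_single <- multivariable_r2(d, "x1", n_boot = 10)$r_squared
  r_dup <- multivariable_r2(d, c("x1", "x2"), n_boot = 10)$r_squared
  expect_equal(r_dup, r_single, tolerance = 1e-12)
})

test_that("pure-noise exposures give near-zero adjusted R^2", {
  set.seed(16)
  n <- 2000
  d <- data.frame(gap = rnorm(n), x1 = rnorm(n), x2 = rnorm(n))
  res <- multivariable_r2(d, c("x1", "x2"), n_boot = 10)
  expect_lt(res$r_squared, 0.01)  # ~ p/n expectation
})
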