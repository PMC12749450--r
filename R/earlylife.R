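#' Declare an early-life exposure for association analysis
#'
#' @param name Column name of the exposure in the analysis table.
#' @param kind `"continuous"`, `"ordinal"` (numeric quantile coding, e.g.
#'   deprivation quintile 1..5) or `"categorical"`.
#' @param contrast How the tabular estimate is reported:
#'   `"per_1sd_decrement"`, `"per_unit_decrement"`, `"quantile"`
#'   (per-quantile linear trend) or `"category_vs_reference"`.
#' @param reference Reference level for category contrasts (e.g. `"6+"`).
#' @param comparison Level reported against the reference (e.g. `"0"` for a
#'   "0 vs 6+ months" contrast).
#' @param n_quantiles Number of quantile groups for ordinal codings
#'   (informational).
#' @return An `exposure_spec` list.
#' @export
exposure_spec <- function(name,
                          kind = c("continuous", "ordinal", "categorical"),
                          contrast = c("per_1sd_decrement",
                                       "per_unit_decrement", "quantile",
                                       "category_vs_reference"),
                          reference = NULL, comparison = NULL,
                          n_quantiles = 5) {
  kind <- match.arg(kind)
  contrast <- match.arg(contrast)
  if (contrast == "category_vs_reference" && kind != "categorical")
    stop("category_vs_reference contrast requires a categorical exposure")
  if (contrast %in% c("per_1sd_decrement", "per_unit_decrement") &&
      kind == "categorical")
    stop("per-SD/per-unit contrasts require a numeric exposure coding")
  if (contrast == "category_vs_reference" &&
      (is.null(reference) || is.null(comparison)))
    stop("category contrast needs both reference and comparison levels")
  structure(list(name = name, kind = kind, contrast = contrast,
                 reference = reference, comparison = comparison,
                 n_quantiles = n_quantiles), class = "exposure_spec")
}

adjust_terms <- function(adjusted) {
  if (adjusted) c("age", "sex", "predicted_height") else character(0)
}

earlylife_frame <- function(data, spec, adjusted) {
  need <- c("gap", spec$name, adjust_terms(adjusted),
            if (spec$name != "sex") NULL)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0)
    stop("analysis table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- data[need]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  x <- df[[spec$name]]
  if (spec$kind == "categorical") {
    x <- factor(x)
    if (nlevels(droplevels(x)) < 2) stop("exposure is constant: ", spec$name)
    df[[spec$name]] <- droplevels(x)
  } else {
    x <- as.numeric(x)
    if (stats::var(x) == 0) stop("exposure is constant: ", spec$name)
    df[[spec$name]] <- x
  }
  df
}

#' Fit paired linear and spline models of height-GaP on an exposure
#'
#' The outcome is height-GaP (cm).  The linear arm is Gaussian least
#' squares on the raw (numeric) exposure coding; the spline arm replaces a
#' continuous exposure with a natural cubic spline basis (`spline_df`
#' degrees of freedom, knots at exposure quantiles; `spline_df = 1` reduces
#' to the raw exposure for the nesting sanity check).  For ordinal
#' exposures the spline arm is the saturated category coding; for
#' categorical exposures both arms are saturated.  Adjusted models add age
#' at assessment, sex and genotype-predicted height; ancestry PCs are
#' deliberately not included here.
#'
#' @param data Analysis table with columns `gap`, the exposure and (when
#'   `adjusted`) `age`, `sex`, `predicted_height`.
#' @param spec An [exposure_spec()].
#' @param adjusted Add the covariate set? Default `TRUE`.
#' @param spline_df Natural-spline degrees of freedom (default 4).
#' @return Object of class `exposure_fit`: list with both `lm` fits, both
#'   AICs, the AIC-chosen model label, the exposure declaration and the
#'   complete-case `n`.
#' @export
fit_exposure_models <- function(data, spec, adjusted = TRUE, spline_df = 4) {
  df <- earlylife_frame(data, spec, adjusted)
  adj <- adjust_terms(adjusted)
  rhs_adj <- if (length(adj)) paste("+", paste(adj, collapse = " + ")) else ""
  x <- spec$name
  lin_term <- x
  spl_term <- if (spec$kind == "continuous") {
    if (spline_df == 1) x else
      sprintf("splines::ns(%s, df = %d)", x, spline_df)
  } else {
    sprintf("factor(%s)", x)
  }
  if (spec$kind == "categorical") lin_term <- spl_term
  f_lin <- stats::as.formula(paste("gap ~", lin_term, rhs_adj))
  f_spl <- stats::as.formula(paste("gap ~", spl_term, rhs_adj))
  fit_lin <- stats::lm(f_lin, data = df)
  fit_spl <- stats::lm(f_spl, data = df)
  p_max <- max(length(coef(fit_lin)), length(coef(fit_spl)))
  if (nrow(df) < 10 * p_max)
    stop("n = ", nrow(df), " below 10 x parameters (", 10 * p_max, ")")
  aic_lin <- stats::AIC(fit_lin)
  aic_spl <- stats::AIC(fit_spl)
  structure(list(linear = fit_lin, spline = fit_spl,
                 aic_linear = aic_lin, aic_spline = aic_spl,
                 chosen = if (aic_spl < aic_lin) "spline" else "linear",
                 spec = spec, adjusted = adjusted, n_used = nrow(df),
                 data = df),
            class = "exposure_fit")
}

#' Report the tabular contrast for an exposure fit
#'
#' Per-1-SD contrasts are computed on the analysis-sample SD of the
#' exposure; decrement contrasts are sign-flipped so that an adverse
#' ("deficit") association is negative cm; quantile contrasts are the
#' per-quantile linear trend; category contrasts compare the stated level
#' against the stated reference.
#'
#' @param fits An `exposure_fit` from [fit_exposure_models()].
#' @param conf_level Confidence level (default 0.95).
#' @return One-row `data.frame`: exposure, chosen model, both AICs,
#'   `estimate` (cm), `ci_low`, `ci_high`, `p_value`, `p_interaction_sex`
#'   and `n_used`.
#' @export
report_contrast <- function(fits, conf_level = 0.95) {
  spec <- fits$spec
  df <- fits$data
  if (spec$contrast == "category_vs_reference") {
    x <- factor(df[[spec$name]])
    if (!spec$reference %in% levels(x))
      stop("reference level absent: ", spec$reference)
    if (!spec$comparison %in% levels(x))
      stop("comparison level absent: ", spec$comparison)
    df[[spec$name]] <- stats::relevel(x, ref = spec$reference)
    fit <- stats::lm(stats::formula(fits$spline), data = df)
    term <- paste0("factor(", spec$name, ")", spec$comparison)
    if (!term %in% names(coef(fit)))
      stop("could not locate category coefficient for ", spec$comparison)
    est <- unname(coef(fit)[term])
    se <- sqrt(diag(vcov(fit))[term])
  } else {
    fit <- fits$linear
    term <- spec$name
    est <- unname(coef(fit)[term])
    se <- unname(sqrt(diag(vcov(fit))[term]))
    if (spec$contrast == "per_1sd_decrement") {
      sdx <- stats::sd(df[[spec$name]])
      est <- -est * sdx; se <- se * sdx
    } else if (spec$contrast == "per_unit_decrement") {
      est <- -est
    } # "quantile": per-quantile trend reported on the raw slope scale
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- 2 * stats::pnorm(-abs(est / se))
  p_int <- tryCatch(
    sex_interaction(fits$data, spec, adjusted = fits$adjusted),
    error = function(e) NA_real_)
  data.frame(exposure = spec$name, chosen = fits$chosen,
             aic_linear = fits$aic_linear, aic_spline = fits$aic_spline,
             estimate = est, ci_low = est - z * se, ci_high = est + z * se,
             p_value = p, p_interaction_sex = p_int, n_used = fits$n_used,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Estimated marginal mean height-GaP at forced exposure levels
#'
#' G-computation: for each requested level, every participant's exposure is
#' set to that level, the model predicts their height-GaP, and predictions
#' are averaged over the observed covariate distribution.  The CI comes
#' from the delta method on the averaged linear predictor.
#'
#' @param fit An `lm` fit (e.g. `fits$spline` from
#'   [fit_exposure_models()]).
#' @param data The analysis table the model was fit on.
#' @param exposure Exposure column name.
#' @param levels Levels (or numeric values) at which to estimate the mean.
#' @param conf_level Confidence level.
#' @return `data.frame` with `level`, `emm`, `se`, `ci_low`, `ci_high`.
#' @export
estimated_marginal_means <- function(fit, data, exposure, levels,
                                     conf_level = 0.95) {
  x_obs <- data[[exposure]]
  if (is.numeric(x_obs)) {
    lv <- as.numeric(levels)
    if (any(lv < min(x_obs) | lv > max(x_obs)))
      warning("EMM level(s) outside the observed exposure range ",
              "(extrapolation)")
  }
  beta <- coef(fit)
  V <- vcov(fit)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(levels, function(l) {
    nd <- data
    if (is.factor(data[[exposure]]) || is.character(data[[exposure]])) {
      nd[[exposure]] <- rep(as.character(l), nrow(nd))
    } else nd[[exposure]] <- as.numeric(l)
    # xlevels keep factor codings intact when a single level is forced
    mf <- stats::model.frame(stats::terms(fit), nd, xlev = fit$xlevels)
    X <- stats::model.matrix(stats::terms(fit), mf)
    a <- colMeans(X)[names(beta)]
    est <- sum(a * beta)
    se <- sqrt(drop(t(a) %*% V %*% a))
    data.frame(level = as.character(l), emm = est, se = se,
               ci_low = est - z * se, ci_high = est + z * se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Wald test for exposure-by-sex interaction on height-GaP
#'
#' Adds exposure-by-sex product term(s) to the (linear-arm) regression and
#' tests them jointly with a Wald chi-square.
#'
#' @param data Analysis table (must contain both sexes).
#' @param spec An [exposure_spec()].
#' @param adjusted Include the covariate set?
#' @return Two-sided interaction p-value.
#' @export
sex_interaction <- function(data, spec, adjusted = TRUE) {
  df <- earlylife_frame(data, spec, adjusted)
  if (length(unique(df$sex)) < 2)
    stop("sex interaction requires both sexes in the analysis sample")
  adj <- setdiff(adjust_terms(adjusted), "sex")
  rhs <- paste(c(sprintf("%s * sex", spec$name), adj), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("gap ~", rhs)), data = df)
  keep <- grepl(":", names(coef(fit)), fixed = TRUE)
  b <- coef(fit)[keep]
  if (anyNA(b)) stop("interaction terms not estimable")
  V <- vcov(fit)[keep, keep, drop = FALSE]
  w <- drop(t(b) %*% solve(V) %*% b)
  unname(1 - stats::pchisq(w, df = sum(keep)))
}

#' Format an interaction p-value with a reporting floor
#'
#' Interaction p-values at or above the floor are reported as
#' `"p-interaction>=<floor>"`, matching conventional table formatting.
#'
#' @param p Numeric p-value.
#' @param floor Reporting floor (default 0.200).
#' @return Character scalar.
#' @export
format_p_interaction <- function(p, floor = 0.200) {
  if (is.na(p)) return(NA_character_)
  if (p >= floor) sprintf("p-interaction>=%.3f", floor)
  else sprintf("p-interaction=%.3f", p)
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise alpha in (0, 1).
#' @param m Number of tests in the family (>= 1).
#' @return `alpha / m`, rounded to 3 decimals for reporting.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (length(m) != 1 || is.na(m) || m < 1) stop("m must be a count >= 1")
  round(alpha / m, 3)
}

#' Variance in height-GaP explained by all early-life exposures jointly
#'
#' R-squared of the joint ordinary-least-squares model of height-GaP on all
#' exposures (complete cases), with a nonparametric bootstrap percentile
#' CI.  Aliased (perfectly collinear) columns are dropped by the fit, so a
#' duplicated exposure leaves R-squared unchanged.
#'
#' @param data Analysis table with `gap` and the exposure columns.
#' @param exposures Character vector of exposure column names, or a list of
#'   [exposure_spec()]s.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf_level Confidence level.
#' @return List: `r_squared`, `ci` (length 2), `n`, `n_boot`.
#' @export
multivariable_r2 <- function(data, exposures, n_boot = 1000,
                             conf_level = 0.95) {
  if (is.list(exposures) && !is.character(exposures))
    exposures <- vapply(exposures, `[[`, character(1), "name")
  df <- data[c("gap", exposures)]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  f <- stats::as.formula(paste("gap ~", paste(exposures, collapse = " + ")))
  fit <- stats::lm(f, data = df)
  p <- fit$rank
  if (nrow(df) < 10 * p)
    stop("n = ", nrow(df), " below 10 x parameters (", 10 * p, ")")
  r2 <- summary(fit)$r.squared
  boots <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(nrow(df), replace = TRUE)
    summary(stats::lm(f, data = df[idx, , drop = FALSE]))$r.squared
  }, numeric(1))
  alpha <- 1 - conf_level
  list(r_squared = r2,
       ci = unname(stats::quantile(boots, c(alpha / 2, 1 - alpha / 2))),
       n = nrow(df), n_boot = n_boot)
}
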