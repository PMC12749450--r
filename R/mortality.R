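#' Standardize height-GaP to the per-1-SD deficit scale
#'
#' `z_i = -GaP_i / sd(GaP)`: one unit is one analysis-sample SD of
#' height-GaP in the deficit direction, so a hazard ratio above 1 means the
#' deficit is harmful.
#'
#' @param gap Numeric height-GaP vector (cm) or a `height_gap_table`.
#' @return Numeric vector of per-SD deficit exposures.
#' @export
per_sd_deficit <- function(gap) {
  if (is.data.frame(gap)) gap <- gap$gap
  s <- stats::sd(gap)
  if (!is.finite(s) || s == 0) stop("height-GaP has zero SD")
  -gap / s
}

#' Sex-specific height-GaP quartiles
#'
#' Cut points at the within-sex 25th/50th/75th percentiles
#' (linear-interpolation quantiles).  Q1 is the largest-deficit (most
#' negative height-GaP) quartile; values tied with a cut point fall in the
#' lower quartile.
#'
#' @param gap Numeric height-GaP vector (cm).
#' @param sex Per-sample sex labels.
#' @return Factor with levels `Q1..Q4`.
#' @export
sex_quartiles <- function(gap, sex) {
  stopifnot(length(gap) == length(sex))
  out <- factor(rep(NA_character_, length(gap)),
                levels = paste0("Q", 1:4))
  for (s in unique(sex)) {
    idx <- sex == s
    if (sum(idx) < 4) stop("fewer than 4 observations for sex ", s)
    cuts <- stats::quantile(gap[idx], c(0.25, 0.5, 0.75), type = 7)
    out[idx] <- cut(gap[idx], breaks = c(-Inf, cuts, Inf),
                    labels = paste0("Q", 1:4), right = TRUE)
  }
  out
}

cox_frame <- function(records, exposure, covariates, cause) {
  stopifnot(all(c("time", "event") %in% names(records)))
  event <- records$event
  if (!is.null(cause)) {
    if (!"cause_label" %in% names(records))
      stop("cause-specific outcome requires a cause_label column")
    # other-cause deaths censored at their death time
    event <- as.integer(event == 1L & records$cause_label %in% cause)
  }
  df <- data.frame(time = records$time, event = event)
  if (!is.null(exposure)) df$exposure <- exposure
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  df
}

#' Fit a proportional-hazards model of mortality on an exposure
#'
#' Cox partial likelihood with Efron tie handling.  Cause-specific
#' outcomes treat other-cause deaths as censored at the death time.  Wald
#' confidence interval and p-value are reported for the exposure term.
#'
#' @param records `data.frame` with `time` (years), `event` (0/1) and
#'   optionally `cause_label`.
#' @param exposure Numeric exposure vector (e.g. from
#'   [per_sd_deficit()]).
#' @param covariates Optional `data.frame` of adjustment covariates (e.g.
#'   age, sex, ancestry PCs for Model 1; plus genotype-predicted height for
#'   Model 2).
#' @param cause Character vector of cause labels defining a cause-specific
#'   outcome; `NULL` for all-cause.
#' @param min_events Minimum number of events (default 50).
#' @param conf_level Confidence level.
#' @return One-row `data.frame` of class `hazard_result`: `term`, `hr`,
#'   `ci_low`, `ci_high`, `p_value`, `n`, `n_events`.
#' @export
fit_cox <- function(records, exposure, covariates = NULL, cause = NULL,
                    min_events = 50, conf_level = 0.95) {
  df <- cox_frame(records, exposure, covariates, cause)
  if (sum(df$event) < min_events)
    stop("only ", sum(df$event), " events; minimum is ", min_events)
  fit <- fit_coxph(df)
  summarize_cox(fit, "exposure", nrow(df), sum(df$event), conf_level)
}

fit_coxph <- function(df) {
  rhs <- paste(setdiff(names(df), c("time", "event")), collapse = " + ")
  f <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- withCallingHandlers(
    survival::coxph(f, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("did not converge|infinite|beta may be infinite",
                conditionMessage(w)))
        stop("Cox fit failed (non-convergence or monotone likelihood): ",
             conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  fit
}

summarize_cox <- function(fit, term, n, n_events, conf_level = 0.95) {
  idx <- grep(term, names(coef(fit)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  b <- coef(fit)[idx]
  se <- sqrt(diag(vcov(fit)))[idx]
  out <- data.frame(term = names(coef(fit))[idx],
                    hr = exp(unname(b)),
                    ci_low = exp(unname(b - z * se)),
                    ci_high = exp(unname(b + z * se)),
                    p_value = 2 * stats::pnorm(-abs(unname(b / se))),
                    n = n, n_events = n_events,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("hazard_result", "data.frame")
  out
}

#' Hazard ratio contrasting extreme height-GaP quartiles
#'
#' Indicator coding with the least-deficit quartile (Q4) as the reference;
#' the headline result is the largest-deficit quartile (Q1) hazard ratio.
#'
#' @param records Survival records (see [fit_cox()]).
#' @param labels Quartile factor from [sex_quartiles()].
#' @param covariates Optional adjustment covariates.
#' @param cause Optional cause labels for a cause-specific outcome.
#' @param min_events Minimum events.
#' @return `hazard_result` rows for Q1-Q3 versus Q4; the Q1 row is the
#'   highest-to-lowest deficit contrast.
#' @export
quartile_contrast <- function(records, labels, covariates = NULL,
                              cause = NULL, min_events = 50) {
  labels <- factor(labels, levels = paste0("Q", 1:4))
  if (any(table(labels) == 0))
    stop("empty quartile: ",
         paste(names(which(table(labels) == 0)), collapse = ", "))
  q <- stats::relevel(labels, ref = "Q4")
  df <- cox_frame(records, NULL, covariates, cause)
  df$quartile <- q
  if (sum(df$event) < min_events)
    stop("only ", sum(df$event), " events; minimum is ", min_events)
  fit <- fit_coxph(df)
  summarize_cox(fit, "^quartile", nrow(df), sum(df$event))
}

#' Kaplan-Meier survival curves by height-GaP quartile
#'
#' Product-limit estimates per quartile with Greenwood-based confidence
#' intervals, as a tidy table, plus a numbers-at-risk table on a time grid.
#'
#' @param records Survival records.
#' @param labels Quartile factor from [sex_quartiles()].
#' @param times Optional time grid for the at-risk table (default: 0 to max
#'   follow-up in 5 steps).
#' @param conf_level Confidence level.
#' @return List with `curves` (`time`, `quartile`, `survival`, `ci_low`,
#'   `ci_high`, `at_risk`) and `at_risk` (grid table).
#' @export
km_by_quartile <- function(records, labels, times = NULL,
                           conf_level = 0.95) {
  df <- data.frame(time = records$time, event = records$event,
                   quartile = factor(labels))
  fit <- survival::survfit(survival::Surv(time, event) ~ quartile,
                           data = df, conf.type = "log",
                           conf.int = conf_level)
  strata_names <- sub("^quartile=", "", names(fit$strata))
  curves <- data.frame(
    time = fit$time,
    quartile = rep(strata_names, fit$strata),
    survival = fit$surv, ci_low = fit$lower, ci_high = fit$upper,
    at_risk = fit$n.risk, stringsAsFactors = FALSE)
  if (is.null(times))
    times <- seq(0, max(records$time), length.out = 5)
  sm <- summary(fit, times = times, extend = TRUE)
  at_risk <- data.frame(time = sm$time,
                        quartile = sub("^quartile=", "",
                                       as.character(sm$strata)),
                        at_risk = sm$n.risk, survival = sm$surv,
                        stringsAsFactors = FALSE)
  list(curves = curves, at_risk = at_risk)
}

#' Test heterogeneity of the mortality association by sex or race-ethnicity
#'
#' Adds stratifier main effect and exposure-by-stratifier product terms to
#' the Cox model and reports the joint Wald p-value of the product terms.
#' For race-ethnicity interactions, ancestry principal components should be
#' excluded from `covariates` (pass `drop_pcs`), since self-identified
#' race-ethnicity and genetic PCs are near-collinear.
#'
#' @param records Survival records.
#' @param exposure Numeric exposure vector.
#' @param by Factor stratifier (sex or race-ethnic label) with >= 2 levels
#'   containing events.
#' @param covariates Optional adjustment covariates.
#' @param drop_pcs If `TRUE`, covariate columns matching `"^PC[0-9]+$"` are
#'   removed before fitting.
#' @param cause Optional cause labels.
#' @return Interaction p-value.
#' @export
interaction_tests <- function(records, exposure, by, covariates = NULL,
                              drop_pcs = FALSE, cause = NULL) {
  by <- droplevels(factor(by))
  if (nlevels(by) < 2) stop("stratifier has a single level")
  if (drop_pcs && !is.null(covariates))
    covariates <- covariates[, !grepl("^PC[0-9]+$", names(covariates)),
                             drop = FALSE]
  df <- cox_frame(records, exposure, covariates, cause)
  df$by <- by
  rhs <- paste(c("exposure * by",
                 setdiff(names(df), c("time", "event", "exposure", "by"))),
               collapse = " + ")
  f <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- survival::coxph(f, data = df, ties = "efron")
  keep <- grepl("^exposure:", names(coef(fit)))
  b <- coef(fit)[keep]
  V <- vcov(fit)[keep, keep, drop = FALSE]
  w <- drop(t(b) %*% solve(V) %*% b)
  unname(1 - stats::pchisq(w, df = sum(keep)))
}
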