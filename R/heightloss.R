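#' Annualized longitudinal height change
#'
#' For each participant with at least two measurements, the annualized
#' change is the height difference between the first and last measurement
#' divided by the elapsed years; the change is attributed to the midpoint
#' age.  Rows with a zero or negative interval, and participants with fewer
#' than two measurements, are rejected with a log message.
#'
#' @param longitudinal `data.frame` with `sample_id`, `sex`, `age`,
#'   `height` (cm), >= 2 rows per included participant.
#' @param verbose Emit a message when rows are rejected.
#' @return `data.frame` with `sample_id`, `sex`, `delta` (cm/year),
#'   `age_mid`.
#' @export
annualized_change <- function(longitudinal, verbose = TRUE) {
  stopifnot(all(c("sample_id", "sex", "age", "height") %in%
                  names(longitudinal)))
  d <- longitudinal[order(longitudinal$sample_id, longitudinal$age), ]
  first <- !duplicated(d$sample_id)
  last <- !duplicated(d$sample_id, fromLast = TRUE)
  dt <- d$age[last] - d$age[first]
  ok <- dt > 0  # single-measurement and zero/negative-interval rows
  if (verbose && any(!ok))
    message("annualized_change: rejected ", sum(!ok),
            " participant(s) with <2 usable measurements")
  out <- data.frame(
    sample_id = d$sample_id[first][ok],
    sex = d$sex[first][ok],
    delta = (d$height[last][ok] - d$height[first][ok]) / dt[ok],
    age_mid = (d$age[first][ok] + d$age[last][ok]) / 2,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Estimate the per-sex onset age of later-life height loss
#'
#' Mean annualized change is computed in 1-year (configurable) age bins per
#' sex; the onset is the youngest bin whose mean falls below zero by more
#' than `z_threshold` standard errors and for which the running mean over
#' all older bins stays negative (a monotone-evidence rule, so a noisy
#' negative bin at a young age does not trigger onset).
#'
#' @param changes Output of [annualized_change()].
#' @param bin_width Age-bin width in years (default 1).
#' @param min_bins Minimum number of populated bins per sex (default 10).
#' @param z_threshold How many bin standard errors below zero a bin mean
#'   must lie to count as evidence of loss (default 2; 0 reduces to the
#'   plain sign rule).
#' @param verbose Echo the estimated onsets.
#' @return Named numeric vector of onset ages (bin lower edges) per sex.
#' @export
estimate_onset <- function(changes, bin_width = 1, min_bins = 10,
                           z_threshold = 2, verbose = TRUE) {
  out <- c()
  for (s in sort(unique(changes$sex))) {
    d <- changes[changes$sex == s, ]
    bins <- floor(d$age_mid / bin_width) * bin_width
    means <- tapply(d$delta, bins, mean)
    ses <- tapply(d$delta, bins, function(x)
      if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else Inf)
    ses[!is.finite(ses)] <- Inf
    ses[is.na(ses)] <- Inf
    ages <- as.numeric(names(means))
    if (length(means) < min_bins)
      stop("fewer than ", min_bins, " populated age bins for sex ", s,
           "; widen the bins")
    onset <- NA_real_
    for (i in seq_along(means)) {
      run <- cumsum(means[i:length(means)]) / seq_len(length(means) - i + 1)
      evident <- means[i] < 0 && is.finite(ses[i]) &&
        means[i] <= -z_threshold * ses[i]
      if (z_threshold == 0) evident <- means[i] < 0
      if (evident && all(run < 0)) { onset <- ages[i]; break }
    }
    if (is.na(onset))
      stop("no onset of height loss detectable for sex ", s,
           " (no age bin with persistently negative mean change); ",
           "consider wider bins")
    out[s] <- onset
  }
  if (verbose)
    message("estimated height-loss onset: ",
            paste(names(out), out, sep = "=", collapse = ", "))
  out
}

#' Fit per-sex percentile curves of annualized height loss
#'
#' For each percentile on the grid, a linear quantile regression of loss
#' (`-delta`, so loss is positive) on age is fitted per sex over
#' post-onset observations.  Crossing percentile curves are repaired at
#' evaluation time by monotone rearrangement across the grid, and rates
#' are clamped at zero (correction never decreases measured height).
#'
#' @param changes Output of [annualized_change()].
#' @param onset Named per-sex onset ages from [estimate_onset()].
#' @param percentiles Percentile grid (default 1:99).
#' @param min_obs Minimum post-onset observations per sex (default 200).
#' @return Object of class `heightloss_model`.
#' @export
fit_loss_percentiles <- function(changes, onset, percentiles = 1:99,
                                 min_obs = 200) {
  stopifnot(all(percentiles > 0 & percentiles < 100))
  coefs <- list()
  for (s in names(onset)) {
    d <- changes[changes$sex == s & changes$age_mid >= onset[s], ]
    if (nrow(d) < min_obs)
      stop("only ", nrow(d), " post-onset observations for sex ", s,
           "; minimum is ", min_obs)
    loss <- -d$delta
    cf <- t(vapply(percentiles / 100,
                   function(tau) fit_quantile_line(d$age_mid, loss, tau),
                   numeric(2)))
    coefs[[s]] <- cf
  }
  structure(list(onset = onset, percentiles = percentiles, coefs = coefs),
            class = "heightloss_model")
}

#' Evaluate the loss-percentile curves at an age
#'
#' @param model A `heightloss_model`.
#' @param sex Sex label (must be a name of `model$onset`).
#' @param age Single age (years).
#' @return Numeric vector of annualized loss rates (cm/year) over the
#'   percentile grid, monotone-rearranged and clamped at zero.
#' @export
loss_quantiles_at_age <- function(model, sex, age) {
  cf <- model$coefs[[sex]]
  if (is.null(cf)) stop("no loss model for sex ", sex)
  q <- cf[, 1] + cf[, 2] * age
  pmax(sort(q), 0)  # monotone rearrangement + non-negativity
}

cumulative_loss <- function(model, sex, age, p_index) {
  # rectangle rule at 1-year steps from onset to age; q evaluated at the
  # start of each year, partial final year weighted by its fraction
  onset <- unname(model$onset[[sex]])
  if (age <= onset) return(0)
  yrs <- age - onset
  full <- floor(yrs)
  frac <- yrs - full
  total <- 0
  for (k in seq_len(full))
    total <- total + loss_quantiles_at_age(model, sex, onset + k - 1)[p_index]
  if (frac > 0)
    total <- total + frac * loss_quantiles_at_age(model, sex, onset + full)[p_index]
  total
}

assert_uncorrected <- function(gap_table) {
  if (isTRUE(attr(gap_table, "heightloss_corrected")))
    stop("table already carries a height-loss correction; ",
         "applying it twice is not allowed")
}

apply_correction <- function(gap_table, increment) {
  out <- gap_table
  out$gap <- out$gap + increment
  out$measured_height <- out$measured_height + increment
  attr(out, "gap_sd") <- stats::sd(out$gap)
  attr(out, "heightloss_corrected") <- TRUE
  out
}

#' Median height-loss correction of height-GaP
#'
#' Corrects each participant's measured height (and hence height-GaP) back
#' to the onset age by adding the cumulative median annualized loss from
#' onset to the participant's age; genotype-predicted height is unchanged.
#' Participants at or below onset are untouched.
#'
#' @param gap_table A `height_gap_table`.
#' @param age Baseline ages, aligned with `gap_table` rows.
#' @param sex Sex labels, aligned with `gap_table` rows.
#' @param model A `heightloss_model`; its grid must contain the 50th
#'   percentile (or be a single-percentile median-only grid).
#' @return Corrected `height_gap_table` (flagged so a second correction is
#'   rejected).
#' @export
correct_median <- function(gap_table, age, sex, model) {
  assert_uncorrected(gap_table)
  stopifnot(nrow(gap_table) == length(age), length(age) == length(sex))
  p_index <- if (length(model$percentiles) == 1) 1L else {
    i <- which(model$percentiles == 50)
    if (length(i) == 0) stop("percentile grid does not contain the median")
    i
  }
  increment <- vapply(seq_along(age), function(i)
    cumulative_loss(model, sex[i], age[i], p_index), numeric(1))
  apply_correction(gap_table, increment)
}

#' Worst-case (percentile-matched) height-loss correction
#'
#' Assumes, percentile by percentile, that a participant with a larger
#' height-GaP deficit experienced correspondingly larger later-life height
#' loss: each participant's within-sex deficit percentile rank (larger
#' deficit = higher percentile) selects the loss-percentile curve applied
#' in the cumulative correction.  Ranks are mapped to the nearest grid
#' percentile (with a log note when the grid is coarse).
#'
#' @inheritParams correct_median
#' @param verbose Emit the nearest-percentile note for coarse grids.
#' @return Corrected `height_gap_table`.
#' @export
correct_worstcase <- function(gap_table, age, sex, model, verbose = TRUE) {
  assert_uncorrected(gap_table)
  stopifnot(nrow(gap_table) == length(age), length(age) == length(sex))
  grid <- model$percentiles
  if (length(grid) < 99 && verbose)
    message("percentile grid has ", length(grid),
            " points; assigning nearest grid percentile to deficit ranks")
  p_index <- integer(nrow(gap_table))
  for (s in unique(sex)) {
    idx <- which(sex == s)
    r <- rank(-gap_table$gap[idx], ties.method = "average")
    pct <- 100 * r / (length(idx) + 1)
    p_index[idx] <- vapply(pct, function(p) which.min(abs(grid - p)),
                           integer(1))
  }
  increment <- vapply(seq_along(age), function(i)
    cumulative_loss(model, sex[i], age[i], p_index[i]), numeric(1))
  apply_correction(gap_table, increment)
}

#' Refit the mortality model after height-loss correction
#'
#' Fits the per-1-SD-deficit Cox model on the uncorrected and the corrected
#' height-GaP (each standardized by its own analysis-sample SD) and reports
#' both together with the attenuation ratio of the log hazard ratios.
#'
#' @param gap_table Uncorrected `height_gap_table`.
#' @param corrected Corrected table from [correct_median()] or
#'   [correct_worstcase()].
#' @param records Survival records aligned with the tables.
#' @param covariates Optional adjustment covariates.
#' @param cause Optional cause labels.
#' @param min_events Minimum events.
#' @return List: `uncorrected`, `corrected` (both `hazard_result`) and
#'   `attenuation` (`log(hr_corrected) / log(hr_uncorrected)`).
#' @export
refit_after_correction <- function(gap_table, corrected, records,
                                   covariates = NULL, cause = NULL,
                                   min_events = 50) {
  fit_u <- fit_cox(records, per_sd_deficit(gap_table), covariates,
                   cause = cause, min_events = min_events)
  fit_c <- fit_cox(records, per_sd_deficit(corrected), covariates,
                   cause = cause, min_events = min_events)
  list(uncorrected = fit_u, corrected = fit_c,
       attenuation = log(fit_c$hr) / log(fit_u$hr))
}
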