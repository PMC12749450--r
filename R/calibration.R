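#' Build a stratum key from stratification columns
#'
#' @param ... Equal-length vectors (e.g. cohort, sex, race/ethnic label).
#' @return Factor with one level per observed stratum, labels joined by
#'   `":"`.
#' @export
make_strata <- function(...) {
  interaction(..., drop = TRUE, sep = ":", lex.order = TRUE)
}

#' Fit stratum-specific calibration of measured height on the polygenic score
#'
#' Ordinary least squares with intercept, fitted separately within each
#' stratum (typically cohort x sex, optionally x race/ethnic label):
#' `H_i = alpha_s + beta_s * PGS_i + e_i`.  The fitted line defines
#' genotype-predicted height; its residual defines height-GaP.
#'
#' @param heights Numeric vector of measured standing heights (cm).
#' @param pgs Numeric vector of polygenic scores (same length).
#' @param strata Factor/vector assigning each sample to a stratum (see
#'   [make_strata()]).
#' @param min_n Minimum complete pairs per stratum (default 30).
#' @return Object of class `calibration_model`: a `data.frame` with one row
#'   per stratum (`stratum`, `intercept`, `slope`, `r_squared`, `n`).
#' @export
fit_calibration <- function(heights, pgs, strata, min_n = 30) {
  stopifnot(length(heights) == length(pgs), length(heights) == length(strata))
  strata <- factor(strata)
  ok <- stats::complete.cases(heights, pgs, strata)
  heights <- heights[ok]; pgs <- pgs[ok]; strata <- droplevels(strata[ok])
  counts <- table(strata)
  if (any(counts < min_n))
    stop("stratum below min_n (", min_n, "): ",
         paste(sprintf("%s (n=%d)", names(counts)[counts < min_n],
                       as.integer(counts[counts < min_n])), collapse = ", "))
  rows <- lapply(levels(strata), function(s) {
    idx <- strata == s
    x <- pgs[idx]; y <- heights[idx]
    if (stats::var(x) == 0)
      stop("zero variance in polygenic score within stratum ", s)
    fit <- stats::lm(y ~ x)
    data.frame(stratum = s,
               intercept = unname(coef(fit)[1]),
               slope = unname(coef(fit)[2]),
               r_squared = summary(fit)$r.squared,
               n = sum(idx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("calibration_model", "data.frame")
  out
}

#' Compute genotype-predicted height and height-GaP
#'
#' Genotype-predicted height is `Hhat_i = alpha_s + beta_s * PGS_i` from the
#' participant's calibration stratum; height-GaP is
#' `GaP_i = H_i - Hhat_i` (cm).  A lower (more negative) height-GaP is a
#' larger deficit of measured relative to genotype-predicted height.
#'
#' @param heights Measured heights (cm).
#' @param pgs Polygenic scores.
#' @param strata Stratum assignment per sample; every stratum must appear in
#'   `model`.
#' @param model A `calibration_model` from [fit_calibration()].
#' @param sample_id Optional sample identifiers.
#' @return `data.frame` of class `height_gap_table` with columns
#'   `sample_id`, `stratum`, `measured_height`, `predicted_height`, `gap`;
#'   the analysis-sample SD of the gap is attached as attribute `gap_sd`.
#' @export
compute_height_gap <- function(heights, pgs, strata, model,
                               sample_id = NULL) {
  strata <- as.character(strata)
  unseen <- setdiff(unique(strata), model$stratum)
  if (length(unseen) > 0)
    stop("stratum absent from calibration model: ",
         paste(unseen, collapse = ", "))
  idx <- match(strata, model$stratum)
  predicted <- model$intercept[idx] + model$slope[idx] * pgs
  gap <- heights - predicted
  if (is.null(sample_id)) sample_id <- as.character(seq_along(heights))
  out <- data.frame(sample_id = as.character(sample_id), stratum = strata,
                    measured_height = heights, predicted_height = predicted,
                    gap = gap, stringsAsFactors = FALSE)
  attr(out, "gap_sd") <- stats::sd(gap)
  attr(out, "heightloss_corrected") <- FALSE
  class(out) <- c("height_gap_table", "data.frame")
  out
}

#' Analysis-sample SD of height-GaP
#'
#' @param gap_table A `height_gap_table`.
#' @return The SD (cm) recomputed over the rows of the table.
#' @export
gap_sd <- function(gap_table) {
  stats::sd(gap_table$gap)
}

#' Summarize a height-GaP table
#'
#' Reports mean, SD and central empirical ranges of height-GaP.  Both the
#' symmetric central 95% range (2.5th-97.5th percentiles) and the 5th-95th
#' percentile range are emitted, since "95th percentile range" admits either
#' reading.  Percentiles use the linear-interpolation convention
#' (`quantile(type = 7)`).
#'
#' @param gap_table A `height_gap_table` (or any data frame with a `gap`
#'   column).
#' @return Named list: `mean`, `sd`, `central95` (length-2), `range5_95`
#'   (length-2), `n`.
#' @export
summarize_gap <- function(gap_table) {
  g <- gap_table$gap
  if (length(g) == 0) stop("empty height-GaP table")
  list(mean = mean(g), sd = stats::sd(g),
       central95 = unname(stats::quantile(g, c(0.025, 0.975), type = 7)),
       range5_95 = unname(stats::quantile(g, c(0.05, 0.95), type = 7)),
       n = length(g))
}
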