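#' Compute cohort effect-allele frequencies
#'
#' Per-variant effect-allele frequency computed over non-missing dosages:
#' `eaf_j = sum(d_ij) / (2 * n_nonmissing_j)`.  When `cohort` is supplied the
#' frequency is computed within each cohort label, mirroring substitution of
#' missing genotypes by "the participant's respective cohort" frequency.
#'
#' @param dosages Samples x variants dosage matrix (effect-allele oriented).
#' @param cohort Optional character/factor vector of cohort labels, one per
#'   sample (row of `dosages`).
#' @return `data.frame` with columns `variant_id`, `eaf` and, when `cohort`
#'   is supplied, `cohort`.
#' @export
compute_cohort_eaf <- function(dosages, cohort = NULL) {
  validate_dosages(dosages)
  one <- function(d, label = NULL) {
    n_obs <- colSums(!is.na(d))
    if (any(n_obs == 0L))
      stop("variant(s) with all dosages missing",
           if (!is.null(label)) paste0(" in cohort ", label), ": ",
           paste(colnames(d)[n_obs == 0L], collapse = ", "))
    eaf <- colSums(d, na.rm = TRUE) / (2 * n_obs)
    data.frame(variant_id = colnames(d), eaf = unname(eaf),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  if (is.null(cohort)) return(one(dosages))
  stopifnot(length(cohort) == nrow(dosages))
  out <- lapply(unique(as.character(cohort)), function(cc) {
    res <- one(dosages[cohort == cc, , drop = FALSE], label = cc)
    res$cohort <- cc
    res
  })
  do.call(rbind, out)
}

#' Compute polygenic height scores
#'
#' Weighted sum of effect-allele dosages, `PGS_i = sum_j w_j * d_ij`, with
#' missing dosages replaced by the cohort-expected diploid dosage
#' `2 * eaf_j` (or by `eaf_j` itself under `missing_impute = "eaf"`, the
#' alternative reading of frequency substitution).
#'
#' @param dosages Samples x variants dosage matrix, already harmonized to
#'   the effect-allele orientation (see [apply_harmonization()]).
#' @param weights Weight table; every dosage-matrix variant must appear in
#'   it (run [harmonize()] first).
#' @param eaf Effect-allele frequency table from [compute_cohort_eaf()].
#' @param cohort Optional per-sample cohort labels; required when `eaf`
#'   carries a `cohort` column.
#' @param missing_impute Either `"expected_dosage"` (default, `2 * eaf`) or
#'   `"eaf"`.
#' @return `data.frame` with `sample_id`, `pgs` (cm scale) and
#'   `n_missing_imputed`.
#' @export
compute_pgs <- function(dosages, weights, eaf, cohort = NULL,
                        missing_impute = c("expected_dosage", "eaf")) {
  missing_impute <- match.arg(missing_impute)
  validate_dosages(dosages)
  vids <- colnames(dosages)
  unknown <- setdiff(vids, weights$variant_id)
  if (length(unknown) > 0)
    stop("variant(s) in dosages absent from weight table (run harmonize ",
         "first): ", paste(utils::head(unknown, 5), collapse = ", "))
  w <- weights$weight[match(vids, weights$variant_id)]
  sample_ids <- rownames(dosages)
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(dosages)))

  fill_for <- function(eaf_sub) {
    e <- eaf_sub$eaf[match(vids, eaf_sub$variant_id)]
    if (anyNA(e))
      stop("eaf table missing variant(s): ",
           paste(utils::head(vids[is.na(e)], 5), collapse = ", "))
    if (missing_impute == "expected_dosage") 2 * e else e
  }

  d <- dosages
  n_imp <- rowSums(is.na(d))
  if ("cohort" %in% names(eaf)) {
    if (is.null(cohort))
      stop("eaf table is per-cohort; supply the per-sample cohort vector")
    stopifnot(length(cohort) == nrow(d))
    for (cc in unique(as.character(cohort))) {
      fill <- fill_for(eaf[eaf$cohort == cc, , drop = FALSE])
      rows <- which(cohort == cc)
      sub <- d[rows, , drop = FALSE]
      na_idx <- which(is.na(sub), arr.ind = TRUE)
      if (nrow(na_idx) > 0) sub[na_idx] <- fill[na_idx[, 2]]
      d[rows, ] <- sub
    }
  } else {
    fill <- fill_for(eaf)
    na_idx <- which(is.na(d), arr.ind = TRUE)
    if (nrow(na_idx) > 0) d[na_idx] <- fill[na_idx[, 2]]
  }
  pgs <- as.numeric(d %*% w)
  data.frame(sample_id = sample_ids, pgs = pgs,
             n_missing_imputed = unname(n_imp), stringsAsFactors = FALSE)
}
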