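#' Read a per-variant weight table
#'
#' Reads a tab-separated table of per-allele height weights, one row per
#' biallelic SNV, in the style of polygenic-score catalogue files.  Only
#' single-nucleotide A/C/G/T alleles are accepted; indels are rejected at
#' parse time so that downstream allele logic (swap, strand flip) stays
#' exact.
#'
#' @param path Path to a tab-separated file whose header names the columns
#'   `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `weight` (cm per copy of the effect allele).
#' @param col_map Optional named character vector mapping required column
#'   names to the headers actually present in the file, e.g.
#'   `c(variant_id = "rsID", weight = "effect_weight")`.
#' @return A validated `data.frame` with the six required columns; row order
#'   is preserved.
#' @export
read_weights <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("weight file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("variant_id", "chrom", "pos", "effect_allele",
                "other_allele", "weight")
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      hit <- names(tab) == col_map[[std]]
      if (any(hit)) names(tab)[hit] <- std
    }
  }
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0)
    stop("weight file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  tab <- tab[required]
  tab$variant_id <- as.character(tab$variant_id)
  tab$chrom <- as.character(tab$chrom)
  tab$pos <- as.integer(tab$pos)
  tab$weight <- as.numeric(tab$weight)
  validate_weights(tab)
  tab
}

#' Validate a weight table
#'
#' Checks the invariants of a weight table: unique variant ids, single
#' A/C/G/T alleles with effect differing from other, finite weights and
#' positive 1-based positions.
#'
#' @param weights A weight table as returned by [read_weights()].
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_weights <- function(weights) {
  dup <- unique(weights$variant_id[duplicated(weights$variant_id)])
  if (length(dup) > 0)
    stop("duplicate variant_id in weight table: ",
         paste(dup, collapse = ", "))
  for (col in c("effect_allele", "other_allele")) {
    bad <- !(weights[[col]] %in% c("A", "C", "G", "T"))
    if (any(bad))
      stop("non-ACGT ", col,
           " (indels/multi-nucleotide alleles unsupported): ",
           paste(unique(weights[[col]][bad]), collapse = ", "))
  }
  same <- weights$effect_allele == weights$other_allele
  if (any(same))
    stop("effect_allele equals other_allele for: ",
         paste(weights$variant_id[same], collapse = ", "))
  if (any(!is.finite(weights$weight)))
    stop("non-finite weight for: ",
         paste(weights$variant_id[!is.finite(weights$weight)],
               collapse = ", "))
  if (any(is.na(weights$pos) | weights$pos < 1L))
    stop("pos must be a positive 1-based integer")
  invisible(weights)
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Harmonize weight-table alleles against genotype ref/alt alleles
#'
#' Reconciles each weight-table variant with the ref/alt orientation of the
#' genotype source.  Possible per-variant actions:
#' \describe{
#'   \item{direct}{effect allele is the genotype alt allele; dosage used
#'     as-is.}
#'   \item{allele_swap}{effect allele is the genotype ref allele; dosage is
#'     transformed as `2 - d`.}
#'   \item{strand_flip}{alleles match after complementing (possibly combined
#'     with a swap, recorded in the `swap` column).}
#'   \item{dropped_palindromic}{A/T or C/G variants are strand-ambiguous and
#'     dropped.}
#'   \item{dropped_unmatched}{variant absent from the genotype source, or
#'     alleles irreconcilable.}
#' }
#'
#' @param weights Weight table from [read_weights()].
#' @param genotype_alleles `data.frame` with columns `variant_id`, `ref`,
#'   `alt` describing the genotype source.
#' @return A list with `plan` (a `data.frame` with one row per weight-table
#'   variant: `variant_id`, `action`, `swap`, `weight`) and `report`
#'   (named integer vector of per-action counts).
#' @export
harmonize <- function(weights, genotype_alleles) {
  stopifnot(all(c("variant_id", "ref", "alt") %in% names(genotype_alleles)))
  idx <- match(weights$variant_id, genotype_alleles$variant_id)
  eff <- weights$effect_allele
  oth <- weights$other_allele
  ref <- as.character(genotype_alleles$ref)[idx]
  alt <- as.character(genotype_alleles$alt)[idx]
  action <- character(nrow(weights))
  swap <- logical(nrow(weights))
  feff <- unname(DNA_COMPLEMENT[eff])
  foth <- unname(DNA_COMPLEMENT[oth])
  palindromic <- eff == foth  # A/T or C/G pairs: strand-ambiguous
  for (i in seq_len(nrow(weights))) {
    if (palindromic[i]) {
      action[i] <- "dropped_palindromic"
    } else if (is.na(idx[i])) {
      action[i] <- "dropped_unmatched"
    } else if (eff[i] == alt[i] && oth[i] == ref[i]) {
      action[i] <- "direct"
    } else if (eff[i] == ref[i] && oth[i] == alt[i]) {
      action[i] <- "allele_swap"
      swap[i] <- TRUE
    } else if (feff[i] == alt[i] && foth[i] == ref[i]) {
      action[i] <- "strand_flip"
    } else if (feff[i] == ref[i] && foth[i] == alt[i]) {
      action[i] <- "strand_flip"
      swap[i] <- TRUE
    } else {
      action[i] <- "dropped_unmatched"
    }
  }
  plan <- data.frame(variant_id = weights$variant_id, action = action,
                     swap = swap, weight = weights$weight,
                     stringsAsFactors = FALSE)
  levels_all <- c("direct", "allele_swap", "strand_flip",
                  "dropped_palindromic", "dropped_unmatched")
  report <- table(factor(action, levels = levels_all))
  report <- setNames(as.integer(report), levels_all)
  if (sum(report[c("direct", "allele_swap", "strand_flip")]) == 0L)
    stop("no weight-table variant survived harmonization")
  list(plan = plan, report = report)
}

#' Apply a harmonization plan to a dosage matrix
#'
#' Subsets the dosage matrix to harmonized variants and flips swapped
#' dosages to the effect-allele orientation (`d' = 2 - d`).
#'
#' @param dosages Numeric matrix, samples in rows, variants in columns
#'   (column names are variant ids); values in `[0, 2]` or `NA`.
#' @param plan Harmonization plan from [harmonize()].
#' @return Dosage matrix restricted to kept variants, effect-allele
#'   oriented.
#' @export
apply_harmonization <- function(dosages, plan) {
  kept <- plan[!startsWith(plan$action, "dropped"), , drop = FALSE]
  missing_in_dosages <- setdiff(kept$variant_id, colnames(dosages))
  if (length(missing_in_dosages) > 0)
    stop("harmonized variants absent from dosage matrix: ",
         paste(utils::head(missing_in_dosages, 5), collapse = ", "))
  out <- dosages[, kept$variant_id, drop = FALSE]
  if (any(kept$swap))
    out[, kept$variant_id[kept$swap]] <- 2 - out[, kept$variant_id[kept$swap], drop = FALSE]
  out
}
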