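#' Read genotype dosages from a VCF file
#'
#' Extracts per-sample effect-allele-count dosages from a VCF.  The `DS`
#' FORMAT field (imputed dosage) is used when present; otherwise `GT` calls
#' are converted to alt-allele counts 0/1/2 with `./.` treated as missing.
#' Multi-allelic records are dropped with a warning (out of scope).
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @return A list with `dosages` (numeric matrix, samples x variants, `NA`
#'   for missing) and `alleles` (`data.frame` with `variant_id`, `chrom`,
#'   `pos`, `ref`, `alt`) suitable for [harmonize()].
#' @export
read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning("dropping ", sum(multi), " multi-allelic VCF record(s)")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  ids <- fix$ID
  no_id <- is.na(ids) | ids == "." | ids == ""
  ids[no_id] <- paste0(fix$CHROM[no_id], ":", fix$POS[no_id], ":",
                       fix$REF[no_id], ":", fix$ALT[no_id])
  fmt <- vcf@gt[, 1]
  has_ds <- all(vapply(strsplit(fmt, ":", fixed = TRUE),
                       function(x) "DS" %in% x, logical(1)))
  if (has_ds) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ds <- apply(gt, 2, gt_to_dosage)
    if (is.null(dim(ds))) ds <- matrix(ds, nrow = nrow(gt), dimnames = dimnames(gt))
  }
  dosages <- t(ds)
  colnames(dosages) <- ids
  bad <- !is.na(dosages) & (dosages < 0 | dosages > 2)
  if (any(bad)) stop("dosage outside [0, 2] in VCF: ", path)
  alleles <- data.frame(variant_id = ids, chrom = fix$CHROM,
                        pos = as.integer(fix$POS), ref = fix$REF,
                        alt = fix$ALT, stringsAsFactors = FALSE)
  list(dosages = dosages, alleles = alleles)
}

gt_to_dosage <- function(gt) {
  al <- strsplit(gt, "[/|]")
  vapply(al, function(a) {
    if (length(a) == 0 || anyNA(a) || any(a == ".")) return(NA_real_)
    sum(a != "0")
  }, numeric(1))
}

#' Read a rectangular dosage table
#'
#' Reads a tab-separated dosage table with a `variant_id` column followed by
#' one column per sample; values are effect-allele dosages in `[0, 2]`,
#' empty or `NA` for missing.
#'
#' @param path Path to the tab-separated file.
#' @return Numeric matrix, samples in rows and variants in columns.
#' @export
read_dosage_table <- function(path) {
  if (!file.exists(path)) stop("dosage table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"variant_id" %in% names(tab))
    stop("dosage table must have a 'variant_id' column")
  ids <- as.character(tab$variant_id)
  m <- as.matrix(tab[setdiff(names(tab), "variant_id")])
  storage.mode(m) <- "double"
  dosages <- t(m)
  colnames(dosages) <- ids
  validate_dosages(dosages)
  dosages
}

#' Write a dosage matrix as a rectangular table
#'
#' @param dosages Samples x variants dosage matrix.
#' @param path Output path (tab-separated, variants in rows).
#' @return `path`, invisibly.
#' @export
write_dosage_table <- function(dosages, path) {
  tab <- data.frame(variant_id = colnames(dosages), t(dosages),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a dosage matrix
#'
#' @param dosages Samples x variants numeric matrix.
#' @return The matrix, invisibly, if every non-missing value lies in
#'   `[0, 2]` and dimnames are present and unique.
#' @export
validate_dosages <- function(dosages) {
  if (is.null(colnames(dosages)) || anyDuplicated(colnames(dosages)))
    stop("dosage matrix needs unique variant ids as column names")
  bad <- !is.na(dosages) & (dosages < 0 | dosages > 2)
  if (any(bad)) {
    j <- which(bad, arr.ind = TRUE)[1, 2]
    stop("dosage outside [0, 2] at variant ", colnames(dosages)[j])
  }
  invisible(dosages)
}
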