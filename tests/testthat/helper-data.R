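# builders for small in-code fixtures shared across test files

write_weight_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- "variant_id\tchrom\tpos\teffect_allele\tother_allele\tweight"
  writeLines(c(header, rows), path)
  path
}

toy_weights <- function(ids = c("rs1", "rs2"),
                        effect = c("A", "T"), other = c("G", "C"),
                        w = c(0.5, -0.25)) {
  data.frame(variant_id = ids, chrom = "1",
             pos = seq_along(ids) * 100L,
             effect_allele = effect, other_allele = other,
             weight = w, stringsAsFactors = FALSE)
}

toy_dosages <- function(m, sample_ids = NULL, variant_ids = NULL) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  rownames(m) <- sample_ids %||% paste0("S", seq_len(nrow(m)))
  colnames(m) <- variant_ids %||% paste0("rs", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cohort with a gap table and survival records, for mortality-module tests
toy_gap_cohort <- function(n, hr_per_sd = 1.11, seed = 1, age_range = c(50, 60),
                           log_hr_age = 0, baseline_hazard = 0.01,
                           censor = 15) {
  set.seed(seed)
  cfg <- sim_config(n_samples = max(n, 2), hr_per_sd_deficit = hr_per_sd,
                    log_hr_age = log_hr_age,
                    baseline_hazard = baseline_hazard,
                    admin_censor_years = censor, age_range = age_range)
  gap <- rnorm(n, 0, 5)
  age <- runif(n, age_range[1], age_range[2])
  surv <- simulate_survival(cfg, gap, age)
  list(gap = gap, age = age, sex = sample(c("female", "male"), n, TRUE),
       surv = surv)
}
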