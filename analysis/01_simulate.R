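#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# Writes the weight table, dosage matrix, phenotype, survival and
# longitudinal tables (plus the generating truth) under results/sim/, in
# the same plain-text formats the readers in the package expect.

suppressPackageStartupMessages(library(heightgap))
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_samples = 8000, n_variants = 150, seed = 2025)
co <- simulate_cohort(cfg)

write.table(co$genotypes$weights, file.path(out, "weights.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_dosage_table(co$genotypes$dosages, file.path(out, "dosages.tsv"))
write.table(co$genotypes$alleles, file.path(out, "alleles.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.csv(co$pheno, file.path(out, "pheno.csv"), row.names = FALSE)
write.csv(co$survival, file.path(out, "survival.csv"), row.names = FALSE)
write.csv(co$longitudinal, file.path(out, "longitudinal.csv"),
          row.names = FALSE)
jsonlite::write_json(
  list(seed = cfg$seed, n_samples = cfg$n_samples,
       n_variants = cfg$n_variants, target_r2 = cfg$target_r2,
       hr_per_sd_deficit = cfg$hr_per_sd_deficit,
       heightloss_onset = as.list(cfg$heightloss_onset)),
  file.path(out, "truth.json"), auto_unbox = TRUE, pretty = TRUE)

cat(sprintf("simulated %d participants x %d variants (seed %d)\n",
            cfg$n_samples, cfg$n_variants, cfg$seed))
cat(sprintf("deaths: %d over %.0f person-years\n", sum(co$survival$event),
            sum(co$survival$time)))
cat("inputs written under", out, "\n")
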