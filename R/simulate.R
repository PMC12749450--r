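#' Default early-life exposure effects for the synthetic cohort
#'
#' Effect magnitudes (cm) are set at the scale of published early-life
#' growth-condition associations: birthweight +2.22 cm per kg (so -2.22 per
#' 1-kg decrement), deprivation -0.2 cm per quintile, maternal smoking up to
#' -1.51 cm for 20+ cigarettes/day, breastfeeding -1.03 cm for none versus
#' 6+ months, gestational age down to -4.09 cm for <32 weeks.  Category
#' effects are mean-centred at draw time so sex-specific mean heights are
#' preserved.
#'
#' @return Named list of exposure definitions (kind, marginal distribution,
#'   true effect on height/height-GaP in cm).
#' @export
default_exposure_effects <- function() {
  list(
    birthweight_kg = list(kind = "continuous", mean = 3.4, sd = 0.5,
                          slope = 2.22),
    deprivation_quintile = list(kind = "ordinal", levels = 1:5,
                                probs = rep(0.2, 5), slope = -0.2),
    maternal_smoking = list(kind = "categorical",
                            levels = c("0", "1-9", "10-19", "20+"),
                            probs = c(0.62, 0.20, 0.11, 0.07),
                            effects = c(0, -0.5, -1.0, -1.51)),
    breastfeeding_months = list(kind = "categorical",
                                levels = c("0", "<3", "3-6", "6+"),
                                probs = c(0.25, 0.25, 0.25, 0.25),
                                effects = c(-1.03, -0.6, -0.3, 0)),
    gestational_age = list(kind = "categorical",
                           levels = c("<32", "32-36", "37", "38+"),
                           probs = c(0.02, 0.08, 0.15, 0.75),
                           effects = c(-4.09, -1.5, -0.5, 0))
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the statistical structure the analysis assumes: biallelic
#' genotypes in Hardy-Weinberg proportions, a polygenic score explaining
#' ~38% of height variance within sex, sex mean heights 166/176 cm with total
#' SD ~6.5 cm, early-life exposure effects at published magnitudes, a
#' proportional-hazards mortality model with HR 1.11 per 1-SD height-GaP
#' deficit, and later-life height loss starting in the sixth decade at
#' 0-0.4 cm/year (median 0.2).
#'
#' @param n_samples,n_variants Cohort and variant-panel size.
#' @param eaf_range Range of simulated effect-allele frequencies.
#' @param target_r2 Variance of height explained by the polygenic score
#'   within sex when exposures are null; attainable iff `residual_sd > 0`
#'   (or exactly 1 with `residual_sd = 0`).
#' @param sex_means Named mean heights (cm) for `female` and `male`.
#' @param residual_sd Non-genetic, non-exposure height SD (cm).
#' @param exposure_effects See [default_exposure_effects()]; may be `NULL`
#'   for a purely genetic phenotype.
#' @param missing_rate Fraction of dosages set missing.
#' @param hr_per_sd_deficit True mortality hazard ratio per 1-SD height-GaP
#'   deficit.
#' @param log_hr_age Log-hazard per year of baseline age.
#' @param baseline_hazard,hazard_shape Weibull baseline hazard scale
#'   (events/year) and shape (1 = exponential).
#' @param admin_censor_years Administrative censoring time.
#' @param age_range Baseline age range (uniform draw).
#' @param cause_probs Probabilities of cause labels among deaths (`chd` and
#'   `stroke` jointly form atherosclerotic cardiovascular death).
#' @param heightloss_onset Named per-sex age (years) at which height loss
#'   begins.
#' @param heightloss_percentiles,heightloss_rates Percentile grid and the
#'   corresponding annualized loss rates (cm/year); a sample's rate is the
#'   inverse-CDF transform of a uniform draw.
#' @param height_meas_sd Stadiometer measurement SD (cm) for longitudinal
#'   measurements.
#' @param followup_interval Range (years) of the interval between the two
#'   longitudinal measurements.
#' @param mortality_driver `"gap"` (hazard depends on height-GaP deficit) or
#'   `"loss"` (hazard depends only on accumulated height loss; used to build
#'   designed-confounding scenarios).
#' @param hr_per_sd_loss Hazard ratio per SD of accumulated loss when
#'   `mortality_driver = "loss"`.
#' @param apply_loss_at_baseline If `TRUE`, baseline measured height already
#'   includes age-accrued height loss.
#' @param seed Integer seed recorded in every output of
#'   [simulate_cohort()].
#' @return Validated configuration list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 2000, n_variants = 200,
                       eaf_range = c(0.05, 0.95), target_r2 = 0.38,
                       sex_means = c(female = 166, male = 176),
                       residual_sd = 5.1,
                       exposure_effects = default_exposure_effects(),
                       missing_rate = 0.02,
                       hr_per_sd_deficit = 1.11, log_hr_age = 0.09,
                       baseline_hazard = 0.006, hazard_shape = 1,
                       admin_censor_years = 15, age_range = c(40, 70),
                       cause_probs = c(chd = 0.106, stroke = 0.095,
                                       other = 0.799),
                       heightloss_onset = c(female = 55, male = 58),
                       heightloss_percentiles = 1:99,
                       heightloss_rates = 0.4 * (1:99) / 100,
                       height_meas_sd = 0.3,
                       followup_interval = c(3, 7),
                       mortality_driver = c("gap", "loss"),
                       hr_per_sd_loss = 1.35,
                       apply_loss_at_baseline = FALSE,
                       seed = NULL) {
  cfg <- list(n_samples = n_samples, n_variants = n_variants,
              eaf_range = eaf_range, target_r2 = target_r2,
              sex_means = sex_means, residual_sd = residual_sd,
              exposure_effects = exposure_effects,
              missing_rate = missing_rate,
              hr_per_sd_deficit = hr_per_sd_deficit,
              log_hr_age = log_hr_age, baseline_hazard = baseline_hazard,
              hazard_shape = hazard_shape,
              admin_censor_years = admin_censor_years,
              age_range = age_range, cause_probs = cause_probs,
              heightloss_onset = heightloss_onset,
              heightloss_percentiles = heightloss_percentiles,
              heightloss_rates = heightloss_rates,
              height_meas_sd = height_meas_sd,
              followup_interval = followup_interval,
              mortality_driver = match.arg(mortality_driver),
              hr_per_sd_loss = hr_per_sd_loss,
              apply_loss_at_baseline = apply_loss_at_baseline,
              seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_samples >= 1, cfg$n_variants >= 1)
  if (!(cfg$target_r2 > 0 && cfg$target_r2 <= 1))
    stop("target_r2 must be in (0, 1]")
  if (cfg$eaf_range[1] < 0 || cfg$eaf_range[2] > 1 ||
      cfg$eaf_range[1] > cfg$eaf_range[2])
    stop("eaf_range must be an ordered subset of [0, 1]")
  if (!all(c("female", "male") %in% names(cfg$sex_means)))
    stop("sex_means must name 'female' and 'male'")
  stopifnot(cfg$residual_sd >= 0, cfg$missing_rate >= 0,
            cfg$missing_rate < 1, cfg$baseline_hazard > 0,
            cfg$hazard_shape > 0, cfg$admin_censor_years > 0,
            cfg$hr_per_sd_deficit > 0)
  if (length(cfg$heightloss_percentiles) != length(cfg$heightloss_rates))
    stop("heightloss_rates must align with heightloss_percentiles")
  if (any(cfg$heightloss_rates < 0))
    stop("heightloss_rates must be non-negative (cm/year of loss)")
  invisible(cfg)
}

#' Simulate genotypes, truth weights and variant metadata
#'
#' Effect-allele frequencies are uniform over `eaf_range`; dosages are
#' `Binomial(2, eaf_j)` (Hardy-Weinberg); truth weights are standard normal;
#' a `missing_rate` fraction of dosages is masked.  Simulated alleles are
#' non-palindromic with the effect allele as alt, so harmonization is the
#' identity on this panel.
#'
#' @param config A [sim_config()].
#' @return List with `dosages` (observed, `NA` for missing),
#'   `dosages_complete`, `weights` (weight table), `alleles` (ref/alt
#'   table) and `eaf_true`.
#' @export
simulate_genotypes <- function(config) {
  n <- config$n_samples; m <- config$n_variants
  eaf <- stats::runif(m, config$eaf_range[1], config$eaf_range[2])
  d <- matrix(stats::rbinom(n * m, 2L, rep(eaf, each = n)), nrow = n)
  vids <- sprintf("rs%06d", seq_len(m))
  rownames(d) <- sprintf("S%05d", seq_len(n))
  colnames(d) <- vids
  # non-palindromic allele pairs, effect allele stored as alt
  pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
  pick <- sample(nrow(pairs), m, replace = TRUE)
  flip <- sample(c(TRUE, FALSE), m, replace = TRUE)
  effect <- ifelse(flip, pairs[pick, 1], pairs[pick, 2])
  other <- ifelse(flip, pairs[pick, 2], pairs[pick, 1])
  weights <- data.frame(variant_id = vids,
                        chrom = as.character(rep_len(1:22, m)),
                        pos = seq_len(m) * 1000L,
                        effect_allele = effect, other_allele = other,
                        weight = stats::rnorm(m), stringsAsFactors = FALSE)
  alleles <- data.frame(variant_id = vids, ref = other, alt = effect,
                        stringsAsFactors = FALSE)
  obs <- d
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n * m) < config$missing_rate, nrow = n)
    obs[mask] <- NA_real_
  }
  storage.mode(obs) <- "double"
  storage.mode(d) <- "double"
  list(dosages = obs, dosages_complete = d, weights = weights,
       alleles = alleles, eaf_true = eaf)
}

draw_exposures <- function(effects, n) {
  if (is.null(effects) || length(effects) == 0)
    return(list(data = NULL, effect = rep(0, n)))
  cols <- list(); eff <- rep(0, n)
  for (nm in names(effects)) {
    e <- effects[[nm]]
    if (e$kind == "continuous") {
      x <- stats::rnorm(n, e$mean, e$sd)
      eff <- eff + e$slope * (x - e$mean)
      cols[[nm]] <- x
    } else if (e$kind == "ordinal") {
      x <- sample(e$levels, n, replace = TRUE, prob = e$probs)
      eff <- eff + e$slope * (x - sum(e$levels * e$probs))
      cols[[nm]] <- x
    } else {
      x <- sample(e$levels, n, replace = TRUE, prob = e$probs)
      centred <- e$effects - sum(e$effects * e$probs)
      eff <- eff + centred[match(x, e$levels)]
      cols[[nm]] <- factor(x, levels = e$levels)
    }
  }
  list(data = as.data.frame(cols, stringsAsFactors = FALSE), effect = eff)
}

#' Simulate measured adult heights and covariates
#'
#' `H_i = mu_sex + c * standardized(genetic value) + sum_k theta_k X_ik +
#' e_i` with `c` chosen analytically so that the genetic share of variance
#' equals `target_r2` when exposures are null:
#' `c = residual_sd * sqrt(r2 / (1 - r2))`.
#'
#' @param config A [sim_config()].
#' @param genotypes Output of [simulate_genotypes()].
#' @return Phenotype `data.frame`: `sample_id`, `cohort`, `sex`,
#'   `race_ethnic`, `age`, ancestry PCs `PC1..PC5` (independent noise),
#'   exposure columns, `height` (cm).  The genetic truth (standardized
#'   genetic value and `c`) is attached as attribute `truth`.
#' @export
simulate_heights <- function(config, genotypes) {
  n <- nrow(genotypes$dosages_complete)
  g_raw <- as.numeric(genotypes$dosages_complete %*% genotypes$weights$weight)
  gs <- if (stats::sd(g_raw) > 0) as.numeric(scale(g_raw)) else rep(0, n)
  if (config$residual_sd == 0) {
    if (config$target_r2 < 1)
      stop("target_r2 unattainable: residual_sd = 0 forces R^2 = 1")
    cc <- 1
  } else {
    if (config$target_r2 >= 1)
      stop("target_r2 unattainable: positive residual_sd forces R^2 < 1")
    cc <- config$residual_sd * sqrt(config$target_r2 / (1 - config$target_r2))
  }
  sex <- sample(c("female", "male"), n, replace = TRUE)
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  expo <- draw_exposures(config$exposure_effects, n)
  height <- unname(config$sex_means[sex]) + cc * gs + expo$effect +
    stats::rnorm(n, 0, config$residual_sd)
  pcs <- matrix(stats::rnorm(n * 5), nrow = n,
                dimnames = list(NULL, paste0("PC", 1:5)))
  pheno <- data.frame(sample_id = rownames(genotypes$dosages_complete),
                      cohort = "synthetic", sex = sex,
                      race_ethnic = "european", age = age,
                      pcs, stringsAsFactors = FALSE)
  if (!is.null(expo$data)) pheno <- cbind(pheno, expo$data)
  pheno$height <- height
  attr(pheno, "truth") <- list(genetic_std = gs, genetic_scale = cc,
                               exposure_effect = expo$effect)
  pheno
}

loss_rate_from_u <- function(config, u) {
  p <- config$heightloss_percentiles
  r <- config$heightloss_rates
  if (length(p) == 1) return(rep(r, length(u)))
  stats::approx(p / 100, r, xout = u, rule = 2)$y
}

true_cum_loss <- function(config, rate, age, sex) {
  onset <- unname(config$heightloss_onset[sex])
  rate * pmax(0, age - onset)
}

#' Simulate survival times under a proportional-hazards truth
#'
#' Event times are drawn by inverse transform from a Weibull baseline with
#' linear predictor `log(hr_per_sd_deficit) * (-GaP_i / sd(GaP)) +
#' log_hr_age * (age_i - mean(age))` (or, under
#' `mortality_driver = "loss"`, a standardized accumulated-loss term), with
#' administrative censoring at `admin_censor_years`.
#'
#' @param config A [sim_config()].
#' @param gap Numeric height-GaP vector (cm).
#' @param age Baseline ages.
#' @param loss_cum Accumulated height loss (cm) at baseline; required for
#'   `mortality_driver = "loss"`.
#' @return `data.frame` with `sample_id`, `time` (years), `event` (0/1) and
#'   `cause_label` (empty for censored).
#' @export
simulate_survival <- function(config, gap, age, loss_cum = NULL) {
  n <- length(gap)
  stopifnot(length(age) == n)
  if (config$mortality_driver == "loss") {
    if (is.null(loss_cum)) stop("mortality_driver 'loss' needs loss_cum")
    lp <- log(config$hr_per_sd_loss) * as.numeric(scale(loss_cum))
  } else {
    if (stats::sd(gap) == 0) stop("height-GaP has zero SD")
    lp <- log(config$hr_per_sd_deficit) * (-gap / stats::sd(gap))
  }
  lp <- lp + config$log_hr_age * (age - mean(age))
  u <- stats::runif(n)
  t_event <- (-log(u) / (config$baseline_hazard * exp(lp)))^(1 / config$hazard_shape)
  event <- as.integer(t_event <= config$admin_censor_years)
  time <- pmin(t_event, config$admin_censor_years)
  cause <- rep("", n)
  if (any(event == 1L))
    cause[event == 1L] <- sample(names(config$cause_probs), sum(event),
                                 replace = TRUE, prob = config$cause_probs)
  data.frame(sample_id = if (!is.null(names(gap))) names(gap) else
               sprintf("S%05d", seq_len(n)),
             time = time, event = event, cause_label = cause,
             stringsAsFactors = FALSE)
}

#' Simulate longitudinal height measurements with later-life loss
#'
#' Two measurements per participant: one at the baseline age and one after a
#' uniform `followup_interval` gap.  After the per-sex onset age, height
#' declines at a per-sample annualized rate drawn by inverse-CDF from the
#' configured percentile grid; before onset the change is zero.  Both
#' measurements carry independent `height_meas_sd` stadiometer noise.
#'
#' @param config A [sim_config()].
#' @param pheno Phenotype table from [simulate_heights()] (`height` is the
#'   true height at the baseline age).
#' @param rates Optional per-sample loss rates (cm/year); drawn from the
#'   configured grid when `NULL`.
#' @return `data.frame` with `sample_id`, `sex`, `age`, `height`, two rows
#'   per sample; the per-sample truth rates are attached as attribute
#'   `rates`.
#' @export
simulate_longitudinal_heights <- function(config, pheno, rates = NULL) {
  n <- nrow(pheno)
  if (is.null(rates)) rates <- loss_rate_from_u(config, stats::runif(n))
  onset <- unname(config$heightloss_onset[pheno$sex])
  gap_years <- stats::runif(n, config$followup_interval[1],
                            config$followup_interval[2])
  a1 <- pheno$age
  a2 <- pheno$age + gap_years
  lost_between <- rates * (pmax(0, a2 - onset) - pmax(0, a1 - onset))
  h1 <- pheno$height + stats::rnorm(n, 0, config$height_meas_sd)
  h2 <- pheno$height - lost_between + stats::rnorm(n, 0, config$height_meas_sd)
  out <- data.frame(sample_id = rep(pheno$sample_id, 2),
                    sex = rep(pheno$sex, 2),
                    age = c(a1, a2), height = c(h1, h2),
                    stringsAsFactors = FALSE)
  out <- out[order(out$sample_id, out$age), ]
  rownames(out) <- NULL
  attr(out, "rates") <- rates
  out
}

#' Simulate a full synthetic cohort with recorded truth
#'
#' Orchestrates genotype, phenotype, survival and longitudinal simulation
#' and runs the scoring/calibration pipeline on the simulated data so the
#' survival generator can condition on height-GaP.  Every component of the
#' generating truth is recorded for downstream recovery tests.
#'
#' @param config A [sim_config()]; `config$seed` (if non-`NULL`) seeds the
#'   RNG and is recorded in the output.
#' @return List: `config`, `genotypes`, `pheno`, `scores`, `calibration`,
#'   `gap` (a `height_gap_table`), `survival`, `longitudinal`, `truth`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  geno <- simulate_genotypes(config)
  pheno <- simulate_heights(config, geno)
  truth_h <- attr(pheno, "truth")
  rates <- loss_rate_from_u(config, stats::runif(nrow(pheno)))
  loss_cum <- true_cum_loss(config, rates, pheno$age, pheno$sex)
  if (config$apply_loss_at_baseline)
    pheno$height <- pheno$height - loss_cum
  eaf <- compute_cohort_eaf(geno$dosages, cohort = pheno$cohort)
  scores <- compute_pgs(geno$dosages, geno$weights, eaf,
                        cohort = pheno$cohort)
  strata <- make_strata(pheno$cohort, pheno$sex)
  calib <- fit_calibration(pheno$height, scores$pgs, strata)
  gap <- compute_height_gap(pheno$height, scores$pgs, strata, calib,
                            sample_id = pheno$sample_id)
  surv <- simulate_survival(config, gap$gap, pheno$age, loss_cum = loss_cum)
  surv$sample_id <- pheno$sample_id
  long <- simulate_longitudinal_heights(config, pheno, rates = rates)
  truth <- list(seed = config$seed,
                weights = geno$weights,
                genetic_std = truth_h$genetic_std,
                genetic_scale = truth_h$genetic_scale,
                exposure_effects = config$exposure_effects,
                log_hr_per_sd_deficit = log(config$hr_per_sd_deficit),
                loss_rates = rates, loss_cum_baseline = loss_cum,
                heightloss_onset = config$heightloss_onset)
  list(config = config, genotypes = geno, pheno = pheno, scores = scores,
       calibration = calib, gap = gap, survival = surv,
       longitudinal = long, truth = truth)
}
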