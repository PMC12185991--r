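# Synthetic cohort generator: compositional species tables with planted
# group effects, a smoking confounder, spirometry-derived outcomes and a
# ground-truth record for recovery testing.

#' Simulation configuration
#'
#' Defaults mirror the cohort structure the pipeline targets: ~350
#' samples with ~45% rapid lung-function decliners and ~10% airflow
#' limitation, 6 planted enriched and 2 planted depleted species at one
#' log2 unit, smoking as the built-in confounder and a logistic link
#' between the planted log10-ratio index and the outcome.
#'
#' @param n_samples cohort size (default 350).
#' @param n_taxa number of species (default 400).
#' @param n_enriched,n_depleted planted taxa counts (defaults 6 and 2).
#' @param effect_log2fc absolute planted log2 fold change in cases
#'   (default 1.0).
#' @param outcome_prevalence rapid-decline prevalence (default 0.447).
#' @param airflow_prevalence airflow-limitation prevalence (default 0.10).
#' @param smoking_or odds ratio linking current smoking to the outcome
#'   (default 1.5; former smokers get the square root of it).
#' @param beta_index log-odds of outcome per unit of the baseline
#'   (pre-shift) planted log10-ratio index (default `log(1.2)`).
#' @param depth multinomial read depth per sample (default 1e5).
#' @param missing_followup fraction of samples without follow-up
#'   spirometry (default 0.10).
#' @param base_mean_log10,base_sd_log10 mean and SD of the per-taxon
#'   baseline log10 abundance centres (heavy-tailed, log-normal across
#'   taxa: a few dominant species, a long tail of rare ones).
#' @param taxon_noise within-taxon, sample-to-sample biological noise
#'   model: `"gamma"` (default; the mixing distribution of the
#'   negative-binomial model, so planted-free taxa are NB-distributed) or
#'   `"lognormal"` (heavier-tailed, variance-matched).
#' @param dispersion_meanlog,dispersion_sdlog log-normal parameters of the
#'   per-taxon biological dispersion (NB alpha) across background taxa.
#' @param planted_dispersion biological dispersion of the planted taxa
#'   (moderately dispersed, consistently colonizing species).
#' @param n_smoking_taxa number of non-planted taxa shifted by current
#'   smoking (half up, half down).
#' @param smoking_taxon_shift log10 shift of those taxa in current
#'   smokers (former smokers get half).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 350, n_taxa = 400, n_enriched = 6,
                       n_depleted = 2, effect_log2fc = 1.0,
                       outcome_prevalence = 0.447, airflow_prevalence = 0.10,
                       smoking_or = 1.5, beta_index = log(1.2), depth = 1e5,
                       missing_followup = 0.10,
                       base_mean_log10 = -1, base_sd_log10 = 1.3,
                       taxon_noise = c("gamma", "lognormal"),
                       dispersion_meanlog = log(0.5), dispersion_sdlog = 0.8,
                       planted_dispersion = 0.6,
                       n_smoking_taxa = 20, smoking_taxon_shift = 0.3) {
  taxon_noise <- match.arg(taxon_noise)
  cfg <- as.list(environment())
  if (cfg$n_enriched + cfg$n_depleted > cfg$n_taxa)
    stop("planted taxa exceed n_taxa")
  if (cfg$outcome_prevalence <= 0 || cfg$outcome_prevalence >= 1 ||
      cfg$airflow_prevalence <= 0 || cfg$airflow_prevalence >= 1)
    stop("prevalences must be in (0, 1)")
  if (cfg$depth < 1) stop("depth must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

# Synthetic species lineages: species nested in genera, families and phyla
# so that taxonomy aggregation is exercised realistically.
.make_lineages <- function(n_taxa) {
  phyla <- c("Bacteroidetes", "Firmicutes", "Proteobacteria",
             "Actinobacteria", "Verrucomicrobia", "Euryarchaeota")
  n_fam <- max(8, round(n_taxa / 10))
  n_gen <- max(n_fam, round(n_taxa / 3))
  fam_phy <- rep_len(seq_along(phyla), n_fam)
  gen_fam <- rep_len(seq_len(n_fam), n_gen)
  sp_gen <- rep_len(seq_len(n_gen), n_taxa)
  vapply(seq_len(n_taxa), function(i) {
    g <- sp_gen[i]
    f <- gen_fam[g]
    p <- fam_phy[f]
    sprintf(paste0("k__Bacteria|p__%s|c__%s_c|o__%s_o|",
                   "f__SimFamily%03d|g__SimGenus%03d|s__SimGenus%03d_sp%03d"),
            phyla[p], phyla[p], phyla[p], f, g, g, i)
  }, character(1))
}

# Intercept making a logistic model hit a target mean probability.
.calibrate_intercept <- function(lin_pred, target) {
  uniroot(function(b0) mean(plogis(b0 + lin_pred)) - target,
          interval = c(-30, 30))$root
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Procedure: (1) per-taxon baseline abundance centres are drawn from a
#' heavy-tailed (log-normal across taxa) community profile and per-sample
#' relative intensities add gamma-distributed biological noise with
#' per-taxon dispersion (so unplanted taxa follow the negative-binomial
#' model after read sampling); planted taxa are placed among the
#' moderately abundant, consistently colonizing species; (2) smoking is
#' drawn and outcome labels are assigned from a logistic model with the
#' configured prevalence, current smoking at `smoking_or`, and
#' `beta_index` times the centred baseline planted log10-ratio (current
#' smoking also shifts a set of non-planted taxa, so smoking adjustment is
#' non-trivial); (3) planted taxa are multiplied by `2^(+/-effect_log2fc)`
#' in cases; (4) compositions are renormalized, multinomial reads drawn at
#' `depth` and converted to the percent scale; (5) spirometry fields are
#' generated consistently with the labels (rapid decliners get FEV1 slopes
#' in (40, 120] mL/yr, others in \[-20, 40\]; airflow-limitation samples
#' get FEV1/FVC < 0.70 and FEV1 %predicted < 80); (6) remaining covariates
#' are drawn from distributions matched to the target cohort's
#' demographics. Deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `abundance` (an [abundance_table()]), `metadata`
#'   (validated data.frame including outcome columns) and `truth`
#'   (class `synthetic_truth`: `enriched_taxa`, `depleted_taxa` as named
#'   log2-effect vectors, `beta_index`, `confounder_effects`, `seed`).
#' @export
generate_cohort <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_samples
  m <- config$n_taxa
  lineages <- .make_lineages(m)
  ids <- sprintf("S%04d", seq_len(n))

  # (1) community profile (heavy-tailed across taxa) + per-sample
  # biological noise with per-taxon dispersion
  centre <- rnorm(m, config$base_mean_log10, config$base_sd_log10)
  alpha_bio <- rlnorm(m, config$dispersion_meanlog, config$dispersion_sdlog)
  mid <- which(centre >= quantile(centre, 0.60) &
                 centre <= quantile(centre, 0.90))
  n_plant <- config$n_enriched + config$n_depleted
  if (length(mid) < n_plant) mid <- order(centre)[seq(m %/% 2, m %/% 2 + 4 * n_plant)]
  planted <- sample(mid, n_plant)
  enriched_idx <- planted[seq_len(config$n_enriched)]
  depleted_idx <- setdiff(planted, enriched_idx)
  alpha_bio[planted] <- config$planted_dispersion
  shape <- rep(1 / alpha_bio, each = n)
  noise <- if (config$taxon_noise == "gamma") {
    matrix(rgamma(n * m, shape = shape, rate = shape), n, m)  # mean 1, var alpha
  } else {
    s2 <- rep(log1p(alpha_bio), each = n)                     # variance-matched
    matrix(rlnorm(n * m, -s2 / 2, sqrt(s2)), n, m)
  }
  lam <- noise * rep(10^centre, each = n)      # relative intensities

  # smoking + smoking-driven shifts of non-planted taxa
  smoking <- sample(c("never", "former", "current"), n, replace = TRUE,
                    prob = c(0.35, 0.41, 0.24))
  non_planted <- setdiff(seq_len(m), planted)
  n_smk <- min(config$n_smoking_taxa, length(non_planted))
  smoking_taxa <- sample(non_planted, n_smk)
  smk_dir <- rep(c(1, -1), length.out = n_smk)
  smk_mult <- ifelse(smoking == "current", 1, ifelse(smoking == "former", 0.5, 0))
  if (n_smk > 0 && config$smoking_taxon_shift != 0)
    lam[, smoking_taxa] <- lam[, smoking_taxa] *
      10^outer(smk_mult, smk_dir * config$smoking_taxon_shift)

  # (2) outcome labels: prevalence-calibrated logistic with smoking as
  # confounder and the baseline planted index as the microbial driver
  t_base <- log10(rowSums(lam[, enriched_idx, drop = FALSE])) -
    log10(rowSums(lam[, depleted_idx, drop = FALSE]))
  b_cur <- log(config$smoking_or)
  b_for <- 0.5 * log(config$smoking_or)
  lin <- b_cur * (smoking == "current") + b_for * (smoking == "former") +
    config$beta_index * (t_base - mean(t_base))
  b0 <- .calibrate_intercept(lin, config$outcome_prevalence)
  y <- rbinom(n, 1, plogis(b0 + lin)) == 1

  # (3) planted effect in cases
  fc <- config$effect_log2fc
  if (fc != 0) {
    lam[y, enriched_idx] <- lam[y, enriched_idx] * 2^fc
    lam[y, depleted_idx] <- lam[y, depleted_idx] * 2^(-fc)
  }

  # (4) renormalize, multinomial reads, percent scale
  probs <- lam / rowSums(lam)
  counts <- t(vapply(seq_len(n), function(i)
    as.numeric(rmultinom(1, config$depth, probs[i, ])), numeric(m)))
  pct <- counts / config$depth * 100
  dimnames(pct) <- list(ids, lineages)
  abund <- abundance_table(pct, rank = "species")

  # (5) spirometry consistent with labels
  age <- rnorm(n, 53.3, 10.8)
  bmi <- rnorm(n, 24.7, 3.7)
  hiv_duration <- pmax(rnorm(n, 15.8, 9.1), 0.5)
  cart_years <- pmax(rnorm(n, 11.9, 6.6), 0.2)
  af_lin <- 0.09 * (age - mean(age)) - 0.08 * (bmi - mean(bmi)) +
    0.06 * (hiv_duration - mean(hiv_duration)) +
    0.05 * (cart_years - mean(cart_years)) +
    1.0 * (smoking == "current") +
    config$beta_index * (t_base - mean(t_base))
  af_b0 <- .calibrate_intercept(af_lin, config$airflow_prevalence)
  airflow <- rbinom(n, 1, plogis(af_b0 + af_lin)) == 1

  fvc <- rnorm(n, 4200, 700)
  ratio <- ifelse(airflow, runif(n, 0.50, 0.68), runif(n, 0.72, 0.85))
  pct_pred <- ifelse(airflow, runif(n, 50, 78), runif(n, 82, 115))
  fev1_base <- fvc * ratio
  slope <- ifelse(y, runif(n, 40, 120), runif(n, -20, 40))
  followup_years <- pmax(rnorm(n, 2.2, 0.35), 0.8)
  fev1_fu <- fev1_base - slope * followup_years
  miss <- runif(n) < config$missing_followup
  fev1_fu[miss] <- NA
  followup_years[miss] <- NA

  # (6) remaining covariates
  meta <- data.frame(
    sample_id = ids,
    fev1_baseline_ml = fev1_base,
    fev1_followup_ml = fev1_fu,
    fvc_baseline_ml = fvc,
    followup_years = followup_years,
    fev1_pct_predicted = pct_pred,
    smoking = smoking,
    age = age,
    sex = ifelse(runif(n) < 0.855, "male", "female"),
    bmi = bmi,
    ethnicity = ifelse(runif(n) < 0.885, "caucasian", "other"),
    transmission_mode = sample(c("msm", "heterosexual", "other"), n,
                               replace = TRUE, prob = c(0.6, 0.3, 0.1)),
    nadir_cd4_lt200 = runif(n) < 0.30,
    hiv_duration = hiv_duration,
    cart_years = cart_years,
    il1b_pg_ml = rlnorm(n, log(0.15), 0.7),
    il10_pg_ml = rlnorm(n, log(0.55), 0.9),
    pneumonia_history = runif(n) < 0.38,
    spiro_grade = sample(LETTERS[1:6], n, replace = TRUE,
                         prob = c(0.50, 0.25, 0.112, 0.07, 0.04, 0.028)),
    stringsAsFactors = FALSE)
  meta <- validate_metadata(meta)
  out <- derive_outcomes(meta)
  meta$fev1_decline_ml_per_year <- out$fev1_decline_ml_per_year
  meta$rapid_decline <- out$rapid_decline
  meta$airflow_limitation <- out$airflow_limitation

  truth <- structure(list(
    enriched_taxa = setNames(rep(fc, config$n_enriched), lineages[enriched_idx]),
    depleted_taxa = setNames(rep(-fc, config$n_depleted), lineages[depleted_idx]),
    beta_index = config$beta_index,
    confounder_effects = c(smoking_current = b_cur, smoking_former = b_for),
    smoking_taxa = lineages[smoking_taxa],
    seed = seed), class = "synthetic_truth")
  if (fc == 0) {
    truth$enriched_taxa <- setNames(numeric(0), character(0))
    truth$depleted_taxa <- setNames(numeric(0), character(0))
    truth$candidate_enriched <- lineages[enriched_idx]
    truth$candidate_depleted <- lineages[depleted_idx]
  }
  list(abundance = abund, metadata = meta, truth = truth)
}

#' Generate a fully null cohort
#'
#' [generate_cohort()] with every planted effect zeroed: no taxon differs
#' by outcome, smoking is unlinked from both the outcome and the taxa, and
#' the index-outcome link is off. Used for type-I-error and coverage
#' suites; the truth object carries empty planted sets.
#'
#' @inheritParams generate_cohort
#' @export
generate_null_cohort <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  config$effect_log2fc <- 0
  config$beta_index <- 0
  config$smoking_or <- 1
  config$smoking_taxon_shift <- 0
  generate_cohort(config, seed = seed)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("synthetic_truth: %d enriched, %d depleted planted taxa; ",
                     "beta_index = %.4f (seed %d)\n"),
              length(x$enriched_taxa), length(x$depleted_taxa),
              x$beta_index, x$seed))
  invisible(x)
}
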