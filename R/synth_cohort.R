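# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes: ~12% ADH1B variant carriers, a four-level ordinal
# alcohol distribution per genotype, species counts from a logistic-normal
# multinomial with genotype-specific planted log-fold changes per unit
# alcohol level, and metabolic outcomes whose insulin-resistance status
# follows a logistic model in alcohol, a latent microbiome-score tertile,
# their product, and covariates. All planted values are returned as ground
# truth for recovery testing.

#' Simulation parameters
#'
#' Builds a validated parameter list for [simulate_cohort()]. Defaults
#' describe a realistic desk-scale cohort: 12% variant carriers, alcohol
#' level probabilities matching the observed genotype-specific margins
#' (non-carriers 38/33/15/14%, carriers 42/33/14/11%), species baselines
#' drawn once from Normal(0, 2) (a steep rank-abundance curve), unit
#' log-scale dispersion, and a mean sequencing depth of 20,000 reads.
#'
#' @param n_participants Cohort size.
#' @param carrier_fraction Probability of carrying the ADH1B rs1229984 T
#'   allele (CT/TT); default 0.12.
#' @param alcohol_level_probs 2 x 4 matrix of level probabilities with rows
#'   `noncarrier`, `carrier`; each row sums to 1.
#' @param n_species Number of species (>= 3).
#' @param baseline_log_abundance Per-species baseline log abundance, or
#'   `NULL` to draw Normal(0, 2) from the seed stream.
#' @param dispersion Log-scale SD of per-species, per-sample noise.
#' @param sequencing_depth_mean Mean of the (rounded log-normal) read depth.
#' @param planted_lfc_noncarrier,planted_lfc_carrier Per-species log-fold
#'   change per unit alcohol level in each genotype stratum; default zero.
#' @param covariate_effect_sizes Effects of (standardized age, male sex,
#'   smoking, diet score) on the insulin-resistance log-odds.
#' @param ir_intercept,ir_alcohol_main,ir_gms_main,ir_alcohol_gms_interaction
#'   Log-odds-scale coefficients of the insulin-resistance model: intercept,
#'   alcohol level (0-3), latent score tertile (1-3), and their product.
#' @param homa_log_sd Residual SD of log HOMA-IR; default 0.6.
#' @param diabetic_fraction Fraction of rows given diabetes-range values to
#'   exercise the exclusion screen; default 0.05.
#' @param seed Integer seed controlling every draw.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_participants = 1592,
                       carrier_fraction = 0.12,
                       alcohol_level_probs = rbind(
                         noncarrier = c(0.38, 0.33, 0.15, 0.14),
                         carrier = c(0.42, 0.33, 0.14, 0.11)),
                       n_species = 200,
                       baseline_log_abundance = NULL,
                       dispersion = 1.0,
                       sequencing_depth_mean = 20000,
                       planted_lfc_noncarrier = numeric(n_species),
                       planted_lfc_carrier = numeric(n_species),
                       covariate_effect_sizes = c(age = 0.3, sex = 0.2,
                                                  smoking = 0.1, diet = -0.1),
                       ir_intercept = 0.3,
                       ir_alcohol_main = -0.1,
                       ir_gms_main = 0,
                       ir_alcohol_gms_interaction = 0,
                       homa_log_sd = 0.6,
                       diabetic_fraction = 0.05,
                       seed = 1L) {
  p <- list(n_participants = as.integer(n_participants),
            carrier_fraction = carrier_fraction,
            alcohol_level_probs = alcohol_level_probs,
            n_species = as.integer(n_species),
            baseline_log_abundance = baseline_log_abundance,
            dispersion = dispersion,
            sequencing_depth_mean = sequencing_depth_mean,
            planted_lfc_noncarrier = planted_lfc_noncarrier,
            planted_lfc_carrier = planted_lfc_carrier,
            covariate_effect_sizes = covariate_effect_sizes,
            ir_intercept = ir_intercept,
            ir_alcohol_main = ir_alcohol_main,
            ir_gms_main = ir_gms_main,
            ir_alcohol_gms_interaction = ir_alcohol_gms_interaction,
            homa_log_sd = homa_log_sd,
            diabetic_fraction = diabetic_fraction,
            seed = as.integer(seed))
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  num <- unlist(p[c("carrier_fraction", "dispersion", "sequencing_depth_mean",
                    "planted_lfc_noncarrier", "planted_lfc_carrier",
                    "covariate_effect_sizes", "ir_intercept", "ir_alcohol_main",
                    "ir_gms_main", "ir_alcohol_gms_interaction",
                    "homa_log_sd", "diabetic_fraction")])
  if (!all(is.finite(num))) stop("sim_params: non-finite parameter values")
  for (f in c("carrier_fraction", "diabetic_fraction")) {
    if (p[[f]] < 0 || p[[f]] > 1) stop("sim_params: ", f, " must lie in [0, 1]")
  }
  ap <- p$alcohol_level_probs
  if (!is.matrix(ap) || ncol(ap) != 4 ||
      !all(rownames(ap) %in% c("noncarrier", "carrier"))) {
    stop("sim_params: alcohol_level_probs must be a 2x4 matrix with rows noncarrier/carrier")
  }
  if (any(ap < 0) || any(abs(rowSums(ap) - 1) > 1e-9)) {
    stop("sim_params: alcohol_level_probs rows must be proportions summing to 1")
  }
  if (p$n_species < 3) stop("sim_params: n_species must be >= 3 (CLR undefined otherwise)")
  if (length(p$planted_lfc_noncarrier) != p$n_species ||
      length(p$planted_lfc_carrier) != p$n_species) {
    stop("sim_params: planted_lfc vectors must have length n_species")
  }
  if (!is.null(p$baseline_log_abundance) &&
      length(p$baseline_log_abundance) != p$n_species) {
    stop("sim_params: baseline_log_abundance must have length n_species")
  }
  if (p$dispersion <= 0 || p$sequencing_depth_mean <= 0 || p$homa_log_sd <= 0) {
    stop("sim_params: dispersion, depth and homa_log_sd must be positive")
  }
  invisible(p)
}

# Softmax closure of per-sample log abundances to compositions; adding a
# constant to one sample's column (multiplying its expected abundances)
# leaves that sample's composition unchanged.
composition_from_log_abundance <- function(eta) {
  pr <- exp(sweep(eta, 2L, apply(eta, 2L, max), `-`))
  sweep(pr, 2L, colSums(pr), `/`)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate metabolic outcomes from an insulin-resistance linear predictor
#'
#' Draws log HOMA-IR from a normal whose location is chosen so that
#' `P(HOMA-IR >= 2.5)` equals `plogis(linear_predictor)` exactly — i.e. the
#' binary insulin-resistance status follows the planted logistic model, and
#' the continuous HOMA-IR is a monotone elaboration of it. Fasting glucose
#' is drawn from Normal(95, 8) truncated to (63, 126) and insulin is
#' back-solved as `HOMA-IR * 405 / glucose`, so [homa_ir()] recovers the
#' drawn value to machine precision. A `diabetic_fraction` of rows is given
#' values violating one diabetes-exclusion criterion each (high fasting or
#' post-load glucose, HbA1c >= 6.5, or a medication/self-report flag) to
#' exercise downstream filtering; their insulin is re-solved after the
#' glucose overwrite so the round trip still holds.
#'
#' @param linear_predictor Per-row insulin-resistance log-odds.
#' @param params A [sim_params()] list (uses `homa_log_sd`,
#'   `diabetic_fraction`).
#' @return Data frame with `fasting_glucose`, `fasting_insulin`, `hba1c`,
#'   `ogtt_2h_glucose`, `fasting_time`, `on_antidiabetic_med`,
#'   `self_reported_t2d`, `true_homa_ir`.
#' @export
simulate_metabolic_outcomes <- function(linear_predictor, params) {
  if (!all(is.finite(linear_predictor))) {
    stop("simulate_metabolic_outcomes: linear predictor must be finite")
  }
  n <- length(linear_predictor)
  s <- params$homa_log_sd
  loc <- log(2.5) + s * stats::qnorm(stats::plogis(linear_predictor))
  homa <- exp(stats::rnorm(n, loc, s))
  glucose <- rtrunc_norm(n, 95, 8, 63, 126)
  hba1c <- rtrunc_norm(n, 5.5, 0.3, 4.0, 6.49)
  ogtt <- rtrunc_norm(n, 120, 25, 40, 199.5)
  fasting_time <- rtrunc_norm(n, 10, 1.5, 6, 16)
  med <- rep(FALSE, n)
  t2d <- rep(FALSE, n)
  # plant diabetes-range rows for the exclusion screen
  diab <- stats::runif(n) < params$diabetic_fraction
  if (any(diab)) {
    mode <- sample(5L, sum(diab), replace = TRUE)
    i <- which(diab)
    i1 <- i[mode == 1]; i2 <- i[mode == 2]; i3 <- i[mode == 3]
    i4 <- i[mode == 4]; i5 <- i[mode == 5]
    glucose[i1] <- stats::runif(length(i1), 126, 170)
    fasting_time[i1] <- stats::runif(length(i1), 9, 14)
    glucose[i2] <- stats::runif(length(i2), 200, 280)
    fasting_time[i2] <- stats::runif(length(i2), 3, 8)
    ogtt[i3] <- stats::runif(length(i3), 200, 320)
    hba1c[i4] <- stats::runif(length(i4), 6.5, 9.5)
    med[i5] <- TRUE
  }
  insulin <- homa * 405 / glucose
  data.frame(fasting_glucose = glucose,
             fasting_insulin = insulin,
             hba1c = hba1c,
             ogtt_2h_glucose = ogtt,
             fasting_time = fasting_time,
             on_antidiabetic_med = med,
             self_reported_t2d = t2d,
             true_homa_ir = homa)
}

#' Simulate a synthetic cohort with planted effects
#'
#' Generates participant metadata, a species-by-sample count table and
#' metabolic outcomes with known ground truth. The random stream layout is
#' fixed: (1) genotype, (2) alcohol level per genotype, (3) weekly drinks
#' consistent with the level, (4) covariates (age, sex, site, smoking,
#' diet), (5) species baselines if not supplied, (6) per-sample species
#' noise, (7) read depths and multinomial counts, (8) the latent-score
#' fallback draw, (9) metabolic outcomes. Identical parameters (including
#' the seed) therefore reproduce the outputs bit for bit.
#'
#' Species counts follow a logistic-normal multinomial: per-sample expected
#' log relative abundance is `baseline + planted_lfc(genotype) * alcohol +
#' Normal(0, dispersion)`, closed by softmax and drawn multinomially at a
#' rounded log-normal depth. The latent microbiome score used in the
#' insulin-resistance model is the planted-weight projection of each
#' sample's realized log-abundance deviations (standardized); when no
#' effects are planted it falls back to independent noise so the tertile
#' term remains defined (and is then null by construction).
#'
#' @param params A [sim_params()] object.
#' @return List with `cohort` (data frame incl. derived HOMA columns),
#'   `counts` (a [taxa_counts()] matrix), and `truth` (planted log-fold
#'   changes, interaction coefficient, per-sample log depths, latent
#'   tertiles, null/non-null species sets, true HOMA-IR).
#' @export
simulate_cohort <- function(params) {
  validate_sim_params(params)
  set.seed(params$seed)
  n <- params$n_participants
  m <- params$n_species
  sample_id <- sprintf("S%05d", seq_len(n))
  species_id <- sprintf("sp%03d", seq_len(m))

  carrier <- stats::runif(n) < params$carrier_fraction
  genotype <- rep("CC", n)
  genotype[carrier] <- ifelse(stats::runif(sum(carrier)) < 0.85, "CT", "TT")

  alc <- integer(n)
  for (g in c("noncarrier", "carrier")) {
    idx <- if (g == "carrier") which(carrier) else which(!carrier)
    if (length(idx)) {
      alc[idx] <- sample(0:3, length(idx), replace = TRUE,
                         prob = params$alcohol_level_probs[g, ])
    }
  }
  weekly <- numeric(n)
  weekly[alc == 1] <- stats::runif(sum(alc == 1), 0.1, 2 - 1e-6)
  weekly[alc == 2] <- stats::runif(sum(alc == 2), 2, 6 - 1e-6)
  weekly[alc == 3] <- 6 + stats::rexp(sum(alc == 3), rate = 1 / 3)

  age <- stats::rnorm(n, 52, 10)
  sex <- as.integer(stats::runif(n) < 0.40)     # 1 = male
  site <- sample(paste0("site", 1:4), n, replace = TRUE)
  smoking <- as.integer(stats::runif(n) < 0.16)
  diet <- stats::rnorm(n)

  baseline <- params$baseline_log_abundance
  if (is.null(baseline)) baseline <- stats::rnorm(m, 0, 2)

  noise <- matrix(stats::rnorm(m * n, 0, params$dispersion), nrow = m)
  lfcM <- outer(params$planted_lfc_noncarrier, alc)
  if (any(carrier)) {
    lfcM[, carrier] <- outer(params$planted_lfc_carrier, alc[carrier])
  }
  eta <- baseline + lfcM + noise
  pr <- composition_from_log_abundance(eta)
  depth <- pmax(1L, as.integer(round(stats::rlnorm(
    n, meanlog = log(params$sequencing_depth_mean), sdlog = 0.3))))
  counts <- matrix(0L, nrow = m, ncol = n, dimnames = list(species_id, sample_id))
  for (j in seq_len(n)) {
    counts[, j] <- stats::rmultinom(1L, depth[j], pr[, j])
  }

  # latent microbiome score: planted-weight projection of realized deviations
  dev <- eta - baseline
  latent_fallback <- stats::rnorm(n)
  w_nc <- params$planted_lfc_noncarrier
  w_c <- params$planted_lfc_carrier
  latent <- vapply(seq_len(n), function(j) {
    w <- if (carrier[j]) w_c else w_nc
    sum(w * dev[, j])
  }, numeric(1))
  if (stats::sd(latent) > 0) {
    latent <- (latent - mean(latent)) / stats::sd(latent)
  } else {
    latent <- latent_fallback
  }
  tert <- as.integer(tertile_assign(latent))

  ces <- params$covariate_effect_sizes
  lp <- params$ir_intercept +
    params$ir_alcohol_main * alc +
    params$ir_gms_main * tert +
    params$ir_alcohol_gms_interaction * alc * tert +
    ces[["age"]] * (age - 52) / 10 + ces[["sex"]] * sex +
    ces[["smoking"]] * smoking + ces[["diet"]] * diet
  met <- simulate_metabolic_outcomes(lp, params)

  cohort <- data.frame(sample_id = sample_id,
                       genotype = genotype,
                       carrier = carrier,
                       alcohol_level = alc,
                       weekly_drinks = weekly,
                       current_drinker = alc > 0,
                       age = age, sex = sex, site = site,
                       smoking = smoking, diet_score = diet,
                       stringsAsFactors = FALSE)
  cohort <- cbind(cohort, met[, setdiff(names(met), "true_homa_ir")])
  cohort <- add_metabolic_traits(cohort)

  truth <- list(planted_lfc_noncarrier = stats::setNames(w_nc, species_id),
                planted_lfc_carrier = stats::setNames(w_c, species_id),
                interaction_coef = params$ir_alcohol_gms_interaction,
                log_depth = stats::setNames(log(depth), sample_id),
                latent_score = stats::setNames(latent, sample_id),
                latent_tertile = stats::setNames(tert, sample_id),
                true_homa_ir = stats::setNames(met$true_homa_ir, sample_id),
                null_species = species_id[w_nc == 0 & w_c == 0],
                nonnull_species = species_id[w_nc != 0 | w_c != 0])
  list(cohort = cohort,
       counts = taxa_counts(counts),
       truth = truth)
}

#' Write simulation outputs to a directory
#'
#' Writes the cohort metadata as TSV, the count matrix as TSV (and BIOM when
#' `biom = TRUE` and biomformat is installed), and the ground truth as a
#' JSON sidecar.
#'
#' @param sim A [simulate_cohort()] result.
#' @param out_dir Output directory (created if needed).
#' @param biom Also write a BIOM copy of the counts; default `FALSE`.
#' @return The output directory, invisibly.
#' @export
write_simulation <- function(sim, out_dir, biom = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(sim$cohort, file.path(out_dir, "cohort.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_taxa_matrix(sim$counts, file.path(out_dir, "counts.tsv"))
  if (biom) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      warning("write_simulation: biomformat not installed; skipping BIOM output")
    } else {
      b <- biomformat::make_biom(unclass(sim$counts))
      biomformat::write_biom(b, file.path(out_dir, "counts.biom"))
    }
  }
  jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
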