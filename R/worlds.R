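# Frozen reference simulation worlds used by the package's calibration and
# recovery checks. Effect sizes were calibrated once from pilot runs and are
# not to be revisited (see the methods vignette, "Reference worlds").

#' Reference simulation worlds
#'
#' Returns frozen [sim_params()] for the package's standard verification
#' scenarios:
#' \describe{
#'   \item{`null`}{n = 800, 200 species, no planted effects anywhere; used
#'     for type-I-error calibration of the interaction test.}
#'   \item{`recovery`}{n = 1500 non-carriers, 100 species, 10 planted
#'     species at log-fold change ±0.4 (5 up, 5 down); used for
#'     differential-abundance recovery checks.}
#'   \item{`genotype_specific`}{Study-scale cohort (n = 1592, 12% carriers,
#'     250 species) with disjoint planted species sets per genotype:
#'     ±0.3 on 2 species in non-carriers, ±0.5 on 8 species in carriers;
#'     used for the genotype-specificity check of the GMS.}
#' }
#' All three use a flat baseline log abundance so every planted species
#' passes the prevalence/abundance filter, and balanced (up/down) planted
#' effects so the compositional closure term vanishes — both choices are
#' discussed in the methods vignette.
#'
#' @param type World name.
#' @param seed Seed stored in the returned parameters.
#' @return A [sim_params()] object.
#' @export
reference_world <- function(type = c("null", "recovery", "genotype_specific"),
                            seed = 1L) {
  type <- match.arg(type)
  switch(type,
    null = sim_params(n_participants = 800, n_species = 200,
                      carrier_fraction = 0,
                      baseline_log_abundance = rep(0, 200),
                      seed = seed),
    recovery = sim_params(n_participants = 1500, n_species = 100,
                          carrier_fraction = 0,
                          baseline_log_abundance = rep(0, 100),
                          planted_lfc_noncarrier = c(rep(0.4, 5), rep(-0.4, 5),
                                                     rep(0, 90)),
                          planted_lfc_carrier = rep(0, 100),
                          seed = seed),
    genotype_specific = sim_params(n_participants = 1592, n_species = 250,
                                   baseline_log_abundance = rep(0, 250),
                                   planted_lfc_noncarrier = c(0.3, -0.3,
                                                              rep(0, 248)),
                                   planted_lfc_carrier = c(rep(0, 242),
                                                           rep(0.5, 4),
                                                           rep(-0.5, 4)),
                                   seed = seed))
}

#' Simulate insulin-resistance data with planted per-tertile alcohol effects
#'
#' Association-level generator: draws ordinal alcohol level from the cohort
#' margins, a uniform modifier tertile, and insulin-resistance status whose
#' log odds are `intercept + log_or[tertile] * alcohol`, with the continuous
#' HOMA-IR drawn through [simulate_metabolic_outcomes()] so that the binary
#' status follows the planted logistic model exactly.
#'
#' @param n Sample size.
#' @param per_tertile_log_or Length-3 vector of alcohol log odds ratios in
#'   tertiles low/middle/high.
#' @param intercept Baseline log odds; default 0.2 (insulin-resistance
#'   prevalence near one half).
#' @param seed Seed.
#' @return List with `ir` (logical), `alcohol_level`, `tertile` (integer
#'   1-3), `homa_ir`.
#' @export
simulate_ir_interaction_data <- function(n, per_tertile_log_or,
                                         intercept = 0.2, seed = 1L) {
  stopifnot(length(per_tertile_log_or) == 3, n >= 30)
  set.seed(seed)
  alcohol <- sample(0:3, n, replace = TRUE, prob = c(0.38, 0.33, 0.15, 0.14))
  tert <- sample(1:3, n, replace = TRUE)
  lp <- intercept + per_tertile_log_or[tert] * alcohol
  met <- simulate_metabolic_outcomes(lp, sim_params(n_species = 3,
                                                    diabetic_fraction = 0))
  hi <- homa_ir(met$fasting_glucose, met$fasting_insulin)
  list(ir = classify_insulin_resistance(hi),
       alcohol_level = alcohol,
       tertile = tert,
       homa_ir = hi)
}
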