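# Shared fixture builders. All randomness is locally seeded so tests are
# order-independent.

# tiny deterministic count matrix (5 species x 6 samples), zero-free rows
# available for pseudocount-0 CLR tests
tiny_counts <- function() {
  m <- rbind(spA = c(100, 200, 0, 0, 0, 0),
             spB = c(300, 0, 0, 0, 0, 0),
             spC = c(10, 10, 10, 10, 10, 10),
             spD = c(120, 90, 300, 55, 70, 61),
             spE = c(900, 400, 150, 700, 420, 380))
  colnames(m) <- paste0("s", 1:6)
  taxa_counts(m)
}

default_covariates <- c("age", "sex", "site", "smoking", "diet_score")

# recovery-test world: flat baselines so every planted species passes the
# prevalence/abundance filter (see the methods vignette)
recovery_params <- function(n = 1500, m = 100, lfc = 0.4, n_planted = 10,
                            seed = 1, ...) {
  sim_params(n_participants = n, n_species = m,
             carrier_fraction = 0,
             baseline_log_abundance = rep(0, m),
             planted_lfc_noncarrier = c(rep(lfc, n_planted), rep(0, m - n_planted)),
             planted_lfc_carrier = rep(0, m),
             seed = seed, ...)
}

planted_ids <- function(n_planted = 10) sprintf("sp%03d", seq_len(n_planted))

# quick null cohort for association-level calibration tests
null_assoc_data <- function(n, seed) {
  set.seed(seed)
  list(outcome = stats::runif(n) < 0.5,
       alcohol = sample(0:3, n, replace = TRUE, prob = c(0.38, 0.33, 0.15, 0.14)),
       tert = sample(1:3, n, replace = TRUE),
       covs = data.frame(age = stats::rnorm(n, 52, 10),
                         sex = stats::rbinom(n, 1, 0.4)))
}
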