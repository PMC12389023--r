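# independent brute-force step-up oracle: q_i = min_{j: p_j >= p_i} p_j * m / rank_j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  r <- numeric(m)
  for (i in seq_len(m)) {
    cand <- sapply(i:m, function(j) p[o[j]] * m / j)
    r[o[i]] <- min(1, min(cand))
  }
  r
}

test_that("bh_fdr matches the brute-force step-up oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 7)), rep(0.2, 7))
  set.seed(5)
  cases <- c(list(c(0.5), c(1, 0), c(0.04, 0.05, 0.04)),
             lapply(1:20, function(i) round(runif(sample(2:6, 1)), 3)))
  for (p in cases) {
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12, info = paste(p, collapse = ","))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(bh_fdr(c(0.01, NA, 0.04)), c(0.02, NA, 0.04))
})

test_that("sampling-fraction offsets are location equivariant and vanish for replicated samples", {
  set.seed(31)
  n <- 40; m <- 25
  Y <- matrix(rnorm(n * m), n, m)
  X <- cbind(`(Intercept)` = 1, alcohol_level = sample(0:3, n, replace = TRUE))
  sf <- estimate_sampling_fractions(Y, X)
  expect_true(sf$converged)
  expect_equal(mean(sf$delta), 0, tolerance = 1e-10)
  # add a constant to one sample's log counts: its relative offset shifts by c
  c0 <- 1.7
  Y2 <- Y; Y2[7, ] <- Y2[7, ] + c0
  sf2 <- estimate_sampling_fractions(Y2, X)
  shift <- sf2$delta - sf$delta
  expect_equal(shift[7], c0 * (1 - 1 / n), tolerance = 1e-8)
  expect_equal(shift[-7], rep(-c0 / n, n - 1), tolerance = 1e-8)
  # lfc estimates unchanged by the per-sample shift
  f1 <- ols_matrix(Y - sf$delta, X, "alcohol_level")
  f2 <- ols_matrix(Y2 - sf2$delta, X, "alcohol_level")
  expect_equal(f1$coef, f2$coef, tolerance = 1e-8)
  # identical samples carry identical (hence zero) offsets
  Yrep <- matrix(rep(rnorm(m), each = 12), nrow = 12)
  Xrep <- cbind(1, rep(c(0, 1), 6))
  sfr <- estimate_sampling_fractions(Yrep, Xrep)
  expect_equal(sfr$delta, rep(0, 12), tolerance = 1e-8)
})

test_that("offsets recover true log depth multipliers under null effects", {
  p <- recovery_params(n = 500, m = 200, lfc = 0, seed = 41)
  sim <- simulate_cohort(p)
  Y <- t(log(unclass(sim$counts) + 0.5))
  X <- cbind(1, alcohol_level = sim$cohort$alcohol_level)
  sf <- estimate_sampling_fractions(Y, X)
  expect_gt(cor(sf$delta, sim$truth$log_depth), 0.95)
})

test_that("rank-deficient designs are rejected with the offending column named", {
  n <- 30
  X <- cbind(`(Intercept)` = 1, a = 1:n, dup = 2 * (1:n))
  expect_error(estimate_sampling_fractions(matrix(rnorm(n * 4), n), X),
               "collinear.*dup")
})

test_that("lfc estimation is depth invariant and affine equivariant", {
  p <- recovery_params(n = 300, m = 30, lfc = 0.4, n_planted = 5, seed = 51,
                       sequencing_depth_mean = 60000)
  sim <- simulate_cohort(p)
  expect_true(all(sim$counts > 0))  # zero-free so the pseudocount is negligible
  covs <- default_covariates
  r1 <- fit_species_associations(sim$counts, sim$cohort, "noncarrier",
                                 covariates = covs, pseudocount = 1e-8,
                                 min_n = 50)
  cx <- unclass(sim$counts); cx[, 4] <- cx[, 4] * 10L
  r2 <- fit_species_associations(taxa_counts(cx), sim$cohort, "noncarrier",
                                 covariates = covs, pseudocount = 1e-8,
                                 min_n = 50)
  expect_equal(r1$lfc, r2$lfc, tolerance = 1e-6)
  # recoding alcohol by an affine map scales the slope inversely
  co2 <- sim$cohort
  co2$alcohol_level <- 2 + 3 * co2$alcohol_level
  r3 <- fit_species_associations(sim$counts, co2, "noncarrier",
                                 covariates = covs, pseudocount = 1e-8,
                                 min_n = 50)
  expect_equal(r3$lfc, r1$lfc / 3, tolerance = 1e-8)
  expect_equal(r3$p_value, r1$p_value, tolerance = 1e-8)
})

test_that("planted log-fold changes are recovered and permutation recenters them", {
  p <- recovery_params(n = 800, m = 60, lfc = 0.5, n_planted = 5, seed = 61)
  sim <- simulate_cohort(p)
  res <- fit_species_associations(sim$counts, sim$cohort, "noncarrier",
                                  covariates = default_covariates)
  planted <- match(planted_ids(5), res$species_id)
  expect_true(all(res$lfc[planted] > 0.3))
  expect_true(all(res$q_value[planted] < 0.05))
  expect_lt(mean(abs(res$lfc[-planted])), 0.1)
  # permuting alcohol labels destroys the signal
  set.seed(62)
  co <- sim$cohort
  co$alcohol_level <- sample(co$alcohol_level)
  rp <- fit_species_associations(sim$counts, co, "noncarrier",
                                 covariates = default_covariates)
  expect_lt(abs(mean(rp$lfc)), 0.05)
  expect_lt(mean(rp$p_value < 0.05), 0.15)
})

test_that("stratum preconditions are enforced", {
  p <- recovery_params(n = 80, m = 10, lfc = 0, seed = 71)
  sim <- simulate_cohort(p)
  expect_error(fit_species_associations(sim$counts, sim$cohort, "carrier"),
               "carrier")
  co <- sim$cohort
  co$alcohol_level <- 1L
  expect_error(fit_species_associations(sim$counts, co, "noncarrier",
                                        min_n = 10), "constant")
})

test_that("genotype-by-alcohol interaction flags opposite planted effects", {
  m <- 40
  p <- sim_params(n_participants = 900, n_species = m, carrier_fraction = 0.2,
                  baseline_log_abundance = rep(0, m),
                  planted_lfc_noncarrier = c(-0.5, rep(0, m - 1)),
                  planted_lfc_carrier = c(0.5, rep(0, m - 1)), seed = 81)
  sim <- simulate_cohort(p)
  res <- genotype_alcohol_interaction(sim$counts, sim$cohort,
                                      covariates = default_covariates)
  expect_lt(res$p_interaction[res$species_id == "sp001"], 0.01)
  expect_gt(res$interaction_coef[res$species_id == "sp001"], 0.5)
  expect_gt(mean(res$p_interaction[-1] > 0.05), 0.8)
  # single-species interface
  one <- genotype_alcohol_interaction(sim$counts, sim$cohort, "sp002",
                                      covariates = default_covariates)
  expect_equal(one$p_interaction, res$p_interaction[2])
  # constant genotype is inestimable
  co <- sim$cohort; co$carrier <- FALSE
  expect_error(genotype_alcohol_interaction(sim$counts, co), "genotype")
})
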