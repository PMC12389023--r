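test_that("parameter validation catches malformed worlds", {
  expect_error(sim_params(carrier_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_params(n_species = 2), ">= 3")
  expect_error(sim_params(n_species = 10, planted_lfc_noncarrier = rep(0, 4)),
               "length n_species")
  expect_error(sim_params(alcohol_level_probs = rbind(
    noncarrier = c(0.5, 0.5, 0.1, 0.1), carrier = c(0.25, 0.25, 0.25, 0.25))),
    "summing to 1")
  expect_error(sim_params(ir_intercept = Inf), "non-finite")
  expect_error(sim_params(dispersion = 0), "positive")
})

test_that("identical seeds give bit-identical cohorts; different seeds differ", {
  p <- recovery_params(n = 120, m = 12, lfc = 0.3, seed = 11)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a$cohort, b$cohort)
  expect_identical(unclass(a$counts), unclass(b$counts))
  expect_identical(a$truth, b$truth)
  p2 <- recovery_params(n = 120, m = 12, lfc = 0.3, seed = 12)
  expect_false(identical(unclass(a$counts), unclass(simulate_cohort(p2)$counts)))
})

test_that("counts are non-negative integers summing to the drawn depth", {
  sim <- simulate_cohort(recovery_params(n = 150, m = 20, lfc = 0, seed = 21))
  expect_true(all(unclass(sim$counts) >= 0))
  expect_true(all(unclass(sim$counts) == round(unclass(sim$counts))))
  expect_equal(unname(colSums(sim$counts)),
               unname(round(exp(sim$truth$log_depth))))
})

test_that("alcohol level margins match the target distribution at n = 5000", {
  probs <- c(0.38, 0.33, 0.15, 0.14)
  p <- sim_params(n_participants = 5000, n_species = 3, carrier_fraction = 0,
                  alcohol_level_probs = rbind(noncarrier = probs,
                                              carrier = probs),
                  seed = 31)
  sim <- simulate_cohort(p)
  obs <- tabulate(sim$cohort$alcohol_level + 1L, nbins = 4) / 5000
  expect_true(all(abs(obs - probs) < 0.02))
  # carrier fraction itself is recovered within binomial error at default 12%
  p2 <- sim_params(n_participants = 5000, n_species = 3, seed = 32)
  frac <- mean(simulate_cohort(p2)$cohort$carrier)
  expect_lt(abs(frac - 0.12), 0.02)
})

test_that("simulated HOMA-IR is exactly recovered from glucose and insulin", {
  sim <- simulate_cohort(recovery_params(n = 200, m = 12, lfc = 0, seed = 41))
  expect_equal(sim$cohort$homa_ir,
               unname(sim$truth$true_homa_ir[sim$cohort$sample_id]),
               tolerance = 1e-12)
  # the worked inverse: HOMA-IR 2.0 at glucose 100 needs insulin 8.1
  expect_equal(2.0 * 405 / 100, 8.1)
  expect_equal(homa_ir(100, 8.1), 2.0)
})

test_that("diabetic fraction plants the expected number of excluded rows", {
  p <- sim_params(n_participants = 2000, n_species = 3,
                  diabetic_fraction = 0.1, seed = 51)
  sim <- simulate_cohort(p)
  n_exc <- sum(sim$cohort$exclude_diabetes)
  # binomial(2000, 0.1): 3.5 sigma ~ 47
  expect_true(abs(n_exc - 200) < 50)
  p0 <- sim_params(n_participants = 500, n_species = 3,
                   diabetic_fraction = 0, seed = 52)
  expect_equal(sum(simulate_cohort(p0)$cohort$exclude_diabetes), 0)
})

test_that("null and non-null species sets partition the species list", {
  p <- recovery_params(n = 100, m = 30, lfc = 0.4, n_planted = 6, seed = 61)
  sim <- simulate_cohort(p)
  expect_setequal(c(sim$truth$null_species, sim$truth$nonnull_species),
                  rownames(sim$counts))
  expect_length(intersect(sim$truth$null_species, sim$truth$nonnull_species), 0)
  expect_length(sim$truth$nonnull_species, 6)
})

test_that("composition closure is invariant to per-sample scaling", {
  set.seed(71)
  eta <- matrix(rnorm(30), 6, 5)
  pr <- composition_from_log_abundance(eta)
  expect_equal(colSums(pr), rep(1, 5), tolerance = 1e-12)
  eta2 <- eta
  eta2[, 2] <- eta2[, 2] + log(7)  # multiply one sample's abundances by 7
  expect_equal(composition_from_log_abundance(eta2), pr, tolerance = 1e-12)
})

test_that("metabolic outcome generator enforces its preconditions", {
  p <- sim_params(n_species = 3)
  expect_error(simulate_metabolic_outcomes(c(0, NaN), p), "finite")
  set.seed(81)
  met <- simulate_metabolic_outcomes(rep(0, 500), p)
  expect_true(all(met$fasting_glucose > 63))
  expect_equal(homa_ir(met$fasting_glucose, met$fasting_insulin),
               met$true_homa_ir, tolerance = 1e-12)
})

test_that("planted interaction produces GMS-tertile-dependent alcohol effects", {
  # stratified odds ratios should be homogeneous when the interaction is 0
  # and ordered when it is planted; single-cohort sanity check at n = 3000
  p0 <- recovery_params(n = 3000, m = 20, lfc = 0.5, n_planted = 10, seed = 91,
                        ir_alcohol_main = -0.3, ir_alcohol_gms_interaction = 0.25)
  sim <- simulate_cohort(p0)
  tert <- sim$truth$latent_tertile[sim$cohort$sample_id]
  fit <- stratified_interaction(sim$cohort$insulin_resistant,
                                sim$cohort$alcohol_level, tert)
  expect_lt(fit$p_interaction, 0.05)
  expect_gt(fit$interaction_coef, 0)
  ors <- fit$per_stratum$estimate
  expect_gt(ors[3], ors[1])
})

test_that("simulation writes a text artifact set", {
  sim <- simulate_cohort(recovery_params(n = 60, m = 12, lfc = 0, seed = 101))
  out <- file.path(tempdir(), "simout")
  write_simulation(sim, out)
  expect_true(all(file.exists(file.path(out, c("cohort.tsv", "counts.tsv",
                                               "truth.json")))))
  back <- read_taxa_counts(file.path(out, "counts.tsv"))
  expect_equal(unclass(back), unclass(sim$counts))
  truth <- jsonlite::read_json(file.path(out, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$interaction_coef, sim$truth$interaction_coef)
  unlink(out, recursive = TRUE)
})
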