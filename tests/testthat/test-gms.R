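test_that("inverse square root matches closed forms", {
  expect_equal(inverse_sqrt_correlation(diag(4)), diag(4), ignore_attr = TRUE)
  # 2x2 with off-diagonal 0.5: eigenvalues 1.5, 0.5
  s <- matrix(c(1, 0.5, 0.5, 1), 2)
  W <- inverse_sqrt_correlation(s)
  d <- (1 / sqrt(1.5) + 1 / sqrt(0.5)) / 2
  o <- (1 / sqrt(1.5) - 1 / sqrt(0.5)) / 2
  expect_equal(W, matrix(c(d, o, o, d), 2), ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(d, 1.1154, tolerance = 1e-3)
  expect_equal(o, -0.2989, tolerance = 1e-3)
  expect_equal(W %*% s %*% W, diag(2), ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("inverse square root validates input and floors duplicated species", {
  expect_error(inverse_sqrt_correlation(matrix(c(1, 0.2, 0.5, 1), 2)), "symmetric")
  expect_error(inverse_sqrt_correlation(matrix(c(2, 0.5, 0.5, 2), 2)), "unit diagonal")
  # correlation 1 (duplicated species): eigenvalue 0 -> floored, with warning
  dup <- matrix(c(1, 1, 1, 1), 2)
  expect_warning(W <- inverse_sqrt_correlation(dup), "floored")
  expect_equal(attr(W, "n_floored"), 1)
  expect_true(all(is.finite(W)))
})

test_that("whitening property holds on random correlation matrices", {
  set.seed(91)
  for (i in 1:25) {
    k <- sample(2:20, 1)
    A <- matrix(rnorm(k * (k + 5)), k + 5, k)
    s <- stats::cov2cor(crossprod(A))
    W <- inverse_sqrt_correlation(s)
    expect_lt(max(abs(W %*% s %*% W - diag(k))), 1e-6)
    expect_lt(max(abs(W - t(W))), 1e-10)
  }
})

make_diff_results <- function(species, lfc, p) {
  data.frame(species_id = species, stratum = "noncarrier", lfc = lfc,
             se = 0.1, p_value = p, q_value = bh_fdr(p),
             n_used = 100L, stringsAsFactors = FALSE)
}

random_clr <- function(m, n, seed = 1) {
  set.seed(seed)
  cm <- matrix(rpois(m * n, 200) + 1L, m, n,
               dimnames = list(sprintf("sp%03d", 1:m), sprintf("S%04d", 1:n)))
  clr_transform(taxa_counts(cm))
}

test_that("model building selects by p-value and passes lfc through as beta", {
  clr <- random_clr(6, 80)
  d <- make_diff_results(rownames(clr), lfc = c(0.5, -0.3, 0.2, 0.1, 0, 0),
                         p = c(0.001, 0.01, 0.04, 0.2, 0.9, 0.5))
  mod <- build_gms_model(d, clr)
  expect_equal(mod$species_ids, rownames(clr)[1:3])
  expect_equal(unname(mod$beta), c(0.5, -0.3, 0.2))
  expect_equal(diag(mod$sigma), rep(1, 3), ignore_attr = TRUE)
  expect_lt(max(abs(mod$whitening %*% mod$sigma %*% mod$whitening - diag(3))), 1e-6)
  expect_error(build_gms_model(d, clr, p_cutoff = 0.005), "need >= 2")
})

test_that("scores follow beta W X with the documented special cases", {
  clr <- random_clr(4, 50)
  # sigma = I: score is the plain weighted sum
  d <- make_diff_results(rownames(clr), c(1, -2, 0.5, 0), c(0.01, 0.02, 0.03, 0.8))
  mod <- build_gms_model(d, clr)
  mod$sigma <- diag(3); mod$whitening <- diag(3)
  sc <- compute_gms(mod, clr)
  expect_equal(unname(sc),
               as.vector(c(1, -2, 0.5) %*% unclass(clr)[1:3, ]), tolerance = 1e-12)
  # k = 2, beta = (1,1), off-diagonal 0.5, X column (1,1): 2 * (1.1154 - 0.2989)
  mod2 <- mod
  mod2$species_ids <- rownames(clr)[1:2]
  mod2$beta <- c(sp001 = 1, sp002 = 1)
  mod2$sigma <- matrix(c(1, 0.5, 0.5, 1), 2)
  mod2$whitening <- inverse_sqrt_correlation(mod2$sigma)
  fake <- matrix(c(1, 1), 2, 1, dimnames = list(rownames(clr)[1:2], "s"))
  expect_equal(unname(compute_gms(mod2, fake)), 1.633, tolerance = 1e-3)
  # k = 1 scalar case via direct algebra
  expect_equal(unname(compute_gms(list(species_ids = "sp001",
                                       beta = c(sp001 = 2),
                                       whitening = matrix(1, 1, 1)),
                                  fake[1, , drop = FALSE])), 2)
  expect_error(compute_gms(mod2, unclass(clr)[3:4, ]), "missing")
})

test_that("scores are invariant to species order and linear in beta", {
  clr <- random_clr(8, 60, seed = 3)
  d <- make_diff_results(rownames(clr), lfc = rnorm(8),
                         p = c(rep(0.01, 5), rep(0.5, 3)))
  mod <- build_gms_model(d, clr)
  sc <- compute_gms(mod, clr)
  perm <- sample(nrow(d))
  mod_p <- build_gms_model(d[perm, ], clr)
  expect_equal(compute_gms(mod_p, clr)[names(sc)], sc, tolerance = 1e-10)
  mod2 <- mod; mod2$beta <- 2 * mod$beta
  expect_equal(compute_gms(mod2, clr), 2 * sc, tolerance = 1e-12)
})

test_that("whitened scores decorrelate independent species at large n", {
  # independent species: sigma ~ I, so W ~ I and GMS ~ beta . X.
  # (a genuine CLR with few parts is never independent — closure induces
  # negative correlation — so simulate the CLR values directly)
  set.seed(7)
  clr <- matrix(rnorm(5 * 5000), 5, 5000,
                dimnames = list(sprintf("sp%03d", 1:5), sprintf("S%04d", 1:5000)))
  d <- make_diff_results(rownames(clr), lfc = c(1, 0.5, -1, 0.3, -0.2),
                         p = rep(0.01, 5))
  mod <- build_gms_model(d, clr)
  expect_lt(max(abs(mod$whitening - diag(5))), 0.1)
  sc <- compute_gms(mod, clr)
  plain <- as.vector(mod$beta %*% unclass(clr))
  expect_gt(cor(sc, plain), 0.99)
  wx <- mod$whitening %*% unclass(clr)[mod$species_ids, ]
  cc <- cor(t(wx))
  expect_lt(max(abs(cc - diag(5))), 0.1)
})

test_that("tertile assignment follows the inclusive type-7 quantile convention", {
  expect_equal(as.character(tertile_assign(1:6)),
               c("low", "low", "middle", "middle", "high", "high"))
  t7 <- table(tertile_assign(1:7))
  expect_equal(unname(as.vector(t7)), c(3, 2, 2))
  expect_error(tertile_assign(rep(1, 10)), "distinct")
  expect_error(tertile_assign(c(1, 2)), "3 non-missing")
  # ties never straddle a boundary
  x <- c(1, 1, 1, 1, 5, 9, 9)
  tt <- tertile_assign(x)
  expect_equal(length(unique(tt[x == 1])), 1)
})

test_that("validate_gms finds the planted trend and a noise score shows none", {
  p <- recovery_params(n = 700, m = 60, lfc = 0.5, n_planted = 8, seed = 101)
  sim <- simulate_cohort(p)
  clr <- clr_transform(filter_species(sim$counts))
  d <- fit_species_associations(filter_species(sim$counts), sim$cohort,
                                "noncarrier", covariates = default_covariates)
  mod <- build_gms_model(d, clr)
  sc <- compute_gms(mod, clr)
  v <- validate_gms(sc, sim$cohort, "noncarrier", default_covariates)
  expect_lt(v$p_value, 1e-6)
  expect_gt(v$coefficient, 0)
  set.seed(102)
  noise <- stats::setNames(rnorm(length(sc)), names(sc))
  vn <- validate_gms(noise, sim$cohort, "noncarrier", default_covariates)
  expect_gt(vn$p_value, 0.001)
})

test_that("GMS models round-trip through JSON", {
  clr <- random_clr(12, 40, seed = 9)
  set.seed(9)
  d <- make_diff_results(rownames(clr), rnorm(12),
                         c(rep(0.01, 5), rep(0.6, 7)))
  mod <- build_gms_model(d, clr)
  path <- tempfile(fileext = ".json")
  write_gms_model(mod, path)
  back <- read_gms_model(path)
  expect_equal(back$beta, mod$beta, tolerance = 1e-12)
  expect_equal(back$whitening, mod$whitening, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(compute_gms(back, clr), compute_gms(mod, clr), tolerance = 1e-10)
})
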