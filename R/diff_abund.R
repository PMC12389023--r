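# Differential abundance of species against ordinal alcohol level within a
# genotype stratum, with a simplified compositional bias correction in the
# spirit of sampling-fraction methods: per-sample offsets are estimated
# iteratively as the mean residual over species and removed before the
# per-species regressions. No mixture model over null/non-null taxa and no
# structural-zero handling are attempted.

# Build a numeric design matrix (intercept + exposure + covariates) from a
# cohort data frame. Categorical covariates are indicator-coded with the
# first level as reference. Errors name rank-deficient columns.
build_design <- function(cohort, exposure = "alcohol_level", covariates = character()) {
  cols <- c(exposure, covariates)
  miss <- setdiff(cols, names(cohort))
  if (length(miss)) stop("design: missing columns: ", paste(miss, collapse = ", "))
  fm <- stats::reformulate(cols)
  mf <- stats::model.frame(fm, cohort, na.action = stats::na.pass)
  X <- stats::model.matrix(fm, mf)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design: rank-deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  X
}

#' Estimate per-sample sampling-fraction offsets
#'
#' Iteratively estimates a per-sample offset `delta_j` capturing differences
#' in sequencing depth / sampling fraction: (1) regress the offset-corrected
#' log counts of every species on the design; (2) set `delta_j` to the mean
#' residual of sample j over species; (3) recenter the offsets to mean zero
#' (they are identifiable only up to a constant). Iteration stops when the
#' largest offset change falls below `tol` or after `max_iter` passes.
#'
#' @param log_counts Samples x species matrix of log counts (pseudocount
#'   already applied), finite.
#' @param design Numeric design matrix, one row per sample, full rank.
#' The offsets are identifiable only up to directions lying in the design's
#' column space (a depth shift aligned with a covariate cannot be told apart
#' from a covariate effect shared by all species). The iteration is started
#' at the centered per-sample mean log count — itself a fixed point — which
#' pins down that free direction so that per-sample location shifts move
#' `delta` one-for-one and leave every species' fold-change estimate
#' untouched. The price is that the mean true effect across species leaks
#' into `delta` (the bias a full mixture-model estimator would remove); see
#' the package vignette.
#'
#' @param log_counts Samples x species matrix of log counts (pseudocount
#'   already applied), finite.
#' @param design Numeric design matrix, one row per sample, full rank.
#' @param tol Convergence tolerance on `max |delta change|`; default 1e-6.
#' @param max_iter Maximum iterations; default 100.
#' @return List with `delta` (length n, mean zero), `iterations`, `converged`.
#' @export
estimate_sampling_fractions <- function(log_counts, design, tol = 1e-6,
                                        max_iter = 100) {
  Y <- as.matrix(log_counts)
  if (!all(is.finite(Y))) stop("estimate_sampling_fractions: log counts must be finite")
  if (nrow(Y) != nrow(design)) stop("estimate_sampling_fractions: dimension mismatch")
  qr_x <- qr(design)
  if (qr_x$rank < ncol(design)) {
    bad <- colnames(design)[qr_x$pivot[(qr_x$rank + 1):ncol(design)]]
    stop("estimate_sampling_fractions: rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  delta <- rowMeans(Y) - mean(Y)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    beta <- qr.coef(qr_x, Y - delta)
    resid <- Y - design %*% beta
    new_delta <- delta + rowMeans(resid - delta)
    new_delta <- new_delta - mean(new_delta)
    if (max(abs(new_delta - delta)) < tol) {
      delta <- new_delta
      converged <- TRUE
      break
    }
    delta <- new_delta
  }
  list(delta = as.vector(delta), iterations = it, converged = converged)
}

#' Per-species alcohol association within a genotype stratum
#'
#' For each species, regresses offset-corrected log counts on continuous
#' ordinal alcohol level (0-3) plus covariates, within the requested genotype
#' stratum. The alcohol coefficient is the per-species log-fold change per
#' unit alcohol level; p-values come from the coefficient t-test and q-values
#' from Benjamini-Hochberg over the stratum's species.
#'
#' @param counts Species x sample count matrix.
#' @param cohort Cohort data frame; needs `sample_id`, `alcohol_level`,
#'   `carrier` (logical) and the covariate columns. Rows with missing model
#'   variables are dropped (complete-case).
#' @param stratum One of `"carrier"`, `"noncarrier"`, `"pooled"`.
#' @param covariates Character vector of covariate column names.
#' @param pseudocount Added to counts before the log; default 0.5.
#' @param min_n Minimum stratum size; default `max(50, 5 * length(covariates))`.
#' @return Data frame with `species_id`, `stratum`, `lfc`, `se`, `p_value`,
#'   `q_value`, `n_used`.
#' @export
fit_species_associations <- function(counts, cohort, stratum = c("noncarrier", "carrier", "pooled"),
                                     covariates = character(),
                                     pseudocount = 0.5,
                                     min_n = max(50, 5 * length(covariates))) {
  stratum <- match.arg(stratum)
  sub <- stratum_subset(cohort, stratum)
  sub <- sub[stats::complete.cases(sub[, c("alcohol_level", covariates), drop = FALSE]), , drop = FALSE]
  if (nrow(sub) < min_n) {
    stop(sprintf("fit_species_associations: stratum '%s' has %d samples, need >= %d",
                 stratum, nrow(sub), min_n))
  }
  if (length(unique(sub$alcohol_level)) < 2) {
    stop("fit_species_associations: alcohol level is constant in the stratum")
  }
  idx <- match(sub$sample_id, colnames(counts))
  if (anyNA(idx)) stop("fit_species_associations: cohort samples missing from count matrix")
  Y <- t(log(unclass(counts)[, idx, drop = FALSE] + pseudocount))
  X <- build_design(sub, "alcohol_level", covariates)
  sf <- estimate_sampling_fractions(Y, X)
  fit <- ols_matrix(Y - sf$delta, X, term = "alcohol_level")
  data.frame(species_id = rownames(counts),
             stratum = stratum,
             lfc = fit$coef,
             se = fit$se,
             p_value = fit$p,
             q_value = bh_fdr(fit$p),
             n_used = nrow(sub),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

# OLS of a response matrix on a shared design; returns coefficient, SE and
# two-sided t-test p for one named term, vectorized over columns of Y.
ols_matrix <- function(Y, X, term) {
  qr_x <- qr(X)
  beta <- qr.coef(qr_x, Y)
  res <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  xtxinv <- chol2inv(chol(crossprod(X)))
  j <- match(term, colnames(X))
  if (is.na(j)) stop("ols_matrix: term not in design: ", term)
  se <- sqrt(sigma2 * xtxinv[j, j])
  tval <- beta[j, ] / se
  p <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  list(coef = as.vector(beta[j, ]), se = as.vector(se), p = as.vector(p), df = df)
}

stratum_subset <- function(cohort, stratum) {
  if (!"carrier" %in% names(cohort)) stop("cohort needs a logical 'carrier' column")
  switch(stratum,
         carrier = cohort[which(cohort$carrier), , drop = FALSE],
         noncarrier = cohort[which(!cohort$carrier), , drop = FALSE],
         pooled = cohort)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: order the m p-values, multiply
#' the i-th smallest by m/i, enforce monotonicity from the largest down, and
#' clip at 1.
#'
#' @param p_values Numeric vector in `[0, 1]`; `NA`s are carried through and
#'   excluded from m.
#' @return Adjusted q-values in the original order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  p <- p_values[ok]
  if (any(p < 0 | p > 1)) stop("bh_fdr: p-values must lie in [0, 1]")
  m <- length(p)
  q <- rep(NA_real_, length(p_values))
  if (m > 0) {
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    adj <- pmin(adj, 1)
    qq <- numeric(m)
    qq[o] <- adj
    q[ok] <- qq
  }
  q
}

#' Genotype-by-alcohol interaction test for one species
#'
#' Pooled model over both genotype groups for a single species: offset-
#' corrected log count regressed on alcohol level, carrier status, their
#' product, and covariates. Returns the two-sided p-value of the product
#' term (plus the coefficient).
#'
#' @inheritParams fit_species_associations
#' @param species_id Species to test (a rowname of `counts`), or `NULL` to
#'   test every species at once.
#' @return Data frame with `species_id`, `interaction_coef`, `p_interaction`.
#' @export
genotype_alcohol_interaction <- function(counts, cohort, species_id = NULL,
                                         covariates = character(),
                                         pseudocount = 0.5) {
  sub <- cohort[stats::complete.cases(cohort[, c("alcohol_level", "carrier", covariates), drop = FALSE]), , drop = FALSE]
  if (length(unique(sub$carrier)) < 2) {
    stop("genotype_alcohol_interaction: both genotype groups must be present")
  }
  for (grp in c(TRUE, FALSE)) {
    if (length(unique(sub$alcohol_level[sub$carrier == grp])) < 2) {
      stop("genotype_alcohol_interaction: alcohol level constant within a genotype stratum")
    }
  }
  idx <- match(sub$sample_id, colnames(counts))
  if (anyNA(idx)) stop("genotype_alcohol_interaction: cohort samples missing from count matrix")
  keep <- if (is.null(species_id)) rownames(counts) else species_id
  missing_sp <- setdiff(keep, rownames(counts))
  if (length(missing_sp)) stop("genotype_alcohol_interaction: unknown species: ",
                               paste(missing_sp, collapse = ", "))
  Y <- t(log(unclass(counts)[, idx, drop = FALSE] + pseudocount))
  sub$carrier_num <- as.numeric(sub$carrier)
  sub$alc_x_carrier <- sub$alcohol_level * sub$carrier_num
  X <- build_design(sub, "alcohol_level",
                    c("carrier_num", "alc_x_carrier", covariates))
  sf <- estimate_sampling_fractions(Y, X)
  fit <- ols_matrix(Y - sf$delta, X, term = "alc_x_carrier")
  out <- data.frame(species_id = rownames(counts),
                    interaction_coef = fit$coef,
                    p_interaction = fit$p,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[match(keep, out$species_id), , drop = FALSE]
}
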