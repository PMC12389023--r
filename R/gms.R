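# Weighted gut microbiome score: GMS = beta %*% Sigma^(-1/2) %*% X, where
# beta holds the per-species log-fold changes of alcohol consumption, Sigma
# is the correlation matrix of the selected species' CLR abundances, and X is
# the CLR matrix. The whitening factor is the unique symmetric PSD inverse
# square root, computed by eigendecomposition with an eigenvalue floor.

#' Symmetric inverse square root of a correlation matrix
#'
#' Eigendecomposes a symmetric unit-diagonal matrix and returns
#' `V diag(1/sqrt(lambda)) V'`. Eigenvalues below `eig_floor` are floored
#' (with a warning) so near-duplicate species do not blow up the weights; in
#' that regime `W %*% sigma %*% W` is no longer the identity on the floored
#' subspace.
#'
#' @param sigma Correlation matrix: symmetric, unit diagonal.
#' @param eig_floor Lower bound applied to eigenvalues before inversion;
#'   default 1e-6.
#' @return Symmetric whitening matrix of the same dimension, with attribute
#'   `n_floored` giving the number of floored eigenvalues.
#' @export
inverse_sqrt_correlation <- function(sigma, eig_floor = 1e-6) {
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != ncol(sigma) || max(abs(sigma - t(sigma))) > 1e-8) {
    stop("inverse_sqrt_correlation: sigma must be symmetric")
  }
  if (max(abs(diag(sigma) - 1)) > 1e-8) {
    stop("inverse_sqrt_correlation: sigma must have unit diagonal")
  }
  e <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  n_floored <- sum(e$values < eig_floor)
  if (n_floored > 0) {
    warning(sprintf("inverse_sqrt_correlation: %d eigenvalue(s) below %g floored; whitening is regularized",
                    n_floored, eig_floor))
  }
  lam <- pmax(e$values, eig_floor)
  W <- e$vectors %*% (t(e$vectors) / sqrt(lam))
  W <- (W + t(W)) / 2
  dimnames(W) <- dimnames(sigma)
  attr(W, "n_floored") <- n_floored
  W
}

#' Build a gut microbiome score model for one genotype stratum
#'
#' Selects the species associated with alcohol level at `p < p_cutoff` in the
#' supplied differential-abundance results, takes their log-fold changes as
#' the weight vector beta, computes the Pearson (or Spearman) correlation of
#' their CLR abundances across the given samples, and forms the whitening
#' matrix.
#'
#' @param diff_results Data frame from [fit_species_associations()].
#' @param clr CLR matrix (species x samples) restricted to the stratum's
#'   samples (or pass `sample_ids`).
#' @param p_cutoff Unadjusted selection p-value cutoff; default 0.05.
#' @param sample_ids Optional subset of columns of `clr` to use for Sigma.
#' @param method Correlation method, `"pearson"` (default) or `"spearman"`.
#' @param eig_floor Passed to [inverse_sqrt_correlation()].
#' @return A `gms_model` list: `stratum`, `species_ids`, `beta`, `sigma`,
#'   `whitening`, `eig_floor`, `p_cutoff`, `method`.
#' @export
build_gms_model <- function(diff_results, clr, p_cutoff = 0.05,
                            sample_ids = colnames(clr),
                            method = c("pearson", "spearman"),
                            eig_floor = 1e-6) {
  method <- match.arg(method)
  sel <- diff_results[!is.na(diff_results$p_value) &
                        diff_results$p_value < p_cutoff, , drop = FALSE]
  if (nrow(sel) < 2) {
    stop(sprintf("build_gms_model: only %d species pass p < %g; need >= 2",
                 nrow(sel), p_cutoff))
  }
  missing_sp <- setdiff(sel$species_id, rownames(clr))
  if (length(missing_sp)) {
    stop("build_gms_model: selected species absent from CLR matrix: ",
         paste(missing_sp, collapse = ", "))
  }
  Xs <- unclass(clr)[sel$species_id, sample_ids, drop = FALSE]
  sds <- apply(Xs, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("build_gms_model: constant CLR row(s): ",
         paste(sel$species_id[sds == 0], collapse = ", "))
  }
  sigma <- stats::cor(t(Xs), method = method)
  W <- inverse_sqrt_correlation(sigma, eig_floor = eig_floor)
  structure(list(stratum = unique(sel$stratum)[1],
                 species_ids = sel$species_id,
                 beta = stats::setNames(sel$lfc, sel$species_id),
                 sigma = sigma,
                 whitening = W,
                 eig_floor = eig_floor,
                 p_cutoff = p_cutoff,
                 method = method),
            class = "gms_model")
}

#' Compute per-sample gut microbiome scores
#'
#' Applies `beta %*% W %*% X` over the model's species. The model may be
#' applied to samples from a different genotype stratum than it was built on
#' (the cross-genotype validation analysis does exactly that).
#'
#' @param model A [build_gms_model()] result.
#' @param clr CLR matrix containing all model species as rows.
#' @return Named numeric vector of scores, one per CLR column.
#' @export
compute_gms <- function(model, clr) {
  missing_sp <- setdiff(model$species_ids, rownames(clr))
  if (length(missing_sp)) {
    stop("compute_gms: species missing from CLR matrix: ",
         paste(missing_sp, collapse = ", "))
  }
  X <- unclass(clr)[model$species_ids, , drop = FALSE]
  scores <- as.vector(rbind(model$beta) %*% model$whitening %*% X)
  if (!all(is.finite(scores))) stop("compute_gms: non-finite scores")
  stats::setNames(scores, colnames(clr))
}

#' Assign tertiles of a score
#'
#' Cuts a numeric vector at its empirical 1/3 and 2/3 quantiles (inclusive
#' linear-interpolation quantiles, R type 7) into ordered levels low /
#' middle / high, with intervals `(-Inf, q1]`, `(q1, q2]`, `(q2, Inf)`.
#' Ties share the interval of their common value, so tied samples never
#' straddle a boundary.
#'
#' @param scores Numeric vector, `n >= 3`, at least 3 distinct values.
#' @return Ordered factor with levels `low < middle < high`.
#' @export
tertile_assign <- function(scores) {
  ok <- !is.na(scores)
  if (sum(ok) < 3) stop("tertile_assign: need at least 3 non-missing scores")
  if (length(unique(scores[ok])) < 3) {
    stop("tertile_assign: need at least 3 distinct score values")
  }
  qs <- stats::quantile(scores[ok], probs = c(1, 2) / 3, type = 7, names = FALSE)
  out <- cut(scores, breaks = c(-Inf, qs, Inf),
             labels = c("low", "middle", "high"),
             right = TRUE, ordered_result = TRUE)
  out
}

#' Validate a GMS against alcohol consumption
#'
#' Linear regression of the score on continuous alcohol level plus
#' covariates within a genotype stratum. A genotype-specific score should
#' show a significant positive trend in its own stratum and none in the
#' other.
#'
#' @param scores Named score vector (names = sample ids).
#' @param cohort Cohort data frame with `sample_id`, `alcohol_level`,
#'   `carrier`, covariates.
#' @param stratum `"carrier"`, `"noncarrier"` or `"pooled"`.
#' @param covariates Covariate column names.
#' @return List with `coefficient`, `se`, `p_value`, `n`.
#' @export
validate_gms <- function(scores, cohort, stratum = c("noncarrier", "carrier", "pooled"),
                         covariates = character()) {
  stratum <- match.arg(stratum)
  sub <- stratum_subset(cohort, stratum)
  sub <- sub[stats::complete.cases(sub[, c("alcohol_level", covariates), drop = FALSE]), , drop = FALSE]
  if (nrow(sub) == 0) stop("validate_gms: empty stratum")
  if (length(unique(sub$alcohol_level)) < 2) {
    stop("validate_gms: alcohol level constant in stratum")
  }
  y <- scores[sub$sample_id]
  if (anyNA(y)) stop("validate_gms: scores missing for some stratum samples")
  X <- build_design(sub, "alcohol_level", covariates)
  fit <- ols_matrix(cbind(score = y), X, term = "alcohol_level")
  list(coefficient = fit$coef, se = fit$se, p_value = fit$p, n = nrow(sub))
}

#' Serialize a GMS model to JSON
#' @param model A `gms_model`.
#' @param path Output path.
#' @export
write_gms_model <- function(model, path) {
  obj <- list(stratum = model$stratum,
              species_ids = model$species_ids,
              beta = unname(model$beta),
              sigma = model$sigma,
              whitening = model$whitening,
              eig_floor = model$eig_floor,
              p_cutoff = model$p_cutoff,
              method = model$method)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read a GMS model from JSON
#' @param path File written by [write_gms_model()].
#' @return A `gms_model` list.
#' @export
read_gms_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(stratum = obj$stratum,
                 species_ids = obj$species_ids,
                 beta = stats::setNames(obj$beta, obj$species_ids),
                 sigma = structure(obj$sigma,
                                   dimnames = list(obj$species_ids, obj$species_ids)),
                 whitening = structure(obj$whitening,
                                       dimnames = list(obj$species_ids, obj$species_ids)),
                 eig_floor = obj$eig_floor,
                 p_cutoff = obj$p_cutoff,
                 method = obj$method),
            class = "gms_model")
}
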