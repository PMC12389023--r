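# Trend and interaction analyses: logistic models of insulin resistance on
# ordinal alcohol level, tertile-stratified effect modification with a
# pooled product-term test, and rank-based robust regression for continuous
# metabolic traits (rank inverse-normal transform + OLS with HC3
# heteroskedasticity-consistent standard errors).

assoc_frame <- function(outcome, alcohol_level, covariates_df = NULL) {
  df <- data.frame(.outcome = outcome, alcohol_level = alcohol_level)
  if (!is.null(covariates_df) && ncol(as.data.frame(covariates_df)) > 0) {
    df <- cbind(df, as.data.frame(covariates_df))
  }
  df[stats::complete.cases(df), , drop = FALSE]
}

check_separation <- function(fit) {
  if (!fit$converged) stop("logistic fit did not converge (possible separation)")
  eps <- 1e-8
  probs <- fit$fitted.values
  if (any(probs < eps) || any(probs > 1 - eps) || any(abs(stats::coef(fit)) > 15)) {
    stop("logistic fit shows signs of (quasi-)separation; estimates unreliable")
  }
}

wald_row <- function(est, se, label, stratum, n, exponentiate = TRUE) {
  z <- est / se
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  if (exponentiate) {
    data.frame(outcome = label, stratum = stratum,
               estimate = exp(est), ci_low = exp(est - 1.96 * se),
               ci_high = exp(est + 1.96 * se), p_trend = p, n = n,
               stringsAsFactors = FALSE)
  } else {
    data.frame(outcome = label, stratum = stratum,
               estimate = est, ci_low = est - 1.96 * se,
               ci_high = est + 1.96 * se, p_trend = p, n = n,
               stringsAsFactors = FALSE)
  }
}

#' Logistic trend of a binary outcome on ordinal alcohol level
#'
#' Maximum-likelihood logistic regression with alcohol level entered as a
#' continuous 0-3 trend variable. The reported estimate is the odds ratio
#' per one-level increase, with a Wald 95% confidence interval.
#'
#' @param outcome Binary (logical or 0/1) outcome vector.
#' @param alcohol_level Ordinal alcohol level, treated as continuous.
#' @param covariates Optional data frame of covariates (factors are
#'   indicator-coded).
#' @param label Outcome label carried into the result; default `"IR"`.
#' @param stratum Stratum label carried into the result; default `"all"`.
#' @return One-row data frame: `outcome`, `stratum`, `estimate` (OR),
#'   `ci_low`, `ci_high`, `p_trend`, `n`.
#' @export
logistic_trend <- function(outcome, alcohol_level, covariates = NULL,
                           label = "IR", stratum = "all") {
  df <- assoc_frame(as.numeric(outcome), alcohol_level, covariates)
  if (length(unique(df$.outcome)) < 2) stop("logistic_trend: outcome has a single class")
  k <- ncol(df) - 1
  if (nrow(df) <= 10 * (k + 1)) {
    stop("logistic_trend: too few observations for the number of covariates")
  }
  fit <- stats::glm(.outcome ~ ., data = df, family = stats::binomial())
  check_separation(fit)
  sm <- summary(fit)$coefficients
  wald_row(sm["alcohol_level", 1], sm["alcohol_level", 2], label, stratum, nrow(df))
}

#' Per-category odds ratios versus non-drinkers
#'
#' Indicator-codes the four alcohol levels with level 0 (non-drinkers) as
#' reference and reports one odds ratio per non-reference level.
#'
#' @inheritParams logistic_trend
#' @return Data frame with one row per non-reference level; the `stratum`
#'   column records the level contrast.
#' @export
category_contrasts <- function(outcome, alcohol_level, covariates = NULL,
                               label = "IR") {
  df <- assoc_frame(as.numeric(outcome), alcohol_level, covariates)
  lv <- sort(unique(df$alcohol_level))
  if (length(lv) < 2) stop("category_contrasts: a single alcohol level is inestimable")
  df$alcohol_level <- factor(df$alcohol_level, levels = lv)
  fit <- stats::glm(.outcome ~ ., data = df, family = stats::binomial())
  check_separation(fit)
  sm <- summary(fit)$coefficients
  rows <- grep("^alcohol_level", rownames(sm), value = TRUE)
  out <- do.call(rbind, lapply(rows, function(r) {
    wald_row(sm[r, 1], sm[r, 2], label,
             paste0("level ", sub("^alcohol_level", "", r), " vs ", lv[1]),
             nrow(df))
  }))
  out
}

#' Tertile-stratified alcohol effect with pooled product-term interaction
#'
#' Fits [logistic_trend()] separately within each tertile of a modifier
#' (e.g. the GMS) and tests effect modification through the coefficient of
#' the product of two continuous codes — tertile 1-3 times alcohol level
#' 0-3 — in a pooled model containing both main effects and the covariates.
#' A categorical-interaction likelihood-ratio test is available behind
#' `categorical = TRUE`.
#'
#' @inheritParams logistic_trend
#' @param modifier_tertile Ordered factor (or integer 1-3) tertile of the
#'   modifying variable, as from [tertile_assign()].
#' @param categorical Use a likelihood-ratio test of the factor-coded
#'   interaction instead of the single product term; default `FALSE`.
#' @return List of class `interaction_result`: `modifier`, `per_stratum`
#'   (data frame of per-tertile fits), `p_interaction`,
#'   `interaction_coef` (`NA` under `categorical = TRUE`).
#' @export
stratified_interaction <- function(outcome, alcohol_level, modifier_tertile,
                                   covariates = NULL, label = "IR",
                                   modifier = "GMS", categorical = FALSE) {
  tert <- as.integer(modifier_tertile)
  if (length(unique(tert[!is.na(tert)])) < 2) {
    stop("stratified_interaction: modifier is constant")
  }
  lev_names <- c("low", "middle", "high")
  per <- do.call(rbind, lapply(sort(unique(tert[!is.na(tert)])), function(t) {
    i <- which(tert == t)
    if (length(i) == 0) stop("stratified_interaction: empty tertile ", t)
    logistic_trend(outcome[i], alcohol_level[i],
                   if (is.null(covariates)) NULL else covariates[i, , drop = FALSE],
                   label = label, stratum = lev_names[t])
  }))
  df2 <- data.frame(.outcome = as.numeric(outcome),
                    alcohol_level = alcohol_level, .tert = tert)
  if (!is.null(covariates)) df2 <- cbind(df2, as.data.frame(covariates))
  df2 <- df2[stats::complete.cases(df2), , drop = FALSE]
  if (categorical) {
    df2$.tertf <- factor(df2$.tert)
    full <- stats::glm(.outcome ~ . - .tert + alcohol_level:.tertf,
                       data = df2, family = stats::binomial())
    null <- stats::glm(.outcome ~ . - .tert, data = df2, family = stats::binomial())
    lrt <- stats::anova(null, full, test = "LRT")
    p_int <- lrt$`Pr(>Chi)`[2]
    coef_int <- NA_real_
  } else {
    df2$.prod <- df2$alcohol_level * df2$.tert
    fit <- stats::glm(.outcome ~ ., data = df2, family = stats::binomial())
    check_separation(fit)
    sm <- summary(fit)$coefficients
    coef_int <- sm[".prod", 1]
    p_int <- sm[".prod", 4]
  }
  structure(list(modifier = modifier, per_stratum = per,
                 p_interaction = p_int, interaction_coef = coef_int),
            class = "interaction_result")
}

#' Rank inverse-normal transform (Blom offset)
#'
#' Maps a numeric vector to normal scores `qnorm((rank - 3/8)/(n + 1/4))`.
#' Ties get average ranks; missing values stay missing.
#'
#' @param x Numeric vector.
#' @return Normal scores of the same length.
#' @export
rank_inverse_normal <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  n <- sum(ok)
  out[ok] <- stats::qnorm((rank(x[ok], ties.method = "average") - 3 / 8) / (n + 1 / 4))
  out
}

# HC3 heteroskedasticity-consistent covariance of OLS coefficients.
hc3_vcov <- function(X, residuals) {
  h <- rowSums((X %*% chol2inv(chol(crossprod(X)))) * X)
  w <- residuals^2 / (1 - h)^2
  bread <- chol2inv(chol(crossprod(X)))
  bread %*% crossprod(X * w, X) %*% bread
}

#' Rank-based robust regression of a continuous trait on alcohol level
#'
#' Replaces the trait by its normal scores ([rank_inverse_normal()]) and
#' fits ordinary least squares on continuous alcohol level plus covariates,
#' with HC3 heteroskedasticity-consistent standard errors. The coefficient
#' is in standard deviations of the normal scores per alcohol level, which
#' makes it invariant to any strictly increasing transform of the trait.
#'
#' @param trait Continuous outcome vector (>= 10 distinct values).
#' @param alcohol_level Ordinal alcohol level (continuous coding).
#' @param covariates Optional covariate data frame.
#' @param label Trait label; default `"trait"`.
#' @param stratum Stratum label; default `"all"`.
#' @return One-row data frame as [logistic_trend()] but with an additive
#'   `estimate` (not an OR).
#' @export
rank_robust_regression <- function(trait, alcohol_level, covariates = NULL,
                                   label = "trait", stratum = "all") {
  if (length(unique(trait[!is.na(trait)])) < 10) {
    stop("rank_robust_regression: trait needs >= 10 distinct values")
  }
  df <- assoc_frame(trait, alcohol_level, covariates)
  df$.outcome <- rank_inverse_normal(df$.outcome)
  X <- stats::model.matrix(.outcome ~ ., data = df)
  y <- df$.outcome
  qr_x <- qr(X)
  beta <- qr.coef(qr_x, y)
  res <- y - as.vector(X %*% beta)
  V <- hc3_vcov(X, res)
  j <- match("alcohol_level", colnames(X))
  wald_row(beta[j], sqrt(V[j, j]), label, stratum, nrow(df), exponentiate = FALSE)
}

# Pooled HC3 product-term interaction test for a continuous (rank-
# transformed) trait: trait ~ alcohol + tertile + alcohol*tertile + covars.
rint_interaction_p <- function(trait, alcohol_level, tert, covariates = NULL) {
  df <- data.frame(.y = trait, alcohol_level = alcohol_level, .tert = tert)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  df$.y <- rank_inverse_normal(df$.y)
  df$.prod <- df$alcohol_level * df$.tert
  X <- stats::model.matrix(.y ~ ., data = df)
  y <- df$.y
  beta <- qr.coef(qr(X), y)
  res <- y - as.vector(X %*% beta)
  V <- hc3_vcov(X, res)
  j <- match(".prod", colnames(X))
  z <- beta[j] / sqrt(V[j, j])
  list(coef = unname(beta[j]),
       p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' Species abundance as an effect modifier
#'
#' Cuts one species' CLR abundance into tertiles and runs the stratified
#' alcohol-outcome analysis with the pooled product-term interaction test.
#'
#' @inheritParams stratified_interaction
#' @param species_clr Numeric vector of CLR abundances for one species,
#'   aligned with `outcome`.
#' @param species_id Label for the result.
#' @return An `interaction_result` (see [stratified_interaction()]).
#' @export
species_modifier_analysis <- function(outcome, alcohol_level, species_clr,
                                      covariates = NULL, species_id = "species") {
  tert <- tertile_assign(species_clr)
  stratified_interaction(outcome, alcohol_level, tert, covariates,
                         modifier = species_id)
}

#' Interaction battery over continuous metabolic traits
#'
#' For each named trait column: per-tertile rank-based robust regressions of
#' the trait on alcohol level, plus a pooled HC3 product-term interaction
#' test (tertile 1-3 times alcohol 0-3). Missing trait columns are skipped
#' with a warning.
#'
#' @param cohort Cohort data frame holding the trait columns.
#' @param alcohol_level Ordinal alcohol level vector aligned with `cohort`.
#' @param modifier_tertile Tertile of the modifier (e.g. GMS).
#' @param covariates Optional covariate data frame.
#' @param traits Character vector of trait column names.
#' @return Data frame grid with one row per trait x tertile (plus the pooled
#'   `p_interaction` repeated per trait).
#' @export
continuous_trait_battery <- function(cohort, alcohol_level, modifier_tertile,
                                     covariates = NULL,
                                     traits = c("homa_ir", "fasting_insulin",
                                                "fasting_glucose", "hba1c",
                                                "ogtt_2h_glucose", "homa_b")) {
  tert <- as.integer(modifier_tertile)
  lev_names <- c("low", "middle", "high")
  out <- list()
  for (tr in traits) {
    if (!tr %in% names(cohort)) {
      warning("continuous_trait_battery: missing trait column skipped: ", tr)
      next
    }
    y <- cohort[[tr]]
    rows <- do.call(rbind, lapply(sort(unique(tert[!is.na(tert)])), function(t) {
      i <- which(tert == t)
      rank_robust_regression(y[i], alcohol_level[i],
                             if (is.null(covariates)) NULL else covariates[i, , drop = FALSE],
                             label = tr, stratum = lev_names[t])
    }))
    pint <- rint_interaction_p(y, alcohol_level, tert, covariates)
    rows$p_interaction <- pint$p
    out[[tr]] <- rows
  }
  if (length(out) == 0) {
    return(data.frame(outcome = character(), stratum = character(),
                      estimate = numeric(), ci_low = numeric(),
                      ci_high = numeric(), p_trend = numeric(), n = integer(),
                      p_interaction = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
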