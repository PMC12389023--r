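#' Homeostasis model assessment of insulin resistance (HOMA-IR)
#'
#' HOMA-IR is the product of fasting glucose (mg/dL) and fasting insulin
#' (mU/L) divided by 405. Values of 2.5 or above are conventionally taken to
#' indicate insulin resistance (see [classify_insulin_resistance()]).
#'
#' @param fasting_glucose Fasting plasma glucose in mg/dL; must be positive.
#' @param fasting_insulin Fasting serum insulin in mU/L; must be positive.
#' @return Dimensionless HOMA-IR, vectorized over the inputs. `NA` inputs
#'   propagate to `NA` outputs.
#' @examples
#' homa_ir(405, 1)      # 1
#' homa_ir(90, 11.25)   # 2.5
#' @export
homa_ir <- function(fasting_glucose, fasting_insulin) {
  ok <- is.na(fasting_glucose) | is.na(fasting_insulin) |
    (fasting_glucose > 0 & fasting_insulin > 0)
  if (!all(ok)) {
    stop("homa_ir: fasting glucose and insulin must be strictly positive")
  }
  fasting_glucose * fasting_insulin / 405
}

#' Homeostasis model assessment of beta-cell function (HOMA-B)
#'
#' HOMA-B is 20 times fasting insulin (mU/L) divided by fasting glucose
#' (mg/dL) minus 63. It is undefined at or below 63 mg/dL glucose.
#'
#' @inheritParams homa_ir
#' @return Dimensionless HOMA-B, vectorized. `NA` inputs propagate.
#' @examples
#' homa_b(83, 10)  # 10
#' @export
homa_b <- function(fasting_glucose, fasting_insulin) {
  ok <- is.na(fasting_glucose) | fasting_glucose > 63
  if (!all(ok)) {
    stop("homa_b: fasting glucose must exceed 63 mg/dL (denominator)")
  }
  if (!all(is.na(fasting_insulin) | fasting_insulin > 0)) {
    stop("homa_b: fasting insulin must be strictly positive")
  }
  20 * fasting_insulin / (fasting_glucose - 63)
}

#' Classify insulin resistance from HOMA-IR
#'
#' A participant is classified insulin resistant when HOMA-IR reaches the
#' cutoff (default 2.5, boundary inclusive; set `inclusive = FALSE` for a
#' strict `>` boundary — the two differ only on the measure-zero boundary).
#'
#' @param homa_ir HOMA-IR values (non-negative).
#' @param cutoff Classification threshold, default 2.5.
#' @param inclusive If `TRUE` (default) the boundary value itself counts as
#'   resistant.
#' @return Logical vector; `NA` where `homa_ir` is `NA`.
#' @export
classify_insulin_resistance <- function(homa_ir, cutoff = 2.5, inclusive = TRUE) {
  if (!all(is.na(homa_ir) | homa_ir >= 0)) {
    stop("classify_insulin_resistance: homa_ir must be non-negative")
  }
  if (inclusive) homa_ir >= cutoff else homa_ir > cutoff
}

#' Diabetes exclusion screen
#'
#' Flags participants meeting any standard diabetes criterion so they can be
#' excluded from insulin-resistance analyses: fasting glucose >= 126 mg/dL
#' after a fast longer than 8 h, fasting glucose >= 200 mg/dL on a fast of
#' 8 h or less, 2-h post-OGTT glucose >= 200 mg/dL, HbA1c >= 6.5%, current
#' antidiabetic medication, or self-reported physician-diagnosed type 2
#' diabetes.
#'
#' Missing values are treated conservatively: a criterion with a missing
#' measurement does not fire, so a row is excluded only on observed evidence.
#'
#' @param fasting_glucose mg/dL.
#' @param fasting_time Hours fasted before the glucose draw.
#' @param ogtt_2h_glucose 2-h post-load glucose, mg/dL.
#' @param hba1c Glycated hemoglobin, percent.
#' @param on_antidiabetic_med Logical flag.
#' @param self_reported_t2d Logical flag.
#' @return Logical vector, `TRUE` = exclude.
#' @export
diabetes_exclusion <- function(fasting_glucose = NA_real_,
                               fasting_time = NA_real_,
                               ogtt_2h_glucose = NA_real_,
                               hba1c = NA_real_,
                               on_antidiabetic_med = FALSE,
                               self_reported_t2d = FALSE) {
  n <- max(length(fasting_glucose), length(fasting_time),
           length(ogtt_2h_glucose), length(hba1c),
           length(on_antidiabetic_med), length(self_reported_t2d))
  g  <- rep_len(fasting_glucose, n)
  ft <- rep_len(fasting_time, n)
  og <- rep_len(ogtt_2h_glucose, n)
  a1 <- rep_len(hba1c, n)
  med <- rep_len(as.logical(on_antidiabetic_med), n)
  t2d <- rep_len(as.logical(self_reported_t2d), n)
  yes <- function(x) !is.na(x) & x
  yes(g >= 126 & ft > 8) |
    yes(g >= 200 & ft <= 8) |
    yes(og >= 200) |
    yes(a1 >= 6.5) |
    yes(med) |
    yes(t2d)
}

#' Ordinal alcohol consumption level
#'
#' Codes weekly alcohol intake into four ordered levels: 0 for non-users
#' (never drank or formerly drank), 1 for current drinkers below the cohort
#' median (< 2 drinks/week), 2 for the median-to-third-quartile band
#' (>= 2 and < 6 drinks/week), and 3 for 6 or more drinks weekly.
#'
#' @param weekly_drinks Current drinks per week (non-negative).
#' @param current_drinker Logical; `FALSE` yields level 0 regardless of
#'   `weekly_drinks`.
#' @return Integer vector in 0..3; `NA` where inputs are missing.
#' @examples
#' alcohol_level(c(5, 1.5, 2, 6), c(FALSE, TRUE, TRUE, TRUE))  # 0 1 2 3
#' @export
alcohol_level <- function(weekly_drinks, current_drinker) {
  if (!all(is.na(weekly_drinks) | weekly_drinks >= 0)) {
    stop("alcohol_level: weekly_drinks must be non-negative")
  }
  n <- max(length(weekly_drinks), length(current_drinker))
  wd <- rep_len(weekly_drinks, n)
  cd <- rep_len(as.logical(current_drinker), n)
  out <- ifelse(!cd, 0L,
         ifelse(wd < 2, 1L,
         ifelse(wd < 6, 2L, 3L)))
  out[is.na(cd) | (cd & is.na(wd))] <- NA_integer_
  as.integer(out)
}

#' Add derived metabolic columns to a cohort table
#'
#' Computes `homa_ir`, `homa_b`, `insulin_resistant`, `alcohol_level` and
#' `exclude_diabetes` columns from the raw measurement columns of a cohort
#' data frame. Rows whose glucose is at or below 63 mg/dL get `NA` HOMA-B.
#' Missing measurements propagate to missing derived values; they are not
#' imputed.
#'
#' @param cohort Data frame with columns `fasting_glucose`, `fasting_insulin`,
#'   `hba1c`, `ogtt_2h_glucose`, `fasting_time`, `on_antidiabetic_med`,
#'   `self_reported_t2d`, `weekly_drinks`, `current_drinker`.
#' @param ir_cutoff HOMA-IR threshold for the insulin-resistance flag.
#' @return The cohort with derived columns appended.
#' @export
add_metabolic_traits <- function(cohort, ir_cutoff = 2.5) {
  need <- c("fasting_glucose", "fasting_insulin")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("add_metabolic_traits: missing columns: ",
                         paste(miss, collapse = ", "))
  g <- cohort$fasting_glucose
  i <- cohort$fasting_insulin
  hir <- rep(NA_real_, nrow(cohort))
  okir <- !is.na(g) & !is.na(i) & g > 0 & i > 0
  hir[okir] <- homa_ir(g[okir], i[okir])
  hb <- rep(NA_real_, nrow(cohort))
  okb <- okir & g > 63
  hb[okb] <- homa_b(g[okb], i[okb])
  cohort$homa_ir <- hir
  cohort$homa_b <- hb
  cohort$insulin_resistant <- classify_insulin_resistance(hir, cutoff = ir_cutoff)
  if (all(c("weekly_drinks", "current_drinker") %in% names(cohort))) {
    cohort$alcohol_level <- alcohol_level(cohort$weekly_drinks,
                                          cohort$current_drinker)
  }
  cohort$exclude_diabetes <- diabetes_exclusion(
    fasting_glucose = cohort$fasting_glucose,
    fasting_time = cohort[["fasting_time"]] %||% NA_real_,
    ogtt_2h_glucose = cohort[["ogtt_2h_glucose"]] %||% NA_real_,
    hba1c = cohort[["hba1c"]] %||% NA_real_,
    on_antidiabetic_med = cohort[["on_antidiabetic_med"]] %||% FALSE,
    self_reported_t2d = cohort[["self_reported_t2d"]] %||% FALSE)
  cohort
}

`%||%` <- function(a, b) if (is.null(a)) b else a
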