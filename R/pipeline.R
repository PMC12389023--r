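# End-to-end orchestration: diabetes exclusion -> alcohol coding -> species
# filtering -> CLR -> stratified differential abundance -> genotype-specific
# GMS -> validation (own and cross stratum) -> interaction analyses. Driven
# by a single config; all analysis stages are deterministic given inputs.

#' Pipeline configuration
#'
#' Collects inputs and thresholds for [run_pipeline()]. Inputs may be given
#' as file paths (`cohort_path`, TSV; `counts_path`, TSV or BIOM) or as
#' in-memory objects (`cohort`, `counts`).
#'
#' @param cohort,cohort_path Cohort table (data frame) or TSV path. Must
#'   contain `sample_id`, `genotype` (CC/CT/TT), `weekly_drinks`,
#'   `current_drinker`, the covariate columns, and the metabolic measurement
#'   columns.
#' @param counts,counts_path Species x sample count matrix or path.
#' @param covariates Covariate column names; default
#'   `c("age", "sex", "site", "smoking", "diet_score")`.
#' @param prevalence_min,mean_count_min Species filter thresholds (0.20, 50).
#' @param pseudocount Log pseudocount shared across stages; default 0.5.
#' @param p_cutoff Species selection cutoff for the GMS; default 0.05.
#' @param fdr_cutoff FDR cutoff defining "top" species for the individual
#'   species analyses; default 0.05.
#' @param ir_cutoff HOMA-IR insulin-resistance threshold; default 2.5.
#' @param eig_floor Whitening eigenvalue floor; default 1e-6.
#' @param traits Continuous trait columns for the interaction battery.
#' @param out_dir Optional output directory for artifacts.
#' @param seed Seed echoed into the report (analysis itself is
#'   deterministic).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, counts = NULL,
                            cohort_path = NULL, counts_path = NULL,
                            covariates = c("age", "sex", "site", "smoking", "diet_score"),
                            prevalence_min = 0.20, mean_count_min = 50,
                            pseudocount = 0.5, p_cutoff = 0.05,
                            fdr_cutoff = 0.05, ir_cutoff = 2.5,
                            eig_floor = 1e-6,
                            traits = c("homa_ir", "fasting_insulin",
                                       "fasting_glucose", "hba1c",
                                       "ogtt_2h_glucose", "homa_b"),
                            out_dir = NULL, seed = 1L) {
  stopifnot(prevalence_min >= 0, prevalence_min < 1, mean_count_min >= 0,
            pseudocount >= 0, p_cutoff > 0, p_cutoff <= 1,
            fdr_cutoff > 0, fdr_cutoff <= 1, ir_cutoff > 0, eig_floor > 0)
  if (!is.null(cohort_path) && !is.null(counts_path) &&
      identical(cohort_path, counts_path)) {
    stop("pipeline_config: cohort and counts paths must be distinct")
  }
  structure(list(cohort = cohort, counts = counts,
                 cohort_path = cohort_path, counts_path = counts_path,
                 covariates = covariates,
                 prevalence_min = prevalence_min,
                 mean_count_min = mean_count_min,
                 pseudocount = pseudocount, p_cutoff = p_cutoff,
                 fdr_cutoff = fdr_cutoff, ir_cutoff = ir_cutoff,
                 eig_floor = eig_floor, traits = traits,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file whose keys match the [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, obj)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the end-to-end analysis pipeline
#'
#' Executes all stages from raw cohort + counts to the interaction analyses
#' and returns a machine-readable report. When `config$out_dir` is set,
#' intermediate artifacts (filtered counts, CLR matrix, per-stratum
#' differential-abundance tables, GMS models and scores, result tables, the
#' JSON report) are written there.
#'
#' Stratified interaction, species-modifier, and trait-battery analyses are
#' run in the non-carrier stratum (the carrier stratum is typically too
#' small to stratify further); GMS validation runs in both strata for both
#' models (own and cross genotype).
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_report`: per-stage record counts, all
#'   result tables, and a settings echo.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  cohort <- stage("load_cohort", {
    ch <- cfg$cohort
    if (is.null(ch)) ch <- utils::read.delim(cfg$cohort_path, stringsAsFactors = FALSE)
    if (!all(ch$genotype %in% c("CC", "CT", "TT"))) {
      bad <- unique(ch$genotype[!ch$genotype %in% c("CC", "CT", "TT")])
      stop("invalid genotype values: ", paste(bad, collapse = ", "))
    }
    ch$carrier <- ch$genotype != "CC"
    ch
  })
  counts <- stage("load_counts", {
    cn <- cfg$counts
    if (is.null(cn)) cn <- read_taxa_counts(cfg$counts_path)
    if (!inherits(cn, "taxa_counts")) cn <- taxa_counts(as.matrix(cn))
    cn
  })
  n_input <- nrow(cohort)

  cohort <- stage("metabolic_traits",
                  add_metabolic_traits(cohort, ir_cutoff = cfg$ir_cutoff))
  excl <- cohort$exclude_diabetes
  cohort <- cohort[!excl, , drop = FALSE]
  n_excluded <- sum(excl)

  keep_samples <- intersect(colnames(counts), cohort$sample_id)
  counts <- counts[, keep_samples, drop = FALSE]
  mb_cohort <- cohort[match(keep_samples, cohort$sample_id), , drop = FALSE]

  n_species_input <- nrow(counts)
  filt <- stage("filter_species",
                filter_species(counts, cfg$prevalence_min, cfg$mean_count_min))
  clr <- stage("clr_transform", clr_transform(filt, cfg$pseudocount))

  strata <- c("noncarrier", "carrier")
  diff_tabs <- list()
  models <- list()
  scores <- list()
  validation <- list()
  for (s in strata) {
    diff_tabs[[s]] <- stage(paste0("diff_abund_", s),
      fit_species_associations(filt, mb_cohort, stratum = s,
                               covariates = cfg$covariates,
                               pseudocount = cfg$pseudocount))
    s_ids <- mb_cohort$sample_id[
      if (s == "carrier") mb_cohort$carrier else !mb_cohort$carrier]
    models[[s]] <- stage(paste0("gms_model_", s),
      build_gms_model(diff_tabs[[s]], clr, p_cutoff = cfg$p_cutoff,
                      sample_ids = s_ids, eig_floor = cfg$eig_floor))
    scores[[s]] <- stage(paste0("gms_scores_", s),
                         compute_gms(models[[s]], clr))
  }
  for (model_s in strata) for (pop_s in strata) {
    key <- paste0(model_s, "_model_in_", pop_s)
    validation[[key]] <- stage(paste0("validate_", key),
      validate_gms(scores[[model_s]], mb_cohort, stratum = pop_s,
                   covariates = cfg$covariates))
  }

  nc <- mb_cohort[!mb_cohort$carrier, , drop = FALSE]
  nc_scores <- scores[["noncarrier"]][nc$sample_id]
  nc_tert <- stage("gms_tertiles", tertile_assign(nc_scores))
  covdf <- nc[, cfg$covariates, drop = FALSE]

  gms_ir <- stage("gms_ir_interaction",
    stratified_interaction(nc$insulin_resistant, nc$alcohol_level, nc_tert,
                           covariates = covdf, modifier = "noncarrier GMS"))

  top_species <- diff_tabs[["noncarrier"]]$species_id[
    !is.na(diff_tabs[["noncarrier"]]$q_value) &
      diff_tabs[["noncarrier"]]$q_value < cfg$fdr_cutoff]
  species_mod <- list()
  for (sp in top_species) {
    species_mod[[sp]] <- tryCatch(
      species_modifier_analysis(nc$insulin_resistant, nc$alcohol_level,
                                unclass(clr)[sp, nc$sample_id],
                                covariates = covdf, species_id = sp),
      error = function(e) NULL)
  }
  species_mod <- Filter(Negate(is.null), species_mod)

  battery <- stage("trait_battery",
    continuous_trait_battery(nc, nc$alcohol_level, nc_tert,
                             covariates = covdf, traits = cfg$traits))

  report <- structure(list(
    counts = list(n_input = n_input,
                  n_excluded_diabetes = n_excluded,
                  n_analysis = nrow(cohort),
                  n_microbiome = nrow(mb_cohort),
                  n_noncarrier = sum(!mb_cohort$carrier),
                  n_carrier = sum(mb_cohort$carrier),
                  n_species_input = n_species_input,
                  n_species_filtered = nrow(filt),
                  n_selected = lapply(models, function(m) length(m$species_ids))),
    diff_abund = diff_tabs,
    gms_models = models,
    gms_validation = validation,
    gms_ir_interaction = gms_ir,
    species_modifiers = species_mod,
    trait_battery = battery,
    settings = cfg[setdiff(names(cfg), c("cohort", "counts"))],
    r_version = as.character(getRversion())),
    class = "pipeline_report")

  if (!is.null(cfg$out_dir)) write_pipeline_report(report, cfg$out_dir,
                                                   filt = filt, clr = clr,
                                                   scores = scores)
  report
}

write_pipeline_report <- function(report, out_dir, filt = NULL, clr = NULL,
                                  scores = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(filt)) write_taxa_matrix(filt, file.path(out_dir, "counts_filtered.tsv"))
  if (!is.null(clr)) write_taxa_matrix(clr, file.path(out_dir, "clr.tsv"))
  for (s in names(report$diff_abund)) {
    utils::write.table(report$diff_abund[[s]],
                       file.path(out_dir, paste0("diff_abund_", s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (s in names(report$gms_models)) {
    write_gms_model(report$gms_models[[s]],
                    file.path(out_dir, paste0("gms_model_", s, ".json")))
  }
  if (!is.null(scores)) {
    sc <- data.frame(sample_id = names(scores[[1]]),
                     lapply(scores, unname), check.names = FALSE)
    names(sc)[-1] <- paste0("gms_", names(scores))
    utils::write.table(sc, file.path(out_dir, "gms_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(report$trait_battery,
                     file.path(out_dir, "trait_battery.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  json <- list(counts = report$counts,
               gms_validation = report$gms_validation,
               gms_ir_interaction = list(
                 p_interaction = report$gms_ir_interaction$p_interaction,
                 interaction_coef = report$gms_ir_interaction$interaction_coef,
                 per_stratum = report$gms_ir_interaction$per_stratum),
               species_modifiers = lapply(report$species_modifiers, function(x) {
                 list(p_interaction = x$p_interaction,
                      interaction_coef = x$interaction_coef)
               }),
               settings = report$settings,
               r_version = report$r_version)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
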