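#' Run the full positive-deviance pipeline
#'
#' End-to-end orchestration: validation, performance indicators, relative
#' performance (median-regression residuals), Pareto ranking, deviance
#' profiling, diverse case selection, and — when a practice catalog is
#' supplied — resource-homologue matching with practice targeting. All
#' stage results are returned in one run summary; with `outdir` set, each
#' stage also writes its CSV/JSON artifact.
#'
#' @param records Household table (raw; validated internally).
#' @param config A [pd_config()].
#' @param catalog Optional practice catalog; when `NULL` the homologue
#'   stage is skipped and flagged in the summary.
#' @param outdir Optional output directory for stage artifacts.
#' @return Object of class `pd_run`: validation report, performance
#'   scores + PCA fit, residuals + models, Pareto result, deviance
#'   profile, correlations, group comparison, case selection, homologue
#'   map and practice targeting (or `NULL`), plus counts and the effective
#'   config.
#' @export
run_positive_deviance <- function(records, config = pd_config(),
                                  catalog = NULL, outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  val <- stage("validate", validate_households(records, config))
  clean <- val$records

  perf <- stage("indicators", performance_matrix(clean, config))
  rel <- stage("residuals", relative_performance(perf, clean, config))
  resid_m <- as.matrix(rel$residuals[, perf_columns()])
  ranks <- stage("pareto", pareto_ranks(resid_m, config$max_front_rank))
  dev_ids <- positive_deviants(ranks, clean$household_id)

  strata <- stage("strata",
                  assign_strata(clean$land_ha, clean$livestock_tlu,
                                config$n_land_deciles))
  profile <- stage("profile",
                   stratum_mean_deviance(rel$residuals, strata, dev_ids))
  correlations <- stage("correlations",
                        deviance_correlations(rel$residuals, dev_ids))
  comparison <- stage("compare",
                      compare_groups(clean, perf$scores, dev_ids,
                                     config$group_test))

  mkt <- market_access_proxy(clean)
  is_dev <- clean$household_id %in% dev_ids
  dev_tab <- data.frame(
    household_id = clean$household_id[is_dev],
    front_rank = ranks$front_rank[is_dev],
    land_decile = strata$land_decile[is_dev],
    livestock_class = strata$livestock_class[is_dev],
    mae = clean$mae[is_dev],
    land_ha = clean$land_ha[is_dev],
    livestock_tlu = clean$livestock_tlu[is_dev],
    market_access = mkt[is_dev],
    stringsAsFactors = FALSE
  )
  selection <- stage("select-cases",
                     select_diverse_cases(dev_tab, config$crowding_mode,
                                          all_strata = strata))

  homologues <- NULL; targeting <- NULL
  if (!is.null(catalog)) {
    profiles <- stage("homologues",
                      resource_profile(clean, config$resource_proxies))
    visited <- selection$selection$household_id
    homologues <- stage("homologues",
                        nearest_homologues(profiles$standardized, visited,
                                           config$homologue_k,
                                           config$homologue_include_self))
    menus <- stage("practices", practice_menu(homologues, catalog))
    targeting <- menus$targeting
  }

  run <- list(
    validation = val$report,
    performance = perf,
    residuals = rel,
    pareto = ranks,
    deviant_ids = dev_ids,
    strata = strata,
    profile = profile,
    correlations = correlations,
    comparison = comparison,
    selection = selection,
    homologues = homologues,
    practice_targeting = targeting,
    counts = list(
      n_input = val$report$n_input,
      n_analysed = nrow(clean),
      n_dropped = val$report$n_dropped,
      n_positive_deviants = length(dev_ids),
      per_rank = ranks$counts,
      n_strata_occupied = length(unique(strata$stratum_id)),
      n_strata_with_deviants = nrow(selection$selection),
      n_cases_selected = nrow(selection$selection),
      pc1_variance_fraction = perf$pca$variance_fraction[1],
      homologue_stage_run = !is.null(catalog)
    ),
    config = config
  )
  class(run) <- "pd_run"

  if (!is.null(outdir)) write_run_outputs(run, clean, outdir)
  run
}

# per-stage CSV artifacts plus a machine-readable run summary
write_run_outputs <- function(run, clean, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, file) utils::write.csv(df, file.path(outdir, file),
                                           row.names = FALSE)
  w(run$performance$scores, "indicators.csv")
  jsonlite::write_json(
    list(loadings = as.list(run$performance$pca$loadings),
         variance_fraction = run$performance$pca$variance_fraction,
         center = as.list(run$performance$pca$center),
         scale = as.list(run$performance$pca$scale)),
    file.path(outdir, "pca_fit.json"), auto_unbox = TRUE, digits = NA)
  w(run$residuals$residuals, "residuals.csv")
  w(data.frame(household_id = clean$household_id,
               front_rank = run$pareto$front_rank,
               positive_deviant = run$pareto$positive_deviant),
    "pareto.csv")
  w(cbind(household_id = clean$household_id, run$strata), "strata.csv")
  w(run$profile$table, "deviance_profile.csv")
  w(as.data.frame(run$correlations$r), "deviance_correlations.csv")
  w(run$comparison, "group_comparison.csv")
  w(run$selection$selection, "case_selection.csv")
  if (!is.null(run$homologues)) {
    w(as.data.frame(run$homologues), "homologues.csv")
    w(run$practice_targeting, "practice_targeting.csv")
  }
  jsonlite::write_json(
    list(counts = run$counts,
         models = lapply(run$residuals$models, function(m)
           list(covariates = m$covariates,
                coefficients = as.list(m$coefficients),
                aic = m$aic)),
         config = unclass(run$config)[
           !vapply(unclass(run$config), is.list, logical(1))]),
    file.path(outdir, "run_summary.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.pd_run <- function(x, ...) {
  cat("<pd_run> positive-deviance pipeline\n")
  cat("  households analysed: ", x$counts$n_analysed,
      " (", x$counts$n_dropped, " dropped)\n", sep = "")
  cat("  positive deviants: ", x$counts$n_positive_deviants, " (",
      paste(sprintf("rank %s: %d", names(x$counts$per_rank),
                    x$counts$per_rank), collapse = ", "), ")\n", sep = "")
  cat("  food-security PC-1 variance: ",
      round(100 * x$counts$pc1_variance_fraction, 1), "%\n", sep = "")
  cat("  strata with deviants: ", x$counts$n_strata_with_deviants,
      " of ", x$counts$n_strata_occupied, " occupied\n", sep = "")
  if (x$counts$homologue_stage_run) {
    cat("  homologue stage: run (", nrow(x$practice_targeting),
        " practices targeted)\n", sep = "")
  } else {
    cat("  homologue stage: skipped (no practice catalog)\n")
  }
  invisible(x)
}
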