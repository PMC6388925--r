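#' Pipeline configuration
#'
#' Builds the effective configuration for a positive-deviance run. Every
#' argument has a default matching the reference study conditions; unknown
#' household types or a quantile other than the median are rejected because
#' the method is defined on median-regression residuals.
#'
#' @param kcal_requirement Recommended daily energy intake per male adult
#'   equivalent (kcal/MAE/day). Default 2550, Tanzania's official
#'   recommendation.
#' @param quantile_tau Quantile for the performance regressions. Fixed at
#'   0.5; any other value is an error.
#' @param cap_percentile Per-indicator validity bound for outlier capping:
#'   values above this empirical percentile are replaced by the maximum
#'   in-range observed value. Default 0.99.
#' @param cap_lower Also cap low-end outliers (below `1 - cap_percentile`).
#'   Default `FALSE` (high-end only).
#' @param cap_bounds Optional named list of absolute upper bounds per
#'   indicator column, overriding the percentile rule for those columns.
#' @param gender_weights Named numeric vector of household-type discount
#'   weights for the gender-equity indicator. Score is
#'   `1 - w * 2 * |female_share - 0.5|`, clipped to `[0, 1]`.
#' @param candidate_covariates Character vector of candidate covariate
#'   groups for the relative-performance regressions. `"region"` enters and
#'   leaves as one dummy group.
#' @param max_front_rank Deepest Pareto front counted as positive deviance.
#'   Default 2.
#' @param n_land_deciles Number of land-endowment strata bins. Default 10.
#' @param homologue_k Number of resource homologues per household. Default 3.
#' @param homologue_include_self Whether a visited deviant may match itself
#'   at distance zero. Default `TRUE`.
#' @param crowding_mode Where crowding distances are computed during case
#'   selection: within the provisional `"selection"` (default) or within the
#'   full deviant `"pool"`.
#' @param group_test Two-sample test for numeric group comparisons:
#'   `"welch"` (default) or `"student"`.
#' @param resource_proxies Named list of six expressions (as strings) mapping
#'   survey fields to the resource-profile axes used for homologue matching.
#' @param seed Integer master seed for all randomised components.
#'
#' @return An object of class `pd_config` (a named list).
#' @seealso [load_config()] for reading a YAML file.
#' @export
pd_config <- function(kcal_requirement = 2550,
                      quantile_tau = 0.5,
                      cap_percentile = 0.99,
                      cap_lower = FALSE,
                      cap_bounds = list(),
                      gender_weights = c(
                        couple = 1,
                        married_woman_absent_spouse = 1,
                        married_man_absent_spouse = 1,
                        single_woman = 0.5,
                        single_man = 0.5
                      ),
                      candidate_covariates = c("land_ha", "livestock_tlu",
                                               "mae", "region",
                                               "market_access"),
                      max_front_rank = 2,
                      n_land_deciles = 10,
                      homologue_k = 3,
                      homologue_include_self = TRUE,
                      crowding_mode = c("selection", "pool"),
                      group_test = c("welch", "student"),
                      resource_proxies = default_resource_proxies(),
                      seed = 1L) {
  if (!isTRUE(all.equal(quantile_tau, 0.5))) {
    stop("quantile_tau must be 0.5: relative performance is defined on ",
         "median-regression residuals", call. = FALSE)
  }
  if (max_front_rank < 1) stop("max_front_rank must be >= 1", call. = FALSE)
  if (homologue_k < 1) stop("homologue_k must be >= 1", call. = FALSE)
  if (cap_percentile <= 0 || cap_percentile > 1) {
    stop("cap_percentile must be in (0, 1]", call. = FALSE)
  }
  crowding_mode <- match.arg(crowding_mode)
  group_test <- match.arg(group_test)
  stopifnot(is.numeric(gender_weights), !is.null(names(gender_weights)))

  cfg <- list(
    kcal_requirement = kcal_requirement,
    quantile_tau = 0.5,
    cap_percentile = cap_percentile,
    cap_lower = cap_lower,
    cap_bounds = cap_bounds,
    gender_weights = gender_weights,
    candidate_covariates = candidate_covariates,
    max_front_rank = as.integer(max_front_rank),
    n_land_deciles = as.integer(n_land_deciles),
    homologue_k = as.integer(homologue_k),
    homologue_include_self = homologue_include_self,
    crowding_mode = crowding_mode,
    group_test = group_test,
    resource_proxies = resource_proxies,
    seed = as.integer(seed)
  )
  class(cfg) <- "pd_config"
  cfg
}

#' Default resource-proxy expressions
#'
#' Maps the six resource axes used for homologue matching to survey fields.
#' These are documented stand-ins: agro-ecological ability is proxied by
#' crop diversity, labour by household size (MAE), financial capital by
#' total income, land and livestock by their holdings, and social capital by
#' village-level market access.
#'
#' @return Named list of expression strings evaluated against the survey
#'   table (with `market_access` available).
#' @export
default_resource_proxies <- function() {
  list(
    agro_ecological_ability = "crop_diversity",
    labor = "mae",
    financial_capital = "farm_income + offfarm_income",
    land_holdings = "land_ha",
    livestock_holdings = "livestock_tlu",
    social_capital = "market_access"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file of configuration keys, applies defaults for absent
#' keys, and validates the result. An empty file yields the full default
#' configuration. Unknown keys raise an error naming them; a quantile other
#' than 0.5 is rejected.
#'
#' @param path Path to a YAML file (may be empty).
#' @return A [pd_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain a YAML mapping", call. = FALSE)

  known <- names(formals(pd_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$gender_weights)) {
    raw$gender_weights <- unlist(raw$gender_weights)
  }
  do.call(pd_config, raw)
}

#' @export
print.pd_config <- function(x, ...) {
  cat("<pd_config>\n")
  cat("  kcal requirement: ", x$kcal_requirement, " kcal/MAE/day\n", sep = "")
  cat("  capping: above p", x$cap_percentile * 100,
      if (x$cap_lower) " (both tails)" else " (upper tail)", "\n", sep = "")
  cat("  candidate covariates: ",
      paste(x$candidate_covariates, collapse = ", "), "\n", sep = "")
  cat("  max front rank: ", x$max_front_rank,
      "; homologue k: ", x$homologue_k, "\n", sep = "")
  cat("  seed: ", x$seed, "\n", sep = "")
  invisible(x)
}
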