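#' Caloric sufficiency ratio
#'
#' Household food availability (kcal per male adult equivalent per day)
#' divided by the recommended daily intake, capped at 100%. Availability is
#' already a per-MAE quantity, so no further division by household size is
#' applied.
#'
#' @param food_availability kcal/MAE/day, non-negative.
#' @param kcal_requirement Recommended intake, kcal/MAE/day (> 0).
#' @return Fraction in `[0, 1]`.
#' @export
caloric_sufficiency <- function(food_availability, kcal_requirement = 2550) {
  if (any(food_availability < 0, na.rm = TRUE)) {
    stop("food_availability must be non-negative", call. = FALSE)
  }
  if (kcal_requirement <= 0) stop("kcal_requirement must be > 0", call. = FALSE)
  pmin(food_availability / kcal_requirement, 1)
}

#' Food-secure months
#'
#' Converts the surveyed number of food-insecure months into its
#' complement, so that larger values are better in every dimension.
#'
#' @param food_insecure_months Integer months in `[0, 12]`.
#' @return `12 - food_insecure_months`.
#' @export
food_secure_months <- function(food_insecure_months) {
  if (any(food_insecure_months < 0 | food_insecure_months > 12,
          na.rm = TRUE)) {
    stop("food_insecure_months must lie in [0, 12]", call. = FALSE)
  }
  12 - food_insecure_months
}

#' Composite caloric food security score
#'
#' Combines the sufficiency ratio and the number of food-secure months into
#' one score: both measures are standardised (mean 0, sd 1) and the
#' households' scores on the first principal component are returned,
#' sign-oriented so that higher scores mean more food-secure (non-negative
#' correlation with both inputs).
#'
#' @param sufficiency Vector of sufficiency ratios.
#' @param secure_months Vector of food-secure months, same length.
#' @return A list: `score` (PC-1 score per household) and `fit` (class
#'   `pd_pca`) holding the loadings, the fraction of variance explained by
#'   each component, the standardisation constants and the orientation sign.
#' @export
caloric_food_security <- function(sufficiency, secure_months) {
  n <- length(sufficiency)
  if (length(secure_months) != n) stop("input lengths differ", call. = FALSE)
  if (n < 3) stop("need at least 3 households for the composite score",
                  call. = FALSE)
  m <- cbind(sufficiency = sufficiency, secure_months = secure_months)
  if (any(apply(m, 2, stats::sd) == 0)) {
    stop("constant input measure: principal component undefined",
         call. = FALSE)
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  score <- pc$x[, 1]
  # orient so the composite increases with both inputs (loadings share a
  # sign because both measures point the same way)
  sgn <- if (sum(pc$rotation[, 1]) < 0) -1 else 1
  score <- sgn * score
  fit <- list(
    loadings = sgn * pc$rotation[, 1],
    variance_fraction = pc$sdev^2 / sum(pc$sdev^2),
    center = pc$center,
    scale = pc$scale,
    sign = sgn
  )
  class(fit) <- "pd_pca"
  list(score = as.numeric(score), fit = fit)
}

#' @export
print.pd_pca <- function(x, ...) {
  cat("<pd_pca> PC-1 explains ",
      round(100 * x$variance_fraction[1], 1), "% of variance\n", sep = "")
  cat("  loadings:", paste(names(x$loadings),
                           round(x$loadings, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Dietary diversity
#'
#' Harmonic mean of the good-season and lean-season Household Dietary
#' Diversity Scores. The harmonic mean penalises a low score in either
#' season more than the arithmetic mean would: a diverse diet in the good
#' season cannot fully compensate a monotonous lean season. Defined as 0
#' (the limiting infimum) when either season's score is 0.
#'
#' @param hdds_good,hdds_lean Food-group counts in `[0, 12]`.
#' @return Harmonic-mean food groups.
#' @export
dietary_diversity <- function(hdds_good, hdds_lean) {
  if (any(c(hdds_good, hdds_lean) < 0 | c(hdds_good, hdds_lean) > 12,
          na.rm = TRUE)) {
    stop("HDDS values must lie in [0, 12]", call. = FALSE)
  }
  out <- 2 / (1 / hdds_good + 1 / hdds_lean)
  out[hdds_good == 0 | hdds_lean == 0] <- 0
  out
}

#' Cash income
#'
#' Disposable household cash: farm-gate sales plus off-farm income.
#'
#' @param farm_income,offfarm_income US$/yr, non-negative.
#' @return US$/yr.
#' @export
cash_income <- function(farm_income, offfarm_income) {
  if (any(farm_income < 0, na.rm = TRUE) ||
      any(offfarm_income < 0, na.rm = TRUE)) {
    stop("income components must be non-negative", call. = FALSE)
  }
  farm_income + offfarm_income
}

#' Greenhouse-gas score
#'
#' Total on-farm emissions multiplied by -1 so that lower emissions yield
#' higher (better) scores; strictly order-reversing. Negative emission
#' totals are unusual and trigger a warning.
#'
#' @param ghg_emissions kg CO2-eq/yr.
#' @return `-ghg_emissions`.
#' @export
ghg_score <- function(ghg_emissions) {
  if (any(ghg_emissions < 0, na.rm = TRUE)) {
    warning("negative GHG emissions encountered; score will be positive",
            call. = FALSE)
  }
  -1 * ghg_emissions
}

#' Gender equity score
#'
#' Decision-making shared equally between women and men (female share 0.5)
#' is defined as fully equitable (score 1). Deviations from 0.5 are
#' discounted linearly with a household-type-specific weight: for
#' single-headed households the discount is halved, since a skewed share is
#' partly structural rather than behavioural. The functional form is a
#' configurable stand-in for type-specific formulae:
#' `score = 1 - w(type) * 2 * |female_share - 0.5|`, clipped to `[0, 1]`.
#'
#' @param female_share Women's (and female youth's) cumulative share of
#'   decision-making, in `[0, 1]`.
#' @param household_type Character vector of household types.
#' @param weights Named weight vector; see [pd_config()].
#' @return Score in `[0, 1]`, maximal exactly at share 0.5.
#' @export
gender_equity <- function(female_share, household_type,
                          weights = pd_config()$gender_weights) {
  if (any(female_share < 0 | female_share > 1, na.rm = TRUE)) {
    stop("female_share must lie in [0, 1]", call. = FALSE)
  }
  unknown <- setdiff(unique(household_type), names(weights))
  if (length(unknown)) {
    stop("unknown household type(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  w <- weights[household_type]
  pmin(pmax(1 - w * 2 * abs(female_share - 0.5), 0), 1)
}

#' Cap outlier scores
#'
#' Replaces values outside a validity bound with the maximum (respectively
#' minimum) value observed inside the bound. By default the bound is the
#' empirical `percentile` quantile of the vector itself; an absolute
#' `upper_bound` overrides it. The operation is idempotent and never
#' introduces values beyond those observed in range.
#'
#' @param x Numeric vector.
#' @param upper_bound Optional absolute validity bound.
#' @param percentile Quantile used when no absolute bound is given
#'   (default 0.99).
#' @param lower Also cap the low end at the mirrored quantile or at
#'   `lower_bound`.
#' @param lower_bound Optional absolute lower validity bound.
#' @return Capped vector, same length and order.
#' @export
cap_outliers <- function(x, upper_bound = NULL, percentile = 0.99,
                         lower = FALSE, lower_bound = NULL) {
  ub <- if (is.null(upper_bound)) {
    stats::quantile(x, percentile, na.rm = TRUE, names = FALSE)
  } else upper_bound
  in_range <- x <= ub
  if (!any(in_range, na.rm = TRUE)) {
    stop("all values above the validity bound; nothing to cap to",
         call. = FALSE)
  }
  x[which(!in_range)] <- max(x[in_range], na.rm = TRUE)
  if (lower || !is.null(lower_bound)) {
    lb <- if (is.null(lower_bound)) {
      stats::quantile(x, 1 - percentile, na.rm = TRUE, names = FALSE)
    } else lower_bound
    in_lo <- x >= lb
    if (!any(in_lo, na.rm = TRUE)) {
      stop("all values below the lower validity bound", call. = FALSE)
    }
    x[which(!in_lo)] <- min(x[in_lo], na.rm = TRUE)
  }
  x
}

perf_columns <- function() {
  c("food_security", "dietary_diversity", "cash_income", "ghg_score",
    "gender_equity")
}

#' Assemble the household performance matrix
#'
#' Computes all five performance indicators for a clean household table and
#' applies outlier capping per indicator. Column order is fixed: caloric
#' food security, dietary diversity, cash income, GHG score, gender equity.
#'
#' @param records Clean table from [validate_households()].
#' @param config A [pd_config()].
#' @return A list: `scores` (data.frame `household_id` + 5 indicator
#'   columns, capped), `pca` (the food-security [caloric_food_security()]
#'   fit), `capped` (logical data.frame marking replaced cells).
#' @export
performance_matrix <- function(records, config = pd_config()) {
  suff <- caloric_sufficiency(records$food_availability,
                              config$kcal_requirement)
  months <- food_secure_months(records$food_insecure_months)
  fs <- caloric_food_security(suff, months)

  raw <- data.frame(
    food_security = fs$score,
    dietary_diversity = dietary_diversity(records$hdds_good,
                                          records$hdds_lean),
    cash_income = cash_income(records$farm_income, records$offfarm_income),
    ghg_score = ghg_score(records$ghg_emissions),
    gender_equity = gender_equity(records$female_share,
                                  records$household_type,
                                  config$gender_weights)
  )

  capped <- raw
  for (col in perf_columns()) {
    ub <- config$cap_bounds[[col]]
    capped[[col]] <- cap_outliers(raw[[col]], upper_bound = ub,
                                  percentile = config$cap_percentile,
                                  lower = config$cap_lower)
  }
  flags <- as.data.frame(lapply(perf_columns(), function(col)
    capped[[col]] != raw[[col]]))
  names(flags) <- perf_columns()

  list(
    scores = cbind(data.frame(household_id = records$household_id,
                              stringsAsFactors = FALSE), capped),
    pca = fs$fit,
    capped = flags
  )
}
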