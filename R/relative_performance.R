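#' Village-level market-access proxy
#'
#' Market access cannot be observed directly in the survey; the mean market
#' orientation of all households in the same village (self included) is
#' used as a proxy for the village's potential market access, evening out
#' intra-village differences in market utilisation.
#'
#' @param records Household table with `village_id` and
#'   `market_orientation`.
#' @return Numeric vector aligned with `records`: the village mean for each
#'   household.
#' @export
market_access_proxy <- function(records) {
  mo <- records$market_orientation
  if (any(is.na(mo))) {
    bad <- unique(records$village_id[is.na(mo)])
    nvals <- tapply(!is.na(mo), records$village_id, sum)
    if (any(nvals[bad] == 0)) {
      stop("village(s) with no valid market_orientation: ",
           paste(names(nvals)[nvals == 0], collapse = ", "), call. = FALSE)
    }
  }
  stats::ave(mo, records$village_id,
             FUN = function(v) mean(v, na.rm = TRUE))
}

check_loss <- function(e, tau = 0.5) {
  sum(e * (tau - (e < 0)))
}

#' Fit a median regression
#'
#' Quantile regression at tau = 0.5: coefficients minimise the check loss
#' `sum(rho_0.5(y - X b))` with `rho_0.5(e) = 0.5 |e|`. Factor covariates
#' are dummy-encoded; an intercept is always included. Fitting uses the
#' Barrodale-Roberts simplex (exact vertex solution).
#'
#' @param y Outcome vector.
#' @param X Data.frame of covariates (may have zero columns for an
#'   intercept-only fit); factors allowed.
#' @return An object of class `pd_median_fit`: coefficients, fitted values,
#'   residuals (input order), `tau`, `n`, `k` (estimated coefficients incl.
#'   intercept), `check_loss`, `aic` and the covariate names used.
#' @export
fit_median_regression <- function(y, X = NULL) {
  n <- length(y)
  if (is.null(X) || ncol(as.data.frame(X)) == 0) {
    Xmat <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- as.data.frame(X)
    if (nrow(X) != n) stop("y and X lengths differ", call. = FALSE)
    Xmat <- stats::model.matrix(~ ., data = X)
  }
  qr_ <- qr(Xmat)
  if (qr_$rank < ncol(Xmat)) {
    dropped <- colnames(Xmat)[qr_$pivot[seq(qr_$rank + 1, ncol(Xmat))]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (n <= ncol(Xmat)) {
    stop("need n > number of coefficients (", ncol(Xmat), ")", call. = FALSE)
  }
  # an exact linear fit is the trivial check-loss optimum; take it directly
  # from the QR factorisation (the simplex can stall on fully degenerate
  # problems)
  b_ls <- qr.coef(qr_, y)
  if (max(abs(y - Xmat %*% b_ls)) <= 1e-10 * (1 + max(abs(y)))) {
    fit <- list(coefficients = b_ls,
                residuals = y - as.numeric(Xmat %*% b_ls))
  } else {
    # ties in discrete outcomes routinely make the vertex solution
    # nonunique; any optimum is acceptable under the check-loss contract
    fit <- withCallingHandlers(
      quantreg::rq.fit.br(Xmat, y, tau = 0.5),
      warning = function(w) {
        if (grepl("nonunique", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  }
  res <- as.numeric(fit$residuals)
  out <- list(
    coefficients = stats::setNames(as.numeric(fit$coefficients),
                                   colnames(Xmat)),
    fitted = as.numeric(Xmat %*% fit$coefficients),
    residuals = res,
    tau = 0.5,
    n = n,
    k = ncol(Xmat),
    check_loss = check_loss(res),
    covariates = if (is.null(X)) character() else names(as.data.frame(X))
  )
  out$aic <- quantreg_aic(out)
  class(out) <- "pd_median_fit"
  out
}

#' @export
print.pd_median_fit <- function(x, ...) {
  cat("<pd_median_fit> tau = 0.5, n = ", x$n, ", k = ", x$k,
      ", AIC = ", signif(x$aic, 6), "\n", sep = "")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' AIC for a median regression
#'
#' Profile form under an asymmetric-Laplace working likelihood, constants
#' dropped: `AIC = 2 k + 2 n log(mean check loss)`, with `k` the number of
#' estimated coefficients including the intercept. A perfect fit (zero
#' check loss) returns `-Inf` with a warning.
#'
#' @param fit A `pd_median_fit`.
#' @return The AIC value.
#' @export
quantreg_aic <- function(fit) {
  if (fit$check_loss <= 0) {
    warning("zero check loss (perfect fit); AIC is -Inf", call. = FALSE)
    return(-Inf)
  }
  2 * fit$k + 2 * fit$n * log(fit$check_loss / fit$n)
}

# all subsets of candidate groups, ordered by size then lexicographically
# by group position -- the tie-break order for model selection
subset_order <- function(groups) {
  subs <- list(character())
  for (sz in seq_along(groups)) {
    cmb <- utils::combn(groups, sz, simplify = FALSE)
    subs <- c(subs, cmb)
  }
  subs
}

#' Select a performance model by AIC
#'
#' Exhaustive search over all subsets of the candidate covariate groups
#' (region's dummy columns enter and leave together as one group). Returns
#' the minimum-AIC median-regression fit; exact ties are broken toward
#' fewer covariate groups, then by the order the candidates were given.
#'
#' @param y Outcome vector.
#' @param covariates Data.frame of candidate covariates (factors allowed).
#' @return The winning `pd_median_fit`, with an `aic_table` attribute
#'   (data.frame: subset label, k, check loss, AIC for every subset).
#' @export
select_model <- function(y, covariates) {
  covariates <- as.data.frame(covariates)
  subs <- subset_order(names(covariates))
  fits <- vector("list", length(subs))
  tab <- data.frame(subset = character(length(subs)),
                    k = integer(length(subs)),
                    check_loss = numeric(length(subs)),
                    aic = numeric(length(subs)),
                    stringsAsFactors = FALSE)
  for (i in seq_along(subs)) {
    s <- subs[[i]]
    Xi <- if (length(s)) covariates[, s, drop = FALSE] else NULL
    tab$subset[i] <- if (length(s)) paste(s, collapse = "+") else "(intercept)"
    # individual subsets may be unfittable (e.g. collinear pairs); the
    # search only fails when every subset does
    fits[i] <- list(tryCatch(fit_median_regression(y, Xi),
                             error = function(e) NULL))
    tab$k[i] <- if (is.null(fits[[i]])) NA_integer_ else fits[[i]]$k
    tab$check_loss[i] <- if (is.null(fits[[i]])) NA_real_ else
      fits[[i]]$check_loss
    tab$aic[i] <- if (is.null(fits[[i]])) NA_real_ else fits[[i]]$aic
  }
  if (all(is.na(tab$aic))) stop("no candidate model could be fitted",
                                call. = FALSE)
  best_aic <- min(tab$aic, na.rm = TRUE)
  # exact ties only; subs is already ordered by size then lexicographic
  winner <- which(!is.na(tab$aic) & tab$aic <= best_aic + 1e-9)[1]
  fit <- fits[[winner]]
  attr(fit, "aic_table") <- tab
  fit
}

#' Relative performance residuals
#'
#' Converts absolute indicator scores into relative performance: for each
#' of the five performance dimensions independently, a median regression on
#' household endowments (land, livestock, household size, region, market
#' access) is selected by AIC, and the residual — observed minus expected
#' performance — is the household's relative performance in that dimension.
#'
#' @param perf Result of [performance_matrix()] (or its `scores`
#'   data.frame).
#' @param records The clean household table the scores were computed from
#'   (same row order).
#' @param config A [pd_config()]; `candidate_covariates` picks the
#'   candidate groups.
#' @return A list of class `pd_residuals`: `residuals` (data.frame
#'   `household_id` + 5 residual columns), `models` (per-dimension winning
#'   `pd_median_fit`), `covariates` (the candidate frame used).
#' @export
relative_performance <- function(perf, records, config = pd_config()) {
  scores <- if (is.list(perf) && !is.data.frame(perf)) perf$scores else perf
  if (nrow(scores) != nrow(records)) {
    stop("performance matrix and records are not aligned", call. = FALSE)
  }
  pool <- data.frame(
    land_ha = records$land_ha,
    livestock_tlu = records$livestock_tlu,
    mae = records$mae,
    region = factor(records$region),
    market_access = market_access_proxy(records)
  )
  cand <- pool[, intersect(config$candidate_covariates, names(pool)),
               drop = FALSE]
  # a single-level factor cannot enter a regression
  cand <- cand[, vapply(cand, function(col)
    !is.factor(col) || nlevels(droplevels(col)) > 1, logical(1)),
    drop = FALSE]

  res <- data.frame(household_id = scores$household_id,
                    stringsAsFactors = FALSE)
  models <- list()
  for (col in perf_columns()) {
    fit <- select_model(scores[[col]], cand)
    res[[col]] <- fit$residuals
    models[[col]] <- fit
  }
  out <- list(residuals = res, models = models, covariates = cand)
  class(out) <- "pd_residuals"
  out
}

#' @export
print.pd_residuals <- function(x, ...) {
  cat("<pd_residuals> ", nrow(x$residuals), " households x 5 dimensions\n",
      sep = "")
  for (col in names(x$models)) {
    m <- x$models[[col]]
    cov <- if (length(m$covariates)) paste(m$covariates, collapse = "+")
           else "(intercept)"
    cat(sprintf("  %-18s ~ %s (AIC %.1f)\n", col, cov, m$aic))
  }
  invisible(x)
}
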