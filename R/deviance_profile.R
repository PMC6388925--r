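#' z-transform residual columns
#'
#' Standardises each column over ALL households (not only deviants):
#' subtract the column mean, divide by the sample standard deviation. The
#' constants are returned so deviant-subgroup means can be expressed on the
#' same scale.
#'
#' @param m Numeric matrix or data.frame of residuals.
#' @return List: `scaled` (same shape, each column mean 0 / sd 1), `center`
#'   and `scale` (named constants).
#' @export
z_transform <- function(m) {
  m <- as.matrix(m)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  centers <- colMeans(m)
  scaled <- sweep(sweep(m, 2, centers), 2, sds, "/")
  list(scaled = scaled, center = centers, scale = sds)
}

#' Assign land-by-livestock resource strata
#'
#' Households are binned by deciles of land endowment (rank-based; tied
#' land values share the lower decile) crossed with a median split of
#' livestock holdings (`low` iff TLU is at or below the median — with a
#' median of zero this reads as absence/presence of livestock), giving up
#' to 20 resource strata.
#'
#' @param land Land holdings (ha).
#' @param livestock Livestock holdings (TLU).
#' @param n_deciles Number of land bins (default 10).
#' @return Data.frame: `land_decile` (1..n_deciles), `livestock_class`
#'   (`"low"`/`"high"`), `stratum_id` (e.g. `"3/low"`).
#' @export
assign_strata <- function(land, livestock, n_deciles = 10) {
  n <- length(land)
  if (n < n_deciles) stop("need at least ", n_deciles, " households",
                          call. = FALSE)
  r <- rank(land, ties.method = "min")
  decile <- as.integer(floor((r - 1) * n_deciles / n) + 1)
  if (length(unique(decile)) == 1 && n_deciles > 1) {
    warning("all land values tie; every household in decile 1",
            call. = FALSE)
  }
  med <- stats::median(livestock)
  cls <- ifelse(livestock <= med, "low", "high")
  data.frame(
    land_decile = decile,
    livestock_class = cls,
    stratum_id = paste(decile, cls, sep = "/"),
    stringsAsFactors = FALSE
  )
}

#' Mean deviance by resource stratum
#'
#' Summarises where positive deviance concentrates: mean residual per
#' performance dimension over the positive deviants of each aggregated
#' stratum. Default aggregation follows the reporting layout of the
#' method: paired land deciles (1+2, ..., 9+10) pooled over livestock
#' classes, then the two livestock classes pooled over land, then an
#' overall mean row in raw units and one scaled by the z-transform over all
#' households. Pooled means are household-weighted.
#'
#' @param residuals Data.frame from [relative_performance()]`$residuals`.
#' @param strata Data.frame from [assign_strata()], aligned by row.
#' @param deviant_ids Character vector of positive-deviant household ids.
#' @param pair_deciles Pool deciles in consecutive pairs (default `TRUE`).
#' @return List of class `pd_profile`: `table` (the aggregated layout with
#'   an `n` column), `by_stratum` (all 20 strata), `z_constants`.
#' @export
stratum_mean_deviance <- function(residuals, strata, deviant_ids,
                                  pair_deciles = TRUE) {
  if (!length(deviant_ids)) stop("deviant set is empty", call. = FALSE)
  cols <- perf_columns()
  is_dev <- residuals$household_id %in% deviant_ids
  zt <- z_transform(residuals[, cols])

  row_mean <- function(idx) {
    if (!any(idx)) return(stats::setNames(rep(NA_real_, length(cols)), cols))
    colMeans(residuals[idx, cols, drop = FALSE])
  }
  rows <- list(); labels <- character(); ns <- integer()
  add <- function(label, idx) {
    rows[[length(rows) + 1]] <<- row_mean(idx)
    labels <<- c(labels, label)
    ns <<- c(ns, sum(idx))
  }

  if (pair_deciles) {
    top <- max(strata$land_decile)
    for (d in seq(1, top, by = 2)) {
      pair <- c(d, min(d + 1, top))
      add(paste0("land ", paste(unique(pair), collapse = "+")),
          is_dev & strata$land_decile %in% pair)
    }
  } else {
    for (d in sort(unique(strata$land_decile))) {
      add(paste0("land ", d), is_dev & strata$land_decile == d)
    }
  }
  add("low livestock", is_dev & strata$livestock_class == "low")
  add("high livestock", is_dev & strata$livestock_class == "high")
  add("overall mean", is_dev)

  tab <- as.data.frame(do.call(rbind, rows))
  tab <- cbind(stratum = labels, tab, n = ns, stringsAsFactors = FALSE)

  z_row <- colMeans(zt$scaled[is_dev, , drop = FALSE])
  tab_z <- data.frame(stratum = "overall mean (scaled)",
                      as.list(z_row), n = sum(is_dev),
                      stringsAsFactors = FALSE)
  tab <- rbind(tab, tab_z)
  rownames(tab) <- NULL

  by_stratum <- do.call(rbind, lapply(
    sort(unique(strata$stratum_id)), function(s) {
      idx <- is_dev & strata$stratum_id == s
      data.frame(stratum_id = s, as.list(row_mean(idx)), n = sum(idx),
                 stringsAsFactors = FALSE)
    }))

  out <- list(table = tab, by_stratum = by_stratum,
              z_constants = zt[c("center", "scale")])
  class(out) <- "pd_profile"
  out
}

#' @export
print.pd_profile <- function(x, ...) {
  cat("<pd_profile> mean deviance of positive deviants\n")
  tab <- x$table
  tab[perf_columns()] <- lapply(tab[perf_columns()], function(v) signif(v, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Correlations between deviance dimensions
#'
#' Pearson correlations between the magnitudes of positive deviance in the
#' five dimensions, computed over positive deviants only, with two-sided
#' p-values and a significance flag at p < .05. Reveals trade-offs in
#' realising deviant outcomes.
#'
#' @param residuals Residual data.frame (with `household_id`).
#' @param deviant_ids Positive-deviant household ids (at least 3).
#' @return List: `r` (5x5 matrix), `p` (5x5), `significant` (logical 5x5),
#'   `n`.
#' @export
deviance_correlations <- function(residuals, deviant_ids) {
  cols <- perf_columns()
  d <- residuals[residuals$household_id %in% deviant_ids, cols]
  if (nrow(d) < 3) stop("need at least 3 deviants", call. = FALSE)
  k <- length(cols)
  r <- diag(k); p <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(p) <- list(cols, cols)
  diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    if (stats::sd(d[[i]]) == 0 || stats::sd(d[[j]]) == 0) {
      warning("constant column among deviants: correlation undefined",
              call. = FALSE)
      r[i, j] <- r[j, i] <- NA_real_
      next
    }
    ct <- stats::cor.test(d[[i]], d[[j]], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p, significant = !is.na(p) & p < 0.05 & r != 1,
       n = nrow(d))
}

#' Compare positive deviants with other households
#'
#' Two-group comparison table: group means and a two-sample t-test for
#' numeric household characteristics, group proportions and a chi-square
#' test for categorical ones, plus group medians of the five performance
#' indicators. Significance flagged at p < .05 (unadjusted).
#'
#' @param records Clean household table.
#' @param performance `scores` data.frame from [performance_matrix()].
#' @param deviant_ids Positive-deviant household ids.
#' @param test `"welch"` (default) or `"student"` for the numeric
#'   comparisons.
#' @return Data.frame: characteristic, type, deviant and other group
#'   summary values, p-value, significance flag.
#' @export
compare_groups <- function(records, performance, deviant_ids,
                           test = c("welch", "student")) {
  test <- match.arg(test)
  g <- records$household_id %in% deviant_ids
  if (!any(g) || all(g)) stop("both groups must be non-empty", call. = FALSE)

  num_chars <- c("mae", "land_ha", "livestock_tlu", "crop_diversity",
                 "livestock_diversity")
  cat_chars <- c("region", "household_type")
  rows <- list()
  safe_p <- function(expr) tryCatch(expr, error = function(e) {
    warning(conditionMessage(e), call. = FALSE); NA_real_ })

  for (v in num_chars) {
    x <- records[[v]][g]; y <- records[[v]][!g]
    p <- safe_p(stats::t.test(x, y, var.equal = (test == "student"))$p.value)
    rows[[length(rows) + 1]] <- data.frame(
      characteristic = paste0("mean ", v), type = "numeric",
      deviants = mean(x), others = mean(y), p_value = p,
      stringsAsFactors = FALSE)
  }
  for (v in cat_chars) {
    tabl <- table(records[[v]], g)
    p <- safe_p(suppressWarnings(stats::chisq.test(tabl)$p.value))
    for (lev in rownames(tabl)) {
      rows[[length(rows) + 1]] <- data.frame(
        characteristic = paste0("share ", v, "=", lev), type = "categorical",
        deviants = tabl[lev, "TRUE"] / sum(g),
        others = tabl[lev, "FALSE"] / sum(!g),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  gd <- performance$household_id %in% deviant_ids
  for (v in perf_columns()) {
    rows[[length(rows) + 1]] <- data.frame(
      characteristic = paste0("median ", v), type = "performance",
      deviants = stats::median(performance[[v]][gd]),
      others = stats::median(performance[[v]][!gd]),
      p_value = NA_real_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p_value) & out$p_value < 0.05
  rownames(out) <- NULL
  out
}
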