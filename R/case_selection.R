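#' Crowding distance
#'
#' Diversity measure over a set of points: per characteristic, points are
#' sorted and each interior point's contribution is the gap between its
#' sorted neighbours divided by the characteristic's range; the two
#' boundary points contribute a finite 2 per characteristic (strictly above
#' the interior maximum of 1, so extremes stay the most diverse while the
#' mean remains usable as an objective). A constant characteristic
#' contributes 0 to everyone. The distance is the sum over
#' characteristics.
#'
#' @param points Numeric matrix, one point per row (at least 2 rows).
#' @return Numeric vector of distances, one per row.
#' @export
crowding_distance <- function(points) {
  points <- as.matrix(points)
  m <- nrow(points)
  if (m < 2) stop("crowding distance needs at least 2 points", call. = FALSE)
  d <- numeric(m)
  for (j in seq_len(ncol(points))) {
    col <- points[, j]
    rng <- max(col) - min(col)
    if (rng == 0) next
    ord <- order(col)
    contrib <- numeric(m)
    contrib[ord[1]] <- 2
    contrib[ord[m]] <- 2
    if (m > 2) {
      for (i in seq(2, m - 1)) {
        contrib[ord[i]] <- (col[ord[i + 1]] - col[ord[i - 1]]) / rng
      }
    }
    d <- d + contrib
  }
  d
}

# objective: mean crowding distance of a point set (0 for < 2 points)
mean_crowding <- function(points) {
  if (nrow(points) < 2) return(0)
  mean(crowding_distance(points))
}

#' Select a diverse positive-deviant case per stratum
#'
#' Picks at most one positive deviant per non-empty resource stratum for
#' qualitative follow-up, maximising the mean crowding distance of the
#' selected set over four household characteristics (household size, land,
#' livestock, market access; region is excluded as categorical). Within a
#' stratum, rank-1 deviants are always preferred over rank-2: the candidate
#' pool is the stratum's rank-1 deviants when any exist. Characteristics
#' are min-max normalised within the deviant pool. The stepwise procedure
#' is a deterministic greedy pass over strata (ascending land decile, low
#' livestock before high), each step adding the candidate that maximises
#' the provisional set's mean crowding distance, followed by single-swap
#' improvement passes until no swap raises the mean.
#'
#' @param deviants Data.frame with one row per positive deviant: columns
#'   `household_id`, `front_rank`, `land_decile`, `livestock_class`, plus
#'   the four characteristics `mae`, `land_ha`, `livestock_tlu`,
#'   `market_access`.
#' @param crowding_mode `"selection"` (distances computed within the
#'   provisional selection; default) or `"pool"` (fixed distances within
#'   the full deviant pool).
#' @param all_strata Optional [assign_strata()] table for the full
#'   household sample, used to flag strata containing households but no
#'   deviant.
#' @return List of class `pd_selection`: `selection` (data.frame stratum,
#'   household_id, front_rank), `mean_crowding_distance`, `empty_strata`
#'   (stratum ids with households but no deviant, when `all_strata` given).
#' @export
select_diverse_cases <- function(deviants,
                                 crowding_mode = c("selection", "pool"),
                                 all_strata = NULL) {
  crowding_mode <- match.arg(crowding_mode)
  need <- c("household_id", "front_rank", "land_decile", "livestock_class",
            "mae", "land_ha", "livestock_tlu", "market_access")
  miss <- setdiff(need, names(deviants))
  if (length(miss)) stop("deviants table lacks: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!nrow(deviants)) stop("no deviants to select from", call. = FALSE)

  chars <- as.matrix(deviants[, c("mae", "land_ha", "livestock_tlu",
                                  "market_access")])
  norm <- apply(chars, 2, function(col) {
    rng <- max(col) - min(col)
    if (rng == 0) rep(0, length(col)) else (col - min(col)) / rng
  })
  norm <- matrix(norm, nrow = nrow(deviants),
                 dimnames = list(NULL, colnames(chars)))

  # candidate pool per stratum: rank-1 deviants when any exist, else rank-2+
  strata <- unique(deviants[, c("land_decile", "livestock_class")])
  strata <- strata[order(strata$land_decile,
                         match(strata$livestock_class, c("low", "high"))), ]
  pools <- lapply(seq_len(nrow(strata)), function(i) {
    idx <- which(deviants$land_decile == strata$land_decile[i] &
                 deviants$livestock_class == strata$livestock_class[i])
    best <- min(deviants$front_rank[idx])
    idx <- idx[deviants$front_rank[idx] == best]
    idx[order(deviants$household_id[idx])]
  })

  pool_dist <- if (crowding_mode == "pool" && nrow(deviants) >= 2) {
    crowding_distance(norm)
  } else NULL

  objective <- function(sel_idx) {
    if (crowding_mode == "pool") {
      if (!length(sel_idx)) return(0)
      mean(pool_dist[sel_idx])
    } else {
      mean_crowding(norm[sel_idx, , drop = FALSE])
    }
  }

  # greedy pass
  sel <- integer(0)
  for (pool in pools) {
    scores <- vapply(pool, function(cand) objective(c(sel, cand)),
                     numeric(1))
    sel <- c(sel, pool[which.max(scores)])
  }

  # single-swap improvement passes
  repeat {
    improved <- FALSE
    for (s in seq_along(pools)) {
      for (cand in pools[[s]]) {
        if (cand == sel[s]) next
        trial <- sel; trial[s] <- cand
        if (objective(trial) > objective(sel) + 1e-12) {
          sel <- trial; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }

  out <- list(
    selection = data.frame(
      stratum_id = paste(strata$land_decile, strata$livestock_class,
                         sep = "/"),
      land_decile = strata$land_decile,
      livestock_class = strata$livestock_class,
      household_id = deviants$household_id[sel],
      front_rank = deviants$front_rank[sel],
      stringsAsFactors = FALSE
    ),
    mean_crowding_distance = objective(sel),
    empty_strata = if (!is.null(all_strata)) {
      setdiff(unique(all_strata$stratum_id),
              paste(strata$land_decile, strata$livestock_class, sep = "/"))
    } else character()
  )
  class(out) <- "pd_selection"
  out
}

#' @export
print.pd_selection <- function(x, ...) {
  cat("<pd_selection> ", nrow(x$selection), " cases, mean crowding distance ",
      signif(x$mean_crowding_distance, 4), "\n", sep = "")
  print(x$selection, row.names = FALSE)
  invisible(x)
}
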