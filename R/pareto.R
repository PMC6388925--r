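#' Pareto dominance
#'
#' `a` dominates `b` when `a` is at least as good in every dimension and
#' strictly better in at least one (all dimensions maximisation-oriented).
#' A point never dominates itself; comparisons are exact on the raw values
#' (ties are structural and lead to co-ranking, not domination).
#'
#' @param a,b Numeric vectors of equal length.
#' @return `TRUE` iff `a` dominates `b`.
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  all(a >= b) && any(a > b)
}

#' Non-dominated front
#'
#' Indices of the rows of `m` not dominated by any other row. Duplicate
#' rows are mutually non-dominating and appear on the front together.
#'
#' @param m Numeric matrix, one point per row, all columns
#'   maximisation-oriented.
#' @return Integer vector of row indices on the front.
#' @export
nondominated_front <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n == 0) return(integer())
  d <- ncol(m)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    ge <- rowSums(m >= rep(m[i, ], each = n)) == d
    gt <- rowSums(m > rep(m[i, ], each = n)) > 0
    dominators <- ge & gt
    dominators[i] <- FALSE
    if (any(dominators)) keep[i] <- FALSE
  }
  which(keep)
}

#' Pareto front ranks
#'
#' Iteratively peels non-dominated fronts: rank 1 is the front of the full
#' set; rank r is the front of what remains after removing ranks below r.
#' Peeling stops after `max_front_rank` fronts; deeper rows are left
#' unranked (`NA`). Households on ranks up to `max_front_rank` are the
#' positive deviants.
#'
#' @param m Numeric matrix of relative-performance scores, one household
#'   per row, higher is better in every column.
#' @param max_front_rank Deepest front to materialise (default 2).
#' @return Object of class `pd_pareto`: `front_rank` (integer per row, `NA`
#'   beyond `max_front_rank`), `positive_deviant` (logical), `counts`
#'   (households per rank), `max_front_rank`.
#' @export
pareto_ranks <- function(m, max_front_rank = 2) {
  m <- as.matrix(m)
  if (max_front_rank < 1) stop("max_front_rank must be >= 1", call. = FALSE)
  n <- nrow(m)
  rank_ <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  r <- 1L
  while (length(remaining) && r <= max_front_rank) {
    fr <- nondominated_front(m[remaining, , drop = FALSE])
    rank_[remaining[fr]] <- r
    remaining <- remaining[-fr]
    r <- r + 1L
  }
  counts <- table(factor(rank_, levels = seq_len(max_front_rank)))
  out <- list(
    front_rank = rank_,
    positive_deviant = !is.na(rank_),
    counts = stats::setNames(as.integer(counts), names(counts)),
    max_front_rank = as.integer(max_front_rank)
  )
  class(out) <- "pd_pareto"
  out
}

#' @export
print.pd_pareto <- function(x, ...) {
  cat("<pd_pareto> ", sum(x$positive_deviant), " positive deviants of ",
      length(x$front_rank), " households (",
      paste(sprintf("rank %s: %d", names(x$counts), x$counts),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Positive-deviant household ids
#'
#' @param result A `pd_pareto` from [pareto_ranks()].
#' @param household_ids Character vector aligned with the ranked matrix
#'   rows.
#' @return Character vector of ids with front rank at most
#'   `max_front_rank`.
#' @export
positive_deviants <- function(result, household_ids) {
  if (length(household_ids) != length(result$front_rank)) {
    stop("household_ids not aligned with ranks", call. = FALSE)
  }
  household_ids[result$positive_deviant]
}
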