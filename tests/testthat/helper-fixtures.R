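# Small deterministic fixtures built in code.

# fixed indicator column order used throughout
perf_cols <- function() c("food_security", "dietary_diversity",
                          "cash_income", "ghg_score", "gender_equity")

# a tiny hand-written household table (valid by construction)
make_records <- function(n = 6) {
  stopifnot(n <= 12)
  data.frame(
    household_id = sprintf("H%02d", seq_len(n)),
    village_id = rep(c("V1", "V2"), length.out = n),
    region = rep(c("R1", "R2"), length.out = n),
    mae = c(2.1, 4.6, 3.2, 6.8, 2.9, 5.4, 4.1, 3.7, 6.1, 2.5, 5.9,
            4.8)[seq_len(n)],
    household_type = rep(c("couple", "single_woman", "couple", "single_man",
                           "couple", "married_woman_absent_spouse"),
                         length.out = n),
    land_ha = seq(0.5, 6, length.out = n),
    livestock_tlu = rep(c(0, 1.5), length.out = n),
    crop_diversity = rep(c(3, 5), length.out = n),
    livestock_diversity = rep(c(0, 2), length.out = n),
    market_orientation = seq(0.1, 0.6, length.out = n),
    food_availability = seq(1200, 3800, length.out = n),
    food_insecure_months = rep(c(4, 1), length.out = n),
    hdds_good = rep(c(6, 9), length.out = n),
    hdds_lean = rep(c(3, 7), length.out = n),
    farm_income = seq(100, 900, length.out = n),
    offfarm_income = rep(c(0, 250), length.out = n),
    ghg_emissions = seq(150, 900, length.out = n),
    female_share = seq(0.2, 0.7, length.out = n),
    male_share = 1 - seq(0.2, 0.7, length.out = n),
    stringsAsFactors = FALSE
  )
}

# a validated synthetic table of moderate size, cached per session
synth_clean <- local({
  cache <- NULL
  function(n = 150, seed = 42, ...) {
    key <- paste(n, seed, ...)
    if (is.null(cache[[key]])) {
      gen <- generate_households(synthetic_spec(n_households = n,
                                                seed = seed, ...))
      cache[[key]] <<- list(
        records = validate_households(gen$records)$records,
        truth = gen$truth)
    }
    cache[[key]]
  }
})

# independent brute-force check-loss minimiser: the exact median-regression
# optimum is attained at a vertex interpolating p+1 observations, so
# enumerate all such exact fits and keep the best
oracle_median_fit <- function(y, Xmat) {
  n <- length(y)
  p <- ncol(Xmat)
  best <- NULL
  best_loss <- Inf
  for (idx in utils::combn(n, p, simplify = FALSE)) {
    A <- Xmat[idx, , drop = FALSE]
    if (abs(det(A)) < 1e-10) next
    b <- solve(A, y[idx])
    loss <- sum(0.5 * abs(y - Xmat %*% b))
    if (loss < best_loss - 1e-12) {
      best_loss <- loss
      best <- b
    }
  }
  list(coefficients = as.numeric(best), check_loss = best_loss)
}

# independent pairwise peel oracle for Pareto ranks
oracle_pareto_ranks <- function(m, max_rank) {
  m <- as.matrix(m)
  n <- nrow(m)
  dom <- function(a, b) all(m[a, ] >= m[b, ]) && any(m[a, ] > m[b, ])
  rank_ <- rep(NA_integer_, n)
  left <- seq_len(n)
  r <- 1L
  while (length(left) && r <= max_rank) {
    on_front <- vapply(left, function(i)
      !any(vapply(left, function(j) j != i && dom(j, i), logical(1))),
      logical(1))
    rank_[left[on_front]] <- r
    left <- left[!on_front]
    r <- r + 1L
  }
  rank_
}
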