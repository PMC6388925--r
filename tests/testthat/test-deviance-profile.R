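test_that("z-transform standardises columns with sample sd", {
  zt <- z_transform(matrix(c(1, 2, 3), dimnames = list(NULL, "a")))
  expect_equal(as.numeric(zt$scaled), c(-1, 0, 1))   # sd({1,2,3}) = 1
  expect_equal(unname(zt$scale), 1)

  set.seed(2)
  m <- matrix(rnorm(60, 5, 3), 20, 3)
  zt2 <- z_transform(m)
  expect_equal(unname(colMeans(zt2$scaled)), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(apply(zt2$scaled, 2, sd)), rep(1, 3),
               tolerance = 1e-9)
  # idempotent on standardised input
  zt3 <- z_transform(zt2$scaled)
  expect_equal(zt3$scaled, zt2$scaled, tolerance = 1e-9)

  expect_error(z_transform(cbind(a = rep(1, 5), b = 1:5)), "constant")
})

test_that("strata cross land deciles with a livestock median split", {
  land <- seq(1, 20)
  livestock <- rep(c(0, 1), times = 10)   # one of each class per decile
  st <- assign_strata(land, livestock)
  expect_equal(sort(unique(st$land_decile)), 1:10)
  expect_equal(as.vector(table(st$land_decile)), rep(2, 10))
  expect_equal(length(unique(st$stratum_id)), 20)
  expect_equal(as.vector(table(st$stratum_id)), rep(1, 20))

  # all-zero livestock: median 0, everyone low
  st0 <- assign_strata(land, rep(0, 20))
  expect_true(all(st0$livestock_class == "low"))

  # all land tied: everyone decile 1, with a warning
  expect_warning(st1 <- assign_strata(rep(2, 20), rep(c(0, 1), 10)), "tie")
  expect_true(all(st1$land_decile == 1))

  # rank-based: invariant to monotone transforms of land
  st2 <- assign_strata(log1p(land), livestock)
  expect_equal(st2$land_decile, st$land_decile)

  # ties share the lower decile
  land_t <- c(rep(1, 5), 2:16)
  st3 <- assign_strata(land_t, rep(0, 20))
  expect_true(all(st3$land_decile[1:5] == 1))

  # sizes differ by at most 1 under distinct values
  st4 <- assign_strata(rnorm(53), rep(0, 53))
  expect_lte(diff(range(table(st4$land_decile))), 1)
})

test_that("stratum deviance means aggregate consistently", {
  dat <- synth_clean(n = 150, seed = 42)
  rec <- dat$records
  rel <- relative_performance(performance_matrix(rec), rec)
  st <- assign_strata(rec$land_ha, rec$livestock_tlu)
  pr <- pareto_ranks(as.matrix(rel$residuals[, -1]), 2)
  dev_ids <- positive_deviants(pr, rec$household_id)

  prof <- stratum_mean_deviance(rel$residuals, st, dev_ids)
  tab <- prof$table
  is_dev <- rel$residuals$household_id %in% dev_ids

  # overall mean row equals the mean over all deviants regardless of strata
  overall <- tab[tab$stratum == "overall mean", ]
  expect_equal(unlist(overall[perf_cols()]),
               colMeans(rel$residuals[is_dev, perf_cols()]),
               ignore_attr = TRUE)
  expect_equal(overall$n, sum(is_dev))

  # paired-decile rows partition the deviants
  land_rows <- grep("^land ", tab$stratum)
  expect_equal(sum(tab$n[land_rows]), sum(is_dev))

  # z-scaled overall row: scaling constants come from ALL households
  zt <- z_transform(rel$residuals[, perf_cols()])
  expect_equal(unlist(tab[tab$stratum == "overall mean (scaled)",
                          perf_cols()]),
               colMeans(zt$scaled[is_dev, ]), ignore_attr = TRUE)
  expect_equal(unname(colMeans(zt$scaled)), rep(0, 5), tolerance = 1e-9)

  # a stratum holding a single deviant reproduces its residual vector
  one <- prof$by_stratum[prof$by_stratum$n == 1, ]
  if (nrow(one)) {
    sid <- one$stratum_id[1]
    idx <- which(st$stratum_id == sid & is_dev)
    expect_equal(unlist(one[1, perf_cols()]),
                 unlist(rel$residuals[idx, perf_cols()]),
                 ignore_attr = TRUE)
  }

  # empty deviant set is rejected
  expect_error(stratum_mean_deviance(rel$residuals, st, character()),
               "empty")
})

test_that("deviance correlations match the textbook formula", {
  res <- data.frame(
    household_id = letters[1:5],
    food_security = c(1, 2, 3, 4, 5),
    dietary_diversity = c(2, 1, 4, 3, 6),
    cash_income = c(5, 4, 3, 2, 1),
    ghg_score = c(1, 3, 2, 5, 4),
    gender_equity = c(2, 2, 3, 5, 1)
  )
  dc <- deviance_correlations(res, res$household_id)
  # hand oracle: cov / (sd * sd)
  hand <- function(x, y) {
    n <- length(x)
    sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sd(x) * sd(y))
  }
  expect_equal(dc$r["food_security", "dietary_diversity"],
               hand(res$food_security, res$dietary_diversity))
  expect_equal(dc$r["food_security", "cash_income"], -1)  # exact reversal
  expect_equal(unname(diag(dc$r)), rep(1, 5))
  expect_equal(dc$r, t(dc$r))
  expect_true(all(dc$r >= -1 & dc$r <= 1))
  expect_error(deviance_correlations(res, letters[1:2]), "at least 3")
})

test_that("group comparisons flag planted differences, not identical groups", {
  rec <- synth_clean(n = 100, seed = 30)$records
  perf <- performance_matrix(rec)$scores

  # arbitrary split of an exchangeable sample: nothing should be flagged
  ids_half <- rec$household_id[seq(1, 100, by = 2)]
  cmp <- suppressWarnings(compare_groups(rec, perf, ids_half))
  expect_false(any(cmp$significant[cmp$type == "numeric"]))

  # planted numeric and categorical contrasts must both be flagged
  rec2 <- rec
  shift_ids <- rec$household_id[1:30]
  rec2$land_ha[1:30] <- rec2$land_ha[1:30] + 50
  rec2$household_type <- rep(c("couple", "single_woman"), times = c(30, 70))
  cmp2 <- suppressWarnings(compare_groups(rec2, perf, shift_ids))
  expect_true(cmp2$significant[cmp2$characteristic == "mean land_ha"])
  expect_true(any(cmp2$significant[cmp2$type == "categorical"]))

  # medians of the five indicators reported per group
  expect_equal(sum(cmp$type == "performance"), 5)
  med_row <- cmp[cmp$characteristic == "median cash_income", ]
  in_g <- perf$household_id %in% ids_half
  expect_equal(med_row$deviants, median(perf$cash_income[in_g]))

  expect_error(compare_groups(rec, perf, character()), "non-empty")
})
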