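test_that("caloric sufficiency is the capped requirement ratio", {
  expect_equal(caloric_sufficiency(2550, 2550), 1)
  expect_equal(caloric_sufficiency(5100, 2550), 1)   # capped at 100%
  expect_equal(caloric_sufficiency(1275, 2550), 0.5)
  expect_error(caloric_sufficiency(-1, 2550), "non-negative")
  # non-decreasing and bounded
  x <- seq(0, 10000, by = 250)
  s <- caloric_sufficiency(x, 2550)
  expect_true(all(diff(s) >= 0))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("food-secure months complement the insecure count", {
  expect_equal(food_secure_months(c(0, 3, 12)), c(12, 9, 0))
  expect_error(food_secure_months(13), "\\[0, 12\\]")
})

test_that("dietary diversity is the harmonic mean with a zero convention", {
  expect_equal(dietary_diversity(6, 3), 4)
  expect_equal(dietary_diversity(4, 4), 4)
  expect_equal(dietary_diversity(5, 0), 0)
  expect_error(dietary_diversity(13, 3), "\\[0, 12\\]")
  # harmonic <= arithmetic, equality iff equal
  g <- rep(0:12, each = 13); l <- rep(0:12, times = 13)
  h <- dietary_diversity(g, l)
  expect_true(all(h <= (g + l) / 2 + 1e-12))
  eq <- abs(h - (g + l) / 2) < 1e-12
  expect_equal(eq, g == l)
})

test_that("cash income sums the two sources", {
  expect_equal(cash_income(100, 50), 150)
  expect_equal(cash_income(0, 0), 0)
  expect_equal(cash_income(686, 0), 686)
  expect_error(cash_income(-5, 0), "non-negative")
})

test_that("GHG score is an order-reversing sign flip", {
  expect_equal(ghg_score(395), -395)
  expect_equal(ghg_score(0), 0)
  expect_warning(out <- ghg_score(-10), "negative")
  expect_equal(out, 10)
  e <- sort(runif(20, 0, 1000))
  expect_true(all(diff(ghg_score(e)) < 0))
})

test_that("gender equity peaks at shared decision-making", {
  expect_equal(gender_equity(0.5, "couple"), c(couple = 1))
  expect_equal(unname(gender_equity(0, "couple")), 0)
  expect_equal(unname(gender_equity(0, "single_man")), 0.5)
  expect_error(gender_equity(0.5, "unknown_type"), "unknown household")
  # unique maximum at 0.5, symmetric about it, for every type
  shares <- seq(0, 1, by = 0.05)
  for (tp in c("couple", "single_woman", "single_man",
               "married_woman_absent_spouse", "married_man_absent_spouse")) {
    sc <- unname(gender_equity(shares, rep(tp, length(shares))))
    expect_equal(sc, rev(sc))                       # symmetry
    expect_equal(which(sc == max(sc)), which(shares == 0.5))
  }
})

test_that("outlier capping replaces out-of-range values by the in-range max", {
  expect_equal(cap_outliers(c(1, 2, 3, 1000), upper_bound = 10),
               c(1, 2, 3, 3))
  v <- c(5, 1, 4, 2)
  expect_equal(cap_outliers(v, upper_bound = 10), v)   # identity when in range
  expect_error(cap_outliers(c(100, 200), upper_bound = 10), "all values")
  # lower-end capping is available
  expect_equal(cap_outliers(c(-50, 1, 2, 3), upper_bound = 10,
                            lower_bound = 0), c(1, 1, 2, 3))
})

test_that("capping is idempotent and never exceeds the in-range maximum", {
  set.seed(11)
  for (rep in 1:20) {
    x <- c(rlnorm(80, 0, 1), rlnorm(3, 4, 1))  # heavy right tail
    once <- cap_outliers(x, percentile = 0.95)
    twice <- cap_outliers(once, percentile = 0.95)
    expect_equal(twice, once)
    bound <- quantile(x, 0.95, names = FALSE)
    expect_lte(max(once), max(x[x <= bound]))
    expect_equal(once[x <= bound], x[x <= bound])  # in-range untouched
  }
})

test_that("food-security composite orients PC-1 with both measures", {
  # perfectly correlated measures: PC-1 explains all variance
  a <- seq(0.1, 1, length.out = 20)
  fs <- caloric_food_security(a, 2 + 10 * a)
  expect_equal(fs$fit$variance_fraction[[1]], 1)
  expect_equal(sum(fs$fit$variance_fraction), 1)

  # independent measures at large n: PC-1 near 50%
  set.seed(5)
  fs2 <- caloric_food_security(runif(4000), rnorm(4000))
  expect_lt(abs(fs2$fit$variance_fraction[1] - 0.5), 0.05)

  # orientation: score correlates non-negatively with both inputs
  set.seed(6)
  suff <- runif(200)
  months <- 12 * pmin(pmax(suff + rnorm(200, 0, 0.3), 0), 1)
  fs3 <- caloric_food_security(suff, months)
  expect_gte(cor(fs3$score, suff), 0)
  expect_gte(cor(fs3$score, months), 0)

  expect_error(caloric_food_security(rep(1, 10), 1:10), "constant")
})

test_that("performance_matrix composes the scalar indicator operations", {
  rec <- synth_clean(n = 60, seed = 9)$records
  cfg <- pd_config()
  pm <- performance_matrix(rec, cfg)
  expect_equal(nrow(pm$scores), nrow(rec))
  expect_equal(names(pm$scores),
               c("household_id", "food_security", "dietary_diversity",
                 "cash_income", "ghg_score", "gender_equity"))

  # composition oracle: each column equals the capped scalar op outputs
  suff <- caloric_sufficiency(rec$food_availability, cfg$kcal_requirement)
  fs <- caloric_food_security(suff,
                              food_secure_months(rec$food_insecure_months))
  expect_equal(pm$scores$food_security,
               cap_outliers(fs$score, percentile = cfg$cap_percentile))
  expect_equal(pm$scores$cash_income,
               cap_outliers(cash_income(rec$farm_income, rec$offfarm_income),
                            percentile = cfg$cap_percentile))
  expect_equal(pm$scores$gender_equity,
               cap_outliers(unname(gender_equity(rec$female_share,
                                                 rec$household_type)),
                            percentile = cfg$cap_percentile))
  expect_true(all(vapply(pm$scores[, -1], function(col) all(is.finite(col)),
                         logical(1))))

  # a single capped cell is flagged
  expect_equal(dim(pm$capped), c(nrow(rec), 5L))
})
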