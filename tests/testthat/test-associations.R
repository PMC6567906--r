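test_that("Woolf odds ratios reproduce hand arithmetic", {
  r <- odds_ratio_2x2(31, 32, 18, 83)
  expect_equal(r$estimate, (31 * 83) / (32 * 18))
  expect_equal(signif(r$estimate, 3), 4.47)
  expect_equal(signif(r$ci_low, 3), 2.20)
  expect_equal(signif(r$ci_high, 3), 9.08)

  expect_equal(signif(odds_ratio_2x2(18, 45, 5, 96)$estimate, 3), 7.68)
  expect_equal(odds_ratio_2x2(1, 1, 1, 1)$estimate, 1)

  # inverse-table product is exactly one, with and without correction
  set.seed(21)
  for (i in 1:20) {
    cells <- rpois(4, 10)
    f <- odds_ratio_2x2(cells[1], cells[2], cells[3], cells[4])
    b <- odds_ratio_2x2(cells[2], cells[1], cells[4], cells[3])
    expect_equal(f$estimate * b$estimate, 1, tolerance = 1e-12)
    expect_true(f$ci_low <= f$estimate && f$estimate <= f$ci_high)
  }
})

test_that("zero cells trigger the Haldane-Anscombe correction", {
  r <- odds_ratio_2x2(5, 0, 3, 7)
  expect_true(r$corrected)
  expect_equal(r$estimate, (5.5 * 7.5) / (0.5 * 3.5))
  expect_error(odds_ratio_2x2(0, 0, 0, 0), "margin")
  expect_error(odds_ratio_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("logistic regression on one binary covariate equals the 2x2 OR", {
  set.seed(31)
  for (i in 1:5) {
    n <- 120
    x <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, plogis(-0.5 + 1.2 * x))
    if (length(unique(y)) < 2) next
    tab <- c(a = sum(y & x), b = sum(!y & x), c = sum(y & !x),
             d = sum(!y & !x))
    if (any(tab == 0)) next
    lf <- logistic_fit(data.frame(x = x, y = y), y ~ x)
    or <- odds_ratio_2x2(tab["a"], tab["b"], tab["c"], tab["d"])
    expect_equal(lf$estimate, or$estimate, tolerance = 1e-6)
  }
})

test_that("the diagnosis-group model reproduces the published odds ratios", {
  out <- diagnosis_odds_ratios()
  expect_equal(signif(out$estimate[out$term == "MCTD"], 3), 8.50)
  expect_equal(signif(out$estimate[out$term == "SLE"], 3), 2.55)
  expect_equal(signif(out$estimate[out$term == "SS"], 3), 8.81)
  expect_true(all(out$ci_low <= out$estimate & out$estimate <= out$ci_high))
})

test_that("degenerate logistic inputs error or get flagged", {
  expect_error(logistic_fit(data.frame(x = rnorm(10), y = 1), y ~ x),
               "single class")
  # perfectly separated covariate
  d <- data.frame(x = c(rep(0, 20), rep(1, 20)),
                  y = c(rep(0, 20), rep(1, 20)))
  expect_warning(out <- logistic_fit(d, y ~ x), "separation")
  expect_true(out$flagged)
})

test_that("linear fits recover planted coefficients", {
  set.seed(41)
  x <- rnorm(100)
  y <- 2 * x + rnorm(100, sd = 0.01)
  lf <- linear_fit(data.frame(x = x, y = y), y ~ x)
  expect_equal(lf$estimate, 2, tolerance = 0.01)
  expect_true(lf$ci_low <= lf$estimate & lf$estimate <= lf$ci_high)

  yc <- rep(3, 100)
  lf2 <- linear_fit(data.frame(x = x, y = yc), y ~ x)
  expect_equal(lf2$estimate, 0, tolerance = 1e-12)

  d <- data.frame(x = x, x2 = 2 * x, y = y)
  expect_error(linear_fit(d, y ~ x + x2), "collinear.*x2")
})

test_that("rank tests match a brute-force U statistic", {
  # identical distributions give p = 1
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  expect_equal(rank_tests(v, g)$p_value, 1)
  expect_equal(rank_tests(rep(5, 10), rep(c("a", "b"), 5))$p_value, 1)

  # complete separation: U = 0 for the lower group
  sep <- rank_tests(c(1:10, 11:20), rep(c("a", "b"), each = 10))
  expect_true(sep$statistic %in% c(0, 100))
  expect_lt(sep$p_value, 1e-3)

  # brute-force pairwise count oracle on random data
  set.seed(51)
  for (i in 1:10) {
    x <- sample(1:8, 6, replace = TRUE)
    y <- sample(1:8, 6, replace = TRUE)
    u_brute <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    got <- rank_tests(c(x, y), rep(c("a", "b"), each = 6))
    expect_equal(unname(got$statistic), u_brute)
  }

  # more than two groups switches to Kruskal-Wallis
  kw <- rank_tests(c(1:5, 6:10, 11:15), rep(c("a", "b", "c"), each = 5))
  expect_identical(kw$method, "Kruskal-Wallis")
  expect_lt(kw$p_value, 0.01)
  expect_error(rank_tests(1:5, rep("a", 5)), "at least 2")
})

test_that("Dunn pairwise z-tests are symmetric and adjusted", {
  set.seed(61)
  v <- c(rnorm(15), rnorm(15, 2), rnorm(15, 4))
  g <- rep(c("a", "b", "c"), each = 15)
  d <- dunn_test(v, g)
  expect_equal(nrow(d), 3)
  expect_true(all(d$p_adjusted >= d$p_value))
  expect_true(all(d$p_adjusted <= 1))
  # extreme groups differ most
  expect_equal(which.max(abs(d$z)),
               which(d$group1 == "a" & d$group2 == "c"))
})

test_that("Fisher exact p values match hypergeometric enumeration", {
  expect_equal(fisher_exact(5, 0, 0, 5), 2 / choose(10, 5))
  expect_equal(fisher_exact(1, 1, 1, 1), 1)
  expect_equal(fisher_exact(3, 7, 5, 2), fisher_exact(5, 2, 3, 7))
})

test_that("the Spearman matrix matches the rank formula and masks correctly", {
  set.seed(71)
  x <- rnorm(30)
  d <- data.frame(x = x, ex = exp(x), neg = -x, z = rnorm(30))
  sm <- spearman_matrix(d)
  expect_equal(sm$r["x", "ex"], 1)
  expect_equal(sm$r["x", "neg"], -1)
  expect_equal(sm$r, t(sm$r))
  expect_equal(unname(diag(sm$r)), rep(1, 4))
  expect_true(sm$significant["x", "ex"])

  # direct rank-formula oracle, no ties
  x10 <- rnorm(10); y10 <- rnorm(10)
  dd <- sum((rank(x10) - rank(y10))^2)
  r_oracle <- 1 - 6 * dd / (10 * (10^2 - 1))
  sm2 <- spearman_matrix(data.frame(a = x10, b = y10))
  expect_equal(sm2$r["a", "b"], r_oracle, tolerance = 1e-12)

  # constant vectors are masked with NA correlations
  sm3 <- spearman_matrix(data.frame(a = x10, k = rep(1, 10)))
  expect_true(is.na(sm3$r["a", "k"]))
  expect_false(sm3$significant["a", "k"])

  td <- tidy(sm)
  expect_equal(nrow(td), 6)
  expect_true(all(c("var1", "var2", "r", "p_value") %in% names(td)))
})

test_that("the antibody-count trend recovers a planted positive gradient", {
  coh <- generate_cohort(cohort_config(seed = 42))
  res <- run_full_analysis(coh, seed = 42)
  trend <- antibody_count_trend(
    coh$patients, dplyr::select(res$scores, sample_id, score, positive)
  )
  expect_gt(trend$trend$estimate, 1.3)
  expect_lt(trend$kruskal$p_value, 0.01)
  expect_true(all(c("n_antibodies", "median", "q1", "q3") %in%
                    names(trend$strata)))
  # zero-antibody patients sit near the low-component median score
  low_med <- trend$strata$median[trend$strata$n_antibodies == 0]
  expect_lt(low_med, 2.466)

  pat_const <- dplyr::mutate(coh$patients, dplyr::across(
    c(dsDNA, Ro, La, Smith, RNP, chromatin, CCP, SSc_specific), ~FALSE))
  expect_error(
    antibody_count_trend(pat_const,
                         dplyr::select(res$scores, sample_id, score,
                                       positive)),
    "constant")
})

test_that("model ladders stack the exposure row across adjustment sets", {
  set.seed(81)
  n <- 150
  d <- data.frame(
    x = rnorm(n), age = rnorm(n, 50, 10),
    gender = sample(c("F", "M"), n, replace = TRUE)
  )
  d$y <- rbinom(n, 1, plogis(0.8 * d$x))
  d$cont <- 0.5 * d$x + rnorm(n)
  lad <- logistic_ladder(d, "y", "x",
                         list(univariate = character(0),
                              adjusted = c("age", "gender")))
  expect_equal(nrow(lad), 2)
  expect_identical(lad$ladder_model, c("univariate", "adjusted"))
  expect_true(all(lad$estimate > 1))

  lin <- linear_ladder(d, "cont", "x",
                       list(univariate = character(0),
                            adjusted = c("age", "gender")))
  expect_equal(nrow(lin), 2)
  expect_equal(lin$estimate[1], 0.5, tolerance = 0.25)
})
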