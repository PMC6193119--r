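test_that("WHR classification uses strict sex-specific cutoffs and normalises tokens", {
  expect_equal(classify_whr("male", 0.98), "abdominal")
  expect_equal(classify_whr("female", 0.79), "non_abdominal")
  expect_equal(classify_whr("male", 0.90), "non_abdominal")     # boundary
  expect_equal(classify_whr("female", 0.85), "non_abdominal")   # boundary
  expect_equal(classify_whr(c("M", "F"), c(0.91, 0.86)),
               c("abdominal", "abdominal"))
  expect_error(classify_whr("other", 0.9), class = "connstates_invalid_argument")
  expect_error(classify_whr("male", -0.1), class = "connstates_invalid_argument")
})

test_that("BH correction reproduces hand-worked step-up examples", {
  r1 <- bh_fdr(rep(0.04, 4), 0.05)
  expect_true(all(r1$reject))
  expect_equal(r1$q, rep(0.04, 4))

  r2 <- bh_fdr(c(0.001, 0.2, 0.3, 0.9), 0.05)
  expect_equal(r2$reject, c(TRUE, FALSE, FALSE, FALSE))

  r3 <- bh_fdr(0.04, 0.05)
  expect_equal(r3$q, 0.04)
  expect_true(r3$reject)

  expect_error(bh_fdr(c(0.5, 0)), class = "connstates_invalid_argument")
  expect_error(bh_fdr(c(0.5, 1.2)), class = "connstates_invalid_argument")
})

test_that("BH rejections agree with the exhaustive threshold oracle", {
  set.seed(21)
  for (i in 1:200) {
    m <- sample(1:6, 1)
    p <- runif(m)^sample(1:3, 1)      # skew some vectors toward small p
    p[p == 0] <- 1e-8
    alpha <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    got <- bh_fdr(p, alpha)$reject
    want <- brute_force_bh_reject(p, alpha)
    expect_identical(got, want)
  }
})

test_that("chi-square independence matches the printed sex-table example and edge cases", {
  tab <- matrix(c(69, 47, 83, 75), 2)     # male/female by group
  res <- chi_square_independence(tab)
  expect_equal(round(res$p_value, 4), 0.2527)
  expect_equal(res$df, 1)

  even <- chi_square_independence(matrix(c(10, 10, 10, 10), 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)

  assoc <- chi_square_independence(matrix(c(20, 0, 0, 20), 2))
  expect_equal(assoc$statistic, 40)
  expect_lt(assoc$p_value, 1e-9)

  expect_error(chi_square_independence(matrix(c(1, 0, 2, 0), 2)),
               class = "connstates_degenerate_input")
})

test_that("summary t-tests reproduce demographic-table p-values and closed forms", {
  # BMI row: 31.37 (5.01) n=152 vs 29.84 (4.40) n=122, pooled variance
  bmi <- t_test_from_summaries(31.37, 5.01, 152, 29.84, 4.40, 122, "pooled")
  expect_lt(abs(bmi$p_value - 0.0086), 2e-4)

  eq <- t_test_from_summaries(5, 1, 30, 5, 1, 30)
  expect_equal(eq$t, 0)
  expect_equal(eq$p_value, 1)

  w <- t_test_from_summaries(0, 1, 30, 1, 1, 30, "welch")
  expect_equal(w$t, -sqrt(30) / sqrt(2))
  expect_equal(w$df, 58)

  # cross-check against t.test on raw data with matching summaries
  set.seed(3)
  x <- rnorm(25); y <- rnorm(30, 0.5)
  ours <- t_test_from_summaries(mean(x), sd(x), 25, mean(y), sd(y), 30, "welch")
  ref <- t.test(x, y)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("the permutation test recovers planted shifts and is exact under duplication", {
  set.seed(13)
  n <- 16; p <- 6
  x <- matrix(rnorm(n * p), n, p)
  x[1:(n / 2), 1:2] <- x[1:(n / 2), 1:2] + 3      # large shift on 2 nodes
  labels <- rep(c("abdominal", "non_abdominal"), each = n / 2)
  res <- permutation_test_dc(x, labels, n_perm = 500, seed = 4)
  expect_true(all(res$significant[1:2]))
  expect_false(any(res$significant[3:6]))
  expect_true(all(res$p > 0))
  expect_equal(res$observed_diff[1],
               mean(x[1:(n / 2), 1]) - mean(x[(n / 2 + 1):n, 1]))

  # identical group rows: every observed difference is exactly zero
  half <- matrix(rnorm(5 * p), 5, p)
  dup <- rbind(half, half)
  res0 <- permutation_test_dc(dup, rep(c("abdominal", "non_abdominal"), each = 5),
                              n_perm = 200, seed = 9)
  expect_equal(res0$observed_diff, rep(0, p))
  expect_false(any(res0$significant))
})

test_that("the permutation test is reproducible and validates its inputs", {
  set.seed(31)
  x <- matrix(rnorm(40), 10, 4)
  labels <- rep(c("a", "b"), 5)
  r1 <- permutation_test_dc(x, labels, n_perm = 300, seed = 7)
  r2 <- permutation_test_dc(x, labels, n_perm = 300, seed = 7)
  expect_identical(r1$p, r2$p)
  expect_error(permutation_test_dc(x, rep("a", 10), n_perm = 10),
               class = "connstates_invalid_argument")
  xm <- x; xm[1, 2] <- NA
  expect_warning(res <- permutation_test_dc(xm, labels, n_perm = 10, seed = 1),
                 "missing")
  expect_equal(nrow(res), 3)
})

test_that("EDE-Q regression recovers planted coefficients and flags collinearity", {
  set.seed(17)
  n <- 200
  dc <- rnorm(n)
  age <- runif(n, 20, 70)
  edeq <- 0.5 * dc + 0.01 * age + 1 + rnorm(n, sd = 0.1)
  fit <- fit_edeq_regression(edeq, dc, age)
  co <- tidy(fit)
  expect_equal(co$estimate[co$term == "dc"], 0.5, tolerance = 0.1)
  expect_gt(glance(fit)$r_squared, 0.9)

  # perfect fit
  exact <- fit_edeq_regression(0.5 * dc + 0.3 * age + 2, dc, age)
  expect_equal(suppressWarnings(glance(exact)$r_squared), 1)

  # collinear predictors are named
  expect_error(fit_edeq_regression(edeq, cbind(a = dc, b = 2 * dc), age),
               "b", class = "connstates_invalid_argument")
})

test_that("regression p-values are invariant to predictor standardisation", {
  set.seed(23)
  n <- 80
  dc <- rnorm(n, sd = 4)
  age <- runif(n, 20, 70)
  edeq <- 0.3 * dc + 0.02 * age + rnorm(n)
  f1 <- fit_edeq_regression(edeq, dc, age)
  f2 <- fit_edeq_regression(edeq, scale(dc)[, 1], age)
  t1 <- tidy(f1); t2 <- tidy(f2)
  expect_equal(t1$p_value[t1$term == "dc"], t2$p_value[t2$term == "dc"],
               tolerance = 1e-10)
  expect_equal(t2$estimate[t2$term == "dc"],
               t1$estimate[t1$term == "dc"] * sd(dc), tolerance = 1e-8)
})

test_that("family-wise regression correction applies BH across the whole table", {
  tab <- tibble::tibble(
    predictor_set = rep("a", 4), scale = c("r", "e", "s", "w"),
    p_model = c(0.01, 0.01, 0.01, 0.01)
  )
  out <- correct_regression_family(tab)
  expect_equal(out$q, rep(0.01, 4))
  expect_true(all(out$significant))

  tab2 <- tibble::tibble(p_model = c(0.001, 0.04, 0.9, 1))
  out2 <- correct_regression_family(tab2)
  expect_true(all(which(out2$significant) %in% which(tab2$p_model < 0.05)))

  out3 <- correct_regression_family(tibble::tibble(p_model = rep(1, 5)))
  expect_false(any(out3$significant))
})
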