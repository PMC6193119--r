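test_that("window length from frequency matches the TR/frequency arithmetic", {
  expect_equal(window_length_from_frequency(0.645, 0.009), 172L)
  expect_equal(window_length_from_frequency(2.0, 0.01), 50L)
  expect_error(window_length_from_frequency(1.0, 1.0),
               class = "connstates_invalid_argument")
  expect_error(window_length_from_frequency(1.0, 0.5),
               class = "connstates_invalid_argument")  # at Nyquist exactly
})

test_that("the taper is a normalised symmetric rect-Gaussian convolution", {
  for (L in c(10, 31, 172)) {
    u <- build_taper(L, 3)
    expect_length(u, L)
    expect_equal(sum(u), 1, tolerance = 1e-12)
    expect_equal(u, rev(u), tolerance = 1e-12)
  }
  # delta-kernel limit: effectively uniform weights
  u0 <- build_taper(20, 1e-6)
  expect_equal(u0, rep(1 / 20, 20), tolerance = 1e-9)
  # interior weights of a long window are flat at 1/L
  u <- build_taper(172, 3)
  expect_equal(u[20:150], rep(u[86], 131), tolerance = 1e-6)
  expect_lt(u[1], u[86])
  # direct convolution oracle
  L <- 25; sg <- 3; h <- ceiling(3 * sg)
  kern <- exp(-(-h:h)^2 / (2 * sg^2)); kern <- kern / sum(kern)
  full <- rep(0, L + 2 * h)
  for (i in seq_len(L)) full[i:(i + 2 * h)] <- full[i:(i + 2 * h)] + kern
  want <- full[(h + 1):(h + L)]; want <- want / sum(want)
  expect_equal(build_taper(L, sg), want, tolerance = 1e-12)
})

test_that("window counts follow floor((t - L)/stride) + 1 and covariances are tapered", {
  ts <- node_time_series(matrix(rnorm(3 * 884), 3), tr = 0.645)
  w <- windowed_covariances(ts, window_config(172, 1, 3))
  expect_length(w, 713)

  ts2 <- node_time_series(matrix(rnorm(2 * 172), 2), tr = 0.645)
  expect_length(windowed_covariances(ts2, window_config(172, 1, 3)), 1)
  expect_error(windowed_covariances(ts2, window_config(173, 1, 3)),
               "172", class = "connstates_invalid_argument")

  # property: count formula over random shapes
  set.seed(10)
  for (i in 1:25) {
    t_len <- sample(30:200, 1); L <- sample(5:30, 1); st <- sample(1:7, 1)
    tsr <- node_time_series(matrix(rnorm(2 * t_len), 2), tr = 1)
    n <- length(windowed_covariances(tsr, window_config(L, st, 2)))
    expect_equal(n, floor((t_len - L) / st) + 1)
  }

  # explicit weighted-covariance oracle on one window
  x <- matrix(rnorm(2 * 12), 2)
  tsx <- node_time_series(x, tr = 1)
  u <- build_taper(12, 2)
  xbar <- x %*% u
  s_want <- matrix(0, 2, 2)
  for (k2 in 1:12) s_want <- s_want + u[k2] * tcrossprod(x[, k2] - xbar)
  got <- windowed_covariances(tsx, window_config(12, 1, 2))[[1]]
  expect_equal(got$s, s_want, tolerance = 1e-12)

  # constant node raises the degenerate flag
  xc <- rbind(rnorm(20), rep(1, 20))
  wc <- windowed_covariances(node_time_series(xc, tr = 1), window_config(10, 5, 2))
  expect_true(all(vapply(wc, `[[`, logical(1), "degenerate")))
})

test_that("graphical lasso matches the unpenalised inverse and the shrinkage limit", {
  set.seed(6)
  a <- matrix(rnorm(40), 10, 4)
  s <- crossprod(a) / 10 + 0.5 * diag(4)
  f0 <- graphical_lasso_fit(s, 0)
  expect_lt(max(abs(f0$theta - solve(s))), 1e-6)
  flarge <- graphical_lasso_fit(s, 1e3)
  expect_equal(flarge$theta, diag(1 / diag(s)), tolerance = 1e-10)
  expect_error(graphical_lasso_fit(s, -1), class = "connstates_invalid_argument")
  sd0 <- s; sd0[1, 1] <- 0
  expect_error(graphical_lasso_fit(sd0, 0.1), class = "connstates_degenerate_input")
})

test_that("graphical lasso matches the two-variable closed form across a penalty grid", {
  set.seed(15)
  for (i in 1:10) {
    v <- runif(2, 0.5, 3)
    c12 <- runif(1, -0.9, 0.9) * sqrt(prod(v))
    s <- matrix(c(v[1], c12, c12, v[2]), 2)
    for (lam in c(0, 0.05, 0.2, abs(c12) * 0.999, abs(c12) * 1.001, 2)) {
      fit <- graphical_lasso_fit(s, lam)
      w12 <- sign(c12) * max(abs(c12) - lam, 0)
      want <- solve(matrix(c(v[1], w12, w12, v[2]), 2))
      expect_equal(fit$theta, want, tolerance = 1e-8)
    }
  }
})

test_that("graphical lasso solutions are first-order optimal and monotone in the penalty", {
  set.seed(33)
  for (i in 1:5) {
    a <- matrix(rnorm(30), 10, 3)
    s <- crossprod(a) / 10 + 0.3 * diag(3)
    prev_support <- matrix(TRUE, 3, 3)
    prev_obj <- Inf
    for (lam in c(0.01, 0.05, 0.1, 0.3, 0.8)) {
      fit <- graphical_lasso_fit(s, lam)
      # no single off-diagonal perturbation improves the objective
      obj <- function(th) {
        d <- determinant(th)
        as.numeric(d$modulus) - sum(s * th) - lam * sum(abs(th[upper.tri(th) | lower.tri(th)]))
      }
      base <- obj(fit$theta)
      for (ij in list(c(1, 2), c(1, 3), c(2, 3))) for (eps in c(-1e-4, 1e-4)) {
        th2 <- fit$theta
        th2[ij[1], ij[2]] <- th2[ij[1], ij[2]] + eps
        th2[ij[2], ij[1]] <- th2[ij[1], ij[2]]
        expect_lt(obj(th2) - base, 1e-8)
      }
      # support shrinks and the optimum value decreases as lambda grows
      support <- abs(fit$theta) > 1e-7
      expect_true(all(support[prev_support == FALSE] == FALSE))
      expect_lte(base, prev_obj + 1e-9)
      prev_support <- support
      prev_obj <- base
    }
  }
})

test_that("cross-validated penalty selection recovers sparse supports and honours ties", {
  # singleton grid: no choice to make
  set.seed(40)
  ws <- windowed_covariances(node_time_series(matrix(rnorm(4 * 120), 4), tr = 1),
                             window_config(20, 10, 3))
  expect_equal(as.numeric(select_lambda_cv(ws, 0.07)), 0.07)
  expect_error(select_lambda_cv(ws, numeric(0)), class = "connstates_invalid_argument")

  # support recovery from data simulated out of a sparse precision; the
  # cross-validated penalty is prediction-optimal (it under-penalises
  # relative to exact-zero selection), so recovered support is read as
  # edges with non-negligible partial correlation (|rho| > 0.05)
  prec <- generate_state_precisions(5, 1, 0.2, seed = 2)[[1]]
  r <- chol(prec)
  set.seed(41)
  x <- backsolve(r, matrix(rnorm(5 * 5000), 5))
  ts <- node_time_series(x, tr = 1)
  wsx <- windowed_covariances(ts, window_config(500, 500, 100))
  grid <- exp(seq(log(0.01), log(1), length.out = 10))
  lam <- select_lambda_cv(wsx, grid, n_folds = 5)
  refit <- graphical_lasso_fit(connstates:::mean_matrices(lapply(wsx, `[[`, "s")),
                               as.numeric(lam))
  rho <- precision_to_partial_corr(refit$theta)$values
  truth <- abs(prec[upper.tri(prec)]) > 0
  est <- abs(rho[upper.tri(rho)]) > 0.05
  f1 <- 2 * sum(truth & est) / (2 * sum(truth & est) + sum(!truth & est) + sum(truth & !est))
  expect_gt(f1, 0.8)
})

test_that("denser true precisions pull the selected penalty down", {
  # sparse-precision data should tolerate (and often prefer) larger penalties
  # than dense-precision data; compare medians of selected lambda
  grid <- c(0.01, 0.03, 0.1, 0.3)
  pick <- function(sparsity, seed) {
    prec <- generate_state_precisions(5, 1, sparsity, seed = seed)[[1]]
    r <- chol(prec)
    set.seed(seed + 5000)
    x <- backsolve(r, matrix(rnorm(5 * 600), 5))
    ws <- windowed_covariances(node_time_series(x, tr = 1),
                               window_config(100, 100, 50))
    as.numeric(select_lambda_cv(ws, grid, n_folds = 3))
  }
  dense <- vapply(1:15, function(s) pick(0.9, s), numeric(1))
  expect_gte(mean(dense <= stats::median(grid)), 0.8)
})

test_that("partial correlations are the negatively scaled precision off-diagonals", {
  expect_equal(precision_to_partial_corr(diag(c(2, 3, 4)))$values, diag(3))
  th <- matrix(c(2, -1, -1, 2), 2)
  expect_equal(precision_to_partial_corr(th)$values[1, 2], 0.5)
  set.seed(50)
  a <- matrix(rnorm(36), 6)
  spd <- crossprod(a) + 6 * diag(6)
  rho <- precision_to_partial_corr(spd)$values
  expect_equal(rho, t(rho))
  expect_equal(diag(rho), rep(1, 6))
  expect_true(all(abs(rho) <= 1))
  expect_error(precision_to_partial_corr(matrix(c(-1, 0, 0, 1), 2)),
               class = "connstates_invalid_argument")
})

test_that("group-state clustering is seeded, occupancy-ordered, and recovers planted means", {
  # construct windows as noisy copies of two far-apart matrices
  set.seed(60)
  mk_state <- function(v) {
    m <- diag(4); m[1, 2] <- m[2, 1] <- v; m[3, 4] <- m[4, 3] <- -v; m
  }
  noisy <- function(m, sd = 0.05) {
    e <- matrix(rnorm(16, sd = sd), 4); e <- (e + t(e)) / 2; diag(e) <- 0
    m + e
  }
  mats <- c(lapply(1:30, function(i) noisy(mk_state(0.6))),
            lapply(1:10, function(i) noisy(mk_state(-0.6))))
  win <- tibble::tibble(subject = "s1", window = seq_along(mats), matrix = mats)
  out <- cluster_group_states(win, 2, seed = 3)
  expect_equal(out$states$occupancy, c(0.75, 0.25))
  expect_equal(sum(out$states$occupancy), 1)
  expect_gt(cor(connstates:::upper_tri_vec(out$states$mean_matrix[[1]]), connstates:::upper_tri_vec(mk_state(0.6))), 0.95)
  expect_gt(cor(connstates:::upper_tri_vec(out$states$mean_matrix[[2]]), connstates:::upper_tri_vec(mk_state(-0.6))), 0.95)

  out2 <- cluster_group_states(win, 2, seed = 3)
  expect_identical(out$assignments$state, out2$assignments$state)

  one <- cluster_group_states(win, 1, seed = 3)
  expect_equal(one$states$mean_matrix[[1]], connstates:::mean_matrices(mats))
  expect_error(cluster_group_states(win[1:3, ], 5, seed = 1),
               class = "connstates_invalid_argument")
})

test_that("state-count selection votes by silhouette across subjects", {
  set.seed(70)
  mk <- function(v12, v34) {
    m <- diag(4); m[1, 2] <- m[2, 1] <- v12; m[3, 4] <- m[4, 3] <- v34; m
  }
  states <- list(mk(0.7, 0), mk(-0.7, 0), mk(0, 0.7))
  subject_windows <- lapply(1:5, function(s) {
    lapply(1:24, function(i) {
      m <- states[[sample(3, 1)]]
      e <- matrix(rnorm(16, sd = 0.04), 4); e <- (e + t(e)) / 2; diag(e) <- 0
      m + e
    })
  })
  k <- select_num_states(subject_windows, 2:5, seed = 2)
  expect_equal(as.integer(k), 3L)
  expect_length(attr(k, "votes"), 5)
  expect_error(select_num_states(subject_windows, integer(0)),
               class = "connstates_invalid_argument")
})

test_that("greedy state matching recovers permutations and is total", {
  set.seed(80)
  mk <- function(i) {
    m <- diag(5)
    m[i, i %% 5 + 1] <- m[i %% 5 + 1, i] <- 0.6
    m
  }
  group <- tibble::tibble(state = 1:3, occupancy = rep(1 / 3, 3),
                          n_windows = rep(10L, 3),
                          mean_matrix = lapply(1:3, mk))
  subj_identical <- tibble::tibble(subject_state = 1:3,
                                   variance_explained = c(0.5, 0.3, 0.2),
                                   n_windows = rep(5L, 3),
                                   mean_matrix = lapply(1:3, mk))
  m1 <- match_states(subj_identical, group)
  expect_equal(m1$group_state, 1:3)

  perm <- c(3, 1, 2)
  subj_perm <- subj_identical
  subj_perm$mean_matrix <- lapply(perm, mk)
  m2 <- match_states(subj_perm, group)
  expect_equal(m2$group_state, perm)

  # an orthogonal subject state is still assigned somewhere
  subj_orth <- subj_identical
  subj_orth$mean_matrix[[3]] <- mk(4) * 0 + diag(5)
  m3 <- match_states(subj_orth, group)
  expect_equal(sort(m3$group_state), 1:3)

  expect_error(match_states(dplyr::bind_rows(subj_identical, subj_identical), group),
               class = "connstates_invalid_argument")
})

test_that("per-state DC collapses correctly and matches the identity-partial closed form", {
  p <- 5
  ident <- diag(p)
  win <- tibble::tibble(subject = "s1", window = 1:4,
                        matrix = replicate(4, ident, simplify = FALSE))
  assign <- tibble::tibble(subject = "s1", window = 1:4, group_state = 1L)
  dc <- per_state_dc(win, assign)
  expect_equal(dc$dc, rep((p - 1) * atanh(0.5^6), p))

  # single-state collapse: per-state mean equals the grand mean matrix
  set.seed(90)
  mats <- lapply(1:6, function(i) {
    e <- matrix(rnorm(9, sd = 0.1), 3); e <- (e + t(e)) / 2; diag(e) <- 0
    diag(3) * 1 + e
  })
  win2 <- tibble::tibble(subject = "s2", window = 1:6, matrix = mats)
  as2 <- tibble::tibble(subject = "s2", window = 1:6, group_state = 2L)
  dc2 <- per_state_dc(win2, as2)
  grand <- connstates:::mean_matrices(mats)
  cm <- connstates:::new_conn_matrix(grand, "partial", paste0("node", 1:3))
  want <- degree_centrality(fisher_z(soft_threshold(cm))$values)
  expect_equal(dc2$dc, want$value)
  expect_equal(unique(dc2$state), 2L)
})

test_that("the full dynamic chain is deterministic given data and seed", {
  coh <- generate_cohort(cohort_config(n_per_group = 2, p = 6, t = 200,
                                       k_states = 2, dwell_mean = 20,
                                       precision_sparsity = 0.15, seed = 14))
  wc <- window_config(16, 20, 3)
  d1 <- dynamic_states(coh$ts, cfg = wc, lambda = 0.05, k = 2, seed = 8)
  d2 <- dynamic_states(coh$ts, cfg = wc, lambda = 0.05, k = 2, seed = 8)
  expect_identical(d1$group_assignments$state, d2$group_assignments$state)
  expect_identical(d1$dc, d2$dc)
  expect_identical(d1$subject_assignments, d2$subject_assignments)
})
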