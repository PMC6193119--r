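#' Sliding-window configuration
#'
#' Parameters of the tapered sliding window used for dynamic connectivity.
#' The defaults reproduce the conventional multiband resting-state setup:
#' a 172-time-point window (111 s at TR = 0.645 s, long enough to capture
#' fluctuations down to 0.009 Hz), stride 1, and a Gaussian taper of
#' standard deviation 3 time points.
#'
#' @param window_len Window length in time points (>= 2).
#' @param stride Window step in time points (>= 1).
#' @param taper_sigma Standard deviation of the Gaussian taper, time points.
#' @return A `window_config` object.
#' @export
window_config <- function(window_len = 172L, stride = 1L, taper_sigma = 3) {
  window_len <- check_count(window_len, "window_len", min = 2L)
  stride <- check_count(stride, "stride", min = 1L)
  check_scalar_number(taper_sigma, "taper_sigma", min = 0, strict_min = TRUE)
  structure(list(window_len = window_len, stride = stride,
                 taper_sigma = taper_sigma),
            class = "window_config")
}

#' Window length needed to capture a minimum frequency
#'
#' One full cycle of the slowest fluctuation of interest must fit in the
#' window: length = round((1 / min_freq) / tr) time points (at least 2).
#' With TR 0.645 s and a 0.009 Hz floor this gives 172 time points (111 s).
#'
#' @param tr Sampling interval in seconds.
#' @param min_freq Lowest frequency to capture, in Hz; must be below the
#'   Nyquist frequency 1 / (2 tr).
#' @return Integer window length in time points.
#' @export
#' @examples
#' window_length_from_frequency(0.645, 0.009) # 172
window_length_from_frequency <- function(tr, min_freq) {
  check_scalar_number(tr, "tr", min = 0, strict_min = TRUE)
  check_scalar_number(min_freq, "min_freq", min = 0, strict_min = TRUE)
  if (min_freq >= 1 / (2 * tr)) {
    stop_invalid(sprintf("min_freq (%g Hz) must be below the Nyquist frequency %g Hz",
                         min_freq, 1 / (2 * tr)))
  }
  max(2L, as.integer(round((1 / min_freq) / tr)))
}

#' Gaussian-tapered window weights
#'
#' A rectangular window convolved with a Gaussian kernel (truncated at
#' +/- 3 sigma), then normalised to sum to one. Interior weights are nearly
#' uniform; only the edges are tapered, which suppresses spectral leakage
#' from windowing without discarding interior samples.
#'
#' @param window_len Window length in time points.
#' @param taper_sigma Gaussian standard deviation in time points.
#' @return Numeric weight vector of length `window_len`, symmetric,
#'   summing to one.
#' @export
build_taper <- function(window_len, taper_sigma = 3) {
  window_len <- check_count(window_len, "window_len", min = 2L)
  check_scalar_number(taper_sigma, "taper_sigma", min = 0, strict_min = TRUE)
  h <- max(1L, as.integer(ceiling(3 * taper_sigma)))
  offs <- seq(-h, h)
  kern <- exp(-offs^2 / (2 * taper_sigma^2))
  kern <- kern / sum(kern)
  rect <- rep(1, window_len)
  # same-length central slice of the full convolution
  w <- vapply(seq_len(window_len), function(i) {
    j <- i - offs
    sum(kern[j >= 1 & j <= window_len])
  }, numeric(1))
  w / sum(w)
}

#' Tapered windowed covariances of node time series
#'
#' Slides a tapered window along the time axis and computes, for each
#' position, the weighted empirical covariance
#' S = sum_k u_k (x_k - xbar_u)(x_k - xbar_u)' with u the taper weights and
#' xbar_u the weighted mean. The number of windows is
#' floor((t - window_len) / stride) + 1.
#'
#' @param ts A [node_time_series()].
#' @param cfg A [window_config()].
#' @return List of `windowed_cov` objects, each holding the covariance `s`,
#'   `window_index`, `center_time` (time points), and a `degenerate` flag
#'   raised when a node is constant inside the window.
#' @export
windowed_covariances <- function(ts, cfg = window_config()) {
  if (!inherits(ts, "node_ts")) stop_invalid("`ts` must be a node_ts")
  if (!inherits(cfg, "window_config")) stop_invalid("`cfg` must be a window_config")
  t_len <- ncol(ts$data)
  L <- cfg$window_len
  if (t_len < L) {
    stop_invalid(sprintf("time series length %d is shorter than window length %d",
                         t_len, L))
  }
  u <- build_taper(L, cfg$taper_sigma)
  starts <- seq(1L, t_len - L + 1L, by = cfg$stride)
  lapply(seq_along(starts), function(i) {
    s0 <- starts[i]
    x <- ts$data[, s0:(s0 + L - 1L), drop = FALSE]
    xbar <- as.numeric(x %*% u)
    xc <- x - xbar
    s <- xc %*% (u * t(xc))
    s <- (s + t(s)) / 2
    structure(
      list(s = s, window_index = i, center_time = s0 + (L - 1) / 2,
           degenerate = any(diag(s) <= 1e-12),
           node_labels = ts$node_labels),
      class = "windowed_cov"
    )
  })
}

#' L1-penalised precision estimation (graphical lasso)
#'
#' Maximises log det(theta) - tr(S theta) - lambda * ||theta||_1 over
#' symmetric positive-definite matrices, with the L1 penalty on the
#' off-diagonal entries only (so the full-shrinkage limit is
#' diag(1/diag(S))). Solved by block coordinate descent over columns of the
#' working covariance with a coordinate-descent lasso inner loop.
#'
#' @param s A `windowed_cov` or a symmetric covariance matrix with positive
#'   diagonal.
#' @param lambda Nonnegative penalty.
#' @param maxit Maximum outer sweeps.
#' @param tol Relative convergence tolerance on the working covariance.
#' @return A `precision_estimate` with elements `theta` (SPD precision),
#'   `w` (estimated covariance), `lambda`, `objective` (attained penalised
#'   log-likelihood), `converged`, and `iterations`.
#' @export
#' @examples
#' s <- matrix(c(2, 0.8, 0.8, 1.5), 2)
#' fit <- graphical_lasso_fit(s, lambda = 0.1)
#' fit$theta
graphical_lasso_fit <- function(s, lambda, maxit = 500L, tol = 1e-8) {
  labels <- NULL
  if (inherits(s, "windowed_cov")) {
    labels <- s$node_labels
    s <- s$s
  }
  check_square_matrix(s, "s")
  if (!is_symmetric_tol(s, 1e-8)) stop_invalid("`s` must be symmetric")
  if (any(diag(s) <= 0)) {
    stop_degenerate("covariance diagonal must be positive (constant node in window?)")
  }
  check_scalar_number(lambda, "lambda", min = 0)
  s <- (s + t(s)) / 2
  fit <- .glasso_cpp(s, lambda, maxit = as.integer(maxit), tol = tol)
  if (!fit$converged) {
    abort(sprintf("graphical lasso did not converge in %d sweeps (objective %.6g)",
                  maxit, fit$objective),
          class = "connstates_convergence_error", objective = fit$objective)
  }
  structure(
    list(theta = fit$theta, w = fit$w, lambda = lambda,
         objective = fit$objective, converged = fit$converged,
         iterations = fit$iterations, node_labels = labels),
    class = "precision_estimate"
  )
}

#' @export
print.precision_estimate <- function(x, ...) {
  cat(sprintf("<precision_estimate: %d nodes, lambda = %g, objective = %.4f>\n",
              nrow(x$theta), x$lambda, x$objective))
  invisible(x)
}

# Unpenalised Gaussian log-likelihood of theta against a test covariance.
gaussian_loglik <- function(theta, s_test) {
  d <- determinant(theta, logarithm = TRUE)
  if (d$sign <= 0) return(-Inf)
  as.numeric(d$modulus) - sum(s_test * theta)
}

#' Cross-validated penalty selection for the graphical lasso
#'
#' Splits the windows into contiguous blocks (contiguity respects the
#' temporal dependence of overlapping windows), fits the precision on the
#' average training-block covariance for each candidate penalty, and scores
#' the unpenalised log-likelihood log det(theta) - tr(S_test theta) on each
#' held-out block's average covariance. Returns the penalty with the
#' highest mean held-out score; ties go to the smaller penalty.
#'
#' @param windows List of `windowed_cov` objects (or covariance matrices).
#' @param lambdas Ascending numeric vector of candidate penalties (>= 0).
#' @param n_folds Number of contiguous folds (default 5).
#' @return The selected penalty, with the per-candidate mean held-out
#'   scores attached as attribute `"scores"`.
#' @export
select_lambda_cv <- function(windows, lambdas, n_folds = 5L) {
  if (length(lambdas) == 0L) stop_invalid("`lambdas` must be non-empty")
  if (any(lambdas < 0)) stop_invalid("penalties must be nonnegative")
  lambdas <- sort(unique(as.numeric(lambdas)))
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  mats <- lapply(windows, function(w) if (inherits(w, "windowed_cov")) w$s else w)
  n <- length(mats)
  if (n < n_folds) {
    stop_invalid(sprintf("need at least n_folds = %d windows, got %d", n_folds, n))
  }
  fold <- cut(seq_len(n), breaks = n_folds, labels = FALSE)
  scores <- matrix(NA_real_, n_folds, length(lambdas))
  for (f in seq_len(n_folds)) {
    s_train <- mean_matrices(mats[fold != f])
    s_test <- mean_matrices(mats[fold == f])
    for (li in seq_along(lambdas)) {
      fit <- graphical_lasso_fit(s_train, lambdas[li])
      scores[f, li] <- gaussian_loglik(fit$theta, s_test)
    }
  }
  mean_scores <- colMeans(scores)
  best <- which(mean_scores >= max(mean_scores) - 1e-12)[1L] # ties -> smaller lambda
  structure(lambdas[best], scores = setNames(mean_scores, lambdas))
}

#' Partial correlations from a precision matrix
#'
#' rho_ij = -theta_ij / sqrt(theta_ii theta_jj) off the diagonal, 1 on the
#' diagonal: the conditional dependence strength between two nodes given
#' all others, on a common \[-1, 1\] scale comparable across windows and
#' subjects.
#'
#' @param theta A `precision_estimate` or an SPD precision matrix.
#' @return A `conn_matrix` at stage `"partial"`.
#' @export
precision_to_partial_corr <- function(theta) {
  labels <- NULL
  if (inherits(theta, "precision_estimate")) {
    labels <- theta$node_labels
    theta <- theta$theta
  }
  check_square_matrix(theta, "theta")
  d <- diag(theta)
  if (any(d <= 0)) stop_invalid("precision diagonal must be positive")
  rho <- -theta / sqrt(outer(d, d))
  diag(rho) <- 1
  rho <- pmin(pmax((rho + t(rho)) / 2, -1), 1)
  if (is.null(labels)) labels <- default_labels(nrow(theta))
  new_conn_matrix(rho, "partial", labels)
}

#' Windowed partial-correlation matrices for one subject
#'
#' The per-subject dynamic-connectivity chain: tapered windowed covariances,
#' graphical-lasso precision per window, partial-correlation scaling.
#'
#' @inheritParams windowed_covariances
#' @param lambda Penalty applied to every window of this subject; if a
#'   vector of candidates, one value is first selected by
#'   [select_lambda_cv()] on this subject's windows.
#' @param n_folds Folds for penalty selection when `lambda` is a grid.
#' @return A tibble with columns `subject`, `window`, `center_time` and a
#'   list-column `matrix` of partial-correlation matrices; the penalty used
#'   is attached as attribute `"lambda"`.
#' @export
window_partial_correlations <- function(ts, cfg = window_config(), lambda = 0.1,
                                        n_folds = 5L) {
  covs <- windowed_covariances(ts, cfg)
  if (length(lambda) > 1L) {
    lambda <- as.numeric(select_lambda_cv(covs, lambda, n_folds = n_folds))
  }
  mats <- lapply(covs, function(w) {
    precision_to_partial_corr(graphical_lasso_fit(w, lambda))$values
  })
  out <- tibble::tibble(
    subject = ts$subject_id,
    window = vapply(covs, `[[`, integer(1), "window_index"),
    center_time = vapply(covs, `[[`, numeric(1), "center_time"),
    matrix = mats
  )
  attr(out, "lambda") <- lambda
  attr(out, "node_labels") <- ts$node_labels
  out
}

windows_to_features <- function(mats) {
  t(vapply(mats, upper_tri_vec, numeric(length(upper_tri_vec(mats[[1]])))))
}

seeded_kmeans <- function(x, k, seed) {
  set.seed(seed)
  kmeans(x, centers = k, nstart = 10L, iter.max = 300L)
}

mean_silhouette <- function(labels, d) {
  if (length(unique(labels)) < 2L) return(-Inf)
  mean(cluster::silhouette(labels, d)[, "sil_width"])
}

#' Choose the number of brain states
#'
#' For each subject the vectorised (upper-triangle) partial-correlation
#' matrices are clustered with K-means for every candidate k and the
#' silhouette-maximising k is recorded as that subject's vote; the most
#' common vote wins. Vote ties are broken by the elbow criterion — the k
#' with the largest second difference of the mean (across subjects)
#' normalised within-cluster dispersion — and then by the smaller k.
#'
#' @param subject_windows A window tibble (from binding
#'   [window_partial_correlations()] rows) or a list, per subject, of lists
#'   of partial-correlation matrices.
#' @param k_range Candidate state counts, e.g. `2:6`.
#' @param seed Integer seed for the K-means restarts.
#' @return The selected k (integer), with per-subject votes and the mean
#'   dispersion curve attached as attributes `"votes"` and `"dispersion"`.
#' @export
select_num_states <- function(subject_windows, k_range, seed = 1L) {
  if (length(k_range) == 0L) stop_invalid("`k_range` must be non-empty")
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1L)) stop_invalid("state counts must be >= 1")
  if (is.data.frame(subject_windows)) {
    subject_windows <- split(subject_windows$matrix, subject_windows$subject)
  }
  n_sub <- length(subject_windows)
  votes <- integer(n_sub)
  disp <- matrix(NA_real_, n_sub, length(k_range))
  for (si in seq_len(n_sub)) {
    mats <- subject_windows[[si]]
    if (length(mats) < max(k_range)) {
      stop_invalid(sprintf("subject %d has %d windows, fewer than max k = %d",
                           si, length(mats), max(k_range)))
    }
    x <- windows_to_features(mats)
    d <- dist(x)
    tot_ss <- sum(scale(x, scale = FALSE)^2)
    sil <- numeric(length(k_range))
    for (ki in seq_along(k_range)) {
      km <- seeded_kmeans(x, k_range[ki], stage_seed(seed, "kselect") + si * 131L + ki)
      sil[ki] <- mean_silhouette(km$cluster, d)
      disp[si, ki] <- km$tot.withinss / tot_ss
    }
    votes[si] <- k_range[which.max(sil)]
  }
  tab <- table(votes)
  cands <- as.integer(names(tab)[tab == max(tab)])
  if (length(cands) > 1L) {
    curve <- colMeans(disp)
    d2 <- rep(-Inf, length(k_range))
    for (i in seq_along(k_range)) {
      if (i > 1L && i < length(k_range)) {
        d2[i] <- curve[i - 1L] - 2 * curve[i] + curve[i + 1L]
      }
    }
    elbow <- d2[match(cands, k_range)]
    cands <- cands[order(-elbow, cands)]
  }
  structure(cands[1L],
            votes = votes,
            dispersion = setNames(colMeans(disp), k_range))
}

#' Group-level brain states by K-means
#'
#' Clusters the vectorised upper triangles of all subjects' windowed
#' partial-correlation matrices (squared Euclidean K-means, 10 seeded
#' restarts). States are indexed in descending occupancy; each state's mean
#' matrix is the element-wise mean of its member matrices.
#'
#' @param windows Window tibble over all subjects (columns `subject`,
#'   `window`, `matrix`).
#' @param k Number of states.
#' @param seed Integer seed.
#' @return A list with `states` (a `brain_states` tibble: `state`,
#'   `occupancy`, `n_windows`, list-column `mean_matrix`) and `assignments`
#'   (the input tibble plus a `state` column).
#' @export
cluster_group_states <- function(windows, k, seed = 1L) {
  k <- check_count(k, "k", min = 1L)
  mats <- windows$matrix
  if (length(mats) < k) {
    stop_invalid(sprintf("%d windows is fewer than k = %d states", length(mats), k))
  }
  x <- windows_to_features(mats)
  km <- seeded_kmeans(x, k, stage_seed(seed, "kmeans_group"))
  sizes <- tabulate(km$cluster, nbins = k)
  ord <- order(sizes, decreasing = TRUE)
  relabel <- match(seq_len(k), ord)      # old label -> new label by occupancy
  labels <- relabel[km$cluster]
  states <- tibble::tibble(
    state = seq_len(k),
    occupancy = sizes[ord] / length(mats),
    n_windows = sizes[ord],
    mean_matrix = lapply(seq_len(k), function(s) mean_matrices(mats[labels == s]))
  )
  class(states) <- c("brain_states", class(states))
  attr(states, "node_labels") <- attr(windows, "node_labels")
  assignments <- windows[c("subject", "window")]
  assignments$state <- labels
  list(states = states, assignments = assignments)
}

#' Participant-level states for one subject
#'
#' K-means on one subject's windowed matrices. Clusters are ordered by the
#' share of the subject's total window dispersion their members account
#' for ("variance explained"), the order in which they are later matched to
#' group states.
#'
#' @param mats List of this subject's partial-correlation matrices.
#' @param k Number of participant-level states (same k as the group level).
#' @param seed Integer seed.
#' @return A list with `states` (tibble: `subject_state`,
#'   `variance_explained`, `n_windows`, list-column `mean_matrix`) and
#'   `labels` (per-window participant-state labels).
#' @export
cluster_subject_states <- function(mats, k, seed = 1L) {
  k <- check_count(k, "k", min = 1L)
  if (length(mats) < k) {
    stop_invalid(sprintf("%d windows is fewer than k = %d states", length(mats), k))
  }
  x <- windows_to_features(mats)
  km <- seeded_kmeans(x, k, stage_seed(seed, "kmeans_subject"))
  grand <- colMeans(x)
  total <- sum(sweep(x, 2, grand)^2)
  ve <- vapply(seq_len(k), function(c) {
    sum(sweep(x[km$cluster == c, , drop = FALSE], 2, grand)^2)
  }, numeric(1))
  ve <- if (total > 0) ve / total else rep(1 / k, k)
  ord <- order(ve, decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  states <- tibble::tibble(
    subject_state = seq_len(k),
    variance_explained = ve[ord],
    n_windows = tabulate(km$cluster, nbins = k)[ord],
    mean_matrix = lapply(ord, function(c) mean_matrices(mats[km$cluster == c]))
  )
  list(states = states, labels = relabel[km$cluster])
}

#' Match participant-level states to group-level states
#'
#' Greedy assignment without replacement: starting from the participant
#' state with the largest variance explained, each is matched to the
#' still-unmatched group state whose vectorised mean matrix has the highest
#' Pearson correlation with it; ties go to the lower group-state index.
#'
#' @param subject_states Tibble from [cluster_subject_states()] (`states`
#'   element), ordered by descending `variance_explained`.
#' @param group_states A `brain_states` tibble from [cluster_group_states()].
#' @return Tibble with columns `subject_state`, `group_state`,
#'   `correlation`; the mapping is injective into the group states.
#' @export
match_states <- function(subject_states, group_states) {
  ns <- nrow(subject_states)
  ng <- nrow(group_states)
  if (ns > ng) {
    stop_invalid(sprintf("more participant states (%d) than group states (%d)", ns, ng))
  }
  free <- rep(TRUE, ng)
  out <- vector("list", ns)
  ord <- order(subject_states$variance_explained, decreasing = TRUE)
  for (i in ord) {
    v <- upper_tri_vec(subject_states$mean_matrix[[i]])
    cors <- vapply(seq_len(ng), function(g) {
      if (!free[g]) return(-Inf)
      gv <- upper_tri_vec(group_states$mean_matrix[[g]])
      if (sd(v) == 0 || sd(gv) == 0) return(0)
      cor(v, gv)
    }, numeric(1))
    g <- which(cors >= max(cors) - 1e-12)[1L]  # ties -> lower index
    free[g] <- FALSE
    out[[i]] <- tibble::tibble(subject_state = subject_states$subject_state[i],
                               group_state = group_states$state[g],
                               correlation = cors[g])
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$subject_state)
}

#' Per-state degree centrality
#'
#' For each subject and each group state the subject visits, the member
#' matrices are averaged and the static chain (soft threshold, Fisher
#' r-to-z, undirected degree centrality) is applied to the mean matrix.
#' States a subject never visits simply have no rows.
#'
#' @param windows Window tibble over all subjects.
#' @param assignments Tibble with columns `subject`, `window`,
#'   `group_state` giving each window's mapped group state.
#' @param beta Soft-threshold exponent.
#' @return Tibble with columns `subject`, `state`, `node`, `dc`.
#' @export
per_state_dc <- function(windows, assignments, beta = 6) {
  joined <- dplyr::inner_join(windows, assignments, by = c("subject", "window"))
  if (nrow(joined) != nrow(windows)) {
    stop_invalid("assignments must cover every window")
  }
  labels <- attr(windows, "node_labels")
  groups <- dplyr::group_by(joined, .data$subject, .data$group_state)
  keys <- dplyr::group_keys(groups)
  res <- dplyr::group_map(groups, function(d, key) {
    m <- mean_matrices(d$matrix)
    lab <- if (is.null(labels)) default_labels(nrow(m)) else labels
    cm <- new_conn_matrix(m, "partial", lab)
    dc <- degree_centrality(weighted_graph(fisher_z(soft_threshold(cm, beta))$values,
                                           node_labels = lab))
    tibble::tibble(subject = key$subject, state = key$group_state,
                   node = dc$node, dc = dc$value)
  })
  dplyr::bind_rows(res)
}

#' Full dynamic-connectivity analysis over a cohort
#'
#' Runs the whole dynamic chain: per-subject tapered windowed covariances,
#' graphical-lasso precision per window (one penalty per subject, selected
#' by cross-validation when a grid is given), partial-correlation scaling,
#' state-count selection by per-subject silhouette voting, group-level
#' K-means states, participant-level clustering matched greedily to group
#' states, and per-(subject, state) degree centrality.
#'
#' @param ts_list List of [node_time_series()] objects, one per subject.
#' @param cfg A [window_config()].
#' @param lambda Single penalty or a candidate grid (grid triggers
#'   per-subject cross-validated selection).
#' @param k Number of states; `NULL` selects it via [select_num_states()].
#' @param k_range Candidate state counts when `k` is `NULL`.
#' @param seed Integer seed driving every stochastic stage.
#' @param beta Soft-threshold exponent for per-state DC.
#' @param n_folds Cross-validation folds for penalty selection.
#' @return A `dynamic_states` list: `windows`, `k`, `group_states`,
#'   `group_assignments`, `subject_assignments` (per-window mapped group
#'   state), `matching`, `dc` (per subject/state/node), `lambdas`.
#' @export
dynamic_states <- function(ts_list, cfg = window_config(), lambda = 0.1,
                           k = NULL, k_range = 2:6, seed = 1L, beta = 6,
                           n_folds = 5L) {
  stopifnot(length(ts_list) >= 1L)
  win_list <- lapply(ts_list, window_partial_correlations, cfg = cfg,
                     lambda = lambda, n_folds = n_folds)
  lambdas <- tibble::tibble(
    subject = vapply(ts_list, `[[`, character(1), "subject_id"),
    lambda = vapply(win_list, attr, numeric(1), "lambda")
  )
  windows <- dplyr::bind_rows(win_list)
  attr(windows, "node_labels") <- ts_list[[1]]$node_labels
  if (is.null(k)) {
    k <- as.integer(select_num_states(split(windows$matrix, windows$subject),
                                      k_range, seed = seed))
  }
  grp <- cluster_group_states(windows, k, seed = seed)
  subj_assign <- vector("list", length(win_list))
  match_list <- vector("list", length(win_list))
  for (i in seq_along(win_list)) {
    wi <- win_list[[i]]
    cs <- cluster_subject_states(wi$matrix, k, seed = seed + i)
    mp <- match_states(cs$states, grp$states)
    match_list[[i]] <- dplyr::mutate(mp, subject = wi$subject[1], .before = 1)
    subj_assign[[i]] <- tibble::tibble(
      subject = wi$subject, window = wi$window,
      group_state = mp$group_state[match(cs$labels, mp$subject_state)]
    )
  }
  subj_assign <- dplyr::bind_rows(subj_assign)
  dc <- per_state_dc(windows, subj_assign, beta = beta)
  structure(
    list(windows = windows, k = k, group_states = grp$states,
         group_assignments = grp$assignments,
         subject_assignments = subj_assign,
         matching = dplyr::bind_rows(match_list),
         dc = dc, lambdas = lambdas, seed = seed),
    class = "dynamic_states"
  )
}

#' @export
print.dynamic_states <- function(x, ...) {
  cat(sprintf("<dynamic_states: %d subjects, %d windows, k = %d states>\n",
              length(unique(x$windows$subject)), nrow(x$windows), x$k))
  invisible(x)
}

#' @export
tidy.brain_states <- function(x, ...) {
  tibble::tibble(state = x$state, occupancy = x$occupancy,
                 n_windows = x$n_windows)
}

#' Plot brain-state mean matrices
#'
#' Heatmap facets, one per state, of the mean partial-correlation matrix.
#'
#' @param object A `brain_states` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.brain_states <- function(object, ...) {
  labels <- attr(object, "node_labels")
  long <- dplyr::bind_rows(lapply(seq_len(nrow(object)), function(i) {
    m <- object$mean_matrix[[i]]
    lab <- if (is.null(labels)) default_labels(nrow(m)) else labels
    expand.grid(row = lab, col = lab, stringsAsFactors = FALSE) |>
      dplyr::mutate(value = as.vector(m),
                    state = sprintf("state %d (%.0f%%)", object$state[i],
                                    100 * object$occupancy[i]))
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::facet_wrap(~state) +
    ggplot2::labs(x = NULL, y = NULL, fill = "partial r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
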