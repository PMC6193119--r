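# Independent brute-force oracles used across the suite.

# Betweenness centrality by exhaustive enumeration of all simple paths.
# Edge length = 1/weight, zero-weight edges absent, fractional counting
# over equal-length shortest paths, unreachable pairs contribute 0.
brute_force_bc <- function(w, directed = FALSE) {
  p <- nrow(w)
  diag(w) <- 0
  len <- ifelse(w > 0, 1 / w, Inf)
  if (!directed) len <- pmin(len, t(len))
  bc <- numeric(p)
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(path, total) {
      v <- path[length(path)]
      if (v == t) {
        paths[[length(paths) + 1L]] <<- list(path = path, len = total)
        return()
      }
      for (u in seq_len(p)) {
        if (is.finite(len[v, u]) && !(u %in% path)) {
          walk(c(path, u), total + len[v, u])
        }
      }
    }
    walk(s, total = 0)
    paths
  }
  for (s in seq_len(p)) for (t in seq_len(p)) {
    if (s == t) next
    paths <- all_paths(s, t)
    if (length(paths) == 0L) next
    lens <- vapply(paths, `[[`, numeric(1), "len")
    shortest <- paths[lens <= min(lens) + 1e-9]
    n_sp <- length(shortest)
    through <- numeric(p)
    for (pp in shortest) {
      inner <- setdiff(pp$path, c(s, t))
      through[inner] <- through[inner] + 1
    }
    bc <- bc + through / n_sp
  }
  if (!directed) bc <- bc / 2
  bc
}

# Benjamini-Hochberg rejections by exhaustively checking every threshold:
# reject all p <= p_(k*) where k* is the largest k with p_(k) <= k alpha / m.
brute_force_bh_reject <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= seq_len(m) * alpha / m)
  if (length(ok) == 0L) return(rep(FALSE, m))
  p <= ps[max(ok)]
}

# Adjusted Rand index between two labelings (contingency-table form).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Planted state label of each window's center time point, concatenated in
# the row order of a windows tibble.
planted_center_labels <- function(cohort, windows) {
  unlist(lapply(unique(windows$subject), function(id) {
    seqs <- cohort$ground_truth$state_sequences[[id]]
    w <- windows[windows$subject == id, ]
    seqs[round(w$center_time)]
  }))
}

# Mean, over recovered states, of the best correlation between the
# recovered mean matrix and any planted partial-correlation matrix.
state_recovery_correlation <- function(cohort, group_states) {
  planted <- lapply(cohort$ground_truth$state_precisions$non_abdominal,
                    function(th) precision_to_partial_corr(th)$values)
  mean(vapply(group_states$mean_matrix, function(m) {
    max(vapply(planted, function(q) {
      cor(q[upper.tri(q)], m[upper.tri(m)])
    }, numeric(1)))
  }, numeric(1)))
}
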