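#' Synthetic cohort configuration
#'
#' Parameters of the synthetic-cohort generator. The defaults describe a
#' small desk-scale cohort: two groups (abdominal / non-abdominal), sparse
#' planted precision matrices per brain state, a Markov state sequence with
#' geometric dwell, a shared fiber-probability base matrix with a
#' multiplicative group effect on selected nodes, and EDE-Q subscale scores
#' generated linearly from planted DC values plus an age effect and
#' Gaussian noise.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param p Node count (>= 3).
#' @param t Time points per subject.
#' @param tr Sampling interval, seconds.
#' @param k_states Number of planted connectivity states (>= 1).
#' @param dwell_mean Mean state dwell time, time points (>= 1).
#' @param precision_sparsity Fraction of off-diagonal pairs that are
#'   nonzero in each state's precision, in \[0, 1\].
#' @param group_effect_nodes Node indices carrying the group effect.
#' @param group_effect_size Multiplicative factor applied, in the abdominal
#'   group, to precision and fiber entries touching the effect nodes.
#' @param edeq_beta Planted coefficient on the (standardised) DC signal in
#'   the EDE-Q scores.
#' @param edeq_age_beta Planted age coefficient.
#' @param edeq_noise_sd Residual standard deviation of the scores.
#' @param seed Integer seed; a fixed seed reproduces the cohort exactly.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_per_group = 20L, p = 10L, t = 600L, tr = 0.645,
                          k_states = 3L, dwell_mean = 40, precision_sparsity = 0.2,
                          group_effect_nodes = 1:2, group_effect_size = 1.5,
                          edeq_beta = 0.5, edeq_age_beta = 0.01,
                          edeq_noise_sd = 0.5, seed = 1L) {
  cfg <- list(
    n_per_group = check_count(n_per_group, "n_per_group", min = 2L),
    p = check_count(p, "p", min = 3L),
    t = check_count(t, "t", min = 10L),
    tr = check_scalar_number(tr, "tr", min = 0, strict_min = TRUE),
    k_states = check_count(k_states, "k_states", min = 1L),
    dwell_mean = check_scalar_number(dwell_mean, "dwell_mean", min = 1),
    precision_sparsity = check_scalar_number(precision_sparsity,
                                             "precision_sparsity", 0, 1),
    group_effect_nodes = as.integer(group_effect_nodes),
    group_effect_size = check_scalar_number(group_effect_size,
                                            "group_effect_size", min = 0,
                                            strict_min = TRUE),
    edeq_beta = check_scalar_number(edeq_beta, "edeq_beta"),
    edeq_age_beta = check_scalar_number(edeq_age_beta, "edeq_age_beta"),
    edeq_noise_sd = check_scalar_number(edeq_noise_sd, "edeq_noise_sd", min = 0),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (any(cfg$group_effect_nodes < 1L) || any(cfg$group_effect_nodes > cfg$p)) {
    stop_invalid("`group_effect_nodes` must be node indices in 1..p")
  }
  structure(cfg, class = "cohort_config")
}

#' Planted sparse precision matrices
#'
#' Generates k symmetric positive-definite precision matrices of dimension
#' p with approximately `sparsity * p * (p - 1) / 2` nonzero off-diagonal
#' pairs. The sparsity pattern is sampled preferring low-degree endpoints
#' (so rows rarely carry more than one or two edges); entries have
#' magnitude 0.4-0.6 and random sign, and the
#' diagonal is set to 0.05 + 1.6 * sum(|off-diagonal|) per row, so strict
#' diagonal dominance (hence positive definiteness) survives a later
#' scaling of off-diagonal entries by factors up to 1.6, while the implied
#' partial correlations stay large enough (roughly 0.3-0.6) to resemble
#' the conditional dependence strengths seen in regularised fMRI
#' connectivity. Each matrix is finally rescaled so its implied covariance
#' has unit diagonal (variance-normalised signals); partial correlations
#' are unaffected.
#'
#' @param p Node count (>= 3).
#' @param k Number of states (>= 1).
#' @param sparsity Fraction of nonzero off-diagonal pairs, in \[0, 1\].
#' @param seed Integer seed.
#' @return List of k SPD matrices.
#' @export
generate_state_precisions <- function(p, k, sparsity, seed = 1L) {
  p <- check_count(p, "p", min = 3L)
  k <- check_count(k, "k", min = 1L)
  check_scalar_number(sparsity, "sparsity", min = 0, max = 1)
  set.seed(stage_seed(seed, "precisions"))
  pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
  n_on <- round(sparsity * nrow(pairs))
  used <- rep(FALSE, nrow(pairs))    # pairs claimed by earlier states
  lapply(seq_len(k), function(s) {
    theta <- matrix(0, p, p)
    if (n_on > 0L) {
      # prefer pairs unused by other states (keeps states far apart) and
      # low-degree endpoints (keeps each planted partial strong after the
      # diagonal-dominance rescaling spreads over the row sum)
      ord <- sample.int(nrow(pairs))
      deg <- integer(p)
      taken <- rep(FALSE, nrow(pairs))
      for (pass in 1:2) for (cap in c(1L, 2L, p)) {
        if (sum(taken) >= n_on) break
        for (idx in ord) {
          if (sum(taken) >= n_on) break
          if (taken[idx] || (pass == 1L && used[idx])) next
          i <- pairs[idx, 1]; j <- pairs[idx, 2]
          if (deg[i] < cap && deg[j] < cap) {
            taken[idx] <- TRUE
            deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
          }
        }
      }
      used[taken] <<- TRUE
      sel <- pairs[taken, , drop = FALSE]
      vals <- runif(nrow(sel), 0.4, 0.6) * sample(c(-1, 1), nrow(sel), replace = TRUE)
      theta[sel] <- vals
      theta[sel[, c(2, 1), drop = FALSE]] <- vals
    }
    diag(theta) <- 0.05 + 1.6 * rowSums(abs(theta))
    # rescale so the implied covariance has unit diagonal; this leaves the
    # partial correlations untouched and mimics variance-normalised signals
    d <- sqrt(diag(solve(theta)))
    theta * outer(d, d)
  })
}

#' Markov state-label sequence with geometric dwell
#'
#' At each time point the chain stays in its current state with
#' probability 1 - 1/dwell_mean and otherwise jumps uniformly to one of the
#' other states, giving geometrically distributed dwell times with the
#' requested mean. The initial state is uniform.
#'
#' @param t Sequence length (>= 1).
#' @param k Number of states (>= 1).
#' @param dwell_mean Mean dwell time in time points (>= 1).
#' @param seed Integer seed.
#' @return Integer vector of labels in 1..k.
#' @export
generate_state_sequence <- function(t, k, dwell_mean, seed = 1L) {
  t <- check_count(t, "t", min = 1L)
  k <- check_count(k, "k", min = 1L)
  check_scalar_number(dwell_mean, "dwell_mean", min = 1)
  set.seed(stage_seed(seed, "sequence"))
  if (k == 1L) return(rep(1L, t))
  labels <- integer(t)
  labels[1] <- sample.int(k, 1L)
  p_exit <- 1 / dwell_mean
  switch_flags <- runif(t) < p_exit
  for (i in seq_len(t - 1L)) {
    if (switch_flags[i]) {
      labels[i + 1L] <- sample(setdiff(seq_len(k), labels[i]), 1L)
    } else {
      labels[i + 1L] <- labels[i]
    }
  }
  labels
}

scale_offdiag_effect <- function(theta, nodes, factor) {
  d <- diag(theta)
  mask <- matrix(FALSE, nrow(theta), ncol(theta))
  mask[nodes, ] <- TRUE
  mask[, nodes] <- TRUE
  diag(mask) <- FALSE
  theta[mask] <- theta[mask] * factor
  diag(theta) <- d
  theta
}

#' Generate a synthetic cohort with known ground truth
#'
#' Produces, per subject: a node-by-time Gaussian time series switching
#' between the planted state precisions (abdominal-group subjects have
#' precision edges touching the effect nodes scaled by the group effect), a
#' directed fiber-probability matrix (a shared base matrix, with effect-node
#' rows/columns scaled in the abdominal group, clipped to \[0, 1\]), and
#' demographics: balanced sexes, age uniform on \[20, 70\], BMI >= 25, WHR
#' drawn from non-overlapping sex-specific bands so that the WHR classifier
#' reproduces the intended group exactly. The four EDE-Q subscale scores
#' are generated as beta * (standardised structural DC + standardised
#' static functional DC at the first effect node) + age effect + constant +
#' Gaussian noise, truncated at zero.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort` list: `subjects` (tibble), `ts` (named list
#'   of [node_time_series()]), `fiber` (named list of
#'   [fiber_probability_matrix()]), and `ground_truth` (state sequences,
#'   state precisions per group, planted effects and coefficients).
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) stop_invalid("`config` must be a cohort_config")
  p <- config$p; n <- config$n_per_group
  base_prec <- generate_state_precisions(p, config$k_states,
                                         config$precision_sparsity, config$seed)
  prec_abd <- lapply(base_prec, scale_offdiag_effect,
                     nodes = config$group_effect_nodes,
                     factor = config$group_effect_size)
  for (th in prec_abd) {
    if (min(eigen(th, symmetric = TRUE, only.values = TRUE)$values) <= 1e-8) {
      stop_invalid("group effect makes a state precision non-positive-definite")
    }
  }

  ids <- sprintf("s%03d", seq_len(2L * n))
  group <- rep(c("abdominal", "non_abdominal"), each = n)
  set.seed(stage_seed(config$seed, "cohort"))
  sex <- as.vector(vapply(seq_len(2L), function(g) {
    rep_len(c("male", "female"), n)[sample.int(n)]
  }, character(n)))
  age <- runif(2L * n, 20, 70)
  whr <- numeric(2L * n)
  abd <- group == "abdominal"
  male <- sex == "male"
  whr[abd & male] <- runif(sum(abd & male), 0.92, 1.05)
  whr[abd & !male] <- runif(sum(abd & !male), 0.87, 1.00)
  whr[!abd & male] <- runif(sum(!abd & male), 0.78, 0.90)
  whr[!abd & !male] <- runif(sum(!abd & !male), 0.72, 0.85)
  stopifnot(identical(classify_whr(sex, whr), group))
  bmi <- pmax(25, rnorm(2L * n, mean = ifelse(abd, 31.4, 29.8),
                        sd = ifelse(abd, 5.0, 4.4)))

  # state sequences and state-switching Gaussian series
  state_seqs <- vector("list", 2L * n)
  ts <- vector("list", 2L * n)
  for (i in seq_len(2L * n)) {
    state_seqs[[i]] <- generate_state_sequence(config$t, config$k_states,
                                               config$dwell_mean,
                                               seed = config$seed * 977L + i)
    prec <- if (abd[i]) prec_abd else base_prec
    set.seed(stage_seed(config$seed, "series") + i)
    z <- matrix(rnorm(p * config$t), p, config$t)
    x <- matrix(0, p, config$t)
    for (s in seq_len(config$k_states)) {
      idx <- which(state_seqs[[i]] == s)
      if (length(idx) > 0L) {
        r <- chol(prec[[s]])            # prec = R'R  =>  x = R^{-1} z has cov prec^{-1}
        x[, idx] <- backsolve(r, z[, idx, drop = FALSE])
      }
    }
    ts[[i]] <- node_time_series(x, tr = config$tr, subject_id = ids[i])
  }
  names(ts) <- ids
  names(state_seqs) <- ids

  # fiber matrices: one shared base, effect rows/columns scaled in group 1
  set.seed(stage_seed(config$seed, "fiber"))
  base_fiber <- matrix(runif(p * p, 0, 0.3), p, p)
  diag(base_fiber) <- 0
  fiber_abd <- scale_offdiag_effect(base_fiber, config$group_effect_nodes,
                                    config$group_effect_size)
  fiber_abd <- pmin(pmax(fiber_abd, 0), 1)
  fiber <- lapply(seq_len(2L * n), function(i) {
    fiber_probability_matrix(if (abd[i]) fiber_abd else base_fiber,
                             subject_id = ids[i])
  })
  names(fiber) <- ids

  # EDE-Q scores from planted DC values plus age effect and noise
  e1 <- config$group_effect_nodes[1]
  dc_s <- vapply(fiber, function(f) structural_dc(f)$value[e1], numeric(1))
  dc_f <- vapply(ts, function(x) static_dc(x)$value[e1], numeric(1))
  zsafe <- function(v) {
    s <- sd(v)
    if (!is.finite(s) || s < 1e-12) v - mean(v) else (v - mean(v)) / s
  }
  signal <- config$edeq_beta * (zsafe(dc_s) + zsafe(dc_f))
  consts <- c(edeq_r = 1.5, edeq_e = 0.4, edeq_s = 1.85, edeq_w = 1.55)
  set.seed(stage_seed(config$seed, "behaviour"))
  scores <- lapply(consts, function(C) {
    pmax(0, signal + config$edeq_age_beta * age + C +
           rnorm(2L * n, sd = config$edeq_noise_sd))
  })

  subjects <- tibble::tibble(
    id = ids, sex = sex, age = age, bmi = bmi, whr = whr, group = group,
    edeq_r = scores$edeq_r, edeq_e = scores$edeq_e,
    edeq_s = scores$edeq_s, edeq_w = scores$edeq_w
  )
  structure(
    list(
      subjects = subjects, ts = ts, fiber = fiber,
      ground_truth = list(
        state_sequences = state_seqs,
        state_precisions = list(non_abdominal = base_prec, abdominal = prec_abd),
        true_dc_effects = list(nodes = config$group_effect_nodes,
                               size = config$group_effect_size),
        true_edeq_betas = list(dc = config$edeq_beta, age = config$edeq_age_beta,
                               constants = consts),
        planted_dc = tibble::tibble(id = ids, dc_structural = unname(dc_s),
                                    dc_static = unname(dc_f))
      ),
      config = config
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d subjects (%d/group), %d nodes, %d time points, %d states>\n",
              nrow(x$subjects), x$config$n_per_group, x$config$p, x$config$t,
              x$config$k_states))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Lays the cohort out in the pipeline's on-disk format: `subjects.tsv`,
#' per-subject `ts_<id>.tsv` (p rows x t columns) and `fiber_<id>.tsv`
#' (p x p), and a `ground_truth/` directory with per-subject state-label
#' files and the planted precision matrices.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "synthetic_cohort")) {
    stop_invalid("`cohort` must be a synthetic_cohort")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt_dir <- file.path(dir, "ground_truth")
  dir.create(gt_dir, showWarnings = FALSE)
  write_subject_table(cohort$subjects, file.path(dir, "subjects.tsv"))
  for (id in cohort$subjects$id) {
    write_matrix_tsv(cohort$ts[[id]]$data, file.path(dir, paste0("ts_", id, ".tsv")))
    write_matrix_tsv(cohort$fiber[[id]]$values,
                     file.path(dir, paste0("fiber_", id, ".tsv")))
    utils::write.table(cohort$ground_truth$state_sequences[[id]],
                       file.path(gt_dir, paste0("states_", id, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  for (g in names(cohort$ground_truth$state_precisions)) {
    precs <- cohort$ground_truth$state_precisions[[g]]
    for (s in seq_along(precs)) {
      write_matrix_tsv(precs[[s]],
                       file.path(gt_dir, sprintf("precision_%s_state%d.tsv", g, s)))
    }
  }
  invisible(dir)
}
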