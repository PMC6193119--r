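# Internal helpers: argument checks, seed bookkeeping, matrix plumbing.

stop_invalid <- function(msg, ...) {
  abort(msg, class = "connstates_invalid_argument", ...)
}

stop_degenerate <- function(msg, ...) {
  abort(msg, class = "connstates_degenerate_input", ...)
}

stop_format <- function(msg, ...) {
  abort(msg, class = "connstates_format_error", ...)
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number", name))
  }
  if (strict_min && x <= min) {
    stop_invalid(sprintf("`%s` must be > %g (got %g)", name, min, x))
  }
  if (!strict_min && x < min) {
    stop_invalid(sprintf("`%s` must be >= %g (got %g)", name, min, x))
  }
  if (x > max) {
    stop_invalid(sprintf("`%s` must be <= %g (got %g)", name, max, x))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_scalar_number(x, name, min = min)
  if (x != as.integer(x)) {
    stop_invalid(sprintf("`%s` must be an integer (got %g)", name, x))
  }
  as.integer(x)
}

check_square_matrix <- function(m, name = "matrix") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop_invalid(sprintf("`%s` must be a numeric matrix", name))
  }
  if (nrow(m) != ncol(m)) {
    stop_invalid(sprintf("`%s` must be square (got %d x %d)", name, nrow(m), ncol(m)))
  }
  if (any(!is.finite(m))) {
    stop_invalid(sprintf("`%s` contains non-finite entries", name))
  }
  invisible(m)
}

is_symmetric_tol <- function(m, tol = 1e-10) {
  max(abs(m - t(m))) <= tol
}

default_labels <- function(p) paste0("node", seq_len(p))

# Per-stage seeds derived from one global seed by fixed offsets, so each
# stochastic stage is independently reproducible. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  offsets <- c(
    cohort = 101L, precisions = 211L, sequence = 307L, series = 401L,
    fiber = 503L, behaviour = 601L, kmeans_group = 701L,
    kmeans_subject = 809L, kselect = 907L, permutation = 1009L
  )
  off <- offsets[[stage]]
  if (is.null(off)) stop_invalid(sprintf("unknown stage `%s`", stage))
  (as.integer(seed) %% 2000000000L) + off
}

# Vectorise the strict upper triangle of a square matrix (row-major pairs).
upper_tri_vec <- function(m) {
  m[upper.tri(m)]
}

mean_matrices <- function(mats) {
  Reduce(`+`, mats) / length(mats)
}
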