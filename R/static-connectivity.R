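#' Node time series
#'
#' A node-by-time matrix of fMRI-derived signals (rows = nodes / independent
#' components, columns = time points) with its sampling interval (TR).
#'
#' @param data Numeric matrix, nodes in rows, time points in columns.
#' @param tr Repetition time in seconds (sampling interval).
#' @param subject_id Optional subject identifier.
#' @param node_labels Optional node names; default `node1`, ...
#' @return A `node_ts` object.
#' @export
node_time_series <- function(data, tr, subject_id = NA_character_,
                             node_labels = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop_invalid("`data` must be a numeric node-by-time matrix")
  }
  if (nrow(data) < 2L) stop_invalid("need at least 2 nodes")
  if (anyNA(data) || any(!is.finite(data))) {
    stop_invalid("time series contain missing or non-finite values")
  }
  check_scalar_number(tr, "tr", min = 0, strict_min = TRUE)
  if (is.null(node_labels)) node_labels <- default_labels(nrow(data))
  if (length(node_labels) != nrow(data)) {
    stop_invalid("`node_labels` length must equal the node count")
  }
  structure(
    list(data = unname(data), tr = tr, subject_id = as.character(subject_id),
         node_labels = as.character(node_labels)),
    class = "node_ts"
  )
}

#' @export
print.node_ts <- function(x, ...) {
  cat(sprintf("<node_ts %s: %d nodes x %d time points, TR = %gs>\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

new_conn_matrix <- function(values, stage, node_labels) {
  structure(
    list(values = unname(values), stage = stage,
         node_labels = as.character(node_labels)),
    class = "conn_matrix"
  )
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix: %d nodes, stage = %s>\n", nrow(x$values), x$stage))
  invisible(x)
}

#' Pearson correlation connectivity
#'
#' Static functional connectivity: the Pearson correlation of the full time
#' series between every pair of nodes.
#'
#' @param ts A [node_time_series()].
#' @return A `conn_matrix` at stage `"correlation"` (diagonal exactly 1).
#' @export
pearson_connectivity <- function(ts) {
  if (!inherits(ts, "node_ts")) stop_invalid("`ts` must be a node_ts")
  if (ncol(ts$data) < 3L) stop_invalid("need at least 3 time points")
  v <- apply(ts$data, 1L, var)
  if (any(v <= 0)) {
    bad <- ts$node_labels[which(v <= 0)]
    stop_degenerate(sprintf("zero-variance node(s): %s", paste(bad, collapse = ", ")))
  }
  r <- cor(t(ts$data))
  diag(r) <- 1
  r <- pmin(pmax(r, -1), 1)
  new_conn_matrix(r, "correlation", ts$node_labels)
}

#' Unsigned soft thresholding of a correlation matrix
#'
#' Maps each correlation r in \[-1, 1\] to an edge weight
#' w = ((r + 1) / 2)^beta in \[0, 1\], a continuous (soft) alternative to a
#' hard cutoff that preserves weight ordering. The default exponent beta = 6
#' gives the conventional unsigned weighted network.
#'
#' @param m A `conn_matrix` at stage `"correlation"` or `"partial"`.
#' @param beta Positive soft-threshold exponent (default 6).
#' @return A `conn_matrix` at stage `"soft"` with entries in \[0, 1\].
#' @export
soft_threshold <- function(m, beta = 6) {
  if (!inherits(m, "conn_matrix")) stop_invalid("`m` must be a conn_matrix")
  if (!m$stage %in% c("correlation", "partial")) {
    stop_invalid(sprintf("soft threshold expects a correlation-scale matrix, got stage `%s`", m$stage))
  }
  check_scalar_number(beta, "beta", min = 0, strict_min = TRUE)
  r <- m$values
  if (any(r < -1 - 1e-12) || any(r > 1 + 1e-12)) {
    stop_invalid("correlation entries must lie in [-1, 1]")
  }
  w <- ((pmin(pmax(r, -1), 1) + 1) / 2)^beta
  new_conn_matrix(w, "soft", m$node_labels)
}

#' Fisher r-to-z transform of soft-thresholded weights
#'
#' Applies z = atanh(w) element-wise off the diagonal. The diagonal is
#' zeroed first: the self-edge weight is 1 and atanh(1) diverges, and
#' self-edges carry no information for degree centrality.
#'
#' @param m A `conn_matrix` at stage `"soft"`.
#' @return A `conn_matrix` at stage `"fisher_z"` with zero diagonal.
#' @export
fisher_z <- function(m) {
  if (!inherits(m, "conn_matrix")) stop_invalid("`m` must be a conn_matrix")
  if (m$stage != "soft") {
    stop_invalid(sprintf("fisher_z expects stage `soft`, got `%s`", m$stage))
  }
  w <- m$values
  diag(w) <- 0
  if (any(w >= 1)) {
    stop_degenerate("off-diagonal weight >= 1: atanh diverges")
  }
  if (any(w < 0)) stop_invalid("soft weights must be nonnegative")
  z <- atanh(w)
  new_conn_matrix(z, "fisher_z", m$node_labels)
}

#' Static degree centrality from node time series
#'
#' The full static chain: Pearson correlation, unsigned soft thresholding,
#' Fisher r-to-z, then undirected degree centrality (column sums of the
#' z-transformed matrix, diagonal excluded).
#'
#' @inheritParams pearson_connectivity
#' @inheritParams soft_threshold
#' @return A `centrality` tibble with one DC value per node.
#' @export
#' @examples
#' set.seed(1)
#' ts <- node_time_series(matrix(rnorm(4 * 300), 4), tr = 0.645)
#' static_dc(ts)
static_dc <- function(ts, beta = 6) {
  z <- fisher_z(soft_threshold(pearson_connectivity(ts), beta = beta))
  degree_centrality(weighted_graph(z$values, directed = FALSE,
                                   node_labels = z$node_labels))
}
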