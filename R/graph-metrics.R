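#' Weighted graph from an adjacency matrix
#'
#' Wraps a square matrix of nonnegative edge weights together with its
#' directedness and node labels. Undirected graphs must be symmetric (within
#' 1e-10). The diagonal is ignored by every metric: self-connections are
#' artifacts of correlation (r = 1 with itself) and of tractography seeding,
#' and carry no centrality information.
#'
#' @param weights Square numeric matrix of nonnegative edge weights.
#' @param directed Logical; if `FALSE`, `weights` must be symmetric.
#' @param node_labels Character vector of node names (default `node1`, ...).
#' @return A `weighted_graph` object.
#' @export
#' @examples
#' g <- weighted_graph(matrix(c(0, 1, 1, 0), 2), directed = FALSE)
#' degree_centrality(g)
weighted_graph <- function(weights, directed = FALSE, node_labels = NULL) {
  check_square_matrix(weights, "weights")
  if (any(weights < 0)) {
    stop_invalid("edge weights must be nonnegative")
  }
  if (!directed && !is_symmetric_tol(weights)) {
    stop_invalid("undirected graph requires a symmetric weight matrix (tolerance 1e-10)")
  }
  p <- nrow(weights)
  if (is.null(node_labels)) node_labels <- default_labels(p)
  if (length(node_labels) != p) {
    stop_invalid("`node_labels` length must equal the node count")
  }
  structure(
    list(weights = unname(weights), directed = isTRUE(directed),
         node_labels = as.character(node_labels)),
    class = "weighted_graph"
  )
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("<weighted_graph: %d nodes, %s>\n", nrow(x$weights),
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

as_weighted_graph <- function(g, directed = FALSE) {
  if (inherits(g, "weighted_graph")) return(g)
  weighted_graph(g, directed = directed)
}

new_centrality <- function(values, labels, metric, normalized = FALSE) {
  out <- tibble::tibble(node = labels, value = unname(values))
  attr(out, "metric") <- metric
  attr(out, "normalized") <- normalized
  class(out) <- c("centrality", class(out))
  out
}

#' Weighted degree centrality
#'
#' Degree centrality (DC) of each node, excluding the diagonal. For a
#' directed graph DC is in-degree plus out-degree, i.e. the column sum plus
#' the row sum of the edge weights at that node; for an undirected graph it
#' is the column sum alone.
#'
#' @param g A [weighted_graph()], or a square weight matrix.
#' @param directed Used only when `g` is a bare matrix.
#' @return A `centrality` tibble with columns `node` and `value`.
#' @export
#' @examples
#' m <- matrix(c(0, 0.2, 0, 0, 0, 0.5, 0.1, 0, 0), 3, byrow = TRUE)
#' degree_centrality(m, directed = TRUE)
degree_centrality <- function(g, directed = FALSE) {
  g <- as_weighted_graph(g, directed)
  w <- g$weights
  diag(w) <- 0
  vals <- if (g$directed) colSums(w) + rowSums(w) else colSums(w)
  new_centrality(vals, g$node_labels, metric = "dc")
}

#' Weighted betweenness centrality
#'
#' Betweenness centrality (BC) over weighted shortest paths where the length
#' of an edge is the reciprocal of its weight (strong edges are short).
#' Edges of weight zero are treated as absent; unreachable pairs contribute
#' nothing. Equal-length shortest paths share their contribution
#' fractionally (Brandes counting, via igraph).
#'
#' @inheritParams degree_centrality
#' @return A `centrality` tibble with columns `node` and `value`.
#' @export
betweenness_centrality <- function(g, directed = FALSE) {
  g <- as_weighted_graph(g, directed)
  w <- g$weights
  diag(w) <- 0
  ig <- igraph::graph_from_adjacency_matrix(
    w, mode = if (g$directed) "directed" else "undirected",
    weighted = TRUE, diag = FALSE
  )
  lens <- 1 / igraph::E(ig)$weight
  vals <- igraph::betweenness(ig, directed = g$directed, weights = lens)
  new_centrality(as.numeric(vals), g$node_labels, metric = "bc")
}

#' Normalise centrality values by their mean
#'
#' Divides every value by the mean value so the normalised vector has mean
#' one; hubness is then read off as a multiple of the average node.
#'
#' @param c A `centrality` tibble.
#' @return The same tibble with `value` rescaled and the `normalized`
#'   attribute set.
#' @export
normalize_centrality <- function(c) {
  if (!inherits(c, "centrality")) stop_invalid("`c` must be a centrality result")
  m <- mean(c$value)
  if (!is.finite(m) || m <= 0) {
    stop_degenerate("cannot normalise: mean centrality is not positive")
  }
  out <- c
  out$value <- c$value / m
  attr(out, "normalized") <- TRUE
  out
}

#' Identify hub nodes
#'
#' A node is a hub when its mean-normalised centrality strictly exceeds the
#' threshold (default 1.5); boundary values are not hubs.
#'
#' @param c A normalised `centrality` tibble (see [normalize_centrality()]).
#' @param threshold Hubness cutoff; strict inequality.
#' @return Integer vector of hub node indices, named by node label.
#' @export
identify_hubs <- function(c, threshold = 1.5) {
  if (!inherits(c, "centrality")) stop_invalid("`c` must be a centrality result")
  if (!isTRUE(attr(c, "normalized"))) {
    stop_invalid("`c` must be normalised first (see normalize_centrality())")
  }
  idx <- which(c$value > threshold)
  setNames(idx, c$node[idx])
}

#' @export
#' @rdname degree_centrality
#' @param object,x A `centrality` tibble.
#' @param ... Unused.
tidy.centrality <- function(x, ...) {
  tibble::tibble(node = x$node, value = x$value,
                 metric = attr(x, "metric"),
                 normalized = attr(x, "normalized"))
}

#' Plot a centrality profile
#'
#' Bar chart of per-node centrality; when the values are normalised the hub
#' threshold is drawn as a dashed line.
#'
#' @param object A `centrality` tibble.
#' @param threshold Hub cutoff drawn for normalised values.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.centrality <- function(object, threshold = 1.5, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$node, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = toupper(attr(object, "metric"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (isTRUE(attr(object, "normalized"))) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}
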