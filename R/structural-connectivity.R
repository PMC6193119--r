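#' Fiber probability matrix
#'
#' A directed, weighted structural connectivity matrix whose entry (i, j) is
#' the probability that probabilistic tractography streamlines seeded in
#' region i reach region j. Entries must lie in \[0, 1\]; the diagonal is
#' forced to zero (self-connection probabilities are a tractography
#' artifact). Asymmetry is preserved: seed-to-target and target-to-seed
#' probabilities differ.
#'
#' @param values Square numeric matrix with entries in \[0, 1\].
#' @param node_labels Optional node (region) names.
#' @param subject_id Optional subject identifier.
#' @return A `fiber_matrix` object.
#' @export
fiber_probability_matrix <- function(values, node_labels = NULL,
                                     subject_id = NA_character_) {
  check_square_matrix(values, "values")
  bad <- which(values < 0 | values > 1, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_format(sprintf("fiber probability out of [0, 1] at row %d col %d (value %g)",
                        bad[1, 1], bad[1, 2], values[bad[1, 1], bad[1, 2]]))
  }
  if (any(diag(values) != 0)) {
    message("nonzero diagonal in fiber matrix; forcing self-connections to 0")
    diag(values) <- 0
  }
  p <- nrow(values)
  if (is.null(node_labels)) node_labels <- default_labels(p)
  if (length(node_labels) != p) {
    stop_invalid("`node_labels` length must equal the node count")
  }
  structure(
    list(values = unname(values), node_labels = as.character(node_labels),
         subject_id = as.character(subject_id)),
    class = "fiber_matrix"
  )
}

#' @export
print.fiber_matrix <- function(x, ...) {
  cat(sprintf("<fiber_matrix %s: %d regions>\n", x$subject_id, nrow(x$values)))
  invisible(x)
}

#' Read a fiber probability matrix from TSV
#'
#' Expects a headerless numeric TSV with as many rows as columns and all
#' entries in \[0, 1\]. A nonzero diagonal is zeroed with a note.
#'
#' @param path Path to the TSV file.
#' @param node_labels Optional node names (e.g. read from a label file).
#' @param subject_id Subject identifier; default the file name stem.
#' @return A [fiber_probability_matrix()].
#' @export
load_fiber_matrix <- function(path, node_labels = NULL, subject_id = NULL) {
  m <- read_matrix_tsv(path, expect_square = TRUE)
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
    subject_id <- sub("^fiber_", "", subject_id)
  }
  fiber_probability_matrix(m, node_labels = node_labels, subject_id = subject_id)
}

#' Structural degree centrality
#'
#' Degree centrality of the directed weighted fiber-probability graph:
#' in-degree (column sum) plus out-degree (row sum) of the raw
#' probabilities at each node.
#'
#' @param m A [fiber_probability_matrix()].
#' @return A `centrality` tibble with one DC value per region.
#' @export
structural_dc <- function(m) {
  if (!inherits(m, "fiber_matrix")) stop_invalid("`m` must be a fiber_matrix")
  degree_centrality(weighted_graph(m$values, directed = TRUE,
                                   node_labels = m$node_labels))
}
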