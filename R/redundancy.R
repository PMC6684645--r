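#' Cosine similarity between binary label vectors
#'
#' Redundancy of two metadata assignments over the same node set:
#' `dot(a, b) / (||a|| ||b||)`. Identical vectors give 1 (maximum
#' redundancy), disjoint supports give 0.
#'
#' @param a,b Numeric 0/1 vectors over the same ordered node set.
#' @return Similarity in `[0, 1]`.
#' @examples
#' cosine_similarity(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 0.5
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) {
    stop("vectors must share the same node set", call. = FALSE)
  }
  na2 <- sum(a^2)
  nb2 <- sum(b^2)
  if (na2 == 0 || nb2 == 0) {
    stop("cosine similarity undefined for an all-zero vector", call. = FALSE)
  }
  sum(a * b) / sqrt(na2 * nb2)
}

#' Redundancy-Relevance pair table
#'
#' For every unordered pair of (non-degenerate) annotations, reports the
#' cosine redundancy of their label vectors together with each member's
#' relevance score — the tabular form of the R-R diagram. Label vectors
#' are built in the canonical sorted node order, fixed once per analysis.
#'
#' @param graph An undirected simple `igraph` graph.
#' @param annotations Named list of at least two [binary_annotation()]s.
#' @return `data.frame` with columns `attribute_a`, `attribute_b`,
#'   `cosine`, `relevance_a`, `relevance_b`, sorted by `cosine`
#'   descending. Pairs involving an annotation excluded from ranking are
#'   omitted.
#' @export
rr_table <- function(graph, annotations) {
  ranked <- rank_metadata(graph, annotations)
  if (nrow(ranked) < 2L) {
    stop("need at least two non-degenerate annotations", call. = FALSE)
  }
  ids <- node_ids(graph)
  vecs <- lapply(annotations, function(a) {
    validate_annotation(graph, a)$labels[ids]
  })
  names(vecs) <- vapply(annotations, function(a) {
    if (inherits(a, "binary_annotation")) a$name else ""
  }, character(1))
  kept <- ranked$attribute
  rel <- stats::setNames(ranked$r, ranked$attribute)
  pairs <- utils::combn(kept, 2L)
  out <- data.frame(
    attribute_a = pairs[1L, ], attribute_b = pairs[2L, ],
    cosine = apply(pairs, 2L, function(p) {
      cosine_similarity(vecs[[p[1L]]], vecs[[p[2L]]])
    }),
    relevance_a = rel[pairs[1L, ]], relevance_b = rel[pairs[2L, ]],
    stringsAsFactors = FALSE)
  out <- out[order(-out$cosine, out$attribute_a, out$attribute_b,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
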