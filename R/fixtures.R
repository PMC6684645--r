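# Synthetic annotated networks used throughout the test suite and in
# examples. All generators are seed-deterministic and emit simple
# undirected graphs with named vertices.

# All unordered pairs among `ids`, as a 2-column character matrix.
all_pairs <- function(ids) {
  if (length(ids) < 2L) {
    return(matrix(character(0), ncol = 2L))
  }
  t(utils::combn(ids, 2L))
}

#' Graph with prescribed dyad counts
#'
#' Builds a simple undirected graph with `n` nodes (the first `n1`
#' flagged) whose dyad counts equal `(m11, m10, m00)` exactly: edges are
#' drawn by seeded sampling without replacement within each of the three
#' dyad classes. Dyadicity and heterophilicity depend only on
#' `(n, m, n1, m11, m10)`, so every seed yields the same `(D, H)`.
#' Isolated nodes may occur; the graph need not be connected.
#'
#' @param n Number of nodes.
#' @param n1 Number of flagged nodes.
#' @param m11,m10,m00 Required dyad counts; must satisfy
#'   `m11 <= choose(n1, 2)`, `m10 <= n1 * (n - n1)`,
#'   `m00 <= choose(n - n1, 2)`.
#' @param seed Integer seed.
#' @return List with elements `graph` (igraph) and `annotation`
#'   ([binary_annotation()]).
#' @examples
#' fx <- counts_constrained_graph(5, 2, m11 = 1, m10 = 2, m00 = 1, seed = 7)
#' count_dyads(fx$graph, fx$annotation)
#' @export
counts_constrained_graph <- function(n, n1, m11, m10, m00, seed = 1L) {
  n0 <- n - n1
  if (m11 > choose(n1, 2) || m10 > n1 * n0 || m00 > choose(n0, 2) ||
      min(m11, m10, m00) < 0) {
    stop("infeasible dyad counts for the given (n, n1)", call. = FALSE)
  }
  flagged <- sprintf("f%02d", seq_len(n1))
  unflagged <- sprintf("u%02d", seq_len(n0))
  pick <- function(pool, k) {
    if (k == 0L || nrow(pool) == 0L) {
      return(pool[0L, , drop = FALSE])
    }
    pool[sample.int(nrow(pool), k), , drop = FALSE]
  }
  edges <- with_seed(seed, rbind(
    pick(all_pairs(flagged), m11),
    pick(as.matrix(expand.grid(flagged, unflagged,
                               stringsAsFactors = FALSE)), m10),
    pick(all_pairs(unflagged), m00)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1L], to = edges[, 2L],
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = c(flagged, unflagged))
  ann <- binary_annotation(
    stats::setNames(as.integer(c(flagged, unflagged) %in% flagged),
                    c(flagged, unflagged)),
    name = "planted")
  list(graph = g, annotation = ann)
}

#' Rich-club toy network
#'
#' A fixed 43-node, 45-edge network in which the four flagged nodes form
#' a clique (`m11 = 6`) and hold the four highest degrees, with 37 mixed
#' dyads and 2 unflagged-unflagged dyads. Despite strongly disassortative
#' mixing, the flagged rich-club makes the configuration highly dyadic
#' (`D ~ 20.07`) and heterophilic (`H ~ 4.76`) — the canonical example of
#' the dyadic effect revealing structure that the assortativity
#' coefficient alone hides. The exact edge set is a deterministic
#' reconstruction from those dyad counts, which fully determine `D` and
#' `H`.
#'
#' @return List with elements `graph` and `annotation` (`n1 = 4`).
#' @examples
#' toy <- rich_club_toy()
#' count_dyads(toy$graph, toy$annotation)  # (6, 37, 2)
#' @export
rich_club_toy <- function() {
  flagged <- sprintf("f%d", 1:4)
  unflagged <- sprintf("u%02d", 1:39)
  clique <- all_pairs(flagged)
  cross <- rbind(cbind("f1", unflagged[1:10]),
                 cbind("f2", unflagged[11:19]),
                 cbind("f3", unflagged[20:28]),
                 cbind("f4", unflagged[29:37]))
  # two 0-0 dyads hanging the last two unflagged nodes off the periphery,
  # keeping the graph connected and all unflagged degrees <= 2
  plain <- rbind(c("u01", "u38"), c("u02", "u39"))
  edges <- rbind(clique, cross, plain)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1L], to = edges[, 2L],
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = c(flagged, unflagged))
  ann <- binary_annotation(
    stats::setNames(as.integer(c(flagged, unflagged) %in% flagged),
                    c(flagged, unflagged)),
    name = "rich_club")
  list(graph = g, annotation = ann)
}

#' Random annotated graph
#'
#' A uniform random simple graph with `n` nodes and `m` edges
#' (Erdos-Renyi G(n, m)) together with a uniform random `n1`-subset of
#' flagged nodes; fully determined by the seed.
#'
#' @param n,m Nodes and edges, `m <= choose(n, 2)`.
#' @param n1 Number of flagged nodes.
#' @param seed Integer seed.
#' @return List with elements `graph` and `annotation`.
#' @examples
#' fx <- random_annotated_graph(25, 32, 5, seed = 1)
#' igraph::ecount(fx$graph)  # 32
#' @export
random_annotated_graph <- function(n, m, n1, seed = 1L) {
  stopifnot(m <= choose(n, 2), n1 <= n)
  ids <- sprintf("v%03d", seq_len(n))
  with_seed(seed, {
    g <- igraph::sample_gnm(n, m)
    igraph::V(g)$name <- ids
    flags <- integer(n)
    flags[sample.int(n, n1)] <- 1L
    ann <- binary_annotation(stats::setNames(flags, ids), name = "random")
    list(graph = g, annotation = ann)
  })
}

#' Write an annotation as a metadata CSV
#'
#' Companion to [write_edge_list()] for round-tripping fixtures through
#' the file-based interface: a two-column CSV (`id`, attribute name).
#'
#' @param annotation A [binary_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_csv <- function(annotation, path) {
  df <- data.frame(id = names(annotation$labels),
                   value = annotation$labels,
                   stringsAsFactors = FALSE)
  names(df)[2L] <- annotation$name
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
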