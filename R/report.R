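#' Full dyadic-effect analysis of a network and its metadata
#'
#' The end-to-end pipeline behind the command-line `analyze` report:
#' read (or accept) the graph and metadata table, optionally dichotomize
#' numeric attributes at their mean, validate each resulting annotation,
#' compute dyad counts, bounds, `D`, `H` and the relevance score per
#' attribute, attach permutation p-values, and sort by relevance. One
#' permutation set per attribute is reused for `p_D`, `p_H` and `p_r`.
#'
#' @param graph An `igraph` graph, or the path of an edge-list file.
#' @param metadata A metadata `data.frame` (first column `id`), or the
#'   path of a metadata CSV.
#' @param binarize Dichotomize numeric attributes at the mean
#'   ([binarize_mean()])? Set `FALSE` when the columns are already 0/1.
#' @param permutations Number of label permutations per attribute.
#' @param seed Integer seed for the permutation null.
#' @param delimiter Optional delimiter overrides, passed to the readers
#'   as `list(edges = ..., metadata = ...)`.
#' @return `data.frame` with columns `attribute`, `n1`, `D`, `H`,
#'   `region`, `r`, `p_D`, `p_H`, `p_r`, sorted by `r` descending;
#'   attributes `seed`, `permutations` and `excluded` carry provenance.
#' @examples
#' toy <- rich_club_toy()
#' md <- data.frame(id = names(toy$annotation$labels),
#'                  rich_club = toy$annotation$labels)
#' analyze_metadata(toy$graph, md, binarize = FALSE,
#'                  permutations = 50, seed = 1)
#' @export
analyze_metadata <- function(graph, metadata, binarize = TRUE,
                             permutations = 1000L, seed = 1L,
                             delimiter = list()) {
  if (is.character(graph)) {
    graph <- read_edge_list(graph, delimiter = delimiter$edges)
  }
  if (is.character(metadata)) {
    metadata <- read_metadata_table(metadata,
                                    delimiter = delimiter$metadata %||% ",")
  }
  anns <- metadata_annotations(metadata, binarize = binarize)
  ranked <- rank_metadata(graph, anns)
  pvals <- lapply(ranked$attribute, function(a) {
    permutation_test(graph, anns[[a]], K = permutations, seed = seed)
  })
  out <- data.frame(
    attribute = ranked$attribute, n1 = ranked$n1,
    D = ranked$D, H = ranked$H, region = ranked$region, r = ranked$r,
    p_D = vapply(pvals, `[[`, numeric(1), "p_D"),
    p_H = vapply(pvals, `[[`, numeric(1), "p_H"),
    p_r = vapply(pvals, `[[`, numeric(1), "p_r"),
    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  attr(out, "permutations") <- as.integer(permutations)
  attr(out, "excluded") <- attr(ranked, "excluded")
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write an analysis table as TSV
#'
#' Fixed column order (`attribute`, `n1`, `D`, `H`, `r`, `p_D`, `p_H`,
#' `p_r`), `D`/`H`/`r` displayed with 2 decimals and p-values with 3;
#' the seed and permutation count are echoed into a header comment for
#' provenance. Full precision is retained in the returned object, only
#' the display is rounded.
#'
#' @param analysis Result of [analyze_metadata()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_analysis_tsv <- function(analysis, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dyadnet analyze: K = %s, seed = %s",
                     format(attr(analysis, "permutations")),
                     format(attr(analysis, "seed"))), con)
  disp <- data.frame(
    attribute = analysis$attribute, n1 = analysis$n1,
    D = sprintf("%.2f", analysis$D), H = sprintf("%.2f", analysis$H),
    r = sprintf("%.2f", analysis$r),
    p_D = sprintf("%.3f", analysis$p_D),
    p_H = sprintf("%.3f", analysis$p_H),
    p_r = sprintf("%.3f", analysis$p_r),
    stringsAsFactors = FALSE)
  utils::write.table(disp, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Degree and betweenness per node
#'
#' The two centralities of the degree-betweenness diagram used to gauge
#' the structural importance of individual nodes. Betweenness is the
#' unnormalized shortest-path count.
#'
#' @param graph A nonempty `igraph` graph.
#' @return `data.frame` with columns `node`, `degree`, `betweenness`,
#'   sorted by degree descending.
#' @examples
#' centrality_table(igraph::make_star(5, mode = "undirected"))
#' @export
centrality_table <- function(graph) {
  if (igraph::vcount(graph) == 0L) stop("empty graph", call. = FALSE)
  ids <- node_ids(graph)
  nm <- igraph::vertex_attr(graph, "name")
  ord <- if (is.null(nm)) seq_along(ids) else match(ids, nm)
  deg <- igraph::degree(graph)[ord]
  btw <- igraph::betweenness(graph, directed = FALSE, normalized = FALSE)[ord]
  out <- data.frame(node = ids, degree = as.integer(deg),
                    betweenness = as.numeric(btw),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a phase diagram for plotting
#'
#' Runs [enumerate_configurations()] and writes the `(m10, m11, count)`
#' rows as TSV, preceded by comment lines carrying the bounds rectangle
#' and the expected point so a heatmap can be drawn without recomputing
#' them.
#'
#' @param graph An undirected simple `igraph` graph.
#' @param n1 Number of flagged nodes.
#' @param path Output file path.
#' @param cap Enumeration cap, as in [enumerate_configurations()].
#' @return The `degeneracy_map`, invisibly.
#' @export
phase_diagram_export <- function(graph, n1, path, cap = 2e6) {
  map <- enumerate_configurations(graph, n1, cap = cap)
  n <- attr(map, "n")
  m <- attr(map, "m")
  bnd <- dyad_bounds(igraph::degree(graph), n1, m = m,
                     connected = igraph::is_connected(graph))
  exp_ <- expected_counts(n, m, n1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# phase diagram: n = %d, m = %d, n1 = %d, configurations = %s",
            n, m, n1, format(attr(map, "total"), scientific = FALSE)),
    sprintf("# bounds: m10 in [%d, %d], m11 in [%d, %d]",
            bnd$m10_lower, bnd$m10_upper, bnd$m11_lower, bnd$m11_upper),
    sprintf("# expected: m10_bar = %.6g, m11_bar = %.6g",
            exp_$m10_bar, exp_$m11_bar)), con)
  utils::write.table(as.data.frame(map), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(map)
}
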