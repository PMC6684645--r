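# Independent brute-force oracle: enumerate every n1-subset of the nodes
# of a small graph and tally dyad counts by scanning the edge list, with
# none of the package's counting or enumeration code involved.
brute_force_configs <- function(graph, n1) {
  n <- igraph::vcount(graph)
  e <- igraph::as_edgelist(graph, names = FALSE)
  subsets <- utils::combn(n, n1)
  t(apply(subsets, 2L, function(s) {
    flag <- logical(n)
    flag[s] <- TRUE
    a <- flag[e[, 1L]]
    b <- flag[e[, 2L]]
    c(m11 = sum(a & b), m10 = sum(a != b))
  }))
}

# A few standard small graphs, vertices named so annotations are explicit.
k3_graph <- function() {
  g <- igraph::make_full_graph(3)
  igraph::V(g)$name <- c("a", "b", "c")
  g
}

star_graph <- function() {
  g <- igraph::make_star(5, mode = "undirected")  # center is vertex 1
  igraph::V(g)$name <- c("hub", "l1", "l2", "l3", "l4")
  g
}

path_graph <- function() {
  g <- igraph::make_ring(3, circular = FALSE)
  igraph::V(g)$name <- c("a", "b", "c")
  g
}

annotate <- function(graph, flagged, name = "attr") {
  ids <- igraph::V(graph)$name
  binary_annotation(stats::setNames(as.integer(ids %in% flagged), ids),
                    name = name)
}
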