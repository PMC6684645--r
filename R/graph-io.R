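#' Read an undirected edge list
#'
#' Parses a plain-text edge list (one edge per line, two node ids per
#' line, `#` starts a comment) into an undirected [igraph][igraph::igraph]
#' graph. Duplicate edges are collapsed with a warning; self-loops are
#' rejected because the dyad-count formulas assume a simple graph.
#'
#' @param path Path to the edge-list file (or a connection).
#' @param delimiter Field separator. `NULL` (default) splits on any run of
#'   whitespace; otherwise the literal string is used.
#' @return An undirected, simple `igraph` graph whose vertices are named
#'   by the ids found in the file.
#' @seealso [write_edge_list()], [read_metadata_table()]
#' @examples
#' f <- tempfile()
#' writeLines(c("# toy", "a b", "b c"), f)
#' g <- read_edge_list(f)
#' igraph::vcount(g)  # 3
#' @export
read_edge_list <- function(path, delimiter = NULL) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) {
    stop("edge list contains no edges", call. = FALSE)
  }
  parts <- if (is.null(delimiter)) {
    strsplit(trimws(lines[keep]), "[[:space:]]+")
  } else {
    strsplit(lines[keep], delimiter, fixed = TRUE)
  }
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    bad <- keep[which(nf < 2L)[1L]]
    stop(sprintf("malformed edge list: line %d has fewer than 2 fields", bad),
         call. = FALSE)
  }
  from <- vapply(parts, `[[`, character(1), 1L)
  to   <- vapply(parts, `[[`, character(1), 2L)
  loop <- from == to
  if (any(loop)) {
    bad <- keep[which(loop)[1L]]
    stop(sprintf("self-loop '%s %s' at line %d: graph must be simple",
                 from[loop][1L], to[loop][1L], bad), call. = FALSE)
  }
  key <- paste(pmin(from, to), pmax(from, to))
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate edge(s)", sum(dup)), call. = FALSE)
    from <- from[!dup]
    to <- to[!dup]
  }
  igraph::graph_from_data_frame(data.frame(from = from, to = to,
                                           stringsAsFactors = FALSE),
                                directed = FALSE)
}

#' Write a graph as a plain-text edge list
#'
#' @param graph An undirected `igraph` graph.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  e <- igraph::as_edgelist(graph, names = TRUE)
  writeLines(paste(e[, 1L], e[, 2L]), path)
  invisible(path)
}

#' Read a node-metadata table
#'
#' Reads a delimited table whose first row is a header and whose first
#' column holds node ids; the remaining columns are numeric attributes.
#'
#' @param path Path to the file (or a connection).
#' @param delimiter Field separator, comma by default.
#' @return A `data.frame` with character column `id` first and one numeric
#'   column per attribute.
#' @export
read_metadata_table <- function(path, delimiter = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#", colClasses = "character")
  if (ncol(tab) < 2L) {
    stop("metadata table needs an id column plus at least one attribute",
         call. = FALSE)
  }
  names(tab)[1L] <- "id"
  if (anyDuplicated(tab$id)) {
    stop(sprintf("duplicate node id '%s' in metadata table",
                 tab$id[duplicated(tab$id)][1L]), call. = FALSE)
  }
  if (anyDuplicated(names(tab))) {
    stop("attribute names must be unique", call. = FALSE)
  }
  for (j in seq_along(tab)[-1L]) {
    num <- suppressWarnings(as.numeric(tab[[j]]))
    bad <- is.na(num) & !is.na(tab[[j]]) & nzchar(trimws(tab[[j]]))
    if (any(bad)) {
      stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                   tab[[j]][bad][1L], names(tab)[j], which(bad)[1L]),
           call. = FALSE)
    }
    tab[[j]] <- num
  }
  tab
}

#' Construct a binary annotation
#'
#' A binary annotation is one named {0,1} label per node; `n1` counts the
#' flagged (label 1) nodes. Annotations are the unit the dyadic-effect
#' machinery works on.
#'
#' @param labels Named vector of 0/1 values, names being node ids.
#' @param name Attribute name carried through reports.
#' @return An object of class `binary_annotation` with fields `name`,
#'   `labels` (named integer vector), `n1` and `n0`.
#' @export
binary_annotation <- function(labels, name = "annotation") {
  if (is.null(names(labels)) || anyDuplicated(names(labels))) {
    stop("labels must be uniquely named by node id", call. = FALSE)
  }
  if (anyNA(labels) || !all(labels %in% c(0, 1))) {
    stop(sprintf("annotation '%s' has labels outside {0, 1}", name),
         call. = FALSE)
  }
  lab <- as.integer(labels)
  names(lab) <- names(labels)
  structure(list(name = name, labels = lab,
                 n1 = sum(lab), n0 = sum(lab == 0L)),
            class = "binary_annotation")
}

#' @export
print.binary_annotation <- function(x, ...) {
  cat(sprintf("<binary_annotation '%s': n = %d, n1 = %d>\n",
              x$name, length(x$labels), x$n1))
  invisible(x)
}

#' Dichotomize a numeric attribute at its mean
#'
#' Flags the nodes whose value is strictly greater than the arithmetic
#' mean of the attribute; values equal to the mean are labelled 0. This is
#' the mean-threshold binarization used to turn scalar indices into
#' over-/under-performer labels.
#'
#' @param values Named numeric vector, one finite value per node.
#' @param name Attribute name for the resulting annotation.
#' @return A [binary_annotation()].
#' @examples
#' binarize_mean(c(a = 1, b = 2, c = 3, d = 4, e = 10), "score")$n1  # 1
#' @export
binarize_mean <- function(values, name = "annotation") {
  if (is.null(names(values))) {
    stop("values must be named by node id", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    miss <- names(values)[!is.finite(values) | is.na(values)][1L]
    stop(sprintf("attribute '%s': missing or non-finite value for node '%s'",
                 name, miss), call. = FALSE)
  }
  thr <- mean(values)
  binary_annotation(stats::setNames(as.integer(values > thr), names(values)),
                    name = name)
}

#' Validate an annotation against a graph
#'
#' Checks that every graph node carries a {0,1} label; an annotation
#' covering a superset of the graph's nodes is restricted to the graph
#' (with `n1` recomputed).
#'
#' @param graph An undirected `igraph` graph.
#' @param annotation A [binary_annotation()] or a named 0/1 vector.
#' @return The validated (possibly restricted) `binary_annotation`.
#' @export
validate_annotation <- function(graph, annotation) {
  if (!inherits(annotation, "binary_annotation")) {
    annotation <- binary_annotation(annotation)
  }
  ids <- node_ids(graph)
  missing <- setdiff(ids, names(annotation$labels))
  if (length(missing) > 0L) {
    stop(sprintf("annotation '%s' lacks labels for %d node(s), e.g. '%s'",
                 annotation$name, length(missing), missing[1L]),
         call. = FALSE)
  }
  binary_annotation(annotation$labels[ids], name = annotation$name)
}

#' Annotations from a metadata table
#'
#' Converts each attribute column of a metadata table into a binary
#' annotation, dichotomizing at the mean when `binarize = TRUE` and
#' otherwise requiring the columns to already be 0/1.
#'
#' @param metadata A `data.frame` as returned by [read_metadata_table()].
#' @param binarize Apply [binarize_mean()] to each column?
#' @return Named list of [binary_annotation()] objects.
#' @export
metadata_annotations <- function(metadata, binarize = TRUE) {
  attrs <- setdiff(names(metadata), "id")
  out <- lapply(attrs, function(a) {
    vals <- stats::setNames(metadata[[a]], metadata$id)
    if (binarize) binarize_mean(vals, name = a) else binary_annotation(vals, name = a)
  })
  stats::setNames(out, attrs)
}

# Canonical node ordering used everywhere labels are vectorized: the
# vertex name (radix sort for locale independence), or the vertex index
# for unnamed graphs.
node_ids <- function(graph) {
  nm <- igraph::vertex_attr(graph, "name")
  if (is.null(nm)) {
    as.character(seq_len(igraph::vcount(graph)))
  } else {
    sort(nm, method = "radix")
  }
}

# Labels of `annotation` aligned to node_ids(graph).
aligned_labels <- function(graph, annotation) {
  annotation$labels[node_ids(graph)]
}

# Edge endpoint positions within node_ids(graph); m x 2 integer matrix.
edge_index <- function(graph) {
  ids <- node_ids(graph)
  e <- igraph::as_edgelist(graph, names = TRUE)
  if (igraph::ecount(graph) == 0L) {
    return(matrix(integer(0), ncol = 2L))
  }
  if (is.null(igraph::vertex_attr(graph, "name"))) {
    e <- igraph::as_edgelist(graph, names = FALSE)
    storage.mode(e) <- "integer"
    return(e)
  }
  cbind(match(e[, 1L], ids), match(e[, 2L], ids))
}
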