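#' Number of label configurations
#'
#' The exact number of ways to place `n1` flags over `n` nodes,
#' `choose(n, n1)` — the size of the space the phase-diagram enumerator
#' must visit. The worst case (`n1 = n/2`) grows as `O(2^n)`, which is
#' why exhaustive enumeration is only feasible for small networks.
#'
#' @param n Number of nodes.
#' @param n1 Number of flagged nodes.
#' @return The binomial coefficient as a double.
#' @examples
#' enumeration_size(43, 4)  # 123410
#' @export
enumeration_size <- function(n, n1) {
  stopifnot(n1 >= 0, n1 <= n)
  choose(n, n1)
}

#' Exhaustive phase-diagram enumeration
#'
#' Visits every one of the `choose(n, n1)` placements of `n1` flags,
#' counts its dyads and accumulates the degeneracy of each realizable
#' `(m10, m11)` pair: the number of distinct label configurations that
#' produce it. High-degeneracy cells sit near the expected counts and
#' mark typical (hence less significant) configurations. This function
#' is the brute-force oracle behind the bound and expectation formulas.
#'
#' @param graph An undirected simple `igraph` graph.
#' @param n1 Number of flagged nodes.
#' @param cap Refuse to enumerate more than this many configurations
#'   (default 2e6).
#' @return A `data.frame` of class `degeneracy_map` with columns `m10`,
#'   `m11`, `count`, sorted by `(m10, m11)`; attributes `n`, `m`, `n1`
#'   and `total = choose(n, n1)`.
#' @examples
#' enumerate_configurations(igraph::make_full_graph(3), 2)
#' @export
enumerate_configurations <- function(graph, n1, cap = 2e6) {
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  total <- enumeration_size(n, n1)
  if (total > cap) {
    stop(sprintf(
      "refusing to enumerate choose(%d, %d) = %s configurations (cap %s)",
      n, n1, format(total, big.mark = ",", scientific = FALSE),
      format(cap, big.mark = ",", scientific = FALSE)), call. = FALSE)
  }
  degs <- igraph::degree(graph)
  ids <- node_ids(graph)
  nm <- igraph::vertex_attr(graph, "name")
  ord <- if (is.null(nm)) seq_len(n) else match(ids, nm)
  degs <- degs[ord]  # degrees in canonical node order
  e <- edge_index(graph)

  if (n1 == 0L || n1 == n) {
    m11 <- if (n1 == n) m else 0L
    out <- data.frame(m10 = 0L, m11 = m11, count = 1)
  } else {
    cmb <- utils::combn(n, n1)  # subsets in lexicographic order
    ncfg <- ncol(cmb)
    adj <- matrix(FALSE, n, n)
    adj[e] <- TRUE
    adj[e[, c(2L, 1L)]] <- TRUE
    m11 <- numeric(ncfg)
    if (n1 >= 2L) {
      for (i in seq_len(n1 - 1L)) {
        for (j in seq.int(i + 1L, n1)) {
          m11 <- m11 + adj[cbind(cmb[i, ], cmb[j, ])]
        }
      }
    }
    degsum <- colSums(matrix(degs[cmb], nrow = n1))
    m10 <- degsum - 2 * m11
    key <- m10 * (m + 1) + m11
    tab <- table(key)
    kv <- as.numeric(names(tab))
    out <- data.frame(m10 = as.integer(kv %/% (m + 1)),
                      m11 = as.integer(kv %% (m + 1)),
                      count = as.numeric(tab))
  }
  out <- out[order(out$m10, out$m11), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n = n, m = m, n1 = n1, total = total,
            class = c("degeneracy_map", "data.frame"))
}

#' Check a degeneracy map against bounds and expectations
#'
#' Oracle harness: asserts that the realizable extremes of an
#' exhaustively enumerated map lie within the degree-sequence bounds,
#' that the degeneracy-weighted means of `m11` and `m10` equal their
#' closed-form expectations exactly (an integer identity, checked in
#' integer arithmetic), and that the degeneracies sum to
#' `choose(n, n1)`.
#'
#' @param map A `degeneracy_map` from [enumerate_configurations()].
#' @param bounds The matching `dyad_bounds`.
#' @param expected The matching `dyad_expected`.
#' @return List with logical `pass`, named logical vector `checks`, and
#'   character vector `failures` describing any violation.
#' @export
verify_against_bounds <- function(map, bounds, expected) {
  n <- attr(map, "n")
  m <- attr(map, "m")
  n1 <- attr(map, "n1")
  total <- attr(map, "total")
  checks <- c(
    m11_within = min(map$m11) >= bounds$m11_lower &&
      max(map$m11) <= bounds$m11_upper,
    m10_within = min(map$m10) >= bounds$m10_lower &&
      max(map$m10) <= bounds$m10_upper,
    # E[m11] = m n1 (n1-1) / (n (n-1)): cross-multiplied integer identity
    m11_mean_exact = sum(map$m11 * map$count) * n * (n - 1) ==
      m * n1 * (n1 - 1) * total,
    m10_mean_exact = sum(map$m10 * map$count) * n * (n - 1) ==
      2 * m * n1 * (n - n1) * total,
    total_count = sum(map$count) == total
  )
  failures <- character(0)
  if (!checks[["m11_within"]]) {
    failures <- c(failures, sprintf(
      "m11 range [%d, %d] escapes bounds [%d, %d]",
      min(map$m11), max(map$m11), bounds$m11_lower, bounds$m11_upper))
  }
  if (!checks[["m10_within"]]) {
    failures <- c(failures, sprintf(
      "m10 range [%d, %d] escapes bounds [%d, %d]",
      min(map$m10), max(map$m10), bounds$m10_lower, bounds$m10_upper))
  }
  if (!checks[["m11_mean_exact"]]) {
    failures <- c(failures, "enumeration mean of m11 differs from m11_bar")
  }
  if (!checks[["m10_mean_exact"]]) {
    failures <- c(failures, "enumeration mean of m10 differs from m10_bar")
  }
  if (!checks[["total_count"]]) {
    failures <- c(failures, sprintf(
      "degeneracies sum to %s, expected choose(%d, %d) = %s",
      format(sum(map$count)), n, n1, format(total)))
  }
  list(pass = all(checks), checks = checks, failures = failures)
}
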