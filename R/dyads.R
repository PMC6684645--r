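#' Count dyad types
#'
#' A dyad is an edge together with the binary labels of its two end
#' nodes. Every edge falls into one of three classes: both ends flagged
#' (1-1), exactly one end flagged (1-0), or neither (0-0).
#'
#' @param graph An undirected simple `igraph` graph.
#' @param annotation A [binary_annotation()] covering the graph's nodes.
#' @return An object of class `dyad_counts`: a list with integer fields
#'   `m11`, `m10`, `m00` and `m` (total edges), satisfying
#'   `m11 + m10 + m00 = m`.
#' @examples
#' g <- igraph::make_full_graph(3)
#' a <- binary_annotation(c("1" = 1, "2" = 1, "3" = 1))
#' count_dyads(g, a)$m11  # 3
#' @export
count_dyads <- function(graph, annotation) {
  annotation <- validate_annotation(graph, annotation)
  lab <- aligned_labels(graph, annotation)
  e <- edge_index(graph)
  s <- lab[e[, 1L]] + lab[e[, 2L]]
  out <- list(m11 = sum(s == 2L), m10 = sum(s == 1L), m00 = sum(s == 0L),
              m = igraph::ecount(graph))
  structure(out, class = "dyad_counts")
}

#' @export
print.dyad_counts <- function(x, ...) {
  cat(sprintf("<dyad_counts: m11 = %d, m10 = %d, m00 = %d (m = %d)>\n",
              x$m11, x$m10, x$m00, x$m))
  invisible(x)
}

#' Expected dyad counts under random label assignment
#'
#' If `n1` flags are placed uniformly at random over the `n` nodes of a
#' graph with `m` edges and density `delta = 2m / (n (n - 1))`, the
#' expected numbers of (1-1) and (1-0) dyads are
#' `m11_bar = choose(n1, 2) * delta` and
#' `m10_bar = n1 * (n - n1) * delta`.
#'
#' @param n Number of nodes (>= 2).
#' @param m Number of edges.
#' @param n1 Number of flagged nodes, `0 <= n1 <= n`.
#' @return An object of class `dyad_expected`: list with fields `n`, `m`,
#'   `n1`, `delta`, `m11_bar`, `m10_bar`.
#' @examples
#' expected_counts(25, 32, 5)  # delta ~ 0.1067, m11_bar ~ 1.067
#' @export
expected_counts <- function(n, m, n1) {
  stopifnot(n >= 2, n1 >= 0, n1 <= n, m >= 0, m <= choose(n, 2))
  delta <- 2 * m / (n * (n - 1))
  structure(list(n = n, m = m, n1 = n1, delta = delta,
                 m11_bar = n1 * (n1 - 1) / 2 * delta,
                 m10_bar = n1 * (n - n1) * delta),
            class = "dyad_expected")
}

#' @export
print.dyad_expected <- function(x, ...) {
  cat(sprintf("<dyad_expected: delta = %.4g, m11_bar = %.4g, m10_bar = %.4g>\n",
              x$delta, x$m11_bar, x$m10_bar))
  invisible(x)
}

#' Degree-sequence bounds on dyad counts
#'
#' Exact combinatorial bounds on `m11` and `m10` given the degree
#' sequence and the number of flagged nodes. With the degree sequence
#' sorted non-increasing, the head `H(k)` is its first `k` entries and
#' the tail `T(k)` its last `k` entries (ties are harmless: only the
#' degree multiset enters the sums). The bounds are
#' \deqn{m_{11}^u = \min\big(m,\ \binom{n_1}{2},\
#'   \lceil \textstyle\sum_{i \in H(n_1)} \min(d_i, n_1 - 1) / 2 \rceil\big)}
#' \deqn{m_{10}^u = \min\big(m,\ n_1 n_0,\
#'   \min(\textstyle\sum_{i \in H(n_1)} \min(d_i, n_0),\
#'        \textstyle\sum_{i \in H(n_0)} \min(d_i, n_1))\big)}
#' \deqn{m_{11}^l = \max\big(0,\ \lfloor (\textstyle\sum_{i \in T(n_1)} d_i
#'   - \textstyle\sum_{i \in H(n_0)} d_i) / 2 \rfloor\big)}
#' \deqn{m_{10}^l = \max\big(1,\ \textstyle\sum_{i \in T(n_1)} d_i
#'   - n_1(n_1 - 1)\big) \quad (0\ \mathrm{if}\ n_1 \in \{0, n\})}
#' The `1` in the `m10` lower bound presumes a connected graph (any
#' connected realization with `0 < n1 < n` has at least one mixed dyad);
#' pass `connected = FALSE` to replace it with 0.
#'
#' @param degrees Integer degree sequence (any order), length `n`.
#' @param n1 Number of flagged nodes.
#' @param m Number of edges; defaults to `sum(degrees) / 2`.
#' @param connected Is the graph known to be connected? Affects only the
#'   `m10` lower bound.
#' @return Object of class `dyad_bounds`: list with integer fields
#'   `m11_lower`, `m11_upper`, `m10_lower`, `m10_upper` plus `n`, `n1`,
#'   `m`.
#' @examples
#' dyad_bounds(c(2, 2, 2), n1 = 2)        # m11 in [1, 1], m10 in [2, 2]
#' dyad_bounds(c(4, 1, 1, 1, 1), n1 = 2)  # m11 in [0, 1], m10 in [1, 4]
#' @export
dyad_bounds <- function(degrees, n1, m = sum(degrees) / 2, connected = TRUE) {
  n <- length(degrees)
  if (sum(degrees) %% 2 != 0 || any(degrees < 0) || sum(degrees) != 2 * m) {
    stop("inconsistent degree sequence: sum must be even and equal 2m",
         call. = FALSE)
  }
  stopifnot(n1 >= 0, n1 <= n)
  d <- sort(degrees, decreasing = TRUE)
  n0 <- n - n1
  head_k <- function(k) d[seq_len(k)]
  tail_k <- function(k) if (k > 0L) d[seq.int(n - k + 1L, n)] else d[0L]

  m11_u <- min(m, choose(n1, 2),
               ceiling(sum(pmin(head_k(n1), n1 - 1)) / 2))
  m10_u <- min(m, n1 * n0,
               sum(pmin(head_k(n1), n0)), sum(pmin(head_k(n0), n1)))
  m11_l <- max(0, floor((sum(tail_k(n1)) - sum(head_k(n0))) / 2))
  m10_l <- if (n1 == 0L || n1 == n) 0 else {
    max(if (connected) 1 else 0, sum(tail_k(n1)) - n1 * (n1 - 1))
  }
  structure(list(m11_lower = as.integer(m11_l), m11_upper = as.integer(m11_u),
                 m10_lower = as.integer(m10_l), m10_upper = as.integer(m10_u),
                 n = n, n1 = n1, m = as.integer(m), connected = connected),
            class = "dyad_bounds")
}

#' @export
print.dyad_bounds <- function(x, ...) {
  cat(sprintf("<dyad_bounds (n = %d, n1 = %d): m11 in [%d, %d], m10 in [%d, %d]>\n",
              x$n, x$n1, x$m11_lower, x$m11_upper, x$m10_lower, x$m10_upper))
  invisible(x)
}

#' Bounds on the number of (0-0) dyads
#'
#' Obtained by the label swap 1 <-> 0: the `m00` bounds equal the `m11`
#' bounds computed for `n0 = n - n1` flagged nodes.
#'
#' @inheritParams dyad_bounds
#' @return List with integer fields `m00_lower`, `m00_upper`.
#' @export
m00_bounds <- function(degrees, n1, m = sum(degrees) / 2, connected = TRUE) {
  b <- dyad_bounds(degrees, length(degrees) - n1, m = m, connected = connected)
  list(m00_lower = b$m11_lower, m00_upper = b$m11_upper)
}

#' Dyadicity and heterophilicity
#'
#' Dyadicity `D = m11 / m11_bar` measures the excess of same-flag dyads
#' over the random expectation (`D > 1`: flagged nodes cluster together);
#' heterophilicity `H = m10 / m10_bar` measures the excess of mixed dyads
#' (`H < 1`: flagged nodes avoid unflagged neighbours).
#'
#' @param counts A `dyad_counts` object from [count_dyads()].
#' @param expected A `dyad_expected` object from [expected_counts()].
#' @return Object of class `hd_metrics`: list with fields `D` and `H`.
#' @examples
#' cnt <- structure(list(m11 = 6, m10 = 37, m00 = 2, m = 45),
#'                  class = "dyad_counts")
#' dyadicity_heterophilicity(cnt, expected_counts(43, 45, 4))
#' @export
dyadicity_heterophilicity <- function(counts, expected) {
  if (expected$m11_bar <= 0) {
    stop("dyadicity undefined: expected m11 is zero (n1 <= 1)", call. = FALSE)
  }
  if (expected$m10_bar <= 0) {
    stop("heterophilicity undefined: expected m10 is zero (n1 in {0, n})",
         call. = FALSE)
  }
  structure(list(D = counts$m11 / expected$m11_bar,
                 H = counts$m10 / expected$m10_bar),
            class = "hd_metrics")
}

#' @export
print.hd_metrics <- function(x, ...) {
  cat(sprintf("<hd_metrics: D = %.2f, H = %.2f>\n", x$D, x$H))
  invisible(x)
}

#' Binary assortativity coefficient from dyad counts
#'
#' The categorical mixing coefficient
#' `r = (sum_i e_ii - sum_i a_i^2) / (1 - sum_i a_i^2)` computed from the
#' 2x2 edge-mixing matrix implied by the dyad counts:
#' `e11 = m11/m`, `e00 = m00/m`, `e10 = e01 = m10/(2m)`, with `a_i` the
#' row marginals. Ranges over `[-1, 1]`; positive values indicate
#' assortative mixing by label.
#'
#' @param counts A `dyad_counts` object (or list with `m11`, `m10`,
#'   `m00`, `m`).
#' @return The mixing coefficient, a number in `[-1, 1]`.
#' @export
binary_assortativity <- function(counts) {
  m <- counts$m
  if (m <= 0) stop("assortativity undefined for an edgeless graph",
                   call. = FALSE)
  e11 <- counts$m11 / m
  e00 <- counts$m00 / m
  e10 <- counts$m10 / (2 * m)
  a1 <- e11 + e10
  a0 <- e00 + e10
  asq <- a1^2 + a0^2
  if (1 - asq <= 0) {
    stop("assortativity undefined: mixing matrix fully concentrated",
         call. = FALSE)
  }
  (e11 + e00 - asq) / (1 - asq)
}
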