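# RNG hygiene: run code under a given seed without disturbing the
# caller's random stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Label-permutation significance test
#'
#' Draws `K` uniform random reassignments of the `n1` flags over the
#' graph's nodes (the null model reshuffles metadata, never edges),
#' recomputes `D`, `H` and the relevance `r` for each, and reports plain
#' Monte-Carlo proportions. `p_r` is the probability of a reshuffled
#' relevance at least as large as the observed one. `p_D` and `p_H` are
#' one-sided in the direction of the observed departure: for `D >= 1`,
#' `p_D` counts permutations with a dyadicity at least as large, and for
#' `D < 1` at most as small; `p_H` mirrors this on the heterophilicity
#' axis (for an observed `H <= 1` it counts lower values, the
#' dyadic-heterophobic convention, and higher values otherwise).
#'
#' Ties count as qualifying (non-strict comparisons) and no smoothing is
#' applied, so each p-value lies on the grid `{0, 1/K, ..., 1}`.
#'
#' @param graph An undirected simple `igraph` graph.
#' @param annotation A [binary_annotation()] with `2 <= n1 <= n - 1`, so
#'   that both `D` and `H` are defined.
#' @param K Number of permutations (default 1000).
#' @param seed Integer seed; required for reproducibility.
#' @return Object of class `permutation_result`: list with fields `p_D`,
#'   `p_H`, `p_r`, `K`, `seed` and `observed` (list with `D`, `H`, `r`).
#' @export
permutation_test <- function(graph, annotation, K = 1000L, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  annotation <- validate_annotation(graph, annotation)
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  n1 <- annotation$n1
  if (n1 < 2L || n1 > n - 1L) {
    stop(sprintf("degenerate annotation '%s': n1 = %d", annotation$name, n1),
         call. = FALSE)
  }
  exp_ <- expected_counts(n, m, n1)
  bnd <- dyad_bounds(igraph::degree(graph), n1, m = m,
                     connected = igraph::is_connected(graph))
  sp <- hd_space(bnd, exp_)
  obs_cnt <- count_dyads(graph, annotation)
  D_obs <- obs_cnt$m11 / exp_$m11_bar
  H_obs <- obs_cnt$m10 / exp_$m10_bar
  r_obs <- relevance(H_obs, D_obs, sp)

  e <- edge_index(graph)
  null_counts <- with_seed(seed, {
    flags <- matrix(FALSE, nrow = n, ncol = K)
    for (k in seq_len(K)) flags[sample.int(n, n1), k] <- TRUE
    m11_k <- colSums(flags[e[, 1L], , drop = FALSE] &
                       flags[e[, 2L], , drop = FALSE])
    m10_k <- colSums(xor(flags[e[, 1L], , drop = FALSE],
                         flags[e[, 2L], , drop = FALSE]))
    list(m11 = m11_k, m10 = m10_k)
  })
  D_k <- null_counts$m11 / exp_$m11_bar
  H_k <- null_counts$m10 / exp_$m10_bar
  r_k <- relevance_vec(H_k, D_k, sp)

  p_D <- if (D_obs >= 1) mean(D_k >= D_obs) else mean(D_k <= D_obs)
  p_H <- if (H_obs <= 1) mean(H_k <= H_obs) else mean(H_k >= H_obs)
  p_r <- mean(r_k >= r_obs)
  structure(list(p_D = p_D, p_H = p_H, p_r = p_r, K = K, seed = seed,
                 observed = list(D = D_obs, H = H_obs, r = r_obs)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("<permutation_result (K = %d, seed = %s): ",
                     "p_D = %.3f, p_H = %.3f, p_r = %.3f>\n"),
              x$K, format(x$seed), x$p_D, x$p_H, x$p_r))
  invisible(x)
}
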