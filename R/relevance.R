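#' The bounded H-D space
#'
#' Dividing the degree-sequence bounds on `m11` and `m10` by their
#' random-assignment expectations yields a rectangle
#' `[Hmin, Hmax] x [Dmin, Dmax]` that contains every realizable `(H, D)`
#' pair for the given graph and `n1`. The pivot `(1, 1)` — the point
#' where both counts equal their expectations — always lies inside it.
#'
#' @param bounds A `dyad_bounds` object.
#' @param expected A `dyad_expected` object (same `n1`).
#' @return Object of class `hd_space`: list with fields `Hmin`, `Hmax`,
#'   `Dmin`, `Dmax`.
#' @examples
#' hd_space(dyad_bounds(c(2, 2, 2), 2), expected_counts(3, 3, 2))
#' @export
hd_space <- function(bounds, expected) {
  if (expected$m11_bar <= 0 || expected$m10_bar <= 0) {
    stop("degenerate H-D space: zero expected count (n1 in {0, 1, n})",
         call. = FALSE)
  }
  structure(list(Hmin = bounds$m10_lower / expected$m10_bar,
                 Hmax = bounds$m10_upper / expected$m10_bar,
                 Dmin = bounds$m11_lower / expected$m11_bar,
                 Dmax = bounds$m11_upper / expected$m11_bar),
            class = "hd_space")
}

#' @export
print.hd_space <- function(x, ...) {
  cat(sprintf("<hd_space: H in [%.3g, %.3g], D in [%.3g, %.3g]>\n",
              x$Hmin, x$Hmax, x$Dmin, x$Dmax))
  invisible(x)
}

#' Classify a point of the H-D space
#'
#' The pivot `(1, 1)` splits the space into four regions:
#' I Heterophobic-Dyadic (`H < 1`, `D > 1`),
#' II Heterophilic-Dyadic (`H > 1`, `D > 1`),
#' III Heterophilic-Antidyadic (`H > 1`, `D < 1`),
#' IV Heterophobic-Antidyadic (`H < 1`, `D < 1`).
#' Boundary convention (the construction leaves it open, so it is fixed
#' here once): `H = 1` joins the heterophilic side (II/III), `D = 1` the
#' dyadic side (I/II); exactly `(1, 1)` is the pivot.
#'
#' @param H,D Coordinates, both non-negative.
#' @return One of `"I"`, `"II"`, `"III"`, `"IV"`, `"pivot"`.
#' @export
classify_region <- function(H, D) {
  stopifnot(length(H) == 1L, length(D) == 1L, H >= 0, D >= 0)
  if (H == 1 && D == 1) return("pivot")
  heterophilic <- H >= 1
  dyadic <- D >= 1
  if (dyadic) {
    if (heterophilic) "II" else "I"
  } else {
    if (heterophilic) "III" else "IV"
  }
}

#' Diagonal vector of a region
#'
#' The vector from the pivot `(1, 1)` to the corner of the given region —
#' the longest vector the region admits, against which observed
#' configurations are normalized.
#'
#' @param space An `hd_space` object.
#' @param region Region label, one of `"I"` to `"IV"`.
#' @return Numeric 2-vector `c(dH, dD)`; a warning is emitted when the
#'   diagonal has zero length (collapsed space).
#' @export
region_diagonal <- function(space, region) {
  corner <- switch(region,
                   I   = c(space$Hmin, space$Dmax),
                   II  = c(space$Hmax, space$Dmax),
                   III = c(space$Hmax, space$Dmin),
                   IV  = c(space$Hmin, space$Dmin),
                   stop(sprintf("unknown region '%s'", region), call. = FALSE))
  u <- corner - c(1, 1)
  if (sum(u^2) == 0) {
    warning(sprintf("region %s has a zero-length diagonal (collapsed space)",
                    region), call. = FALSE)
  }
  u
}

#' Relevance of an (H, D) configuration
#'
#' With `v = (H - 1, D - 1)` and `u` the diagonal of the region the
#' point lies in, the relevance is the projection of `v` onto `u`
#' normalized by the diagonal length:
#' `r = (v . u) / (u . u) = p(v) / ||u||` where `p(v) = (v . u) / ||u||`.
#' It equals 0 at the pivot, 1 at the region corner, and lies in `[0, 1]`
#' for every point of the rectangle. A collapsed region (zero-length
#' diagonal) yields 0.
#'
#' @param H,D Observed heterophilicity and dyadicity.
#' @param space The `hd_space` rectangle for the same graph and `n1`.
#' @return Relevance score in `[0, 1]`.
#' @examples
#' sp <- structure(list(Hmin = 0.5, Hmax = 2, Dmin = 0, Dmax = 3),
#'                 class = "hd_space")
#' relevance(0.8, 1.72, sp)  # ~ 0.3624
#' @export
relevance <- function(H, D, space) {
  tol <- 1e-9
  if (H < space$Hmin - tol || H > space$Hmax + tol ||
      D < space$Dmin - tol || D > space$Dmax + tol) {
    stop(sprintf(paste0("point (H = %.4g, D = %.4g) outside the H-D ",
                        "rectangle [%.4g, %.4g] x [%.4g, %.4g]: ",
                        "inconsistent inputs"),
                 H, D, space$Hmin, space$Hmax, space$Dmin, space$Dmax),
         call. = FALSE)
  }
  region <- classify_region(H, D)
  if (region == "pivot") return(0)
  u <- suppressWarnings(region_diagonal(space, region))
  uu <- sum(u^2)
  if (uu == 0) return(0)
  v <- c(H - 1, D - 1)
  min(max(sum(v * u) / uu, 0), 1)
}

# Vectorized relevance over parallel H/D vectors in a fixed space; used
# by the permutation test. Matches relevance() pointwise, without the
# rectangle check (inputs come from realizable configurations).
relevance_vec <- function(H, D, space) {
  uh <- ifelse(H >= 1, space$Hmax, space$Hmin) - 1
  ud <- ifelse(D >= 1, space$Dmax, space$Dmin) - 1
  uu <- uh^2 + ud^2
  r <- ifelse(uu > 0, ((H - 1) * uh + (D - 1) * ud) / uu, 0)
  pmin(pmax(r, 0), 1)
}

#' Rank binary metadata by relevance
#'
#' Runs the full per-attribute pipeline — dyad counts, expectations,
#' degree-sequence bounds, H-D space, relevance — and sorts attributes by
#' decreasing relevance (ties broken by attribute name). Attributes with
#' `n1` in `{0, 1, n - 1, n}`, for which the metrics or their bounds
#' degenerate, are excluded and reported via the `"excluded"` attribute.
#'
#' @param graph An undirected simple `igraph` graph.
#' @param annotations Named list of [binary_annotation()] objects (or a
#'   single annotation).
#' @return A `data.frame` with columns `attribute`, `n1`, `m11`, `m10`,
#'   `m00`, `D`, `H`, `region`, `r`, sorted by `r` descending. The
#'   attribute `"excluded"` names skipped annotations.
#' @export
rank_metadata <- function(graph, annotations) {
  if (inherits(annotations, "binary_annotation")) {
    annotations <- list(annotations)
  }
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  degs <- igraph::degree(graph)
  connected <- igraph::is_connected(graph)
  rows <- list()
  excluded <- character(0)
  for (ann in annotations) {
    ann <- validate_annotation(graph, ann)
    if (ann$n1 < 2L || ann$n1 > n - 2L) {
      message(sprintf("skipping '%s': n1 = %d is degenerate for D/H bounds",
                      ann$name, ann$n1))
      excluded <- c(excluded, ann$name)
      next
    }
    cnt <- count_dyads(graph, ann)
    exp_ <- expected_counts(n, m, ann$n1)
    bnd <- dyad_bounds(degs, ann$n1, m = m, connected = connected)
    sp <- hd_space(bnd, exp_)
    hd <- dyadicity_heterophilicity(cnt, exp_)
    rows[[length(rows) + 1L]] <- data.frame(
      attribute = ann$name, n1 = ann$n1,
      m11 = cnt$m11, m10 = cnt$m10, m00 = cnt$m00,
      D = hd$D, H = hd$H,
      region = classify_region(hd$H, hd$D),
      r = relevance(hd$H, hd$D, sp),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows) == 0L) {
    data.frame(attribute = character(0), n1 = integer(0), m11 = integer(0),
               m10 = integer(0), m00 = integer(0), D = numeric(0),
               H = numeric(0), region = character(0), r = numeric(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  out <- out[order(-out$r, out$attribute, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
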