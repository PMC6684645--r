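test_that("dyad counts scan edge endpoint labels", {
  g <- k3_graph()
  cnt <- count_dyads(g, annotate(g, c("a", "b", "c")))
  expect_equal(c(cnt$m11, cnt$m10, cnt$m00), c(3L, 0L, 0L))

  p <- path_graph()
  cnt <- count_dyads(p, annotate(p, "b"))
  expect_equal(c(cnt$m11, cnt$m10, cnt$m00), c(0L, 2L, 0L))

  toy <- rich_club_toy()
  cnt <- count_dyads(toy$graph, toy$annotation)
  expect_equal(c(cnt$m11, cnt$m10, cnt$m00), c(6L, 37L, 2L))
})

test_that("dyad counts partition the edge set and swap under complement", {
  for (seed in 1:10) {
    fx <- random_annotated_graph(12, 20, sample(2:10, 1), seed = seed)
    cnt <- count_dyads(fx$graph, fx$annotation)
    expect_equal(cnt$m11 + cnt$m10 + cnt$m00, cnt$m)
    flipped <- binary_annotation(1L - fx$annotation$labels, "flip")
    fc <- count_dyads(fx$graph, flipped)
    expect_equal(fc$m11, cnt$m00)
    expect_equal(fc$m10, cnt$m10)
    expect_equal(fc$m00, cnt$m11)
  }
})

test_that("expected counts follow the density formula", {
  ex <- expected_counts(25, 32, 5)
  expect_equal(ex$delta, 32 / 300)
  expect_equal(ex$m11_bar, 10 * 32 / 300)
  expect_equal(ex$m10_bar, 100 * 32 / 300)

  expect_equal(expected_counts(10, 5, 0)$m11_bar, 0)
  expect_equal(expected_counts(10, 5, 0)$m10_bar, 0)

  # K3, n1 = 2: expectation equals the mean over all 3 assignments
  oracle <- brute_force_configs(k3_graph(), 2)
  ex3 <- expected_counts(3, 3, 2)
  expect_equal(mean(oracle[, "m11"]), ex3$m11_bar)
  expect_equal(mean(oracle[, "m10"]), ex3$m10_bar)
})

test_that("degree-sequence bounds match hand and brute-force values", {
  b <- dyad_bounds(c(2, 2, 2), 2)
  expect_equal(c(b$m11_lower, b$m11_upper), c(1L, 1L))
  expect_equal(c(b$m10_lower, b$m10_upper), c(2L, 2L))

  b <- dyad_bounds(c(4, 1, 1, 1, 1), 2)
  expect_equal(c(b$m11_lower, b$m11_upper), c(0L, 1L))
  expect_equal(c(b$m10_lower, b$m10_upper), c(1L, 4L))
  oracle <- brute_force_configs(star_graph(), 2)
  expect_true(all(oracle[, "m11"] >= b$m11_lower &
                    oracle[, "m11"] <= b$m11_upper))
  expect_true(all(oracle[, "m10"] >= b$m10_lower &
                    oracle[, "m10"] <= b$m10_upper))

  expect_equal(dyad_bounds(c(2, 2, 2), 0)$m10_lower, 0L)
  expect_equal(dyad_bounds(c(2, 2, 2), 3)$m10_lower, 0L)
  # the mixed-dyad floor of 1 presumes connectivity
  expect_equal(dyad_bounds(c(1, 1, 1, 1), 2, connected = FALSE)$m10_lower, 0L)
  expect_error(dyad_bounds(c(2, 1), 1), "inconsistent")
})

test_that("bounds contain brute-force extremes on random graphs", {
  for (seed in 1:10) {
    fx <- random_annotated_graph(9, 14, 3, seed = 100 + seed)
    g <- fx$graph
    connected <- igraph::is_connected(g)
    for (n1 in 1:8) {
      oracle <- brute_force_configs(g, n1)
      b <- dyad_bounds(igraph::degree(g), n1, connected = connected)
      expect_gte(min(oracle[, "m11"]), b$m11_lower)
      expect_lte(max(oracle[, "m11"]), b$m11_upper)
      expect_gte(min(oracle[, "m10"]), b$m10_lower)
      expect_lte(max(oracle[, "m10"]), b$m10_upper)
    }
  }
})

test_that("m00 bounds are the m11 bounds under the label swap", {
  b <- m00_bounds(c(2, 2, 2), 1)
  expect_equal(c(b$m00_lower, b$m00_upper), c(1L, 1L))
  expect_equal(unname(unlist(m00_bounds(c(2, 2, 2), 3))), c(0L, 0L))

  star <- m00_bounds(c(4, 1, 1, 1, 1), 2)
  swapped <- dyad_bounds(c(4, 1, 1, 1, 1), 3)
  expect_equal(star$m00_lower, swapped$m11_lower)
  expect_equal(star$m00_upper, swapped$m11_upper)
  # and the brute-force realizable m00 values respect them
  oracle <- brute_force_configs(star_graph(), 2)
  m00 <- 4L - oracle[, "m11"] - oracle[, "m10"]
  expect_true(all(m00 >= star$m00_lower & m00 <= star$m00_upper))
})

test_that("dyadicity and heterophilicity are count/expectation ratios", {
  toy_exp <- expected_counts(43, 45, 4)
  cnt <- structure(list(m11 = 6L, m10 = 37L, m00 = 2L, m = 45L),
                   class = "dyad_counts")
  hd <- dyadicity_heterophilicity(cnt, toy_exp)
  expect_equal(hd$D, 6 * 1806 / 540)   # 20.0667
  expect_equal(hd$H, 37 * 1806 / (156 * 90))
  expect_equal(round(hd$D, 2), 20.07)
  expect_equal(round(hd$H, 2), 4.76)

  # m11 equal to its expectation pins D at 1
  ex <- expected_counts(10, 9, 4)
  cnt1 <- structure(list(m11 = ex$m11_bar, m10 = 3L, m00 = 2L, m = 9L),
                    class = "dyad_counts")
  expect_equal(dyadicity_heterophilicity(cnt1, ex)$D, 1)

  # K3: every assignment with n1 = 2 sits exactly at the pivot
  g <- k3_graph()
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    hd <- dyadicity_heterophilicity(count_dyads(g, annotate(g, pair)),
                                    expected_counts(3, 3, 2))
    expect_equal(hd$D, 1)
    expect_equal(hd$H, 1)
  }

  expect_error(
    dyadicity_heterophilicity(cnt, expected_counts(43, 45, 1)),
    "dyadicity undefined")
  expect_error(
    dyadicity_heterophilicity(cnt, expected_counts(43, 45, 0)),
    "undefined")
})

test_that("binary assortativity reproduces the mixing-matrix coefficient", {
  two_tri <- structure(list(m11 = 3L, m10 = 0L, m00 = 3L, m = 6L),
                       class = "dyad_counts")
  expect_equal(binary_assortativity(two_tri), 1)

  k22 <- structure(list(m11 = 0L, m10 = 4L, m00 = 0L, m = 4L),
                   class = "dyad_counts")
  expect_equal(binary_assortativity(k22), -1)

  toy <- structure(list(m11 = 6L, m10 = 37L, m00 = 2L, m = 45L),
                   class = "dyad_counts")
  expect_equal(binary_assortativity(toy), -0.6575, tolerance = 1e-4)

  all11 <- structure(list(m11 = 5L, m10 = 0L, m00 = 0L, m = 5L),
                     class = "dyad_counts")
  expect_error(binary_assortativity(all11), "concentrated")

  # cross-check against igraph's categorical assortativity
  fx <- random_annotated_graph(15, 30, 6, seed = 3)
  r_pkg <- binary_assortativity(count_dyads(fx$graph, fx$annotation))
  lab <- fx$annotation$labels[igraph::V(fx$graph)$name]
  r_ig <- igraph::assortativity_nominal(fx$graph, types = lab + 1)
  expect_equal(r_pkg, r_ig, tolerance = 1e-12)
})

test_that("D and H are invariant under node relabeling", {
  fx <- random_annotated_graph(12, 22, 4, seed = 5)
  g <- fx$graph
  ex <- expected_counts(12, 22, 4)
  hd1 <- dyadicity_heterophilicity(count_dyads(g, fx$annotation), ex)
  set.seed(9)
  perm <- sample(igraph::vcount(g))
  g2 <- igraph::permute(g, perm)
  hd2 <- dyadicity_heterophilicity(count_dyads(g2, fx$annotation), ex)
  expect_equal(hd1$D, hd2$D)
  expect_equal(hd1$H, hd2$H)
})
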