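test_that("closest distance reproduces hand-computed path-graph cases", {
  g <- path_graph_5()
  expect_equal(closest_distance(c("1"), c("3", "5"), g), 3.0)
  expect_equal(closest_distance(c("1", "2"), c("1", "2"), g), 0.0)
  expect_equal(closest_distance(c("2"), c("2"), g), 0.0)
  expect_error(closest_distance(c("99"), c("1"), g), "disease set")
  expect_error(closest_distance(c("1"), c("99"), g), "target set")
})

test_that("closest distance equals the per-target BFS oracle on random graphs", {
  for (i in 1:40) {
    set.seed(4000 + i)
    g <- random_connected_graph(sample(5:50, 1), runif(1, 0.08, 0.3))
    nodes <- igraph::V(g)$name
    S <- sample(nodes, sample(seq_len(min(4, length(nodes))), 1))
    T <- sample(nodes, sample(seq_len(min(6, length(nodes))), 1))
    want <- oracle_closest_distance(adjacency_list(g), S, T)
    expect_equal(closest_distance(S, T, g), want)
    # the precomputed-matrix path must agree exactly with the search path
    expect_equal(closest_distance(S, T, g, dmat = all_pairs_distances(g)),
                 want)
  }
})

test_that("closest distance is monotone under set edits", {
  for (i in 1:10) {
    set.seed(5000 + i)
    g <- random_connected_graph(30, 0.15)
    nodes <- igraph::V(g)$name
    S <- sample(nodes, 3)
    T <- sample(nodes, 5)
    d0 <- closest_distance(S, T, g)
    # enlarging S never increases d_c
    S_big <- union(S, sample(nodes, 3))
    expect_lte(closest_distance(S_big, T, g), d0)
    # removing a maximally distant target never increases d_c
    dmap <- multi_source_shortest_paths(g, S)
    worst <- T[which.max(dmap[T])]
    if (length(T) > 1) {
      expect_lte(closest_distance(S, setdiff(T, worst), g), d0)
    }
  }
})

test_that("degree-matched samples respect size, distinctness and bin structure", {
  g <- generate_interactome(500, 3, seed = 99)
  bins <- build_degree_bins(g, min_bin_size = 50)
  deg <- igraph::degree(g)
  set.seed(1)
  reference <- sample(igraph::V(g)$name, 20)
  ref_bins <- sort(unique(bins$bin_of[reference]))
  for (i in 1:100) {
    s <- degree_matched_sample(reference, bins)
    expect_length(s, length(reference))
    expect_equal(anyDuplicated(s), 0)
    # every sampled protein's bin must be one of the reference bins
    expect_true(all(bins$bin_of[s] %in% ref_bins))
  }
})

test_that("degree-matched sampling is seed-deterministic", {
  g <- generate_interactome(500, 3, seed = 99)
  bins <- build_degree_bins(g, min_bin_size = 50)
  reference <- igraph::V(g)$name[1:10]
  set.seed(42)
  s1 <- degree_matched_sample(reference, bins)
  set.seed(42)
  s2 <- degree_matched_sample(reference, bins)
  set.seed(43)
  s3 <- degree_matched_sample(reference, bins)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
})

test_that("a singleton bin forces itself as the only candidate", {
  # star: hub degree 5, leaves degree 1; min_bin_size 1 isolates the hub
  g <- make_graph_from_edges("H", "a", "H", "b", "H", "c", "H", "d",
                             "H", "e")
  bins <- build_degree_bins(g, min_bin_size = 1)
  expect_equal(degree_matched_sample("H", bins), "H")
})

test_that("exhausted bins widen to their neighbours", {
  g <- make_graph_from_edges("H", "a", "H", "b", "H", "c", "H", "d",
                             "H", "e")
  bins <- build_degree_bins(g, min_bin_size = 1)
  # two proteins wanted from the singleton degree-5 bin: must widen
  set.seed(1)
  expect_message(
    s <- degree_matched_sample(c("H", "H2" = "H"), bins),
    "widened")
  expect_length(unique(s), 2)
})

test_that("null reference distribution behaves on enumerable graphs", {
  # complete graph K5: any closest distance is 0, 0.5 or 1 for |S|=|T|=2
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- paste0("k", 1:5)
  bins <- build_degree_bins(k5, min_bin_size = 1)
  set.seed(11)
  ref <- reference_distribution(c("k1", "k2"), c("k3", "k4"), k5, bins,
                                n_iterations = 400)
  expect_true(all(ref$samples %in% c(0, 0.5, 1)))
  expect_gte(ref$mu, 0)
  expect_lte(ref$mu, 1)
  expect_gte(ref$sigma, 0)

  # cycle C6, |S|=|T|=1: all nodes share one bin, so mu converges to the
  # mean distance over independent uniform ordered node pairs,
  # (0+1+1+2+2+3)/6 = 1.5
  c6 <- igraph::make_ring(6)
  igraph::V(c6)$name <- paste0("c", 1:6)
  bins6 <- build_degree_bins(c6, min_bin_size = 1)
  set.seed(12)
  ref6 <- reference_distribution("c1", "c4", c6, bins6,
                                 n_iterations = 4000)
  expect_equal(ref6$mu, 1.5, tolerance = 0.05)
})

test_that("degenerate nulls yield the undefined-z sentinel", {
  expect_equal(proximity_zscore(1.0, 2.0, 0.5), -2.0)
  expect_equal(proximity_zscore(1.7, 1.7, 0.4), 0.0)
  expect_true(is.na(proximity_zscore(1.0, 2.0, 0)))
  expect_true(is.na(proximity_zscore(1.0, 2.0, 1e-15)))
  expect_error(proximity_zscore(1, 1, -1), "non-negative")
})

test_that("the null sigma uses the population (denominator-n) formula", {
  set.seed(5)
  g <- generate_interactome(120, 2, seed = 5)
  bins <- build_degree_bins(g, min_bin_size = 10)
  nodes <- igraph::V(g)$name
  ref <- reference_distribution(nodes[1:4], nodes[5:8], g, bins,
                                n_iterations = 25)
  x <- ref$samples
  expect_equal(ref$sigma, sqrt(mean((x - mean(x))^2)))
  expect_false(isTRUE(all.equal(ref$sigma, stats::sd(x))))
})

test_that("screening ranks a planted zero-distance compound first", {
  g <- generate_interactome(150, 2, seed = 21)
  nodes <- igraph::V(g)$name
  S <- nodes[1:10]
  inside <- do.call(rbind, lapply(S[1:5], function(t) cti_row("hit", t)))
  d <- multi_source_shortest_paths(g, S)
  far <- names(sort(d, decreasing = TRUE))[1:5]
  outside <- do.call(rbind, lapply(far, function(t) cti_row("miss", t)))
  res <- suppressMessages(screen_compounds(
    rbind(inside, outside), S, g, min_bin_size = 20, n_iterations = 100,
    seed = 2))
  expect_equal(res$compound_id[1], "hit")
  expect_equal(res$d_c[1], 0)
  expect_equal(res$n_direct_interactions[1], 5)
  expect_true(res$d_c[2] > 0)
})

test_that("screening a single compound returns one ordered row with bookkeeping", {
  g <- generate_interactome(100, 2, seed = 31)
  nodes <- igraph::V(g)$name
  cti <- rbind(cti_row("only", nodes[20]), cti_row("only", "unknown_prot"))
  res <- suppressMessages(screen_compounds(
    cti, nodes[1:5], g, min_bin_size = 10, n_iterations = 50, seed = 9))
  expect_equal(nrow(res), 1)
  expect_equal(res$n_targets_used, 1)
  expect_equal(res$n_targets_dropped, 1)
  expect_equal(res$n_iterations, 50)
  expect_equal(res$z, (res$d_c - res$mu) / res$sigma)
})

test_that("screening is deterministic and independent of row order", {
  g <- generate_interactome(150, 2, seed = 41)
  nodes <- igraph::V(g)$name
  set.seed(1)
  cti <- do.call(rbind, lapply(1:4, function(i)
    do.call(rbind, lapply(sample(nodes, 6), function(t)
      cti_row(paste0("c", i), t)))))
  S <- sample(nodes, 8)
  res1 <- suppressMessages(screen_compounds(
    cti, S, g, min_bin_size = 20, n_iterations = 60, seed = 77))
  res2 <- suppressMessages(screen_compounds(
    cti, S, g, min_bin_size = 20, n_iterations = 60, seed = 77))
  shuffled <- cti[rev(seq_len(nrow(cti))), ]
  res3 <- suppressMessages(screen_compounds(
    shuffled, S, g, min_bin_size = 20, n_iterations = 60, seed = 77))
  expect_identical(res1, res2)
  expect_equal(res1, res3, ignore_attr = TRUE)
})
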