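test_that("minimal subnetwork: one target adjacent to one disease protein", {
  g <- make_graph_from_edges("t", "s")
  sn <- extract_subnetwork("cmp", cti_row("cmp", "t"), "s", g)
  expect_setequal(sn$nodes$node, c("t", "s"))
  expect_equal(sum(sn$edges$kind == "ppi"), 1)
  expect_equal(sum(sn$edges$kind == "cti"), 1)
  expect_equal(sn$edges$from[sn$edges$kind == "cti"], "cmp")
  expect_error(extract_subnetwork("nope", cti_row("cmp", "t"), "s", g),
               "unknown compound")
})

test_that("disease proteins beyond one hop are excluded unless bridged", {
  g <- make_graph_from_edges("t", "b", "b", "s")
  cti <- cti_row("cmp", "t")
  off <- extract_subnetwork("cmp", cti, "s", g, include_bridges = FALSE)
  expect_equal(off$disease_nodes, character(0))
  expect_equal(off$nodes$node, "t")

  on <- extract_subnetwork("cmp", cti, "s", g, include_bridges = TRUE)
  expect_setequal(on$nodes$node, c("t", "b", "s"))
  expect_equal(on$bridge_nodes, "b")
  expect_true(on$nodes$is_bridge[on$nodes$node == "b"])
  expect_setequal(on$disease_nodes, "s")
  expect_equal(sum(on$edges$kind == "ppi"), 2)
})

test_that("a node can be simultaneously target and disease protein", {
  g <- make_graph_from_edges("t", "s")
  sn <- extract_subnetwork("cmp", cti_row("cmp", "t"), c("t", "s"), g)
  row_t <- sn$nodes[sn$nodes$node == "t", ]
  expect_true(row_t$is_target && row_t$is_disease)
})

test_that("subnetwork invariants hold on synthetic scenarios", {
  s <- suppressMessages(generate_scenario(
    n_nodes = 200, module_size = 15, n_proximal = 3, n_distal = 3,
    targets_per_compound = c(5, 10), seed = 17))
  edge_keys <- function(g) {
    e <- igraph::as_data_frame(g, what = "edges")
    paste(pmin(e$from, e$to), pmax(e$from, e$to))
  }
  interactome_edges <- edge_keys(s$interactome)
  for (cid in s$cohorts$compound_id) {
    for (bridges in c(FALSE, TRUE)) {
      sn <- extract_subnetwork(cid, s$cti, s$disease, s$interactome,
                               include_bridges = bridges)
      ppi <- sn$edges[sn$edges$kind == "ppi", ]
      # every ppi edge joins two subnetwork nodes and exists upstream
      expect_true(all(ppi$from %in% sn$nodes$node))
      expect_true(all(ppi$to %in% sn$nodes$node))
      expect_true(all(paste(pmin(ppi$from, ppi$to),
                            pmax(ppi$from, ppi$to)) %in%
                        interactome_edges))
      # every cti edge joins the compound to one of its targets
      cti_e <- sn$edges[sn$edges$kind == "cti", ]
      expect_true(all(cti_e$from == cid))
      expect_true(all(cti_e$to %in% sn$target_nodes))
      # disease process groups carried through
      labelled <- sn$nodes[sn$nodes$is_disease, "process_group"]
      expect_false(anyNA(labelled))
    }
  }
})

test_that("subnetwork export writes importable node and edge tables", {
  g <- make_graph_from_edges("t", "s")
  sn <- extract_subnetwork("cmp", cti_row("cmp", "t"), "s", g)
  prefix <- file.path(withr::local_tempdir(), "sub")
  paths <- write_subnetwork(sn, prefix)
  nodes <- read.delim(paths[1])
  edges <- read.delim(paths[2])
  expect_setequal(nodes$node, c("t", "s"))
  expect_equal(nrow(edges), 2)
})

test_that("Benjamini-Hochberg matches the hand-computed step-up cases", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)),
               c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(0.05, 4)), rep(0.05, 4))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
  # permutation equivariance
  p <- c(0.001, 0.2, 0.04, 0.9, 0.04)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(benjamini_hochberg(p)[perm], benjamini_hochberg(p[perm]))
  # adjusted >= raw, <= 1
  expect_true(all(benjamini_hochberg(p) >= p))
  expect_true(all(benjamini_hochberg(p) <= 1))
})

test_that("overrepresentation arithmetic and degenerate cases", {
  universe <- sprintf("u%03d", 1:100)
  term <- universe[1:10]
  query <- c(universe[1:5], universe[50:54])
  res <- overrepresentation(query, list(term1 = term), universe)
  expect_equal(res$n_hit, 5)
  expect_equal(res$fold_enrichment, (5 / 10) / (10 / 100))
  expect_equal(res$fold_enrichment, 5.0)

  # saturated table: query = term = universe
  sat <- overrepresentation(universe, list(all = universe), universe)
  expect_equal(sat$p_fisher, 1)

  # term set equal to the universe: p = 1 for any query
  any_q <- overrepresentation(universe[1:7], list(all = universe),
                              universe)
  expect_equal(any_q$p_fisher, 1)
  expect_equal(any_q$p_adjusted, 1)

  expect_error(overrepresentation("x", list(t = "x"), character(0)),
               "non-empty")
  expect_error(overrepresentation("zz", list(t = universe[1]), universe),
               "outside the universe")
})

test_that("overrepresentation p equals fisher.test and the shared hypergeometric oracle", {
  set.seed(91)
  for (i in 1:10) {
    N <- sample(15:40, 1)
    universe <- sprintf("g%03d", seq_len(N))
    term <- sample(universe, sample(3:10, 1))
    query <- sample(universe, sample(3:10, 1))
    res <- overrepresentation(query, list(t = term), universe)
    K <- res$n_term
    n <- res$n_query
    k <- res$n_hit
    # independent route 1: one-sided Fisher exact test
    tab <- matrix(c(k, K - k, n - k, N - K - n + k), nrow = 2)
    expect_equal(res$p_fisher,
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
    # independent route 2: exhaustive enumeration (small N)
    if (N <= 25) {
      expect_equal(res$p_fisher, oracle_hyper_tail(N, K, n, k),
                   tolerance = 1e-9)
    }
  }
})

test_that("process groups resolve by the fixed priority order", {
  groups <- list("lipid metabolism" = c("A", "B"),
                 "inflammation" = c("B", "C"),
                 "oxidative stress" = c("C", "D"))
  expect_equal(assign_process_group("A", groups), "lipid metabolism")
  expect_equal(assign_process_group("B", groups), "lipid metabolism")
  expect_equal(assign_process_group("C", groups), "inflammation")
  expect_equal(assign_process_group("D", groups), "oxidative stress")
  expect_equal(assign_process_group("Z", groups), "other")
  expect_equal(assign_process_group(c("A", "Z", "C"), groups),
               c("lipid metabolism", "other", "inflammation"))
})

test_that("term sets load from pair files and GMT files", {
  pairs <- withr::local_tempfile(lines = c(
    "term1\tp1", "term1\tp2", "term2\tp3"))
  ts <- read_term_sets(pairs, format = "pairs")
  expect_setequal(ts$term1, c("p1", "p2"))
  expect_equal(ts$term2, "p3")

  gmt <- withr::local_tempfile(fileext = ".gmt", lines = c(
    "GO:1\tlipid metabolic process\tp1\tp2\tp3",
    "GO:2\tinflammatory response\tp4"))
  ts2 <- read_term_sets(gmt)
  expect_length(ts2[["GO:1"]], 3)
  expect_equal(unname(attr(ts2, "term_names")["GO:2"]),
               "inflammatory response")
})
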