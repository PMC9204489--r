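# Textbook queue-based BFS, independent of the package's super-source /
# igraph implementation path. Works on an adjacency list keyed by node name.
adjacency_list <- function(g) {
  nodes <- igraph::V(g)$name
  e <- igraph::as_data_frame(g, what = "edges")
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(e))) {
    adj[[e$from[i]]] <- c(adj[[e$from[i]]], e$to[i])
    adj[[e$to[i]]] <- c(adj[[e$to[i]]], e$from[i])
  }
  adj
}

oracle_bfs <- function(adj, source) {
  dist <- stats::setNames(rep(NA_integer_, length(adj)), names(adj))
  dist[source] <- 0L
  queue <- source
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  dist[!is.na(dist)]
}

# Minimum over per-source single-source BFS runs.
oracle_multi_source <- function(adj, sources) {
  per_source <- lapply(sources, function(s) oracle_bfs(adj, s))
  nodes <- unique(unlist(lapply(per_source, names)))
  out <- vapply(nodes, function(v) {
    min(vapply(per_source, function(d)
      if (v %in% names(d)) d[[v]] else NA_integer_, integer(1)),
      na.rm = TRUE)
  }, integer(1))
  out
}

oracle_closest_distance <- function(adj, S, T) {
  d <- oracle_multi_source(adj, S)
  mean(d[T])
}

# Connected Erdos-Renyi-style test graph: G(n, p) restricted to its largest
# component, vertices named letter-number.
random_connected_graph <- function(n, p) {
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p
  nm <- sprintf("n%02d", seq_len(n))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nm)
  if (any(keep)) {
    ends <- pairs[, keep, drop = FALSE]
    g <- igraph::add_edges(g, as.vector(rbind(nm[ends[1, ]],
                                              nm[ends[2, ]])))
  }
  suppressMessages(largest_connected_component(g))
}

make_graph_from_edges <- function(...) {
  e <- matrix(c(...), ncol = 2, byrow = TRUE)
  igraph::graph_from_edgelist(e, directed = FALSE)
}

path_graph_5 <- function() {
  make_graph_from_edges("1", "2", "2", "3", "3", "4", "4", "5")
}

cti_row <- function(compound, target, action = "inhibitory",
                    source = "predicted", score = 0.9) {
  data.frame(compound_id = compound, target_id = target, action = action,
             source = source, score = score, stringsAsFactors = FALSE)
}

# Exhaustive enumeration oracle for the upper-tail hypergeometric
# P(overlap >= k): enumerate every n-subset of an N-element universe whose
# first K elements are "gold" and count overlaps directly.
oracle_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  ov <- colSums(draws <= K)
  mean(ov >= k)
}
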