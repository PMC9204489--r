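#' Generate a degree-heterogeneous interactome by preferential attachment
#'
#' Growth process: the graph starts from `attachment` unlinked seed nodes;
#' every subsequent node attaches to `attachment` distinct existing nodes
#' chosen with probability proportional to (current degree + 1) — the +1
#' offset lets the zero-degree seeds be chosen, so no seed clique is needed.
#' The first added node necessarily links to all seeds, which makes the
#' graph connected by construction; the edge count is exactly
#' `attachment * (n_nodes - attachment)` and the degree distribution is
#' heavy-tailed, emulating the hub structure of a real protein-protein
#' interactome. `attachment = 1` yields a tree.
#'
#' @param n_nodes Number of nodes (>= `attachment + 1`).
#' @param attachment Edges added per new node.
#' @param seed Optional RNG seed.
#' @return An `igraph` graph with vertices named `P0001`, `P0002`, ...
#' @export
generate_interactome <- function(n_nodes, attachment = 3L, seed = NULL) {
  n_nodes <- as.integer(n_nodes)
  m <- as.integer(attachment)
  if (m < 1L || n_nodes < m + 1L) {
    stop("need n_nodes >= attachment + 1 and attachment >= 1",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  deg <- integer(n_nodes)
  from <- integer(m * (n_nodes - m))
  to <- integer(m * (n_nodes - m))
  e <- 0L
  for (v in (m + 1L):n_nodes) {
    w <- sample.int(v - 1L, m, replace = FALSE, prob = deg[1:(v - 1L)] + 1)
    idx <- e + seq_len(m)
    from[idx] <- v
    to[idx] <- w
    e <- e + m
    deg[w] <- deg[w] + 1L
    deg[v] <- m
  }
  width <- max(4L, nchar(as.character(n_nodes)))
  nm <- sprintf(paste0("P%0", width, "d"), seq_len(n_nodes))
  g <- igraph::make_empty_graph(n_nodes, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nm)
  igraph::add_edges(g, as.vector(rbind(nm[from], nm[to])))
}

#' Plant a connected disease module in a network
#'
#' Grows a connected protein set by breadth-first expansion from a random
#' start node, with ties at each frontier broken by the RNG, until `size`
#' nodes are collected. Each protein is assigned one of the four process
#' groups (lipid metabolism, inflammation, oxidative stress, other)
#' uniformly at random.
#'
#' @param g An `igraph` graph with named vertices.
#' @param size Module size (1 to number of nodes; the component of the
#'   start node must be large enough).
#' @param seed Optional RNG seed.
#' @return Data frame with columns `protein` and `process_group`; the
#'   induced subgraph on `protein` is connected.
#' @export
plant_disease_module <- function(g, size, seed = NULL) {
  n <- igraph::vcount(g)
  size <- as.integer(size)
  if (size < 1L || size > n) {
    stop("module size must be between 1 and the number of nodes (", n, ")",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  nodes <- igraph::V(g)$name
  start <- sample(nodes, 1L)
  visited <- character(0)
  queue <- start
  seen <- start
  while (length(visited) < size && length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    visited <- c(visited, v)
    nb <- setdiff(names(igraph::neighbors(g, v)), seen)
    if (length(nb) > 1L) nb <- sample(nb)
    queue <- c(queue, nb)
    seen <- c(seen, nb)
  }
  if (length(visited) < size) {
    stop("component of the start node is smaller than the requested ",
         "module size", call. = FALSE)
  }
  data.frame(
    protein = visited[seq_len(size)],
    process_group = sample(c("lipid metabolism", "inflammation",
                             "oxidative stress", "other"),
                           size, replace = TRUE),
    stringsAsFactors = FALSE)
}

#' Generate proximal and distal compound cohorts with prediction scores
#'
#' Creates compounds with known proximity ground truth: proximal compounds
#' draw their targets uniformly from the nodes within `proximity_radius`
#' hops of the disease module (so with radius 0 their closest distance is
#' exactly 0), distal compounds from the nodes farther than the radius (if
#' that pool is smaller than the largest target set, the complement of the
#' module and its direct neighbours is used instead, with a message).
#' Target-set sizes are uniform over `targets_per_compound`. Every pair
#' receives a prediction score: proximal-cohort scores are uniform on
#' (0.82, 1.0) and distal on (0.5, 0.95), so the two distributions straddle
#' the 0.82 call threshold and score filtering is exercised on both sides.
#' Action labels are drawn with an inhibitory-heavy mix resembling curated
#' compound-target tables.
#'
#' @param g An `igraph` interactome.
#' @param module Character vector of module proteins, or the data frame from
#'   [plant_disease_module()].
#' @param n_proximal,n_distal Cohort sizes (>= 0).
#' @param targets_per_compound Integer range `c(lo, hi)` of targets per
#'   compound.
#' @param proximity_radius Hop radius defining "proximal" (>= 0).
#' @param seed Optional RNG seed.
#' @return List with `cti` (a CTI data frame, all rows
#'   `source = "predicted"`) and `cohorts` (data frame `compound_id`,
#'   `cohort` in `proximal`/`distal`).
#' @export
generate_compound_cohorts <- function(g, module, n_proximal = 20L,
                                      n_distal = 20L,
                                      targets_per_compound = c(10L, 30L),
                                      proximity_radius = 1L, seed = NULL) {
  if (is.data.frame(module)) module <- module$protein
  module <- unique(as.character(module))
  if (n_proximal < 0L || n_distal < 0L || proximity_radius < 0L) {
    stop("cohort sizes and radius must be non-negative", call. = FALSE)
  }
  if (n_proximal + n_distal == 0L) {
    stop("at least one compound must be requested", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  d <- multi_source_shortest_paths(g, module)
  lo <- min(targets_per_compound)
  hi <- max(targets_per_compound)
  prox_pool <- names(d)[d <= proximity_radius]
  dist_pool <- names(d)[d > proximity_radius]
  if (length(dist_pool) < hi) {
    dist_pool <- names(d)[d > 1L]
    message("generate_compound_cohorts: far pool too small; falling back ",
            "to the complement of the module and its neighbours")
  }
  if (n_proximal > 0L && length(prox_pool) < hi) {
    stop("not enough nodes within the proximity radius to draw target ",
         "sets; enlarge the graph or the radius", call. = FALSE)
  }
  if (n_distal > 0L && length(dist_pool) < hi) {
    stop("not enough nodes beyond the proximity radius to draw target ",
         "sets; enlarge the graph or shrink the module", call. = FALSE)
  }
  draw <- function(id, pool, score_lo, score_hi) {
    n_t <- if (lo == hi) lo else sample(lo:hi, 1L)
    targets <- sample(pool, n_t)
    data.frame(
      compound_id = id,
      target_id = targets,
      action = sample(c("activatory", "inhibitory", "other"), n_t,
                      replace = TRUE, prob = c(0.09, 0.87, 0.04)),
      source = "predicted",
      score = stats::runif(n_t, score_lo, score_hi),
      stringsAsFactors = FALSE)
  }
  parts <- list()
  cohorts <- list()
  for (i in seq_len(n_proximal)) {
    id <- sprintf("proximal_%02d", i)
    parts[[id]] <- draw(id, prox_pool, 0.82, 1.0)
    cohorts[[id]] <- "proximal"
  }
  for (i in seq_len(n_distal)) {
    id <- sprintf("distal_%02d", i)
    parts[[id]] <- draw(id, dist_pool, 0.5, 0.95)
    cohorts[[id]] <- "distal"
  }
  list(
    cti = do.call(rbind, c(parts, list(make.row.names = FALSE))),
    cohorts = data.frame(compound_id = names(cohorts),
                         cohort = unlist(cohorts),
                         row.names = NULL, stringsAsFactors = FALSE))
}

#' Generate annotation term sets with one planted enrichment
#'
#' Produces `n_terms` random protein sets over the universe; the first term
#' is deliberately over-sampled from `enrich_first_term_in` so that its
#' expected overlap with that set is `enrich_fold` times the chance level
#' (capped by the term and set sizes). With the enrichment set equal to the
#' whole universe the first term is indistinguishable from random.
#'
#' @param universe Character vector of proteins (or an `igraph` graph, whose
#'   vertex names are used).
#' @param n_terms Number of terms (>= 1).
#' @param term_size_range Integer range `c(lo, hi)` of term sizes.
#' @param enrich_first_term_in Optional character vector: the protein set
#'   the first term is enriched in (default `NULL`: no planted signal).
#' @param enrich_fold Target fold enrichment of the first term (default 5).
#' @param seed Optional RNG seed.
#' @return Named list `term_01`, `term_02`, ... of member-protein vectors.
#' @export
generate_annotations <- function(universe, n_terms = 20L,
                                 term_size_range = c(20L, 50L),
                                 enrich_first_term_in = NULL,
                                 enrich_fold = 5, seed = NULL) {
  if (inherits(universe, "igraph")) universe <- igraph::V(universe)$name
  universe <- unique(as.character(universe))
  N <- length(universe)
  lo <- min(term_size_range)
  hi <- max(term_size_range)
  if (n_terms < 1L || lo < 1L || hi > N) {
    stop("infeasible annotation sizes: need 1 <= term size <= |universe|",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sizes <- if (lo == hi) rep(lo, n_terms) else
    sample(lo:hi, n_terms, replace = TRUE)
  terms <- vector("list", n_terms)
  names(terms) <- sprintf("term_%02d", seq_len(n_terms))
  for (i in seq_len(n_terms)) {
    m <- sizes[i]
    if (i == 1L && !is.null(enrich_first_term_in)) {
      E <- intersect(unique(as.character(enrich_first_term_in)), universe)
      h <- min(length(E), m, round(enrich_fold * m * length(E) / N))
      inside <- sample(E, h)
      outside_pool <- setdiff(universe, E)
      outside <- if (m - h > 0L) sample(outside_pool, m - h) else
        character(0)
      terms[[i]] <- sample(c(inside, outside))
    } else {
      terms[[i]] <- sample(universe, m)
    }
  }
  terms
}

#' Generate a complete synthetic screening scenario
#'
#' One call produces every input the pipeline needs, with known ground
#' truth: a preferential-attachment interactome, a connected planted disease
#' module with process-group labels, proximal/distal compound cohorts with
#' prediction scores straddling the 0.82 threshold, per-compound QED scores
#' straddling the 0.35 threshold, and annotation terms with one planted
#' enrichment (in the first proximal compound's target set). The default
#' parameters define the package's reference benchmark: 500 nodes,
#' attachment 3, a 30-protein module, 20 proximal (radius 1) and 20 distal
#' compounds with 10-30 targets each. Regenerating with the same seed and
#' parameters reproduces the scenario bit-identically; sub-stages use
#' seeds derived from `seed` by fixed offsets.
#'
#' @param n_nodes,attachment Interactome size and attachment parameter.
#' @param module_size Disease-module size.
#' @param n_proximal,n_distal,targets_per_compound,proximity_radius Cohort
#'   parameters (see [generate_compound_cohorts()]).
#' @param n_terms,term_size_range,enrich_fold Annotation parameters (see
#'   [generate_annotations()]).
#' @param seed Master seed.
#' @return An object of class `synthetic_scenario`: list with
#'   `interactome`, `disease`, `cti`, `cohorts`, `annotations`, `qed`,
#'   `seed` and `params` (the full generator parameter record).
#' @export
generate_scenario <- function(n_nodes = 500L, attachment = 3L,
                              module_size = 30L, n_proximal = 20L,
                              n_distal = 20L,
                              targets_per_compound = c(10L, 30L),
                              proximity_radius = 1L, n_terms = 20L,
                              term_size_range = c(20L, 50L),
                              enrich_fold = 5, seed = 1L) {
  params <- list(n_nodes = n_nodes, attachment = attachment,
                 module_size = module_size, n_proximal = n_proximal,
                 n_distal = n_distal,
                 targets_per_compound = targets_per_compound,
                 proximity_radius = proximity_radius, n_terms = n_terms,
                 term_size_range = term_size_range,
                 enrich_fold = enrich_fold, seed = seed)
  g <- generate_interactome(n_nodes, attachment, seed = seed)
  disease <- plant_disease_module(g, module_size, seed = seed + 1L)
  coh <- generate_compound_cohorts(
    g, disease$protein, n_proximal = n_proximal, n_distal = n_distal,
    targets_per_compound = targets_per_compound,
    proximity_radius = proximity_radius, seed = seed + 2L)
  first_compound <- coh$cohorts$compound_id[1L]
  enrich_set <- unique(coh$cti$target_id[coh$cti$compound_id ==
                                           first_compound])
  ann <- generate_annotations(
    igraph::V(g)$name, n_terms = n_terms,
    term_size_range = term_size_range,
    enrich_first_term_in = enrich_set, enrich_fold = enrich_fold,
    seed = seed + 3L)
  set.seed(seed + 4L)
  compounds <- coh$cohorts$compound_id
  qed <- stats::setNames(round(stats::runif(length(compounds), 0.2, 0.9),
                               3),
                         compounds)
  structure(
    list(interactome = g, disease = disease, cti = coh$cti,
         cohorts = coh$cohorts, annotations = ann, qed = qed,
         seed = seed, params = params),
    class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("Synthetic screening scenario (seed", x$seed, ")\n")
  cat("  interactome:", igraph::vcount(x$interactome), "nodes,",
      igraph::ecount(x$interactome), "edges\n")
  cat("  disease module:", nrow(x$disease), "proteins\n")
  cat("  compounds:", nrow(x$cohorts), "(",
      sum(x$cohorts$cohort == "proximal"), "proximal /",
      sum(x$cohorts$cohort == "distal"), "distal ),",
      nrow(x$cti), "CTI rows\n")
  cat("  annotations:", length(x$annotations), "terms\n")
  invisible(x)
}

#' Write a synthetic scenario to disk in the pipeline's file dialects
#'
#' Emits `edges.tsv` (edge list), `cti.tsv` (CTI table), `disease.tsv`
#' (protein + process group), `cohorts.tsv` (ground-truth labels),
#' `annotations.tsv` (term/protein pairs), `qed.tsv` (compound + QED) and
#' `manifest.yaml` (all generator parameters), so a scenario can be re-read
#' by [load_edge_list()], [read_cti_table()], [read_term_sets()] and
#' [run_screen()].
#'
#' @param scenario A `synthetic_scenario`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    interactome = file.path(dir, "edges.tsv"),
    cti = file.path(dir, "cti.tsv"),
    disease = file.path(dir, "disease.tsv"),
    cohorts = file.path(dir, "cohorts.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    qed = file.path(dir, "qed.tsv"),
    manifest = file.path(dir, "manifest.yaml"))
  edges <- igraph::as_data_frame(scenario$interactome, what = "edges")
  utils::write.table(edges[, c("from", "to")], paths[["interactome"]],
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_cti_table(scenario$cti, paths[["cti"]])
  utils::write.table(scenario$disease, paths[["disease"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(scenario$cohorts, paths[["cohorts"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ann <- data.frame(
    term_id = rep(names(scenario$annotations),
                  lengths(scenario$annotations)),
    protein_id = unlist(scenario$annotations, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(ann, paths[["annotations"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(compound_id = names(scenario$qed),
               qed = unname(scenario$qed), stringsAsFactors = FALSE),
    paths[["qed"]], sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(scenario$params, paths[["manifest"]])
  invisible(paths)
}
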