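#' Extract a compound -> target -> disease-protein mechanism subnetwork
#'
#' Builds the local network a mechanism figure shows: the compound's targets
#' present on the interactome, the disease proteins directly adjacent to at
#' least one target, all interactome edges within that node set, and one
#' compound-target edge per target. With `include_bridges = TRUE`,
#' non-target, non-disease proteins adjacent to both a target and a disease
#' protein are admitted as one-hop bridge nodes (and disease proteins
#' reachable only through such a bridge are then admitted too, so bridges
#' never dangle).
#'
#' @param compound_id Compound to extract.
#' @param cti CTI data frame.
#' @param disease Character vector of disease proteins, or a data frame with
#'   `protein` and optional `process_group` columns.
#' @param g An `igraph` interactome.
#' @param include_bridges Admit one-hop intermediary proteins (default
#'   `FALSE`).
#' @return An object of class `mechanism_subnetwork`: list with
#'   `compound_id`, `target_nodes`, `disease_nodes`, `bridge_nodes`,
#'   `edges` (data frame `from`, `to`, `kind` in `ppi`/`cti`) and `nodes`
#'   (data frame `node`, `is_target`, `is_disease`, `is_bridge`,
#'   `process_group`).
#' @export
extract_subnetwork <- function(compound_id, cti, disease, g,
                               include_bridges = FALSE) {
  cti <- validate_cti(cti)
  rows <- cti[cti$compound_id == compound_id, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("unknown compound: ", compound_id, call. = FALSE)
  }
  groups <- NULL
  if (is.data.frame(disease)) {
    if ("process_group" %in% names(disease)) {
      groups <- stats::setNames(as.character(disease$process_group),
                                disease$protein)
    }
    disease <- disease$protein
  }
  nodes_g <- igraph::V(g)$name
  targets <- intersect(unique(rows$target_id), nodes_g)
  if (length(targets) == 0L) {
    stop("compound ", compound_id,
         " has no target present on the interactome", call. = FALSE)
  }
  S <- intersect(unique(as.character(disease)), nodes_g)

  neighbor_names <- function(vs) {
    if (length(vs) == 0L) return(character(0))
    unique(names(unlist(igraph::ego(g, order = 1, nodes = vs,
                                    mindist = 1))))
  }
  nbr_targets <- neighbor_names(targets)
  disease_nodes <- intersect(S, nbr_targets)
  bridge_nodes <- character(0)
  if (isTRUE(include_bridges)) {
    cand <- setdiff(nbr_targets, union(S, targets))
    nbr_S <- neighbor_names(S)
    bridge_nodes <- intersect(cand, nbr_S)
    if (length(bridge_nodes) > 0L) {
      nbr_bridges <- neighbor_names(bridge_nodes)
      disease_nodes <- union(disease_nodes, intersect(S, nbr_bridges))
    }
  }
  node_set <- unique(c(targets, disease_nodes, bridge_nodes))
  sub <- igraph::induced_subgraph(g, node_set)
  ppi <- igraph::as_data_frame(sub, what = "edges")[, c("from", "to")]
  edges <- rbind(
    if (nrow(ppi) > 0L) data.frame(ppi, kind = "ppi",
                                   stringsAsFactors = FALSE),
    data.frame(from = compound_id, to = targets, kind = "cti",
               stringsAsFactors = FALSE))
  rownames(edges) <- NULL
  nodes <- data.frame(
    node = node_set,
    is_target = node_set %in% targets,
    is_disease = node_set %in% S,
    is_bridge = node_set %in% bridge_nodes,
    process_group = if (is.null(groups)) NA_character_ else
      unname(groups[node_set]),
    stringsAsFactors = FALSE)
  structure(
    list(compound_id = compound_id, target_nodes = targets,
         disease_nodes = disease_nodes, bridge_nodes = bridge_nodes,
         edges = edges, nodes = nodes),
    class = "mechanism_subnetwork")
}

#' @export
print.mechanism_subnetwork <- function(x, ...) {
  cat("Mechanism subnetwork for", x$compound_id, "\n")
  cat("  targets:", length(x$target_nodes),
      " disease proteins:", length(x$disease_nodes),
      " bridges:", length(x$bridge_nodes), "\n")
  cat("  edges:", sum(x$edges$kind == "ppi"), "ppi +",
      sum(x$edges$kind == "cti"), "cti\n")
  invisible(x)
}

#' Write a mechanism subnetwork as node and edge tables
#'
#' Emits two delimited files (`<prefix>_nodes.tsv`, `<prefix>_edges.tsv`)
#' suitable for import into standard graph-visualization tools.
#'
#' @param sn A `mechanism_subnetwork`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two paths written.
#' @export
write_subnetwork <- function(sn, prefix) {
  node_path <- paste0(prefix, "_nodes.tsv")
  edge_path <- paste0(prefix, "_edges.tsv")
  utils::write.table(sn$nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sn$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(node_path, edge_path))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement; the output
#' order matches the input order. Thin validated wrapper over
#' [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must all lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Overrepresentation analysis of a protein set against annotation terms
#'
#' For each term, counts the overlap `k` between the query set and the term
#' members (both restricted to the universe), computes the one-sided Fisher
#' exact p-value for over-representation — identical to the upper-tail
#' hypergeometric `P(X >= k)` — the fold enrichment `(k/n) / (K/N)`, and
#' applies Benjamini-Hochberg correction across all tested terms.
#'
#' @param query Character vector of proteins; must be a subset of
#'   `universe`.
#' @param term_sets Named list mapping term identifier to a character vector
#'   of member proteins (members outside the universe are ignored).
#' @param universe Character vector: the annotation background. The choice
#'   of background changes fold enrichments and p-values, so report it with
#'   any result.
#' @param term_names Optional named character vector of human-readable term
#'   names.
#' @return Data frame with one row per term: `term_id`, `term_name`,
#'   `n_universe`, `n_term`, `n_query`, `n_hit`, `fold_enrichment`,
#'   `p_fisher`, `p_adjusted`; sorted by `p_adjusted` then `term_id`.
#' @export
overrepresentation <- function(query, term_sets, universe,
                               term_names = NULL) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) {
    stop("universe must be non-empty", call. = FALSE)
  }
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    stop("query protein(s) outside the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "), call. = FALSE)
  }
  if (length(term_sets) == 0L || is.null(names(term_sets))) {
    stop("term_sets must be a non-empty named list", call. = FALSE)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(term_sets), function(tid) {
    members <- intersect(unique(as.character(term_sets[[tid]])), universe)
    K <- length(members)
    k <- length(intersect(query, members))
    fold <- if (K > 0L && n > 0L) (k / n) / (K / N) else NA_real_
    data.frame(
      term_id = tid,
      term_name = if (!is.null(term_names) && tid %in% names(term_names))
        unname(term_names[tid]) else tid,
      n_universe = N, n_term = K, n_query = n, n_hit = k,
      fold_enrichment = fold,
      p_fisher = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- benjamini_hochberg(out$p_fisher)
  out <- out[order(out$p_adjusted, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign a protein to its highest-priority biological process group
#'
#' Groups are checked in the order given (by convention: lipid metabolism,
#' then inflammation, then oxidative stress); a protein belonging to several
#' groups receives the first match, and a protein in none receives
#' `"other"`.
#'
#' @param proteins Character vector of proteins to label.
#' @param groups Ordered named list mapping group label to a character
#'   vector of member proteins.
#' @return Character vector of group labels, one per protein.
#' @export
assign_process_group <- function(proteins, groups) {
  if (is.null(names(groups))) {
    stop("groups must be a named list in priority order", call. = FALSE)
  }
  vapply(as.character(proteins), function(p) {
    for (lab in names(groups)) {
      if (p %in% groups[[lab]]) return(lab)
    }
    "other"
  }, character(1), USE.NAMES = FALSE)
}

#' Read annotation term sets
#'
#' Accepts either a two-column delimited file (`term_id`, `protein_id`; one
#' membership per line, `#` comments allowed) or a GMT file (one term per
#' line: term id, description, then member proteins, tab-separated).
#'
#' @param path Path to the file.
#' @param format `"auto"` (by `.gmt` extension), `"pairs"` or `"gmt"`.
#' @return Named list mapping term identifier to member-protein vectors. For
#'   GMT input the descriptions are attached as attribute `term_names`.
#' @export
read_term_sets <- function(path, format = c("auto", "pairs", "gmt")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("cannot read term sets: ", path, call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else
      "pairs"
  }
  if (format == "pairs") {
    tab <- utils::read.table(path, header = FALSE, sep = "",
                             stringsAsFactors = FALSE, comment.char = "#",
                             col.names = c("term_id", "protein_id"))
    return(split(trimws(tab$protein_id), trimws(tab$term_id)))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short) > 0L) {
    stop("GMT line ", short[1L], " has fewer than 3 fields", call. = FALSE)
  }
  terms <- lapply(parts, function(x) unique(trimws(x[-(1:2)])))
  names(terms) <- vapply(parts, `[[`, character(1), 1L)
  attr(terms, "term_names") <-
    stats::setNames(vapply(parts, `[[`, character(1), 2L), names(terms))
  terms
}
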