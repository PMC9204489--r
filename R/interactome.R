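#' Load a protein-protein interactome from a delimited edge list
#'
#' Reads a two-column edge list of protein identifiers into an undirected,
#' simple [igraph] graph. Self-loops and duplicate (unordered) pairs are
#' dropped with a message reporting how many; identifiers are stripped of
#' surrounding whitespace. Lines starting with `#` are treated as comments.
#'
#' @param path Path to a tab- or comma-delimited file; each non-comment line
#'   must carry at least two fields (extra fields are ignored).
#' @param delimiter Field separator. `NULL` (default) auto-detects: tab if the
#'   first data line contains one, comma otherwise.
#' @param header Logical; set `TRUE` to skip the first non-comment line.
#' @param mapping Optional two-column delimited file (`source_id`,
#'   `target_id`) applied to node identifiers at load time; identifiers
#'   without a mapping entry are kept as-is.
#' @return An undirected simple `igraph` object whose vertices are named by
#'   protein identifier.
#' @export
load_edge_list <- function(path, delimiter = NULL, header = FALSE, mapping = NULL) {
  if (!file.exists(path)) {
    stop("cannot read edge list: file does not exist: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (isTRUE(header) && length(lines) > 0) {
    lines <- lines[-1]
    line_no <- line_no[-1]
  }
  if (length(lines) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  }
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad) > 0L) {
    stop("edge list parse error: line ", line_no[bad[1L]],
         " has fewer than 2 fields", call. = FALSE)
  }
  a <- trimws(vapply(parts, `[[`, character(1), 1L))
  b <- trimws(vapply(parts, `[[`, character(1), 2L))
  if (!is.null(mapping)) {
    map <- read_id_mapping(mapping)
    a <- ifelse(a %in% names(map), unname(map[a]), a)
    b <- ifelse(b %in% names(map), unname(map[b]), b)
  }
  n_self <- sum(a == b)
  ok <- a != b
  a <- a[ok]
  b <- b[ok]
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  n_dup <- sum(duplicated(key))
  first <- !duplicated(key)
  g <- igraph::graph_from_edgelist(cbind(a[first], b[first]), directed = FALSE)
  if (n_self > 0L || n_dup > 0L) {
    message("load_edge_list: dropped ", n_self, " self-loop(s) and ",
            n_dup, " duplicate edge(s)")
  }
  message("load_edge_list: ", igraph::vcount(g), " nodes, ",
          igraph::ecount(g), " edges")
  g
}

read_id_mapping <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read node-mapping file: ", path, call. = FALSE)
  }
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE,
                           col.names = c("source_id", "target_id"),
                           comment.char = "#", fill = FALSE)
  stats::setNames(trimws(tab$target_id), trimws(tab$source_id))
}

#' Restrict a graph to its largest connected component
#'
#' Ties between equally sized components are broken in favour of the
#' component containing the lexicographically smallest vertex name. The
#' number of discarded vertices is reported with a message.
#'
#' @param g An `igraph` graph with named vertices (an empty graph is returned
#'   unchanged).
#' @return The induced subgraph on the largest component.
#' @export
largest_connected_component <- function(g) {
  if (igraph::vcount(g) == 0L) {
    return(g)
  }
  comp <- igraph::components(g)
  cand <- which(comp$csize == max(comp$csize))
  if (length(cand) > 1L) {
    nm <- igraph::V(g)$name
    mins <- vapply(cand, function(ci) min(nm[comp$membership == ci]),
                   character(1))
    cand <- cand[order(mins)][1L]
  }
  dropped <- igraph::vcount(g) - comp$csize[cand]
  if (dropped > 0L) {
    message("largest_connected_component: discarded ", dropped,
            " node(s) outside the largest component")
  }
  igraph::induced_subgraph(g, which(comp$membership == cand))
}

#' Hop distance from every node to the nearest of a set of source nodes
#'
#' One breadth-first sweep from a set of sources: equivalent to taking, for
#' every node, the minimum over per-source single-source BFS distances.
#' Implemented by attaching a temporary super-source adjacent to every source
#' and running one unweighted single-source search from it.
#'
#' @param g An `igraph` graph with named vertices.
#' @param sources Non-empty character vector of vertex names; each must be a
#'   vertex of `g`.
#' @return Named integer vector of hop counts for every node reachable from
#'   at least one source (sources map to 0); unreachable nodes are absent.
#' @export
multi_source_shortest_paths <- function(g, sources) {
  sources <- unique(as.character(sources))
  if (length(sources) == 0L) {
    stop("sources must be non-empty", call. = FALSE)
  }
  nodes <- igraph::V(g)$name
  missing <- setdiff(sources, nodes)
  if (length(missing) > 0L) {
    stop("source node(s) not in graph: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  super <- "..proxscreen.super.source.."
  while (super %in% nodes) super <- paste0(super, ".")
  gg <- igraph::add_vertices(g, 1L, name = super)
  gg <- igraph::add_edges(gg, as.vector(rbind(super, sources)))
  d <- igraph::distances(gg, v = super, to = nodes,
                         algorithm = "unweighted")[1L, ] - 1
  names(d) <- nodes
  d <- d[is.finite(d)]
  stats::setNames(as.integer(d), names(d))
}

#' All-pairs hop distances of a graph
#'
#' Convenience wrapper returning the dense unweighted distance matrix with
#' vertex names on both dimensions. Intended for graphs of a few thousand
#' nodes at most, where repeated proximity evaluations (e.g. a 1000-iteration
#' null ensemble) are much faster against a precomputed matrix than by
#' per-iteration searches.
#'
#' @param g An `igraph` graph with named vertices.
#' @return Numeric matrix of hop counts (`Inf` across components).
#' @export
all_pairs_distances <- function(g) {
  d <- igraph::distances(g, algorithm = "unweighted")
  dimnames(d) <- list(igraph::V(g)$name, igraph::V(g)$name)
  d
}

#' Partition network nodes into degree bins of a minimum size
#'
#' Distinct degree values are visited in ascending order and merged into one
#' interval until the interval holds at least `min_bin_size` nodes; a
#' trailing undersized interval is merged into its predecessor. The result is
#' a complete partition of the vertex set used for degree-matched null
#' sampling: a random stand-in for a protein is drawn from the bin covering
#' that protein's degree, so the null ensemble respects hub bias.
#'
#' @param g A non-empty `igraph` graph with named vertices.
#' @param min_bin_size Minimum number of nodes per bin after merging;
#'   defaults to 100, the convention of the proximity framework this package
#'   follows.
#' @return An object of class `degree_bins`: list with `bins` (data frame of
#'   `lo`, `hi`, `size`), `members` (list of vertex-name vectors per bin),
#'   `bin_of` (named integer vector node -> bin index) and `min_bin_size`.
#' @export
build_degree_bins <- function(g, min_bin_size = 100L) {
  n <- igraph::vcount(g)
  if (n == 0L) {
    stop("graph is empty; cannot build degree bins", call. = FALSE)
  }
  if (min_bin_size < 1L) {
    stop("min_bin_size must be >= 1", call. = FALSE)
  }
  if (min_bin_size > n) {
    stop("min_bin_size (", min_bin_size, ") exceeds the number of nodes (",
         n, ")", call. = FALSE)
  }
  deg <- igraph::degree(g)
  tab <- table(deg)
  dvals <- as.integer(names(tab))
  counts <- as.integer(tab)
  lo <- integer(0)
  hi <- integer(0)
  size <- integer(0)
  cur_lo <- NA_integer_
  cur_n <- 0L
  for (i in seq_along(dvals)) {
    if (is.na(cur_lo)) cur_lo <- dvals[i]
    cur_n <- cur_n + counts[i]
    if (cur_n >= min_bin_size) {
      lo <- c(lo, cur_lo)
      hi <- c(hi, dvals[i])
      size <- c(size, cur_n)
      cur_lo <- NA_integer_
      cur_n <- 0L
    }
  }
  if (cur_n > 0L) {
    if (length(lo) == 0L) {
      # cannot happen: min_bin_size <= n guarantees at least one full pass
      lo <- cur_lo
      hi <- dvals[length(dvals)]
      size <- cur_n
    } else {
      # trailing undersized interval absorbed by its predecessor
      hi[length(hi)] <- dvals[length(dvals)]
      size[length(size)] <- size[length(size)] + cur_n
    }
  }
  idx <- findInterval(deg, lo)
  members <- split(names(deg), idx)
  members <- members[as.character(seq_along(lo))]
  names(members) <- NULL
  structure(
    list(bins = data.frame(lo = lo, hi = hi, size = size),
         members = members,
         bin_of = stats::setNames(as.integer(idx), names(deg)),
         min_bin_size = as.integer(min_bin_size)),
    class = "degree_bins")
}

#' @export
print.degree_bins <- function(x, ...) {
  cat("Degree bins:", nrow(x$bins), "bin(s), min size",
      x$min_bin_size, "\n")
  print(x$bins, row.names = FALSE)
  invisible(x)
}
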