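#' Average closest distance between a target set and a disease set
#'
#' For a disease-protein set `S` and a compound-target set `T` on an
#' unweighted interactome, computes
#' \deqn{d_c(S, T) = \frac{1}{|T|} \sum_{t \in T} \min_{s \in S} d(s, t),}
#' the mean over targets of the hop distance to the nearest disease protein.
#' A target that is itself a disease protein contributes 0, so `d_c = 0`
#' exactly when every usable target lies in `S`. Members of either set not
#' present in the graph are dropped before the computation (the caller is
#' expected to track drop counts; [screen_compounds()] does).
#'
#' @param S Character vector: disease-associated proteins.
#' @param T Character vector: compound targets.
#' @param g An `igraph` graph with named vertices; distances must be finite
#'   between the restricted sets, which holds on a connected component (see
#'   [largest_connected_component()]).
#' @param dmat Optional precomputed all-pairs distance matrix (see
#'   [all_pairs_distances()]); when supplied, distances are looked up rather
#'   than searched, which is much faster for repeated calls on one graph.
#' @return A single non-negative number.
#' @export
closest_distance <- function(S, T, g, dmat = NULL) {
  nodes <- igraph::V(g)$name
  S <- intersect(unique(as.character(S)), nodes)
  T <- intersect(unique(as.character(T)), nodes)
  if (length(S) == 0L) {
    stop("disease set S is empty after restriction to the network",
         call. = FALSE)
  }
  if (length(T) == 0L) {
    stop("target set T is empty after restriction to the network",
         call. = FALSE)
  }
  if (!is.null(dmat)) {
    d <- apply(dmat[S, T, drop = FALSE], 2L, min)
  } else {
    dist_to_S <- multi_source_shortest_paths(g, S)
    d <- dist_to_S[T]
  }
  if (anyNA(d) || any(!is.finite(d))) {
    stop("some targets are unreachable from the disease set; restrict ",
         "inputs to the largest connected component first", call. = FALSE)
  }
  mean(d)
}

#' Draw a degree-matched random protein set
#'
#' Returns a set of exactly `length(reference)` distinct proteins: for each
#' reference protein one node is drawn uniformly from that protein's degree
#' bin, without replacement across the whole sample. If a bin cannot supply
#' enough distinct nodes it is temporarily widened to adjacent bins (a
#' message is emitted). Randomness comes from R's global RNG; seed with
#' `set.seed()` for reproducibility.
#'
#' @param reference Character vector of node names to match in size and
#'   degree; must all belong to the binned graph.
#' @param bins A `degree_bins` object from [build_degree_bins()].
#' @return Character vector of sampled node names, same length as
#'   `reference`, all distinct.
#' @export
degree_matched_sample <- function(reference, bins) {
  reference <- as.character(reference)
  if (length(reference) == 0L) {
    stop("reference set must be non-empty", call. = FALSE)
  }
  if (length(reference) > length(bins$bin_of)) {
    stop("cannot sample ", length(reference), " distinct proteins from a ",
         length(bins$bin_of), "-node graph", call. = FALSE)
  }
  missing <- setdiff(reference, names(bins$bin_of))
  if (length(missing) > 0L) {
    stop("reference protein(s) not covered by the degree bins: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  counts <- table(bins$bin_of[reference])
  n_bins <- length(bins$members)
  chosen <- character(0)
  for (b in sort(as.integer(names(counts)))) {
    need <- counts[[as.character(b)]]
    pool <- setdiff(bins$members[[b]], chosen)
    if (length(pool) >= need) {
      chosen <- c(chosen, sample(pool, need))
      next
    }
    picked <- pool
    need <- need - length(pool)
    w <- 1L
    while (need > 0L) {
      adj <- c(b - w, b + w)
      adj <- adj[adj >= 1L & adj <= n_bins]
      if (length(adj) == 0L) {
        stop("degree-matched sampling exhausted all bins", call. = FALSE)
      }
      cand <- setdiff(unique(unlist(bins$members[adj])), c(chosen, picked))
      take <- min(length(cand), need)
      if (take > 0L) picked <- c(picked, sample(cand, take))
      need <- need - take
      w <- w + 1L
    }
    message("degree_matched_sample: bin ", b,
            " exhausted; widened to adjacent bins")
    chosen <- c(chosen, picked)
  }
  chosen
}

#' Reference distribution of closest distances under degree-matched nulls
#'
#' Draws `n_iterations` independent pairs of random protein sets matched in
#' size and degree to `S` and to `T` (each set drawn independently via
#' [degree_matched_sample()]), computes the closest distance for each pair,
#' and summarizes the ensemble. The standard deviation uses the population
#' (denominator-n) formula: the draws *are* the null ensemble being
#' described, not a sample from a larger one.
#'
#' @inheritParams closest_distance
#' @param bins A `degree_bins` object for the same graph.
#' @param n_iterations Number of null draws (>= 2); default 1000.
#' @return List with `mu` (mean), `sigma` (population SD) and `samples`
#'   (numeric vector of all null distances, kept for diagnostics).
#' @export
reference_distribution <- function(S, T, g, bins, n_iterations = 1000L,
                                   dmat = NULL) {
  if (n_iterations < 2L) {
    stop("n_iterations must be >= 2", call. = FALSE)
  }
  nodes <- igraph::V(g)$name
  S <- intersect(unique(as.character(S)), nodes)
  T <- intersect(unique(as.character(T)), nodes)
  samples <- vapply(seq_len(n_iterations), function(i) {
    S_star <- degree_matched_sample(S, bins)
    T_star <- degree_matched_sample(T, bins)
    closest_distance(S_star, T_star, g, dmat = dmat)
  }, numeric(1))
  mu <- mean(samples)
  sigma <- sqrt(mean((samples - mu)^2))
  list(mu = mu, sigma = sigma, samples = samples)
}

#' Proximity z-score of an observed closest distance
#'
#' Standardizes `d_c` against the null mean and SD:
#' \eqn{Z = (d_c - \mu) / \sigma}. When the null is degenerate
#' (`sigma <= tolerance`) the z-score is undefined and `NA` is returned
#' rather than an infinity, so downstream sorting and serialization stay
#' well-defined.
#'
#' @param d_c Observed average closest distance.
#' @param mu Null-ensemble mean.
#' @param sigma Null-ensemble standard deviation (>= 0).
#' @param tolerance Smallest `sigma` treated as non-degenerate (default
#'   1e-12).
#' @return A number, or `NA_real_` when undefined.
#' @export
proximity_zscore <- function(d_c, mu, sigma, tolerance = 1e-12) {
  if (sigma < 0) {
    stop("sigma must be non-negative", call. = FALSE)
  }
  if (sigma > tolerance) (d_c - mu) / sigma else NA_real_
}

# Deterministic per-compound child seed: a string hash of the compound id
# folded into the master seed, so screen output does not depend on compound
# order. Kept below 2^31 - 1 (R integers are 32-bit).
child_seed <- function(seed, id) {
  h <- 0
  for (code in utf8ToInt(id)) h <- (h * 31 + code) %% 1e9
  as.integer((abs(seed) + h * 7919) %% 2147483646 + 1)
}

#' Screen compounds by network proximity to a disease-protein set
#'
#' The main entry point of the analysis: for every compound in the CTI table
#' with at least one target on the interactome, computes the average closest
#' distance `d_c` to the disease proteins, a degree/size-matched null
#' reference distribution, and the proximity z-score; more negative z means
#' more proximal. Results are ordered by z ascending, ties broken by `d_c`
#' ascending then compound identifier; compounds with an undefined z sort
#' last (by `d_c`). All computation is restricted to the largest connected
#' component of `g`; disease proteins and targets outside it are dropped and
#' counted.
#'
#' @param cti CTI data frame (columns `compound_id`, `target_id`, ...).
#' @param disease Character vector of disease proteins, or a data frame with
#'   a `protein` column (e.g. from [plant_disease_module()]).
#' @param g An `igraph` interactome.
#' @param min_bin_size Minimum degree-bin occupancy for the null sampler
#'   (default 100).
#' @param n_iterations Null draws per compound (default 1000).
#' @param seed Master seed; each compound derives a deterministic child seed
#'   from it, so results are reproducible and independent of row order.
#' @param sigma_tolerance Degenerate-null cutoff passed to
#'   [proximity_zscore()].
#' @param use_distance_matrix `NULL` (default) precomputes the all-pairs
#'   distance matrix when the component has at most 3000 nodes; set
#'   `TRUE`/`FALSE` to force either path. The choice affects speed only.
#' @return A data frame with one row per screened compound: `compound_id`,
#'   `n_targets_used`, `n_targets_dropped`, `d_c`, `mu`, `sigma`, `z`,
#'   `n_direct_interactions` (|T intersect S|), `seed` (child seed),
#'   `n_iterations`. The number of disease proteins dropped outside the
#'   component is attached as attribute `n_disease_dropped`, skipped
#'   compounds (no usable target) as attribute `skipped_compounds`.
#' @export
screen_compounds <- function(cti, disease, g, min_bin_size = 100L,
                             n_iterations = 1000L, seed = 1L,
                             sigma_tolerance = 1e-12,
                             use_distance_matrix = NULL) {
  cti <- validate_cti(cti)
  if (nrow(cti) == 0L) {
    stop("CTI table is empty; nothing to screen", call. = FALSE)
  }
  if (is.data.frame(disease)) disease <- disease$protein
  disease <- unique(as.character(disease))
  g <- largest_connected_component(g)
  nodes <- igraph::V(g)$name
  S <- intersect(disease, nodes)
  n_disease_dropped <- length(disease) - length(S)
  if (n_disease_dropped > 0L) {
    message("screen_compounds: dropped ", n_disease_dropped,
            " disease protein(s) outside the largest component")
  }
  if (length(S) == 0L) {
    stop("no disease protein is present on the interactome", call. = FALSE)
  }
  bins <- build_degree_bins(g, min_bin_size)
  if (is.null(use_distance_matrix)) {
    use_distance_matrix <- igraph::vcount(g) <= 3000L
  }
  dmat <- if (use_distance_matrix) all_pairs_distances(g) else NULL

  targets_by_compound <- split(cti$target_id, cti$compound_id)
  skipped <- character(0)
  rows <- lapply(names(targets_by_compound), function(cid) {
    T_raw <- unique(targets_by_compound[[cid]])
    T_used <- intersect(T_raw, nodes)
    if (length(T_used) == 0L) {
      return(NULL)
    }
    d_c <- closest_distance(S, T_used, g, dmat = dmat)
    cs <- child_seed(seed, cid)
    set.seed(cs)
    ref <- reference_distribution(S, T_used, g, bins,
                                  n_iterations = n_iterations, dmat = dmat)
    data.frame(
      compound_id = cid,
      n_targets_used = length(T_used),
      n_targets_dropped = length(T_raw) - length(T_used),
      d_c = d_c,
      mu = ref$mu,
      sigma = ref$sigma,
      z = proximity_zscore(d_c, ref$mu, ref$sigma, sigma_tolerance),
      n_direct_interactions = length(intersect(T_used, S)),
      seed = cs,
      n_iterations = as.integer(n_iterations),
      stringsAsFactors = FALSE)
  })
  ok <- !vapply(rows, is.null, logical(1))
  skipped <- names(targets_by_compound)[!ok]
  if (length(skipped) > 0L) {
    message("screen_compounds: skipped ", length(skipped),
            " compound(s) with no usable target: ",
            paste(utils::head(skipped, 5L), collapse = ", "))
  }
  if (!any(ok)) {
    stop("no compound has a usable target on the interactome",
         call. = FALSE)
  }
  out <- do.call(rbind, rows[ok])
  z_key <- ifelse(is.na(out$z), Inf, out$z)
  out <- out[order(z_key, out$d_c, out$compound_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_disease_dropped") <- n_disease_dropped
  attr(out, "skipped_compounds") <- skipped
  out
}
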