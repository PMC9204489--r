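# Pair sets may be given as two-column data frames (compound, target) or as
# character keys; internally everything becomes a character key.
pair_keys <- function(x, what = "pair set") {
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) {
      stop(what, " data frame needs at least two columns", call. = FALSE)
    }
    unique(paste(as.character(x[[1L]]), as.character(x[[2L]]), sep = "\r"))
  } else {
    unique(as.character(x))
  }
}

#' Hypergeometric recovery test of predicted against validated interactions
#'
#' Tests whether a set of predicted compound-target pairs recovers a
#' validated gold standard more often than chance. With `N` predictable
#' pairs (the universe), `K` of them validated, `n` called positive and `k`
#' recovered (`gold` intersect `predicted`), the p-value is the upper tail
#' `P(X >= k)` of the hypergeometric distribution — the standard
#' over-representation tail. Optionally an empirical permutation twin is run:
#' each permutation draws `n` pairs uniformly without replacement from the
#' universe and records the overlap with the gold standard; the empirical
#' p-value uses the add-one estimator `(1 + #{overlap >= k}) / (1 + B)` so
#' it is never exactly zero.
#'
#' @param universe All predictable pairs: a two-column data frame
#'   (compound, target) or a character vector of keys.
#' @param gold Validated pairs; must be a subset of `universe`.
#' @param predicted Pairs called positive; must be a subset of `universe`.
#' @param n_permutations If >= 1, also run the permutation null with this
#'   many draws (default 0: analytic test only).
#' @param seed Optional seed for the permutation draws.
#' @return An object of class `recovery_test`: list with `n_universe`,
#'   `n_gold`, `n_predicted`, `n_overlap`, `p_hypergeometric`,
#'   `p_empirical` (`NA` unless permutations were run), `n_permutations`.
#' @export
hypergeometric_recovery_test <- function(universe, gold, predicted,
                                         n_permutations = 0L, seed = NULL) {
  u <- pair_keys(universe, "universe")
  gk <- pair_keys(gold, "gold")
  pk <- pair_keys(predicted, "predicted")
  bad_g <- setdiff(gk, u)
  if (length(bad_g) > 0L) {
    stop("gold pairs outside the universe: ",
         paste(gsub("\r", "/", utils::head(bad_g, 5L)), collapse = ", "),
         call. = FALSE)
  }
  bad_p <- setdiff(pk, u)
  if (length(bad_p) > 0L) {
    stop("predicted pairs outside the universe: ",
         paste(gsub("\r", "/", utils::head(bad_p, 5L)), collapse = ", "),
         call. = FALSE)
  }
  N <- length(u)
  K <- length(gk)
  n <- length(pk)
  k <- length(intersect(gk, pk))
  p_hyper <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_emp <- NA_real_
  if (n_permutations >= 1L) {
    ov <- empirical_recovery_null(u, gk, n, n_permutations, seed = seed)
    p_emp <- (1 + sum(ov >= k)) / (1 + n_permutations)
  }
  structure(
    list(n_universe = N, n_gold = K, n_predicted = n, n_overlap = k,
         p_hypergeometric = p_hyper, p_empirical = p_emp,
         n_permutations = as.integer(n_permutations)),
    class = "recovery_test")
}

#' @export
print.recovery_test <- function(x, ...) {
  cat("Recovery test (upper-tail hypergeometric)\n")
  cat("  universe:", x$n_universe, " gold:", x$n_gold,
      " predicted:", x$n_predicted, " recovered:", x$n_overlap, "\n")
  cat("  p (hypergeometric):", format(x$p_hypergeometric, digits = 4), "\n")
  if (x$n_permutations > 0L) {
    cat("  p (empirical,", x$n_permutations, "permutations):",
        format(x$p_empirical, digits = 4), "\n")
  }
  invisible(x)
}

#' Permutation null for the recovery overlap count
#'
#' Each permutation draws `n_predicted` pairs uniformly without replacement
#' from the universe and records how many fall in the gold standard.
#'
#' @inheritParams hypergeometric_recovery_test
#' @param n_predicted Number of pairs drawn per permutation.
#' @param n_permutations Number of permutations (>= 1).
#' @return Integer vector of overlap counts, one per permutation.
#' @export
empirical_recovery_null <- function(universe, gold, n_predicted,
                                    n_permutations, seed = NULL) {
  u <- pair_keys(universe, "universe")
  gk <- pair_keys(gold, "gold")
  if (n_permutations < 1L) {
    stop("n_permutations must be >= 1", call. = FALSE)
  }
  if (n_predicted > length(u)) {
    stop("n_predicted (", n_predicted,
         ") exceeds the universe size (", length(u), ")", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  is_gold <- u %in% gk
  vapply(seq_len(n_permutations), function(i) {
    sum(is_gold[sample.int(length(u), n_predicted)])
  }, integer(1))
}
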