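#' @keywords internal
cti_actions <- c("activatory", "inhibitory", "other")
cti_sources <- c("validated", "predicted")

validate_cti <- function(t, what = "CTI table") {
  required <- c("compound_id", "target_id", "action", "source")
  missing <- setdiff(required, names(t))
  if (length(missing) > 0L) {
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"score" %in% names(t)) t$score <- NA_real_
  t$compound_id <- trimws(as.character(t$compound_id))
  t$target_id <- trimws(as.character(t$target_id))
  t$action <- as.character(t$action)
  t$source <- as.character(t$source)
  t$score <- as.numeric(t$score)
  bad_action <- setdiff(unique(t$action), cti_actions)
  if (length(bad_action) > 0L) {
    stop(what, " has unknown action label(s): ",
         paste(bad_action, collapse = ", "),
         " (expected ", paste(cti_actions, collapse = "/"), ")",
         call. = FALSE)
  }
  bad_source <- setdiff(unique(t$source), cti_sources)
  if (length(bad_source) > 0L) {
    stop(what, " has unknown source label(s): ",
         paste(bad_source, collapse = ", "), call. = FALSE)
  }
  out_of_range <- !is.na(t$score) & (t$score < 0 | t$score > 1)
  if (any(out_of_range)) {
    stop(what, " has score(s) outside [0, 1]", call. = FALSE)
  }
  if (any(t$source == "predicted" & is.na(t$score))) {
    stop(what, " has predicted row(s) without a prediction score",
         call. = FALSE)
  }
  rownames(t) <- NULL
  t[c("compound_id", "target_id", "action", "source", "score")]
}

#' Read a compound-target interaction table
#'
#' Expects a delimited file with header columns `compound_id`, `target_id`,
#' `action` (one of `activatory`/`inhibitory`/`other`), `source`
#' (`validated`/`predicted`) and optional `score` in `[0, 1]`. Unknown action
#' or source labels are rejected rather than coerced, and every `predicted`
#' row must carry a score.
#'
#' @param path Path to the file.
#' @param sep Field separator (default tab).
#' @return A validated data frame with the five canonical columns.
#' @export
read_cti_table <- function(path, sep = "\t") {
  if (!file.exists(path)) {
    stop("cannot read CTI table: ", path, call. = FALSE)
  }
  t <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, comment.char = "#",
                         quote = "")
  validate_cti(t, what = path)
}

#' Write a compound-target interaction table
#'
#' Emits the same dialect [read_cti_table()] reads.
#'
#' @param t A CTI data frame.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @export
write_cti_table <- function(t, path, sep = "\t") {
  t <- validate_cti(t)
  utils::write.table(t, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter compounds by drug-likeness (QED) score
#'
#' Keeps compounds whose quantitative estimate of drug-likeness is greater
#' than or equal to the threshold (the boundary is inclusive: a compound at
#' exactly the threshold passes). Compounds without a QED entry are excluded
#' and reported with a message.
#'
#' @param compounds Character vector of compound identifiers.
#' @param qed_scores Named numeric vector mapping compound identifier to a
#'   QED score in `[0, 1]`.
#' @param threshold QED cutoff in `[0, 1]`; default 0.35, the mean QED of
#'   approved drugs commonly used as a drug-likeness floor.
#' @return The subset of `compounds` passing the filter (input order kept).
#' @export
filter_compounds_by_qed <- function(compounds, qed_scores, threshold = 0.35) {
  if (threshold < 0 || threshold > 1) {
    stop("QED threshold must be in [0, 1]", call. = FALSE)
  }
  compounds <- as.character(compounds)
  if (length(compounds) == 0L) {
    return(character(0))
  }
  has <- compounds %in% names(qed_scores)
  if (any(!has)) {
    message("filter_compounds_by_qed: excluded ", sum(!has),
            " compound(s) with no QED score: ",
            paste(utils::head(compounds[!has], 5L), collapse = ", "))
  }
  kept <- compounds[has][qed_scores[compounds[has]] >= threshold]
  kept
}

#' Filter predicted interactions by prediction score
#'
#' Predicted rows are kept only when their score is strictly greater than
#' the threshold; validated rows always pass. The default 0.82 is the score
#' at which the upstream interaction predictor reports a 1% false discovery
#' rate, so a row at exactly 0.82 is excluded.
#'
#' @param t A CTI data frame (see [read_cti_table()]).
#' @param threshold Strict lower bound in `[0, 1]` for predicted scores.
#' @return The filtered CTI data frame.
#' @export
filter_predictions_by_score <- function(t, threshold = 0.82) {
  if (threshold < 0 || threshold > 1) {
    stop("score threshold must be in [0, 1]", call. = FALSE)
  }
  t <- validate_cti(t)
  keep <- t$source == "validated" |
    (t$source == "predicted" & t$score > threshold)
  out <- t[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

collapse_within_source <- function(t, what) {
  key <- paste(t$compound_id, t$target_id, sep = "\r")
  acts <- tapply(t$action, key, function(a) length(unique(a)))
  conflicts <- names(acts)[acts > 1L]
  if (length(conflicts) > 0L) {
    pairs <- gsub("\r", " / ", utils::head(conflicts, 5L), fixed = TRUE)
    stop("conflicting duplicate rows (same pair, different action) in ",
         what, " table: ", paste(pairs, collapse = "; "), call. = FALSE)
  }
  dup <- duplicated(key)
  out <- t[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge validated and predicted compound-target tables
#'
#' Produces one consolidated row per (compound, target) pair. A pair present
#' in both inputs is recorded with `source = "validated"`; its action label
#' is the validated one, except that a validated `"other"` label is refined
#' by a directional (`activatory`/`inhibitory`) predicted label — the
#' experiment confirms the interaction, the prediction supplies its
#' direction. Duplicate rows with conflicting actions inside a single input
#' are an error.
#'
#' @param validated CTI data frame with `source == "validated"` rows.
#' @param predicted CTI data frame with `source == "predicted"` rows.
#' @return The merged CTI data frame.
#' @export
merge_validated_predicted <- function(validated, predicted) {
  v <- collapse_within_source(validate_cti(validated, "validated"),
                              "validated")
  p <- collapse_within_source(validate_cti(predicted, "predicted"),
                              "predicted")
  vkey <- paste(v$compound_id, v$target_id, sep = "\r")
  pkey <- paste(p$compound_id, p$target_id, sep = "\r")
  both <- intersect(vkey, pkey)
  if (length(both) > 0L) {
    vi <- match(both, vkey)
    p_idx <- match(both, pkey)
    refine <- v$action[vi] == "other" & p$action[p_idx] %in%
      c("activatory", "inhibitory")
    v$action[vi[refine]] <- p$action[p_idx[refine]]
    v$source[vi] <- "validated"
    take_score <- is.na(v$score[vi]) & !is.na(p$score[p_idx])
    v$score[vi[take_score]] <- p$score[p_idx[take_score]]
  }
  out <- rbind(v, p[!(pkey %in% both), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Descriptive statistics of a compound-target network
#'
#' Treats the table as a bipartite graph (compounds + targets as nodes, one
#' edge per consolidated interaction) and summarizes its size, the action
#' split and the per-compound target counts.
#'
#' @param t A CTI data frame.
#' @return An object of class `cti_stats`: list with `n_compounds`,
#'   `n_targets`, `n_nodes`, `n_edges`, `edges_by_action` (named integer),
#'   `mean_targets_per_compound` and `targets_per_compound` (named integer
#'   vector, one entry per compound).
#' @export
cti_network_stats <- function(t) {
  if (nrow(t) == 0L) {
    return(structure(
      list(n_compounds = 0L, n_targets = 0L, n_nodes = 0L, n_edges = 0L,
           edges_by_action = stats::setNames(integer(length(cti_actions)),
                                             cti_actions),
           mean_targets_per_compound = 0,
           targets_per_compound = integer(0)),
      class = "cti_stats"))
  }
  t <- validate_cti(t)
  per_compound <- table(t$compound_id)
  by_action <- stats::setNames(integer(length(cti_actions)), cti_actions)
  obs <- table(t$action)
  by_action[names(obs)] <- as.integer(obs)
  n_compounds <- length(unique(t$compound_id))
  n_targets <- length(unique(t$target_id))
  structure(
    list(n_compounds = n_compounds,
         n_targets = n_targets,
         n_nodes = n_compounds + n_targets,
         n_edges = nrow(t),
         edges_by_action = by_action,
         mean_targets_per_compound = nrow(t) / n_compounds,
         targets_per_compound = stats::setNames(as.integer(per_compound),
                                                names(per_compound))),
    class = "cti_stats")
}

#' @export
print.cti_stats <- function(x, ...) {
  cat("Compound-target network\n")
  cat("  compounds:", x$n_compounds, "  targets:", x$n_targets,
      "  nodes:", x$n_nodes, "  edges:", x$n_edges, "\n")
  cat("  edges by action:",
      paste(names(x$edges_by_action), x$edges_by_action,
            sep = "=", collapse = ", "), "\n")
  cat("  mean targets per compound:",
      round(x$mean_targets_per_compound, 1), "\n")
  invisible(x)
}
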