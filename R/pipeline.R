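run_config_keys <- c("interactome", "cti", "disease", "qed", "annotations",
                     "qed_threshold", "score_threshold", "min_bin_size",
                     "n_iterations", "seed", "sigma_tolerance",
                     "output_dir")

#' Build and validate a screening run configuration
#'
#' Collects the input paths, thresholds and proximity parameters of one
#' screening run and validates them eagerly (thresholds in range, iteration
#' count sane, all declared input paths present), so a misconfigured run
#' fails before any computation starts.
#'
#' @param interactome Path to the interactome edge list.
#' @param cti Path to the CTI table.
#' @param disease Path to the disease-protein list (delimited, header with a
#'   `protein` column; optional `process_group` column).
#' @param qed Optional path to a per-compound QED table (header
#'   `compound_id`, `qed`).
#' @param annotations Optional path to an annotation term-set file.
#' @param qed_threshold Inclusive QED cutoff (default 0.35).
#' @param score_threshold Strict prediction-score cutoff (default 0.82).
#' @param min_bin_size Degree-bin occupancy for the null sampler (default
#'   100).
#' @param n_iterations Null draws per compound (default 1000).
#' @param seed Master seed (default 1).
#' @param sigma_tolerance Degenerate-null cutoff (default 1e-12).
#' @param output_dir Directory the run writes into.
#' @return An object of class `run_config` (a validated named list).
#' @export
run_config <- function(interactome, cti, disease, qed = NULL,
                       annotations = NULL, qed_threshold = 0.35,
                       score_threshold = 0.82, min_bin_size = 100L,
                       n_iterations = 1000L, seed = 1L,
                       sigma_tolerance = 1e-12, output_dir = ".") {
  cfg <- list(interactome = interactome, cti = cti, disease = disease,
              qed = qed, annotations = annotations,
              qed_threshold = qed_threshold,
              score_threshold = score_threshold,
              min_bin_size = as.integer(min_bin_size),
              n_iterations = as.integer(n_iterations),
              seed = as.integer(seed),
              sigma_tolerance = sigma_tolerance,
              output_dir = output_dir)
  if (cfg$qed_threshold < 0 || cfg$qed_threshold > 1 ||
      cfg$score_threshold < 0 || cfg$score_threshold > 1) {
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_iterations < 2L) {
    stop("n_iterations must be >= 2", call. = FALSE)
  }
  for (key in c("interactome", "cti", "disease", "qed", "annotations")) {
    p <- cfg[[key]]
    if (!is.null(p) && !file.exists(p)) {
      stop("configured ", key, " path does not exist: ", p, call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

#' Read a screening run configuration from a YAML file
#'
#' The file is a flat key-value document over the keys of [run_config()].
#' Unknown keys are an error — this catches typos in threshold names rather
#' than silently running with defaults. Relative paths are resolved against
#' the file's directory.
#'
#' @param path Path to the YAML file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read config file: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), run_config_keys)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  for (key in c("interactome", "cti", "disease", "qed", "annotations",
                "output_dir")) {
    p <- raw[[key]]
    if (!is.null(p) && !grepl("^(/|[A-Za-z]:)", p)) {
      raw[[key]] <- file.path(base, p)
    }
  }
  do.call(run_config, raw)
}

#' Read a disease-protein list
#'
#' Delimited file with a header; requires a `protein` column, keeps an
#' optional `process_group` column.
#'
#' @param path Path to the file.
#' @param sep Field separator (default tab).
#' @return Data frame with `protein` (and `process_group` if present).
#' @export
read_disease_proteins <- function(path, sep = "\t") {
  if (!file.exists(path)) {
    stop("cannot read disease-protein list: ", path, call. = FALSE)
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (!"protein" %in% names(tab)) {
    stop("disease-protein file needs a 'protein' column", call. = FALSE)
  }
  tab$protein <- trimws(as.character(tab$protein))
  keep <- intersect(c("protein", "process_group"), names(tab))
  tab[keep]
}

#' Run the full proximity screen from a configuration
#'
#' Orchestrates load, filter and screen: reads the interactome, CTI table
#' and disease proteins; applies the QED filter (when a QED table is
#' configured) and the prediction-score filter; screens every remaining
#' compound with [screen_compounds()]; and writes the ranked table
#' (`ranked_proximity.tsv`) plus a run manifest (`manifest.yaml` — seed,
#' parameters, package version, input checksums, dropped counts) under the
#' configured output directory. Rerunning with the same configuration and
#' seed reproduces the ranked table byte-identically.
#'
#' @param config A `run_config` (or a path to a YAML config file).
#' @return Invisibly, a list with `results` (the ranked data frame),
#'   `manifest` and `paths` of the files written.
#' @export
run_screen <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  g <- load_edge_list(config$interactome)
  cti <- read_cti_table(config$cti)
  disease <- read_disease_proteins(config$disease)

  n_qed_excluded <- 0L
  if (!is.null(config$qed)) {
    qtab <- utils::read.table(config$qed, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    if (!all(c("compound_id", "qed") %in% names(qtab))) {
      stop("QED table needs 'compound_id' and 'qed' columns",
           call. = FALSE)
    }
    qed <- stats::setNames(as.numeric(qtab$qed),
                           trimws(qtab$compound_id))
    compounds <- unique(cti$compound_id)
    kept <- filter_compounds_by_qed(compounds, qed, config$qed_threshold)
    n_qed_excluded <- length(compounds) - length(kept)
    cti <- cti[cti$compound_id %in% kept, , drop = FALSE]
  }
  n_before <- nrow(cti)
  cti <- filter_predictions_by_score(cti, config$score_threshold)
  n_score_excluded <- n_before - nrow(cti)

  results <- screen_compounds(
    cti, disease, g, min_bin_size = config$min_bin_size,
    n_iterations = config$n_iterations, seed = config$seed,
    sigma_tolerance = config$sigma_tolerance)

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  ranked_path <- file.path(config$output_dir, "ranked_proximity.tsv")
  out <- results
  out$d_c <- format(out$d_c, digits = 15)
  out$mu <- format(out$mu, digits = 15)
  out$sigma <- format(out$sigma, digits = 15)
  out$z <- format(out$z, digits = 15)
  utils::write.table(out, ranked_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  input_paths <- Filter(Negate(is.null),
                        config[c("interactome", "cti", "disease", "qed",
                                 "annotations")])
  manifest <- list(
    package = "proxscreen",
    version = as.character(utils::packageVersion("proxscreen")),
    seed = config$seed,
    parameters = list(qed_threshold = config$qed_threshold,
                      score_threshold = config$score_threshold,
                      min_bin_size = config$min_bin_size,
                      n_iterations = config$n_iterations,
                      sigma_tolerance = config$sigma_tolerance),
    inputs = lapply(input_paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    dropped = list(
      compounds_failing_qed = n_qed_excluded,
      rows_failing_score = n_score_excluded,
      disease_proteins_outside_component =
        attr(results, "n_disease_dropped"),
      compounds_without_usable_target =
        length(attr(results, "skipped_compounds"))))
  manifest_path <- file.path(config$output_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(list(results = results, manifest = manifest,
                 paths = c(ranked = ranked_path,
                           manifest = manifest_path)))
}
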