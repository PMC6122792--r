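#' Pipeline run configuration
#'
#' Validated bundle of the knobs the end-to-end workflow needs. A config can
#' also be read from YAML with [read_run_config()]; explicit arguments
#' override file values.
#'
#' @param variant Cohort variant.
#' @param n Cohort size.
#' @param seed Integer root seed for all stages.
#' @param bootstrap_B Bootstrap replicates for model averaging.
#' @param restarts Hill-climb random restarts.
#' @param threshold_override Optional fixed arc-strength threshold.
#' @param propagation_draws Minimum accepted draws per propagation condition.
#' @param output_dir Directory artifacts are written to.
#' @param blacklist_extra Optional data frame of extra forbidden
#'   `from`/`to` pairs.
#' @return An object of class `bn_run_config`.
#' @export
run_config <- function(variant = "total_pa", n = 333, seed = 1,
                       bootstrap_B = 500, restarts = 0,
                       threshold_override = NULL, propagation_draws = 1e5,
                       output_dir = ".", blacklist_extra = NULL) {
  variant <- match.arg(variant, c("total_pa", "mvpa_sedentary"))
  stopifnot(n >= 1, bootstrap_B >= 1, restarts >= 0, propagation_draws >= 1)
  cfg <- list(variant = variant, n = as.integer(n), seed = as.integer(seed),
              bootstrap_B = as.integer(bootstrap_B),
              restarts = as.integer(restarts),
              threshold_override = threshold_override,
              propagation_draws = propagation_draws,
              output_dir = output_dir, blacklist_extra = blacklist_extra)
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "bn_run_config")
}

config_hash <- function(cfg) {
  keep <- cfg[setdiff(names(cfg), "hash")]
  sprintf("%08x", fnv1a31(paste(deparse(keep), collapse = "")))
}

#' @rdname run_config
#' @param path YAML file with any subset of the config fields.
#' @param ... Overrides passed to [run_config()].
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$blacklist_extra)) {
    vals$blacklist_extra <- purrr::map_dfr(vals$blacklist_extra,
                                           tibble::as_tibble)
  }
  args <- utils::modifyList(vals, list(...))
  do.call(run_config, args)
}

#' @export
print.bn_run_config <- function(x, ...) {
  cat("<run config ", x$hash, ": ", x$variant, ", n = ", x$n,
      ", seed = ", x$seed, ", B = ", x$bootstrap_B, ">\n", sep = "")
  invisible(x)
}

stage_log <- function(stage, t0) {
  message(sprintf("[%s] done in %.1fs", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Simulate a synthetic cohort to disk
#'
#' Calibrates the ground-truth network for the configured variant, samples a
#' cohort, validates its marginals, and writes `cohort.csv` plus a
#' provenance YAML into the output directory.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the cohort tibble, the calibrated network,
#'   and the marginal validation report.
#' @export
pipeline_simulate <- function(config) {
  t0 <- as.numeric(Sys.time())
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  gt_cfg <- ground_truth_config(config$variant, n = config$n,
                                seed = config$seed)
  truth <- calibrate_network(gt_cfg)
  cohort <- sample_cohort(truth, config$n, config$seed)
  attr(cohort, "provenance") <- c(attr(cohort, "provenance"),
                                  list(config_hash = config$hash))
  report <- validate_marginals(cohort, gt_cfg)
  path <- file.path(config$output_dir, "cohort.csv")
  write_cohort(cohort, path)
  message("calibration summary: ",
          sum(report$flag), " of ", nrow(report), " marginals flagged")
  stage_log("simulate", t0)
  invisible(list(cohort = cohort, truth = truth, marginals = report,
                 path = path))
}

#' Learn, average and fit a network from a cohort file
#'
#' Runs the full analysis chain: bootstrap structure learning under the
#' tier blacklist, arc/direction strengths, threshold selection, averaged
#' network, parameter fitting, and the coefficient and BIC reports. Writes
#' `network.graphml`, `network.dot`, `arc_strengths.csv`,
#' `coefficients.csv`, and `bic.json` into the output directory.
#'
#' @param cohort_path Cohort CSV (schema checked against the variant).
#' @param config A [run_config()].
#' @return Invisibly, a list with the averaged network, fitted parameters,
#'   coefficient table and BIC report.
#' @export
pipeline_analyze <- function(cohort_path, config) {
  t0 <- as.numeric(Sys.time())
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  schema <- cohort_schema(config$variant)
  cohort <- read_cohort(cohort_path, schema)
  bl <- default_blacklist(schema, extra = config$blacklist_extra)
  graphs <- bootstrap_structures(cohort, B = config$bootstrap_B,
                                 blacklist = bl, seed = config$seed,
                                 restarts = config$restarts,
                                 progress_every = 50)
  avg <- averaged_network(graphs,
                          threshold_override = config$threshold_override)
  message("threshold chosen: ", format(avg$threshold, digits = 3),
          "; arcs retained: ", nrow(avg$graph$edges))
  fit <- fit_network(avg$graph, cohort)
  coefs <- coefficient_report(fit, avg$strengths)
  bic <- network_bic(avg$graph, cohort, label = "averaged")
  out_dir <- config$output_dir
  write_network(avg$graph, file.path(out_dir, "network.graphml"),
                schema = schema, strengths = avg$strengths)
  write_network(avg$graph, file.path(out_dir, "network.dot"),
                schema = schema, strengths = avg$strengths)
  readr::write_csv(avg$strengths, file.path(out_dir, "arc_strengths.csv"))
  readr::write_csv(coefs, file.path(out_dir, "coefficients.csv"))
  jsonlite::write_json(c(as.list(bic),
                         list(seed = config$seed, config_hash = config$hash)),
                       file.path(out_dir, "bic.json"), auto_unbox = TRUE,
                       digits = NA)
  stage_log("analyze", t0)
  invisible(list(averaged = avg, fit = fit, coefficients = coefs, bic = bic))
}

#' Score structural edits against a reference network
#'
#' Each edit is either `list(isolate = node)` or
#' `list(delete = c(from, to))`; the edited structure is refitted and
#' reported against the reference with its BIC difference / log Bayes
#' factor. Results go to `comparisons.json` in the output directory.
#'
#' @param cohort_path Cohort CSV.
#' @param network Reference `bn_dag` (or `bn_fit`).
#' @param edits List of edits (possibly empty).
#' @param config A [run_config()].
#' @return Invisibly, the combined `bn_bic_report` tibble.
#' @export
pipeline_compare <- function(cohort_path, network, edits, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  schema <- cohort_schema(config$variant)
  cohort <- read_cohort(cohort_path, schema)
  graph <- if (inherits(network, "bn_fit")) network$graph else network
  reports <- network_bic(graph, cohort, label = "reference")
  for (edit in edits) {
    if (!is.null(edit$isolate)) {
      alt <- isolate_node(graph, edit$isolate)
      lab <- paste0("isolate ", edit$isolate)
    } else if (!is.null(edit$delete)) {
      alt <- delete_edge(graph, edit$delete[1], edit$delete[2])
      lab <- paste0("delete ", edit$delete[1], " -> ", edit$delete[2])
    } else {
      bn_abort("each edit must be list(isolate = ...) or list(delete = ...)")
    }
    reports <- dplyr::bind_rows(reports,
                                compare_networks(graph, alt, cohort,
                                                 labels = c("reference", lab))[2, ])
  }
  reports <- structure(reports, class = c("bn_bic_report", class(reports)))
  jsonlite::write_json(list(seed = config$seed, config_hash = config$hash,
                            reports = as.data.frame(reports)),
                       file.path(config$output_dir, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(reports)
}

#' Run propagation queries and write a published-style results table
#'
#' @param network A calibrated or fitted `bn_fit`.
#' @param queries Query tibble ([intervention_queries()] or
#'   [read_queries_yaml()]).
#' @param config A [run_config()].
#' @return Invisibly, the `bn_propagation` results tibble; also written as
#'   `propagation.json` and a formatted `propagation.txt`.
#' @export
pipeline_propagate <- function(network, queries, config) {
  t0 <- as.numeric(Sys.time())
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  res <- propagate_all(network, queries,
                       min_accepted = config$propagation_draws,
                       seed = config$seed)
  jsonlite::write_json(list(seed = config$seed, config_hash = config$hash,
                            results = as.data.frame(res)),
                       file.path(config$output_dir, "propagation.json"),
                       auto_unbox = TRUE, digits = NA)
  txt <- utils::capture.output(print(res))
  writeLines(txt, file.path(config$output_dir, "propagation.txt"))
  stage_log("propagate", t0)
  invisible(res)
}
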