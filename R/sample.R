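#' Ancestral sampling of a synthetic cohort
#'
#' Draws `n` complete subject records from a fitted (or calibrated
#' ground-truth) network by sampling each node in topological order from its
#' local distribution given already-sampled parents. Each node consumes its
#' own RNG substream derived from `seed` and the node's name, so cohorts are
#' bit-reproducible and adding a variable to a network does not perturb the
#' draws of the others.
#'
#' @param network A `bn_fit`.
#' @param n Number of rows.
#' @param seed Integer seed.
#' @return A tibble with one column per node, in canonical node order;
#'   binary columns are 0/1 integers. Attribute `"provenance"` records the
#'   seed, `n` and variant when known.
#' @export
sample_cohort <- function(network, n, seed) {
  stopifnot(inherits(network, "bn_fit"), n >= 1)
  order <- topo_sort(network$graph)
  cols <- list()
  for (node in order) {
    cpd <- network$locals[[node]]
    set.seed(substream_seed(seed, paste0("sample:", node)))
    lp <- rep(cpd$intercept, n)
    for (p in cpd$parents) lp <- lp + cpd$coefficients[[p]] * cols[[p]]
    cols[[node]] <- switch(
      cpd$form,
      linear_gaussian = {
        x <- lp + stats::rnorm(n, 0, cpd$residual_sd)
        cfg <- attr(network, "config")
        if (node == "BMI" && !is.null(cfg) && isTRUE(cfg$truncate_bmi_at_25)) {
          low <- x < 25
          while (any(low)) {
            x[low] <- lp[low] + stats::rnorm(sum(low), 0, cpd$residual_sd)
            low <- x < 25
          }
        }
        x
      },
      lognormal_root = stats::rlnorm(n, cpd$intercept, cpd$residual_sd),
      logistic = stats::rbinom(n, 1, stats::plogis(lp)))
  }
  out <- tibble::as_tibble(cols)[network$graph$nodes]
  cfg <- attr(network, "config")
  attr(out, "provenance") <- list(
    variant = if (!is.null(cfg)) cfg$variant else NA_character_,
    seed = seed, n = n, generator = "behavnet ancestral sampler")
  out
}

#' Check a cohort's marginals against its ground-truth targets
#'
#' For each variable, computes the z-score of the deviation of the empirical
#' mean (or prevalence) from the configured target, using the target SD (or
#' binomial SD) over `sqrt(n)` as the reference scale, and flags any
#' variable with `|z| > 4`.
#'
#' @param cohort A sampled cohort tibble.
#' @param config The [ground_truth_config()] it should match.
#' @return A tibble with columns `node`, `kind`, `target`, `observed`, `z`,
#'   `flag`, ordered as in the schema.
#' @export
validate_marginals <- function(cohort, config) {
  stopifnot(nrow(cohort) > 0)
  n <- nrow(cohort)
  purrr::pmap_dfr(config$target_marginals, function(...) {
    row <- tibble::tibble(...)
    mom <- target_moments(row)
    obs <- mean(cohort[[row$node]])
    z <- (obs - mom$mean) / (mom$sd / sqrt(n))
    tibble::tibble(node = row$node, kind = row$dist, target = mom$mean,
                   observed = obs, z = z, flag = abs(z) > 4)
  })
}

#' Write / read a cohort CSV with a provenance sidecar
#'
#' The CSV column order is the canonical schema order; binary variables are
#' stored as 0/1 integers; log-transformed biomarkers are stored already
#' transformed under their `log*` column names so they can never be
#' double-transformed. A YAML sidecar (`<path>.prov.yaml`) records the
#' variant, seed, n and generator.
#'
#' @param cohort Cohort tibble from [sample_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  prov <- attr(cohort, "provenance")
  if (!is.null(prov)) {
    yaml::write_yaml(prov, paste0(path, ".prov.yaml"))
  }
  invisible(path)
}

#' @rdname write_cohort
#' @param schema Optional schema to validate columns against; mismatches
#'   raise an error listing missing and extra columns.
#' @export
read_cohort <- function(path, schema = NULL) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    missing <- setdiff(schema$name, names(dat))
    extra <- setdiff(names(dat), schema$name)
    if (length(missing) || length(extra)) {
      bn_abort(paste0(
        "cohort columns do not match the schema.",
        if (length(missing)) paste0(" Missing: ",
                                    paste(missing, collapse = ", "), "."),
        if (length(extra)) paste0(" Extra: ",
                                  paste(extra, collapse = ", "), ".")),
        class = "behavnet_schema_error")
    }
    dat <- dat[schema$name]
  }
  bad <- names(dat)[!vapply(dat, is.numeric, logical(1))]
  if (length(bad)) {
    for (col in bad) {
      v <- suppressWarnings(as.numeric(dat[[col]]))
      row <- which(is.na(v) & !is.na(dat[[col]]))[1]
      if (!is.na(row)) {
        bn_abort(paste0("non-numeric value in column '", col, "', row ", row,
                        ": '", dat[[col]][row], "'"),
                 class = "behavnet_parse_error")
      }
      dat[[col]] <- v
    }
  }
  dat
}
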