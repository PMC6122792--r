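#' Evidence predicates for logic-sampling queries
#'
#' Three predicate types describe the conditioning events of an
#' intervention-prediction query:
#' * `evidence_interval(var, lo, hi)` — a half-open interval `[lo, hi)` on a
#'   continuous variable (use `-Inf`/`Inf` for one-sided events);
#' * `evidence_category(var, value)` — an exact 0/1 value on a binary
#'   variable;
#' * `evidence_quantile(var, above, below)` — a tail of the variable's
#'   *marginal* distribution, e.g. `above = 0.75` for "above Q3" or
#'   `below = 0.25` for "below Q1"; the quantile is resolved against an
#'   unconditioned sampled population at propagation time.
#'
#' @param var Variable name.
#' @param lo,hi Interval bounds, `lo < hi`.
#' @param value 0 or 1.
#' @param above,below Quantile probabilities in (0, 1); give exactly one.
#' @return An object of class `bn_evidence`.
#' @export
evidence_interval <- function(var, lo, hi) {
  stopifnot(is.character(var), lo < hi)
  structure(list(var = var, type = "interval", lo = lo, hi = hi),
            class = "bn_evidence")
}

#' @rdname evidence_interval
#' @export
evidence_category <- function(var, value) {
  stopifnot(value %in% c(0, 1))
  structure(list(var = var, type = "category", value = value),
            class = "bn_evidence")
}

#' @rdname evidence_interval
#' @export
evidence_quantile <- function(var, above = NULL, below = NULL) {
  if (is.null(above) == is.null(below)) {
    bn_abort("give exactly one of `above` or `below`")
  }
  q <- above %||% below
  stopifnot(q > 0, q < 1)
  structure(list(var = var, type = "quantile",
                 side = if (is.null(above)) "below" else "above", q = q),
            class = "bn_evidence")
}

#' @export
print.bn_evidence <- function(x, ...) {
  cat(format_evidence(list(x)), "\n")
  invisible(x)
}

format_evidence <- function(evs) {
  paste(vapply(evs, function(e) {
    switch(e$type,
           interval = paste0(e$var, " in [", format(e$lo, digits = 4), ", ",
                             format(e$hi, digits = 4), ")"),
           category = paste0(e$var, " = ", e$value),
           quantile = paste0(e$var, if (e$side == "above") " > Q" else " < Q",
                             format(100 * e$q)))
  }, character(1)), collapse = " & ")
}

# resolve quantile predicates into intervals against a reference sample
resolve_evidence <- function(evs, ref) {
  lapply(evs, function(e) {
    if (e$type != "quantile") return(e)
    q <- stats::quantile(ref[[e$var]], e$q, names = FALSE)
    if (e$side == "above") evidence_interval(e$var, q, Inf)
    else evidence_interval(e$var, -Inf, q)
  })
}

accept_rows <- function(draws, evs) {
  ok <- rep(TRUE, nrow(draws))
  for (e in evs) {
    x <- draws[[e$var]]
    ok <- ok & switch(e$type,
                      interval = x >= e$lo & x < e$hi,
                      category = x == e$value)
  }
  ok
}

#' Predict an intervention contrast by logic sampling
#'
#' Logic sampling: forward (ancestral) sampling of the full joint with
#' rejection against evidence. The network is sampled in batches; draws
#' satisfying condition A and condition B are accumulated separately until
#' both reach `min_accepted` (or `max_batches` is exhausted, in which case
#' the result is flagged low-precision). The reported contrast is the
#' difference of the conditional outcome means, `mean_B - mean_A`. Quantile
#' predicates are resolved once against an unconditioned reference sample
#' drawn from the same network.
#'
#' This is observational conditioning (what logic sampling estimates), not a
#' do-calculus intervention: evidence on a variable also updates the
#' posterior of its non-descendants.
#'
#' @param network A `bn_fit`.
#' @param outcome Outcome variable name (must not appear in the evidence).
#' @param condition_a,condition_b Lists of [evidence_interval()] /
#'   [evidence_category()] / [evidence_quantile()] predicates.
#' @param min_accepted Minimum accepted draws per condition (default 1e5).
#' @param batch_size Draws per sampling batch.
#' @param max_batches Cap on batches before flagging low precision.
#' @param seed Integer seed.
#' @param label Optional query label.
#' @return A one-row tibble of class `bn_propagation`: outcome, condition
#'   descriptions, conditional means/SDs, `delta`, accepted counts, and a
#'   `low_precision` flag.
#' @export
propagate <- function(network, outcome, condition_a, condition_b,
                      min_accepted = 1e5, batch_size = 250000,
                      max_batches = 60, seed = 1, label = NULL) {
  stopifnot(inherits(network, "bn_fit"))
  if (inherits(condition_a, "bn_evidence")) condition_a <- list(condition_a)
  if (inherits(condition_b, "bn_evidence")) condition_b <- list(condition_b)
  vars <- c(vapply(condition_a, `[[`, "", "var"),
            vapply(condition_b, `[[`, "", "var"))
  check_node(network$graph, c(outcome, vars))
  if (outcome %in% vars) {
    bn_abort("degenerate query: outcome appears among the evidence variables")
  }
  ref <- sample_cohort(network, max(100000, min_accepted),
                       substream_seed(seed, "marginal"))
  ca <- resolve_evidence(condition_a, ref)
  cb <- resolve_evidence(condition_b, ref)
  acc_a <- numeric(0)
  acc_b <- numeric(0)
  for (b in seq_len(max_batches)) {
    if (length(acc_a) >= min_accepted && length(acc_b) >= min_accepted) break
    draws <- sample_cohort(network, batch_size,
                           substream_seed(seed, paste0("batch:", b)))
    if (length(acc_a) < min_accepted) {
      acc_a <- c(acc_a, draws[[outcome]][accept_rows(draws, ca)])
    }
    if (length(acc_b) < min_accepted) {
      acc_b <- c(acc_b, draws[[outcome]][accept_rows(draws, cb)])
    }
  }
  if (!length(acc_a) || !length(acc_b)) {
    bn_abort(paste0("no draws satisfied ",
                    if (!length(acc_a)) "condition A" else "condition B",
                    " after ", max_batches, " batches; ",
                    "consider wider predicates"),
             class = "behavnet_rejection_error")
  }
  low <- length(acc_a) < min_accepted || length(acc_b) < min_accepted
  if (low) {
    warning("low precision: accepted draws below the requested minimum")
  }
  out <- tibble::tibble(
    label = label %||% paste0(format_evidence(condition_a), " vs ",
                              format_evidence(condition_b)),
    outcome = outcome,
    condition_a = format_evidence(ca),
    condition_b = format_evidence(cb),
    mean_a = mean(acc_a), sd_a = stats::sd(acc_a),
    mean_b = mean(acc_b), sd_b = stats::sd(acc_b),
    delta = mean(acc_b) - mean(acc_a),
    accepted_a = length(acc_a), accepted_b = length(acc_b),
    low_precision = low)
  structure(out, class = c("bn_propagation", class(out)))
}

#' Run a table of propagation queries
#'
#' @param network A `bn_fit`.
#' @param queries A query tibble as returned by [intervention_queries()] or
#'   [read_queries_yaml()]: columns `label`, `outcome`, `condition_a`,
#'   `condition_b` (list columns of evidence lists).
#' @param ... Passed on to [propagate()].
#' @return A `bn_propagation` tibble, one row per query.
#' @export
propagate_all <- function(network, queries, ...) {
  out <- purrr::pmap_dfr(queries, function(label, outcome, condition_a,
                                           condition_b) {
    propagate(network, outcome, condition_a, condition_b,
              label = label, ...)
  })
  structure(out, class = c("bn_propagation", class(out)))
}

#' Published intervention-contrast presets
#'
#' The nine outcome contrasts reported for the survivor cohort: conditioning
#' total physical activity below 270 vs at or above 380 counts/min/day for
#' BMI; the obese vs non-obese BMI categories (threshold 30 kg/m^2) for
#' log-insulin, log-CRP, and both quality-of-life scores; the sleep
#' impairment interquartile contrast (above Q3 vs below Q1 of its marginal)
#' for both quality-of-life scores; and the joint sleep + BMI change for
#' both quality-of-life scores (joint conditioning). Condition A is the
#' less favorable state, so improvements appear as positive `delta` for
#' quality of life and negative for biomarkers and BMI.
#'
#' @param variant Cohort variant; the activity query is only available for
#'   `"total_pa"`.
#' @return Query tibble for [propagate_all()].
#' @export
intervention_queries <- function(variant = "total_pa") {
  q <- function(label, outcome, a, b) {
    tibble::tibble(label = label, outcome = outcome,
                   condition_a = list(a), condition_b = list(b))
  }
  obese <- list(evidence_interval("BMI", 30, Inf))
  lean <- list(evidence_interval("BMI", -Inf, 30))
  s2hi <- list(evidence_quantile("Sleep2", above = 0.75))
  s2lo <- list(evidence_quantile("Sleep2", below = 0.25))
  rows <- dplyr::bind_rows(
    if (variant == "total_pa")
      q("PA < 270 to >= 380", "BMI",
        list(evidence_interval("PA", -Inf, 270)),
        list(evidence_interval("PA", 380, Inf))),
    q("BMI >= 30 to < 30", "loginsulin", obese, lean),
    q("BMI >= 30 to < 30", "logcrp", obese, lean),
    q("BMI >= 30 to < 30", "QOLp", obese, lean),
    q("BMI >= 30 to < 30", "QOLm", obese, lean),
    q("Sleep2 > Q3 to < Q1", "QOLp", s2hi, s2lo),
    q("Sleep2 > Q3 to < Q1", "QOLm", s2hi, s2lo),
    q("Sleep2 > Q3 & BMI >= 30 to Sleep2 < Q1 & BMI < 30", "QOLp",
      c(s2hi, obese), c(s2lo, lean)),
    q("Sleep2 > Q3 & BMI >= 30 to Sleep2 < Q1 & BMI < 30", "QOLm",
      c(s2hi, obese), c(s2lo, lean))
  )
  rows
}

#' Read a propagation query specification from YAML
#'
#' The YAML format is a list of queries, each with `label`, `outcome`, and
#' `condition_a` / `condition_b` lists whose entries have a `variable`, a
#' `type` (`interval`, `category`, `quantile`), and the matching fields
#' (`lo`/`hi`, `value`, or `side`/`q`). The shipped preset
#' `system.file("extdata", "intervention_queries.yaml", package =
#' "behavnet")` encodes [intervention_queries()].
#'
#' @param path YAML file path.
#' @return Query tibble for [propagate_all()].
#' @export
read_queries_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  parse_ev <- function(e) {
    switch(e$type,
           interval = evidence_interval(e$variable,
                                        lo = e$lo %||% -Inf,
                                        hi = e$hi %||% Inf),
           category = evidence_category(e$variable, e$value),
           quantile = if (e$side == "above")
             evidence_quantile(e$variable, above = e$q)
           else evidence_quantile(e$variable, below = e$q),
           bn_abort(paste0("invalid predicate type: ", e$type)))
  }
  purrr::map_dfr(spec, function(qq) {
    tibble::tibble(label = qq$label, outcome = qq$outcome,
                   condition_a = list(lapply(qq$condition_a, parse_ev)),
                   condition_b = list(lapply(qq$condition_b, parse_ev)))
  })
}

#' @export
print.bn_propagation <- function(x, ...) {
  cat("<propagation results: ", nrow(x), " quer",
      if (nrow(x) == 1) "y" else "ies", ">\n", sep = "")
  df <- data.frame(
    Outcome = x$outcome,
    Change = x$label,
    `A: mean (SD)` = sprintf("%.2f (%.2f)", x$mean_a, x$sd_a),
    `B: mean (SD)` = sprintf("%.2f (%.2f)", x$mean_b, x$sd_b),
    Delta = sprintf("%+.2f", x$delta),
    check.names = FALSE)
  print(df, row.names = FALSE, right = FALSE)
  invisible(x)
}
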