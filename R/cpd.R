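#' Local conditional distributions
#'
#' Each node of a fitted network carries one local model. Continuous nodes
#' use a linear-Gaussian form: `child = intercept + sum(beta * parent) + e`,
#' `e ~ Normal(0, residual_sd)`; a binary parent enters as a 0/1 additive
#' shift. Binary nodes use a logistic form with log-odds-ratio coefficients
#' and require all parents to be binary (the conditional-Gaussian
#' restriction). Parentless continuous nodes may instead use a log-normal
#' marginal (`lognormal_root`), used for right-skewed, strictly positive
#' measures such as monthly alcohol intake.
#'
#' @param child Child node name.
#' @param parents Character vector of parent names (order fixed).
#' @param intercept Numeric intercept (log-odds for logistic; meanlog for
#'   lognormal_root).
#' @param coefficients Named numeric vector of per-parent coefficients.
#' @param residual_sd Positive residual standard deviation (linear_gaussian),
#'   or sdlog (lognormal_root).
#' @param coefficient_se Optional named numeric vector of standard errors.
#' @return An object of class `bn_cpd`.
#' @export
cpd_linear <- function(child, parents = character(0), intercept,
                       coefficients = stats::setNames(numeric(0), character(0)),
                       residual_sd, coefficient_se = NULL) {
  new_cpd(child, parents, "linear_gaussian", intercept, coefficients,
          residual_sd, coefficient_se)
}

#' @rdname cpd_linear
#' @export
cpd_logistic <- function(child, parents = character(0), intercept,
                         coefficients = stats::setNames(numeric(0), character(0)),
                         coefficient_se = NULL) {
  new_cpd(child, parents, "logistic", intercept, coefficients, NULL,
          coefficient_se)
}

#' @rdname cpd_linear
#' @export
cpd_lognormal <- function(child, intercept, residual_sd) {
  new_cpd(child, character(0), "lognormal_root", intercept,
          stats::setNames(numeric(0), character(0)), residual_sd, NULL)
}

new_cpd <- function(child, parents, form, intercept, coefficients,
                    residual_sd, coefficient_se) {
  stopifnot(is.character(child), length(child) == 1,
            is.numeric(intercept), length(intercept) == 1)
  parents <- as.character(parents)
  if (length(parents) && !setequal(names(coefficients), parents)) {
    bn_abort(paste0("coefficients must be named by the parents of ", child))
  }
  coefficients <- coefficients[parents]  # fixed order
  if (form %in% c("linear_gaussian", "lognormal_root")) {
    stopifnot(is.numeric(residual_sd), length(residual_sd) == 1)
    if (residual_sd <= 0) bn_abort(paste0("residual_sd must be > 0 for ", child))
  } else {
    residual_sd <- NULL
  }
  structure(list(child = child, parents = parents, form = form,
                 intercept = unname(intercept),
                 coefficients = coefficients,
                 residual_sd = residual_sd,
                 coefficient_se = coefficient_se),
            class = "bn_cpd")
}

#' @export
print.bn_cpd <- function(x, ...) {
  rhs <- if (length(x$parents)) paste(x$parents, collapse = ", ") else "(none)"
  cat("<bn_cpd ", x$form, "> ", x$child, " | ", rhs, "\n", sep = "")
  cat("  intercept: ", format(x$intercept, digits = 4), "\n", sep = "")
  if (length(x$coefficients)) {
    cat("  coefficients: ",
        paste(names(x$coefficients), format(x$coefficients, digits = 4),
              sep = "=", collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$residual_sd)) {
    cat("  residual_sd: ", format(x$residual_sd, digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' Fitted network: a DAG plus one local distribution per node
#'
#' @param graph A `bn_dag`.
#' @param locals Named list of `bn_cpd`, one per node; each local's parents
#'   must equal the node's parents in `graph`.
#' @param n Sample size the parameters were fitted on (or the pilot size for
#'   calibrated ground-truth networks).
#' @return An object of class `bn_fit`.
#' @export
bn_fit <- function(graph, locals, n) {
  stopifnot(inherits(graph, "bn_dag"), is.list(locals))
  if (!setequal(names(locals), graph$nodes)) {
    bn_abort("locals must contain exactly one distribution per node")
  }
  for (node in graph$nodes) {
    cpd <- locals[[node]]
    stopifnot(inherits(cpd, "bn_cpd"), cpd$child == node)
    if (!setequal(cpd$parents, parents(graph, node))) {
      bn_abort(paste0("local model parents for ", node,
                      " do not match the graph"))
    }
  }
  structure(list(graph = graph, locals = locals[graph$nodes], n = n),
            class = "bn_fit")
}

#' @export
print.bn_fit <- function(x, ...) {
  cat("<bn_fit: ", length(x$graph$nodes), " nodes, ",
      nrow(x$graph$edges), " edges, n = ", x$n, ">\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted network into a coefficient tibble
#'
#' One row per (child, parent) edge with the estimated coefficient, its
#' standard error when available, and the local model form; matches the
#' layout of a published parameter-estimate table.
#'
#' @param x A `bn_fit`.
#' @param ... Unused.
#' @return A tibble with columns `child`, `parent`, `estimate`, `se`, `form`.
#' @method tidy bn_fit
#' @export
tidy.bn_fit <- function(x, ...) {
  rows <- purrr::map_dfr(x$locals, function(cpd) {
    if (!length(cpd$parents)) return(NULL)
    tibble::tibble(
      child = cpd$child, parent = cpd$parents,
      estimate = unname(cpd$coefficients[cpd$parents]),
      se = if (!is.null(cpd$coefficient_se))
        unname(cpd$coefficient_se[cpd$parents]) else NA_real_,
      form = cpd$form)
  })
  if (!nrow(rows)) {
    return(tibble::tibble(child = character(), parent = character(),
                          estimate = numeric(), se = numeric(),
                          form = character()))
  }
  dplyr::arrange(rows, .data$child, .data$parent)
}

#' @rdname tidy.bn_fit
#' @return For `glance`: a one-row tibble with node, edge and parameter
#'   counts and the fitting sample size.
#' @method glance bn_fit
#' @export
glance.bn_fit <- function(x, ...) {
  tibble::tibble(
    nodes = length(x$graph$nodes),
    edges = nrow(x$graph$edges),
    parameters = sum(vapply(x$locals, cpd_n_params, numeric(1))),
    n = x$n)
}

# parameter count used in BIC: slopes + intercept (+ variance for gaussian)
cpd_n_params <- function(cpd) {
  switch(cpd$form,
         linear_gaussian = length(cpd$parents) + 2,
         lognormal_root = 2,
         logistic = length(cpd$parents) + 1)
}

#' Joint log-likelihood of data under a fitted network
#'
#' Sums, over rows and nodes, the log density of each variable under its
#' local model: Gaussian density for linear-Gaussian children, log-normal
#' density for log-normal roots, and a Bernoulli likelihood with logistic
#' mean for binary children. This is the log of the factorized joint
#' `prod_i P(X_i | parents(X_i))` evaluated at the stored parameters.
#'
#' @param network A `bn_fit`.
#' @param data Data frame covering every node, no missing values.
#' @return A single number.
#' @export
log_likelihood <- function(network, data) {
  stopifnot(inherits(network, "bn_fit"))
  missing <- setdiff(network$graph$nodes, names(data))
  if (length(missing)) {
    bn_abort(paste0("data is missing column(s): ",
                    paste(missing, collapse = ", ")))
  }
  dat <- data[network$graph$nodes]
  if (any(!vapply(dat, is.numeric, logical(1)))) {
    bn_abort("all modeled columns must be numeric")
  }
  if (any(vapply(dat, function(x) any(!is.finite(x)), logical(1)))) {
    bn_abort("data contains missing or non-finite values")
  }
  total <- 0
  for (cpd in network$locals) {
    y <- dat[[cpd$child]]
    lp <- rep(cpd$intercept, length(y))
    for (p in cpd$parents) lp <- lp + cpd$coefficients[[p]] * dat[[p]]
    total <- total + switch(
      cpd$form,
      linear_gaussian = sum(stats::dnorm(y, lp, cpd$residual_sd, log = TRUE)),
      lognormal_root = sum(stats::dlnorm(y, cpd$intercept, cpd$residual_sd,
                                         log = TRUE)),
      logistic = {
        pr <- stats::plogis(lp)
        sum(y * log(pr) + (1 - y) * log1p(-pr))
      })
  }
  total
}
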