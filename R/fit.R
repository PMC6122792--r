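#' Fit local conditional distributions of a fixed DAG
#'
#' For each continuous node, ordinary least squares of the node on its
#' parents (reported residual SD uses the unbiased `n - p` denominator; BIC
#' scoring elsewhere uses the ML `n` denominator). For each binary node,
#' unpenalized maximum-likelihood logistic regression (IRLS to convergence
#' tolerance 1e-10); coefficients are log-odds ratios. Standard errors come
#' from the usual OLS / observed-information covariance estimates.
#'
#' @param graph A `bn_dag`.
#' @param data Complete numeric data frame covering all nodes.
#' @param ridge Optional ridge penalty for degenerate logistic fits
#'   (default 0 = unpenalized ML; the calibrated cohorts never separate).
#' @return A `bn_fit` with per-parent `coefficient_se` populated.
#' @export
fit_network <- function(graph, data, ridge = 0) {
  missing <- setdiff(graph$nodes, names(data))
  if (length(missing)) {
    bn_abort(paste0("data is missing column(s): ",
                    paste(missing, collapse = ", ")))
  }
  dat <- data[graph$nodes]
  if (any(vapply(dat, function(x) any(!is.finite(x)), logical(1)))) {
    bn_abort("data contains missing or non-finite values")
  }
  is_bin <- infer_binary(dat)
  n <- nrow(dat)
  locals <- list()
  for (node in graph$nodes) {
    pa <- parents(graph, node)
    y <- dat[[node]]
    if (is_bin[[node]]) {
      if (length(pa) && any(!is_bin[pa])) {
        bn_abort(paste0("binary node ", node,
                        " has continuous parent(s) (CG violation)"))
      }
      locals[[node]] <- fit_logistic_node(node, pa, y, dat, ridge)
    } else {
      locals[[node]] <- fit_linear_node(node, pa, y, dat, n)
    }
  }
  bn_fit(graph, locals, n)
}

fit_linear_node <- function(node, pa, y, dat, n) {
  X <- if (length(pa)) {
    cbind(`(Intercept)` = rep(1, n), as.matrix(dat[pa]))
  } else {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bn_abort(paste0("singular design for ", node, " with parents {",
                    paste(pa, collapse = ", "), "}"),
             class = "behavnet_singular_error")
  }
  coef <- qr.coef(qr_x, y)
  res <- y - X %*% coef
  p <- ncol(X)
  rss <- sum(res^2)
  sigma <- max(sqrt(rss / (n - p)), 1e-6)
  XtX_inv <- chol2inv(qr.R(qr_x))
  se <- sigma * sqrt(diag(XtX_inv))
  names(se) <- colnames(X)
  cpd_linear(node, pa, intercept = coef[[1]],
             coefficients = stats::setNames(coef[-1], pa),
             residual_sd = sigma,
             coefficient_se = stats::setNames(se[-1], pa))
}

fit_logistic_node <- function(node, pa, y, dat, ridge = 0) {
  if (!length(pa)) {
    p <- mean(y)
    return(cpd_logistic(node, intercept = stats::qlogis(p)))
  }
  X <- as.matrix(dat[pa])
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, X), y, family = stats::binomial(),
                   control = list(epsilon = 1e-10, maxit = 200)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        bn_abort(paste0("perfect separation fitting logistic node ", node),
                 class = "behavnet_separation_error")
      }
      invokeRestart("muffleWarning")
    })
  if (any(abs(fit$coefficients) > 15)) {
    if (ridge > 0) {
      return(fit_logistic_ridge(node, pa, y, X, ridge))
    }
    bn_abort(paste0("perfect separation fitting logistic node ", node),
             class = "behavnet_separation_error")
  }
  # observed-information covariance
  eta <- as.vector(cbind(1, X) %*% fit$coefficients)
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  info <- crossprod(cbind(1, X) * sqrt(w))
  se <- sqrt(diag(solve(info)))
  cpd_logistic(node, pa, intercept = fit$coefficients[[1]],
               coefficients = stats::setNames(fit$coefficients[-1], pa),
               coefficient_se = stats::setNames(se[-1], pa))
}

# ridge fallback for degenerate user data; not used on calibrated cohorts
fit_logistic_ridge <- function(node, pa, y, X, ridge) {
  Z <- cbind(1, X)
  beta <- rep(0, ncol(Z))
  for (i in 1:200) {
    eta <- as.vector(Z %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    H <- crossprod(Z * sqrt(w)) + diag(ridge, ncol(Z))
    g <- crossprod(Z, y - mu) - ridge * beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  se <- sqrt(diag(solve(H)))
  cpd_logistic(node, pa, intercept = beta[[1]],
               coefficients = stats::setNames(beta[-1], pa),
               coefficient_se = stats::setNames(se[-1], pa))
}

#' Coefficient table in published layout
#'
#' Merges a fitted network's coefficients with bootstrap arc/direction
#' strengths into the layout of a parameter-estimates table: one row per
#' (child, parent) edge, sorted by child then parent.
#'
#' @param network A `bn_fit`.
#' @param strengths Optional [arc_strengths()] table; edges absent from it
#'   get `NA` strength with a warning.
#' @return A tibble of class `bn_coefficient_table` with columns `child`,
#'   `parent`, `strength`, `direction`, `estimate`, `se`.
#' @export
coefficient_report <- function(network, strengths = NULL) {
  coefs <- tidy(network)
  if (!nrow(coefs)) {
    out <- tibble::tibble(child = character(), parent = character(),
                          strength = numeric(), direction = numeric(),
                          estimate = numeric(), se = numeric())
    return(structure(out, class = c("bn_coefficient_table", class(out))))
  }
  if (is.null(strengths)) {
    coefs$strength <- NA_real_
    coefs$direction <- NA_real_
  } else {
    idx <- match(paste(coefs$parent, coefs$child),
                 paste(strengths$from, strengths$to))
    if (anyNA(idx)) {
      warning("edge(s) missing from the strength table: ",
              paste(coefs$parent[is.na(idx)], "->", coefs$child[is.na(idx)],
                    collapse = ", "))
    }
    coefs$strength <- strengths$strength[idx]
    coefs$direction <- strengths$direction[idx]
  }
  out <- dplyr::arrange(
    coefs[c("child", "parent", "strength", "direction", "estimate", "se")],
    .data$child, .data$parent)
  structure(out, class = c("bn_coefficient_table", class(out)))
}

#' @export
print.bn_coefficient_table <- function(x, ...) {
  if (!nrow(x)) {
    cat("<empty coefficient table>\n")
    return(invisible(x))
  }
  txt <- data.frame(
    Child = x$child, Parent = x$parent,
    Strength = ifelse(is.na(x$strength), "", sprintf("%.2f", x$strength)),
    Direction = ifelse(is.na(x$direction), "", sprintf("%.2f", x$direction)),
    `Coefficient (SE)` = sprintf("%.3f (%.3f)", x$estimate, x$se),
    check.names = FALSE)
  print(txt, row.names = FALSE, right = FALSE)
  invisible(x)
}
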