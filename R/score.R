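# Decomposable network score: per-node BIC contributions on the rescaled
# convention bic = logLik - 0.5 * k * log(n), higher is better.

# variance floor for the Gaussian ML fit, so constant columns score finitely
SIGMA2_FLOOR <- 1e-8

# Maximized Gaussian log-likelihood of y ~ 1 + X (ML variance RSS/n).
# Returns NA for a singular design.
gauss_ml_loglik <- function(y, X, n) {
  Z <- if (is.null(X)) matrix(1, n, 1) else cbind(rep(1, n), X)
  fit <- stats::.lm.fit(Z, y)
  if (fit$rank < ncol(Z)) return(NA_real_)
  rss <- sum(fit$residuals^2)
  sigma2 <- max(rss / n, SIGMA2_FLOOR)
  -n / 2 * log(2 * pi * sigma2) - rss / (2 * sigma2)
}

# Maximized Bernoulli log-likelihood of binary y on binary X via logistic
# regression, aggregated over the (at most 2^k) parent patterns for speed.
logistic_ml_loglik <- function(y, X, n) {
  if (is.null(X) || ncol(X) == 0) {
    s <- sum(y); f <- n - s
    ll <- 0
    if (s > 0 && f > 0) {
      p <- s / n
      ll <- s * log(p) + f * log(1 - p)
    }
    return(ll)
  }
  pat <- as.vector(X %*% 2^(seq_len(ncol(X)) - 1))
  s <- rowsum(y, pat)
  tot <- rowsum(rep(1, n), pat)
  ux <- X[!duplicated(pat), , drop = FALSE]
  ux <- ux[order(unique(pat)), , drop = FALSE]
  Z <- cbind(1, ux)
  if (qr(Z)$rank < ncol(Z)) return(NA_real_)
  prop <- as.vector(s / tot)
  fit <- suppressWarnings(stats::glm.fit(
    Z, prop, weights = as.vector(tot),
    family = stats::binomial(),
    control = list(epsilon = 1e-10, maxit = 100)))
  p <- fit$fitted.values
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(s * log(p) + (tot - s) * log(1 - p))
}

# fast internal scorer over a numeric data matrix
# p (parameter count): gaussian |pa|+2, logistic |pa|+1
score_node_raw <- function(X, j, pa_idx, is_bin, n, log_n) {
  y <- X[, j]
  if (is_bin[j]) {
    if (length(pa_idx) && any(!is_bin[pa_idx])) return(NA_real_)
    ll <- logistic_ml_loglik(y, if (length(pa_idx))
      X[, pa_idx, drop = FALSE] else NULL, n)
    k <- length(pa_idx) + 1
  } else {
    ll <- gauss_ml_loglik(y, if (length(pa_idx))
      X[, pa_idx, drop = FALSE] else NULL, n)
    k <- length(pa_idx) + 2
  }
  if (is.na(ll)) return(NA_real_)
  ll - 0.5 * k * log_n
}

# memoising wrapper: per-child cache keyed by the parent-set bitmask
# (node counts here are far below the 2^52 mask limit)
make_scorer <- function(X, is_bin) {
  n <- nrow(X)
  log_n <- log(n)
  pow2 <- 2^(seq_len(ncol(X)) - 1)
  caches <- lapply(seq_len(ncol(X)),
                   function(i) new.env(parent = emptyenv(), hash = TRUE))
  function(j, pa_idx) {
    key <- as.character(sum(pow2[pa_idx]))
    env <- caches[[j]]
    hit <- env[[key]]
    if (!is.null(hit)) return(hit)
    val <- score_node_raw(X, j, pa_idx, is_bin, n, log_n)
    env[[key]] <- val
    val
  }
}

# infer which columns are binary 0/1 (constant columns are treated as
# degenerate continuous variables and fall back to the variance floor)
infer_binary <- function(data) {
  vapply(data, function(x) all(x %in% c(0, 1)) && length(unique(x)) == 2,
         logical(1))
}

#' Local BIC score of one node given a candidate parent set
#'
#' The network score is decomposable: the total BIC is the sum over nodes of
#' `logLik(child | parents) - 0.5 * p * log(n)`, where the local
#' log-likelihood is the maximized Gaussian log-likelihood of the OLS fit
#' for a continuous child (`p = |parents| + 2`: intercept, slopes, residual
#' variance) or the maximized Bernoulli log-likelihood of the logistic fit
#' for a binary child (`p = |parents| + 1`). Higher scores indicate better
#' fit.
#'
#' @param child Child column name.
#' @param parents Character vector of parent column names.
#' @param data Data frame of complete numeric data.
#' @return A one-row tibble with columns `child`, `parents` (list column)
#'   and `value`.
#' @export
local_score <- function(child, parents, data) {
  stopifnot(child %in% names(data), all(parents %in% names(data)))
  n <- nrow(data)
  if (n <= length(parents) + 2) {
    bn_abort("need n > |parents| + 2 observations")
  }
  is_bin <- infer_binary(data)
  names(is_bin) <- names(data)
  if (is_bin[[child]] && length(parents) && any(!is_bin[parents])) {
    bn_abort(paste0("binary child ", child,
                    " may only have binary parents (CG restriction)"))
  }
  X <- as.matrix(data)
  j <- match(child, colnames(X))
  pa_idx <- match(parents, colnames(X))
  val <- score_node_raw(X, j, pa_idx, unname(is_bin[colnames(X)]), n, log(n))
  if (is.na(val)) {
    bn_abort(paste0("singular design for ", child, " with parents {",
                    paste(parents, collapse = ", "), "}"),
             class = "behavnet_singular_error")
  }
  tibble::tibble(child = child, parents = list(parents), value = val)
}

#' Total network BIC as a sum of local scores
#'
#' @param graph A `bn_dag` whose nodes are columns of `data`.
#' @param data Data frame of complete numeric data.
#' @return A single number.
#' @export
network_score <- function(graph, data) {
  dat <- data[graph$nodes]
  X <- as.matrix(dat)
  is_bin <- unname(infer_binary(dat))
  n <- nrow(X); log_n <- log(n)
  pa <- adj_parents(graph)
  sum(vapply(seq_along(graph$nodes), function(j) {
    pa_idx <- match(pa[[graph$nodes[j]]], graph$nodes)
    score_node_raw(X, j, pa_idx, is_bin, n, log_n)
  }, numeric(1)))
}
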