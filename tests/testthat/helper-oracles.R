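# Independent oracles and small fixtures used across the test suite.
# These deliberately use naive algorithms (path enumeration, exhaustive
# search, grid integration) so they stay independent of the package's
# implementations.

# ---- random graphs ---------------------------------------------------------

random_dag <- function(n_nodes, p_edge = 0.3) {
  nodes <- LETTERS[seq_len(n_nodes)]
  ord <- sample(nodes)
  from <- character(0); to <- character(0)
  for (i in seq_len(n_nodes - 1)) {
    for (j in seq((i + 1), n_nodes)) {
      if (stats::runif(1) < p_edge) {
        from <- c(from, ord[i]); to <- c(to, ord[j])
      }
    }
  }
  bn_dag(nodes, tibble::tibble(from = from, to = to))
}

# ---- d-separation by exhaustive path enumeration ---------------------------

# all simple undirected paths between a and b in the skeleton
enumerate_paths <- function(graph, a, b) {
  nbrs <- function(v) {
    unique(c(graph$edges$to[graph$edges$from == v],
             graph$edges$from[graph$edges$to == v]))
  }
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == b) {
      paths[[length(paths) + 1]] <<- path
      return()
    }
    for (w in setdiff(nbrs(v), path)) walk(c(path, w))
  }
  walk(a)
  paths
}

has_edge <- function(graph, u, v) {
  any(graph$edges$from == u & graph$edges$to == v)
}

# blocking rules applied literally along one path
path_blocked <- function(graph, path, cond) {
  if (length(path) == 2) return(FALSE)
  for (k in 2:(length(path) - 1)) {
    prev <- path[k - 1]; mid <- path[k]; nxt <- path[k + 1]
    collider <- has_edge(graph, prev, mid) && has_edge(graph, nxt, mid)
    if (collider) {
      desc <- c(mid, descendants_oracle(graph, mid))
      if (!any(desc %in% cond)) return(TRUE)
    } else {
      if (mid %in% cond) return(TRUE)
    }
  }
  FALSE
}

descendants_oracle <- function(graph, node) {
  out <- character(0)
  frontier <- graph$edges$to[graph$edges$from == node]
  while (length(frontier)) {
    new <- setdiff(frontier, out)
    out <- c(out, new)
    frontier <- graph$edges$to[graph$edges$from %in% new]
  }
  out
}

d_separated_oracle <- function(graph, A, B, cond) {
  for (a in A) {
    for (b in B) {
      for (p in enumerate_paths(graph, a, b)) {
        if (!path_blocked(graph, p, cond)) return(FALSE)
      }
    }
  }
  TRUE
}

# ---- exhaustive DAG search over small variable sets ------------------------

# all DAGs on the given nodes as lists of parent-set assignments
all_dags <- function(nodes) {
  nb <- length(nodes)
  pairs <- expand.grid(from = seq_len(nb), to = seq_len(nb))
  pairs <- pairs[pairs$from != pairs$to, ]
  out <- list()
  for (mask in 0:(2^nrow(pairs) - 1)) {
    sel <- bitwAnd(mask, 2^(seq_len(nrow(pairs)) - 1)) > 0
    ed <- pairs[sel, , drop = FALSE]
    pa <- rep(list(integer(0)), nb)
    for (i in seq_len(nrow(ed))) pa[[ed$to[i]]] <- c(pa[[ed$to[i]]], ed$from[i])
    if (is_acyclic_pa(pa, nb)) out[[length(out) + 1]] <- pa
  }
  out
}

is_acyclic_pa <- function(pa, nb) {
  indeg <- lengths(pa)
  done <- logical(nb)
  for (step in seq_len(nb)) {
    free <- which(!done & indeg == 0)
    if (!length(free)) return(FALSE)
    v <- free[1]
    done[v] <- TRUE
    for (w in seq_len(nb)) if (v %in% pa[[w]]) indeg[w] <- indeg[w] - 1
  }
  TRUE
}

# direct (non-package) Gaussian BIC of child on parents, for the oracle
oracle_gauss_score <- function(y, X, n) {
  df <- data.frame(y = y)
  if (!is.null(X) && ncol(X)) df <- cbind(df, as.data.frame(X))
  fit <- stats::lm(y ~ ., data = df)
  s2 <- mean(stats::residuals(fit)^2)
  ll <- sum(stats::dnorm(y, stats::fitted(fit), sqrt(s2), log = TRUE))
  ll - 0.5 * (length(stats::coef(fit)) + 1) * log(n)
}

# best score over all DAGs by exhaustive enumeration (continuous data only)
exhaustive_best_score <- function(data, dags) {
  X <- as.matrix(data)
  n <- nrow(X)
  nb <- ncol(X)
  cache <- list()
  local_sc <- function(j, pa) {
    key <- paste(j, paste(sort(pa), collapse = ","), sep = "|")
    if (is.null(cache[[key]])) {
      cache[[key]] <<- oracle_gauss_score(
        X[, j], if (length(pa)) X[, pa, drop = FALSE] else NULL, n)
    }
    cache[[key]]
  }
  best <- -Inf
  for (pa in dags) {
    sc <- sum(vapply(seq_len(nb), function(j) local_sc(j, pa[[j]]),
                     numeric(1)))
    if (sc > best) best <- sc
  }
  best
}

# ---- threshold selection by grid integration -------------------------------

# Exact L1 distance via the closed form: F(x) <= p0 left of t and >= p0
# right of t, and the integral of an empirical CDF over [0, t) is
# mean(pmax(0, t - s)). Derivation independent of the package's
# segment-walk implementation.
threshold_oracle <- function(strengths) {
  I01 <- mean(1 - strengths)
  cand <- sort(unique(strengths))
  dist <- vapply(cand, function(t) {
    p0 <- mean(strengths < t)
    I0t <- mean(pmax(0, t - strengths))
    (p0 * t - I0t) + (I01 - I0t) - p0 * (1 - t)
  }, numeric(1))
  best <- min(dist)
  max(cand[dist <= best + 1e-12])  # ties toward the larger candidate
}

# ---- small generative fixtures ---------------------------------------------

# data from A -> B (slope, residual sd 1), plus optional independent noise
chain_data <- function(n, slope = 5, seed = 1) {
  set.seed(seed)
  A <- stats::rnorm(n)
  B <- slope * A + stats::rnorm(n)
  tibble::tibble(A = A, B = B)
}

fig_graph <- function(variant = "total_pa") {
  ground_truth_config(variant)$structure
}

cached_truth <- local({
  memo <- list()
  function(variant = "total_pa") {
    if (is.null(memo[[variant]])) {
      memo[[variant]] <<- calibrate_network(ground_truth_config(variant))
    }
    memo[[variant]]
  }
})
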