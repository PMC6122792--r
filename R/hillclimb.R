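#' Greedy hill-climbing structure search maximizing network BIC
#'
#' Starting from the empty graph, repeatedly applies the best
#' strictly-improving single-edge move (add, delete, or reverse) that keeps
#' the graph acyclic and blacklist-compliant, until no move improves the
#' score by more than `tol`. The conditional-Gaussian restriction (no
#' continuous parent of a binary node) is always enforced in addition to the
#' supplied blacklist. With `restarts > 0`, the search is repeated from
#' random admissible DAGs and the best-scoring local optimum is returned;
#' the procedure is deterministic given `seed`.
#'
#' Ties between equal-scoring moves are broken lexicographically by
#' (child, parent) name so results are reproducible.
#'
#' @param data Data frame of complete numeric data (binary columns coded
#'   0/1).
#' @param blacklist Optional tibble of forbidden `from`/`to` pairs, e.g.
#'   from [default_blacklist()].
#' @param seed Integer seed (used only for random restarts).
#' @param restarts Number of random restarts (default 0).
#' @param tol Minimum score improvement for a move to be accepted.
#' @return A `bn_dag`; attribute `"score"` holds its network BIC.
#' @export
hill_climb <- function(data, blacklist = NULL, seed = 1, restarts = 0,
                       tol = 1e-6) {
  nodes <- names(data)
  X <- as.matrix(data)
  is_bin <- unname(infer_binary(data))
  nb <- length(nodes)
  black <- blacklist_matrix(blacklist, nodes)
  # CG restriction: continuous -> binary always forbidden
  black[!is_bin, is_bin] <- TRUE
  diag(black) <- TRUE
  scorer <- make_scorer(X, is_bin)

  run <- function(start_pa) {
    climb_from(start_pa, scorer, black, nb, nodes, tol)
  }

  best <- run(rep(list(integer(0)), nb))
  if (restarts > 0) {
    for (r in seq_len(restarts)) {
      set.seed(substream_seed(seed, paste0("restart:", r)))
      best_r <- run(random_start(nb, black))
      if (best_r$score > best$score + tol) best <- best_r
    }
  }
  edges <- pa_to_edges(best$pa, nodes)
  g <- bn_dag(nodes, edges)
  attr(g, "score") <- best$score
  g
}

# random admissible DAG: random topological order, sparse random edges
random_start <- function(nb, black) {
  ord <- sample.int(nb)
  pa <- rep(list(integer(0)), nb)
  p_edge <- min(0.5, 2 / max(1, nb - 1))
  for (i in seq_len(nb)) {
    for (j in seq_len(nb)) {
      u <- ord[i]; v <- ord[j]
      if (i < j && !black[u, v] && stats::runif(1) < p_edge) {
        pa[[v]] <- c(pa[[v]], u)
      }
    }
  }
  pa
}

pa_to_edges <- function(pa, nodes) {
  from <- integer(0); to <- integer(0)
  for (v in seq_along(pa)) {
    from <- c(from, pa[[v]])
    to <- c(to, rep(v, length(pa[[v]])))
  }
  tibble::tibble(from = nodes[from], to = nodes[to])
}

# core greedy loop over integer parent sets
climb_from <- function(pa, scorer, black, nb, nodes, tol) {
  sc <- vapply(seq_len(nb), function(v) scorer(v, pa[[v]]), numeric(1))
  if (any(is.na(sc))) {  # singular random start: fall back to empty graph
    pa <- rep(list(integer(0)), nb)
    sc <- vapply(seq_len(nb), function(v) scorer(v, pa[[v]]), numeric(1))
  }
  repeat {
    reach <- reachability(pa, nb)  # reach[u, v]: path u ~> v exists
    best_delta <- tol
    best <- NULL
    consider <- function(delta, child, parent, what, self) {
      if (is.na(delta)) return()
      if (delta > best_delta + 1e-9 ||
          (delta > best_delta - 1e-9 && !is.null(best) &&
           lex_before(nodes[child], nodes[parent],
                      nodes[best$child], nodes[best$parent]))) {
        best <<- list(child = child, parent = parent, what = what,
                      delta = delta, extra = self)
        best_delta <<- max(best_delta, delta)
      }
    }
    for (v in seq_len(nb)) {
      cur <- pa[[v]]
      for (u in seq_len(nb)) {
        if (u == v) next
        if (u %in% cur) {
          # delete u -> v
          d <- scorer(v, setdiff(cur, u)) - sc[v]
          consider(d, v, u, "delete", NULL)
          # reverse to v -> u
          if (!black[v, u]) {
            # acyclic iff no path u ~> v that avoids the direct edge
            if (!path_avoiding(pa, nb, u, v)) {
              d2 <- scorer(u, c(pa[[u]], v)) - sc[u]
              if (!is.na(d2)) consider(d + d2, v, u, "reverse", d2)
            }
          }
        } else if (!black[u, v] && !reach[v, u]) {
          d <- scorer(v, c(cur, u)) - sc[v]
          consider(d, v, u, "add", NULL)
        }
      }
    }
    if (is.null(best)) break
    v <- best$child; u <- best$parent
    if (best$what == "add") {
      pa[[v]] <- c(pa[[v]], u)
      sc[v] <- scorer(v, pa[[v]])
    } else if (best$what == "delete") {
      pa[[v]] <- setdiff(pa[[v]], u)
      sc[v] <- scorer(v, pa[[v]])
    } else {
      pa[[v]] <- setdiff(pa[[v]], u)
      pa[[u]] <- c(pa[[u]], v)
      sc[v] <- scorer(v, pa[[v]])
      sc[u] <- scorer(u, pa[[u]])
    }
  }
  list(pa = pa, score = sum(sc))
}

lex_before <- function(c1, p1, c2, p2) {
  c1 < c2 || (c1 == c2 && p1 < p2)
}

# boolean descendant matrix from parent-set representation
reachability <- function(pa, nb) {
  ch <- rep(list(integer(0)), nb)
  for (v in seq_len(nb)) for (u in pa[[v]]) ch[[u]] <- c(ch[[u]], v)
  reach <- matrix(FALSE, nb, nb)
  for (s in seq_len(nb)) {
    stack <- ch[[s]]
    while (length(stack)) {
      x <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (!reach[s, x]) {
        reach[s, x] <- TRUE
        stack <- c(stack, ch[[x]])
      }
    }
  }
  reach
}

# is there a directed path u ~> v not using the edge u -> v itself?
path_avoiding <- function(pa, nb, u, v) {
  ch <- rep(list(integer(0)), nb)
  for (w in seq_len(nb)) for (p in pa[[w]]) ch[[p]] <- c(ch[[p]], w)
  seen <- logical(nb)
  stack <- setdiff(ch[[u]], v)  # drop the direct edge
  while (length(stack)) {
    x <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (x == v) return(TRUE)
    if (!seen[x]) {
      seen[x] <- TRUE
      stack <- c(stack, ch[[x]])
    }
  }
  FALSE
}
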