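#' Learn network structures on bootstrap resamples
#'
#' Draws `B` nonparametric bootstrap resamples (rows with replacement, full
#' `n`) and runs [hill_climb()] on each. Replicate `r` uses an RNG
#' substream derived from `(seed, r)`, so the set of structures is
#' deterministic given `seed` and independent of `B` for the shared
#' replicates.
#'
#' @param data Cohort data frame.
#' @param B Number of bootstrap replicates (study default 500).
#' @param blacklist Forbidden edge tibble, e.g. [default_blacklist()].
#' @param seed Integer seed.
#' @param restarts Random restarts per replicate (default 0).
#' @param resample_fn Optional `function(n, r)` returning row indices for
#'   replicate `r`; defaults to bootstrap resampling. Supplying
#'   `function(n, r) seq_len(n)` reproduces the original-data fit.
#' @param progress_every Emit a progress message every this many replicates
#'   (`0` to disable).
#' @return A list of `B` `bn_dag` objects.
#' @export
bootstrap_structures <- function(data, B = 500, blacklist = NULL, seed = 1,
                                 restarts = 0, resample_fn = NULL,
                                 progress_every = 0) {
  stopifnot(B >= 1)
  n <- nrow(data)
  out <- vector("list", B)
  for (r in seq_len(B)) {
    sub <- substream_seed(seed, paste0("boot:", r))
    set.seed(sub)
    idx <- if (is.null(resample_fn)) sample.int(n, n, replace = TRUE)
    else resample_fn(n, r)
    out[[r]] <- hill_climb(data[idx, , drop = FALSE], blacklist = blacklist,
                           seed = sub, restarts = restarts)
    if (progress_every > 0 && r %% progress_every == 0) {
      message("bootstrap replicate ", r, "/", B)
    }
  }
  out
}

#' Arc and direction strengths across a set of learned structures
#'
#' For every ordered node pair, `strength` is the fraction of structures
#' containing the edge in either orientation (orientation-blind occurrence),
#' and `direction` is, among the structures containing the edge, the
#' fraction oriented `from -> to` (0 when the edge never occurs). For pairs
#' with positive strength, `direction(a,b) + direction(b,a) = 1`.
#'
#' @param graphs Nonempty list of `bn_dag` with identical node sets.
#' @return A tibble of class `bn_arc_strength` with columns `from`, `to`,
#'   `strength`, `direction`; attribute `"replicates"` records the count.
#' @export
arc_strengths <- function(graphs) {
  stopifnot(length(graphs) >= 1)
  nodes <- graphs[[1]]$nodes
  for (g in graphs) {
    if (!setequal(g$nodes, nodes)) {
      bn_abort("graphs have inconsistent node sets")
    }
  }
  B <- length(graphs)
  nb <- length(nodes)
  D <- matrix(0, nb, nb, dimnames = list(nodes, nodes))
  for (g in graphs) {
    if (nrow(g$edges)) {
      D[cbind(g$edges$from, g$edges$to)] <-
        D[cbind(g$edges$from, g$edges$to)] + 1
    }
  }
  U <- D + t(D)
  pairs <- tidyr::expand_grid(from = nodes, to = nodes)
  pairs <- dplyr::filter(pairs, .data$from != .data$to)
  u <- U[cbind(pairs$from, pairs$to)]
  d <- D[cbind(pairs$from, pairs$to)]
  out <- dplyr::mutate(pairs, strength = u / B,
                       direction = ifelse(u > 0, d / u, 0))
  structure(out, class = c("bn_arc_strength", class(out)), replicates = B)
}

#' L1-optimal significance threshold for arc strengths
#'
#' The averaged network keeps arcs whose strength exceeds a data-driven
#' threshold. Candidate thresholds are the distinct observed strengths; for
#' each candidate `t`, the empirical CDF of the strengths is compared with
#' the idealized two-point CDF of a perfectly separated strength
#' distribution placing mass `F(t-)` at 0 and `1 - F(t-)` at 1, and the
#' candidate minimizing the L1 distance between the two CDFs is chosen
#' (ties broken toward the larger threshold).
#'
#' @param strengths Numeric vector of arc strengths in `[0, 1]`.
#' @return The selected threshold (a single number).
#' @export
significance_threshold <- function(strengths) {
  if (!length(strengths)) bn_abort("empty strength vector")
  stopifnot(all(strengths >= 0 & strengths <= 1))
  cand <- sort(unique(strengths))
  best_t <- cand[1]
  best_d <- Inf
  for (t in cand) {
    p0 <- mean(strengths < t)
    d <- cdf_l1_distance(strengths, p0)
    # ties (up to floating-point noise) break toward the larger threshold
    if (d <= best_d + 1e-12) { best_d <- min(best_d, d); best_t <- t }
  }
  best_t
}

# integral over [0,1) of |F_emp(x) - p0|  (both CDFs equal 1 at x = 1)
cdf_l1_distance <- function(strengths, p0) {
  v <- sort(unique(c(0, strengths, 1)))
  cdf <- stats::ecdf(strengths)
  heights <- cdf(v[-length(v)])  # F on [v_i, v_{i+1})
  widths <- diff(v)
  sum(widths * abs(heights - p0))
}

#' Averaged (consensus) network from bootstrap structures
#'
#' Keeps every undirected edge whose arc strength is at least the
#' significance threshold (estimated by [significance_threshold()] from the
#' unordered-pair strengths unless overridden), orients each retained edge
#' by its majority direction, breaks exact 50/50 direction ties by the
#' orientation that keeps the graph acyclic (then lexicographically), and
#' finally guarantees acyclicity by dropping the weakest edge of any
#' residual cycle (recorded in `dropped`, with a message).
#'
#' @param graphs List of bootstrap `bn_dag` structures.
#' @param threshold_override Optional fixed threshold in place of the
#'   estimated one.
#' @return An object of class `bn_averaged`: list with `graph`, `threshold`,
#'   `strengths` (full [arc_strengths()] table), `replicates`, `dropped`.
#' @export
averaged_network <- function(graphs, threshold_override = NULL) {
  strengths <- arc_strengths(graphs)
  nodes <- graphs[[1]]$nodes
  # one row per unordered pair
  upper <- dplyr::filter(strengths,
                         match(.data$from, nodes) < match(.data$to, nodes))
  threshold <- threshold_override %||%
    significance_threshold(upper$strength)
  keep <- dplyr::filter(upper, .data$strength >= threshold,
                        .data$strength > 0)
  edges <- tibble::tibble(from = character(), to = character(),
                          strength = numeric())
  if (nrow(keep)) {
    oriented <- purrr::pmap_dfr(keep, function(from, to, strength, direction) {
      a <- from; b <- to
      if (direction < 0.5) { a <- to; b <- from }
      tibble::tibble(from = a, to = b, strength = strength,
                     tie = direction == 0.5)
    })
    # place non-ties first, then resolve ties with acyclicity preference
    final <- oriented[!oriented$tie, c("from", "to", "strength")]
    for (i in which(oriented$tie)) {
      a <- oriented$from[i]; b <- oriented$to[i]; s <- oriented$strength[i]
      lex <- sort(c(a, b))
      first <- tibble::tibble(from = lex[1], to = lex[2], strength = s)
      alt <- tibble::tibble(from = lex[2], to = lex[1], strength = s)
      trial <- try_dag(nodes, dplyr::bind_rows(final, first))
      final <- if (!is.null(trial)) dplyr::bind_rows(final, first)
      else dplyr::bind_rows(final, alt)
    }
    edges <- final
  }
  dropped <- tibble::tibble(from = character(), to = character(),
                            strength = numeric())
  repeat {
    g <- try_dag(nodes, edges)
    if (!is.null(g)) break
    cyc <- find_cycle_edges(nodes, edges)
    if (!nrow(cyc)) bn_abort("internal error: unresolvable cycle state")
    w <- cyc[which.min(cyc$strength), ]
    message("averaged network: dropping cycle edge ", w$from, " -> ", w$to,
            " (strength ", format(w$strength, digits = 3), ")")
    dropped <- dplyr::bind_rows(dropped, w)
    edges <- dplyr::anti_join(edges, w[c("from", "to")],
                              by = c("from", "to"))
  }
  structure(list(graph = g, threshold = threshold, strengths = strengths,
                 replicates = attr(strengths, "replicates"),
                 dropped = dropped),
            class = "bn_averaged")
}

try_dag <- function(nodes, edges) {
  g <- list(nodes = nodes, edges = edges)
  if (is.null(topo_sort(g))) NULL else bn_dag(nodes, edges[c("from", "to")])
}

# edges lying on some directed cycle (strongly connected component > 1)
find_cycle_edges <- function(nodes, edges) {
  ig <- igraph::graph_from_data_frame(as.data.frame(edges[c("from", "to")]),
                                      directed = TRUE,
                                      vertices = data.frame(name = nodes))
  comp <- igraph::components(ig, mode = "strong")
  memb <- comp$membership[nodes]
  on_cycle <- memb[edges$from] == memb[edges$to] &
    comp$csize[memb[edges$from]] > 1
  edges[on_cycle, ]
}

#' @export
print.bn_averaged <- function(x, ...) {
  cat("<averaged network: ", nrow(x$graph$edges), " arcs at threshold ",
      format(x$threshold, digits = 3), " over ", x$replicates,
      " replicates>\n", sep = "")
  print(x$graph)
  invisible(x)
}

#' Tidy an averaged network into its retained-arc table
#' @param x A `bn_averaged`.
#' @param ... Unused.
#' @return Tibble with `from`, `to`, `strength`, `direction` for retained
#'   arcs, sorted by descending strength.
#' @method tidy bn_averaged
#' @export
tidy.bn_averaged <- function(x, ...) {
  dplyr::arrange(
    dplyr::inner_join(x$graph$edges, x$strengths, by = c("from", "to")),
    dplyr::desc(.data$strength), .data$from, .data$to)
}

#' @rdname tidy.bn_averaged
#' @method glance bn_averaged
#' @export
glance.bn_averaged <- function(x, ...) {
  tibble::tibble(arcs = nrow(x$graph$edges), threshold = x$threshold,
                 replicates = x$replicates, dropped = nrow(x$dropped))
}
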