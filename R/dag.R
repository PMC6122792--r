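#' Directed acyclic graph over cohort variables
#'
#' Lightweight DAG container: a character vector of node names plus an edge
#' tibble (`from`, `to`). Construction validates that every edge endpoint is
#' a known node and that the graph is acyclic (by topological sort).
#'
#' @param nodes Character vector of node names (unique).
#' @param edges A data frame with columns `from`, `to`; may have zero rows.
#' @return An object of class `bn_dag`.
#' @examples
#' g <- bn_dag(c("A", "B", "C"), data.frame(from = "A", to = "B"))
#' parents(g, "B")
#' @export
bn_dag <- function(nodes, edges = NULL) {
  stopifnot(is.character(nodes), length(nodes) > 0)
  if (anyDuplicated(nodes)) bn_abort("duplicate node names")
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble::tibble(from = character(), to = character())
  } else {
    edges <- tibble::as_tibble(edges[c("from", "to")])
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
  }
  bad <- setdiff(c(edges$from, edges$to), nodes)
  if (length(bad)) {
    bn_abort(paste0("edge endpoint(s) not in node set: ",
                    paste(unique(bad), collapse = ", ")))
  }
  if (any(edges$from == edges$to)) bn_abort("self-loops are not allowed")
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) edges <- edges[!duplicated(key), ]
  g <- structure(list(nodes = nodes, edges = edges), class = "bn_dag")
  if (is.null(topo_sort(g))) bn_abort("graph contains a directed cycle")
  g
}

#' @export
print.bn_dag <- function(x, ...) {
  cat("<bn_dag: ", length(x$nodes), " nodes, ", nrow(x$edges), " edges>\n",
      sep = "")
  if (nrow(x$edges)) {
    ch <- split(x$edges$to, factor(x$edges$from, levels = x$nodes))
    for (p in names(ch)) {
      if (length(ch[[p]])) {
        cat("  ", p, " -> ", paste(ch[[p]], collapse = ", "), "\n", sep = "")
      }
    }
  }
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @method as_tibble bn_dag
#' @export
as_tibble.bn_dag <- function(x, ...) x$edges

# adjacency list: children of each node
adj_children <- function(graph) {
  split(graph$edges$to, factor(graph$edges$from, levels = graph$nodes))
}

adj_parents <- function(graph) {
  split(graph$edges$from, factor(graph$edges$to, levels = graph$nodes))
}

#' Topological order of a DAG
#'
#' Kahn's algorithm; returns `NULL` when the edge set contains a directed
#' cycle (which [bn_dag()] treats as a construction error).
#'
#' @param graph A `bn_dag` (or a list with `nodes`/`edges` of the same shape).
#' @return Character vector of nodes in topological order, or `NULL`.
#' @export
topo_sort <- function(graph) {
  nodes <- graph$nodes
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(graph$edges$to)
  indeg[names(tab)] <- as.integer(tab)
  ch <- split(graph$edges$to, factor(graph$edges$from, levels = nodes))
  queue <- nodes[indeg == 0]
  out <- character(0)
  while (length(queue)) {
    n <- queue[[1]]; queue <- queue[-1]
    out <- c(out, n)
    for (c in ch[[n]]) {
      indeg[[c]] <- indeg[[c]] - 1L
      if (indeg[[c]] == 0L) queue <- c(queue, c)
    }
  }
  if (length(out) != length(nodes)) NULL else out
}

#' Parents / children of a node
#' @param graph A `bn_dag`.
#' @param node Node name.
#' @return Character vector.
#' @export
parents <- function(graph, node) {
  check_node(graph, node)
  graph$edges$from[graph$edges$to == node]
}

#' @rdname parents
#' @export
children <- function(graph, node) {
  check_node(graph, node)
  graph$edges$to[graph$edges$from == node]
}

check_node <- function(graph, node) {
  missing <- setdiff(node, graph$nodes)
  if (length(missing)) {
    bn_abort(paste0("unknown node(s): ", paste(missing, collapse = ", ")),
             class = "behavnet_unknown_node")
  }
  invisible(node)
}

#' Markov blanket of a node
#'
#' The parents, children, and children's other parents of `node`.
#' Conditional on its Markov blanket, a node is independent of every other
#' variable in the network, which is what makes the blanket the graphical
#' summary of a variable's direct associations.
#'
#' @param graph A `bn_dag`.
#' @param node Node name.
#' @return Character vector (possibly empty), never containing `node`.
#' @export
markov_blanket <- function(graph, node) {
  check_node(graph, node)
  ch <- children(graph, node)
  co <- unlist(lapply(ch, function(c) parents(graph, c)), use.names = FALSE)
  setdiff(unique(c(parents(graph, node), ch, co)), node)
}

#' Maximum in-degree (largest parent set) of a DAG
#' @param graph A `bn_dag`.
#' @return Integer.
#' @export
max_in_degree <- function(graph) {
  if (!nrow(graph$edges)) return(0L)
  max(tabulate(factor(graph$edges$to, levels = graph$nodes)))
}

#' Canonical factorization string of the joint distribution
#'
#' Renders the joint density implied by the DAG as a product of local terms
#' `P(child|parents)` in node order, with parentless nodes printed `P(node)`
#' and parents listed in node order.
#'
#' @param graph A `bn_dag`.
#' @return A single string, terms joined by the dot operator.
#' @export
factorization <- function(graph) {
  pa <- adj_parents(graph)
  terms <- vapply(graph$nodes, function(n) {
    p <- intersect(graph$nodes, pa[[n]])  # canonical parent order
    if (length(p)) paste0("P(", n, "|", paste(p, collapse = ","), ")")
    else paste0("P(", n, ")")
  }, character(1))
  paste(terms, collapse = "\u22c5")
}

# set of nodes from which `targets` are reachable, plus targets themselves
ancestors_of <- function(graph, targets) {
  pa <- adj_parents(graph)
  seen <- character(0)
  stack <- targets
  while (length(stack)) {
    n <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (n %in% seen) next
    seen <- c(seen, n)
    stack <- c(stack, pa[[n]])
  }
  seen
}

descendants_of <- function(graph, node) {
  ch <- adj_children(graph)
  seen <- character(0)
  stack <- ch[[node]]
  while (length(stack)) {
    n <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (n %in% seen) next
    seen <- c(seen, n)
    stack <- c(stack, ch[[n]])
  }
  seen
}

#' Test d-separation of two node sets
#'
#' `TRUE` iff every path between `setA` and `setB` is blocked given
#' `conditioning`, under standard d-separation semantics: chains and forks
#' are blocked when their middle node is conditioned on; colliders block
#' unless the collider or one of its descendants is conditioned on.
#' Implemented by the moralized-ancestral-graph reduction: restrict to the
#' ancestors of all three sets, moralize (marry co-parents, drop directions),
#' delete the conditioning nodes, and test undirected connectivity.
#'
#' @param graph A `bn_dag`.
#' @param setA,setB,conditioning Character vectors of node names; `setA`,
#'   `setB` and `conditioning` must be pairwise disjoint.
#' @return Logical scalar.
#' @export
d_separated <- function(graph, setA, setB, conditioning = character(0)) {
  check_node(graph, c(setA, setB, conditioning))
  if (length(intersect(setA, setB)) || length(intersect(setA, conditioning)) ||
      length(intersect(setB, conditioning))) {
    bn_abort("setA, setB and conditioning must be pairwise disjoint")
  }
  anc <- ancestors_of(graph, unique(c(setA, setB, conditioning)))
  sub <- graph$edges[graph$edges$from %in% anc & graph$edges$to %in% anc, ]
  # undirected adjacency of the moral graph on `anc`
  und <- rbind(cbind(sub$from, sub$to), cbind(sub$to, sub$from))
  pa <- split(sub$from, factor(sub$to, levels = anc))
  for (n in anc) {
    p <- pa[[n]]
    if (length(p) > 1) {
      comb <- utils::combn(p, 2)
      und <- rbind(und, t(comb), t(comb[2:1, , drop = FALSE]))
    }
  }
  keep <- setdiff(anc, conditioning)
  if (!length(keep)) return(TRUE)
  und <- und[und[, 1] %in% keep & und[, 2] %in% keep, , drop = FALSE]
  nbr <- split(und[, 2], factor(und[, 1], levels = keep))
  # BFS from A within the pruned moral graph
  seen <- stats::setNames(logical(length(keep)), keep)
  stack <- intersect(setA, keep)
  seen[stack] <- TRUE
  while (length(stack)) {
    n <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    for (m in nbr[[n]]) {
      if (!seen[[m]]) { seen[[m]] <- TRUE; stack <- c(stack, m) }
    }
  }
  !any(seen[intersect(setB, keep)])
}

#' Remove all edges incident to a node
#'
#' Used in network-comparison analyses to quantify a variable's contribution:
#' the isolated-node network is refitted and its BIC compared with the full
#' network's.
#'
#' @param graph A `bn_dag`.
#' @param node Node to isolate.
#' @return A new `bn_dag` with the same node set.
#' @export
isolate_node <- function(graph, node) {
  check_node(graph, node)
  keep <- graph$edges$from != node & graph$edges$to != node
  bn_dag(graph$nodes, graph$edges[keep, ])
}

#' Delete a single directed edge
#' @param graph A `bn_dag`.
#' @param from,to Edge endpoints; the edge must exist.
#' @return A new `bn_dag`.
#' @export
delete_edge <- function(graph, from, to) {
  check_node(graph, c(from, to))
  hit <- graph$edges$from == from & graph$edges$to == to
  if (!any(hit)) {
    bn_abort(paste0("edge ", from, " -> ", to, " is not in the graph"),
             class = "behavnet_unknown_edge")
  }
  bn_dag(graph$nodes, graph$edges[!hit, ])
}
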