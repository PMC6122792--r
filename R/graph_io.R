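#' Convert a bn_dag to an igraph object
#'
#' Node attributes `kind` and `tier` are attached when a schema is supplied;
#' edge attributes `strength` and `direction` are attached when an arc
#' strength table is supplied.
#'
#' @param graph A `bn_dag`.
#' @param schema Optional [cohort_schema()].
#' @param strengths Optional arc strength tibble (`from`, `to`, `strength`,
#'   `direction`).
#' @return An `igraph` directed graph.
#' @export
as_igraph <- function(graph, schema = NULL, strengths = NULL) {
  verts <- data.frame(name = graph$nodes, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    idx <- match(graph$nodes, schema$name)
    verts$kind <- schema$kind[idx]
    verts$tier <- schema$tier[idx]
  }
  ed <- as.data.frame(graph$edges)
  if (!is.null(strengths) && nrow(ed)) {
    idx <- match(paste(ed$from, ed$to), paste(strengths$from, strengths$to))
    ed$strength <- strengths$strength[idx]
    ed$direction <- strengths$direction[idx]
  }
  igraph::graph_from_data_frame(ed, directed = TRUE, vertices = verts)
}

#' Write a network as GraphML or DOT
#'
#' GraphML goes through igraph and carries node `kind`/`tier` and edge
#' `strength`/`direction` attributes; DOT is written directly with the same
#' information encoded as standard attributes (`penwidth` scaled by strength).
#'
#' @param graph A `bn_dag`.
#' @param path Output file path; format chosen by extension unless given.
#' @param format `"graphml"` or `"dot"` (default: from the file extension).
#' @inheritParams as_igraph
#' @return `path`, invisibly.
#' @export
write_network <- function(graph, path, format = NULL, schema = NULL,
                          strengths = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  if (format %in% c("gv", "dot")) {
    lines <- c("digraph network {", "  rankdir=LR;")
    for (n in graph$nodes) {
      attrs <- character(0)
      if (!is.null(schema)) {
        i <- match(n, schema$name)
        attrs <- c(attrs, paste0("kind=\"", schema$kind[i], "\""),
                   paste0("tier=\"", schema$tier[i], "\""))
      }
      lines <- c(lines, paste0("  \"", n, "\"",
                               if (length(attrs))
                                 paste0(" [", paste(attrs, collapse = ", "), "]"),
                               ";"))
    }
    if (nrow(graph$edges)) {
      for (i in seq_len(nrow(graph$edges))) {
        e <- graph$edges[i, ]
        attrs <- character(0)
        if (!is.null(strengths)) {
          j <- match(paste(e$from, e$to),
                     paste(strengths$from, strengths$to))
          if (!is.na(j)) {
            attrs <- c(attrs,
                       sprintf("strength=%.3f", strengths$strength[j]),
                       sprintf("direction=%.3f", strengths$direction[j]),
                       sprintf("penwidth=%.2f",
                               0.5 + 2.5 * strengths$strength[j]))
          }
        }
        lines <- c(lines, paste0("  \"", e$from, "\" -> \"", e$to, "\"",
                                 if (length(attrs))
                                   paste0(" [", paste(attrs, collapse = ", "), "]"),
                                 ";"))
      }
    }
    writeLines(c(lines, "}"), path)
  } else if (format == "graphml") {
    ig <- as_igraph(graph, schema = schema, strengths = strengths)
    igraph::write_graph(ig, path, format = "graphml")
  } else {
    bn_abort(paste0("unsupported network format: ", format))
  }
  invisible(path)
}

#' Read a GraphML network back as a bn_dag
#' @param path GraphML file written by [write_network()] (or any GraphML
#'   digraph with named nodes).
#' @return A `bn_dag`.
#' @export
read_network <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::vertex_attr(ig, "name")
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(ig)))
  el <- igraph::as_edgelist(ig, names = TRUE)
  bn_dag(nodes, tibble::tibble(from = el[, 1], to = el[, 2]))
}
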