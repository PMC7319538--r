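#' Write a graph in SIF format
#'
#' One line per edge, tab-separated `source relation target`. The relation
#' vocabulary is `dir` (directed; source is the cause), `undir`
#' (undirected) and `conf` (conflicted, arrow--arrow). For `undir` and
#' `conf` edges the lexicographically smaller node is written first.
#' Isolated nodes are emitted as bare node-name lines. Lines are sorted
#' lexicographically so output is deterministic.
#'
#' @param graph An [endpoint_graph()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_sif <- function(graph, path) {
  e <- graph$edges
  k <- edge_kinds(graph)
  lines <- character(0)
  if (nrow(e)) {
    src <- ifelse(k == "dir" & e$mark_a == "arrow", e$b, e$a)
    dst <- ifelse(k == "dir" & e$mark_a == "arrow", e$a, e$b)
    lines <- paste(src, k, dst, sep = "\t")
  }
  iso <- setdiff(graph$nodes, unique(c(e$a, e$b)))
  lines <- sort(c(lines, iso))
  con <- tryCatch(file(path, "w"), error = function(err)
    stop("cannot write SIF file '", path, "': ", conditionMessage(err)))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a graph from SIF format
#'
#' Inverse of [write_sif()]; accepts the `dir`/`undir`/`conf` relation
#' vocabulary and bare node-name lines for isolated nodes.
#'
#' @param path Input file path.
#' @return An [endpoint_graph()].
#' @export
read_sif <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nodes <- character(0)
  from <- to <- kind <- character(0)
  for (pp in parts) {
    if (length(pp) == 1L) {
      nodes <- c(nodes, pp)
    } else if (length(pp) == 3L) {
      if (!pp[2L] %in% c("dir", "undir", "conf"))
        stop("unknown SIF relation '", pp[2L], "'")
      from <- c(from, pp[1L]); kind <- c(kind, pp[2L]); to <- c(to, pp[3L])
    } else stop("malformed SIF line: ", paste(pp, collapse = " "))
  }
  nodes <- sort(unique(c(nodes, from, to)))
  graph_from_edges(nodes, from, to, kind)
}

#' Write a graph as a Cytoscape.js JSON elements document
#'
#' Produces the standard elements structure: a `nodes` array of objects
#' with `data.id`, and an `edges` array with `data.id`, `data.source`,
#' `data.target` and `data.interaction` in `dir`/`undir`/`conf` (same
#' vocabulary and source/target orientation as [write_sif()]). Ordering
#' is deterministic.
#'
#' @param graph An [endpoint_graph()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_cytoscape_json <- function(graph, path) {
  e <- graph$edges
  k <- edge_kinds(graph)
  nodes <- lapply(sort(graph$nodes), function(nm) list(data = list(id = nm)))
  edges <- list()
  if (nrow(e)) {
    src <- ifelse(k == "dir" & e$mark_a == "arrow", e$b, e$a)
    dst <- ifelse(k == "dir" & e$mark_a == "arrow", e$a, e$b)
    ord <- order(paste(src, k, dst))
    edges <- lapply(ord, function(i) list(data = list(
      id = paste0(src[i], " (", k[i], ") ", dst[i]),
      source = src[i], target = dst[i], interaction = k[i])))
  }
  doc <- list(elements = list(nodes = nodes, edges = edges))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  con <- tryCatch(file(path, "w"), error = function(err)
    stop("cannot write JSON file '", path, "': ", conditionMessage(err)))
  on.exit(close(con))
  writeLines(txt, con)
  invisible(path)
}

#' Read a graph from a Cytoscape.js JSON elements document
#'
#' Inverse of [write_cytoscape_json()].
#'
#' @param path Input file path.
#' @return An [endpoint_graph()].
#' @export
read_cytoscape_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  el <- doc$elements
  nodes <- vapply(el$nodes, function(x) x$data$id, character(1))
  if (length(el$edges)) {
    from <- vapply(el$edges, function(x) x$data$source, character(1))
    to <- vapply(el$edges, function(x) x$data$target, character(1))
    kind <- vapply(el$edges, function(x) x$data$interaction, character(1))
  } else from <- to <- kind <- character(0)
  graph_from_edges(sort(unique(c(nodes, from, to))), from, to, kind)
}
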