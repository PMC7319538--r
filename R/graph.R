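#' Endpoint-marked graph
#'
#' A graph whose edges carry an endpoint mark (`"tail"` or `"arrow"`) at
#' each end: tail--tail is an undirected edge, tail--arrow a directed edge
#' (arrow at the effect), and arrow--arrow a conflicted/ambiguous edge.
#' Each unordered node pair holds at most one edge and self-loops are
#' forbidden. Edges are stored canonically with `a < b` lexicographically.
#'
#' @param nodes Character vector of unique node names.
#' @param edges Optional data.frame with columns `a`, `b`, `mark_a`,
#'   `mark_b` (marks at the `a` and `b` ends respectively).
#' @return An object of class `endpoint_graph`.
#' @export
endpoint_graph <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("node names must be unique")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(a = character(), b = character(),
                        mark_a = character(), mark_b = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    stopifnot(all(c("a", "b", "mark_a", "mark_b") %in% names(edges)))
    flip <- edges$a > edges$b
    if (any(flip)) {
      tmp <- edges$a[flip]; edges$a[flip] <- edges$b[flip]; edges$b[flip] <- tmp
      tmp <- edges$mark_a[flip]; edges$mark_a[flip] <- edges$mark_b[flip]
      edges$mark_b[flip] <- tmp
    }
    if (any(edges$a == edges$b)) stop("self-loops are not allowed")
    if (!all(c(edges$a, edges$b) %in% nodes)) stop("edge endpoint not in nodes")
    if (!all(c(edges$mark_a, edges$mark_b) %in% c("tail", "arrow")))
      stop("endpoint marks must be 'tail' or 'arrow'")
    key <- paste(edges$a, edges$b)
    if (anyDuplicated(key)) stop("at most one edge per node pair")
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges), class = "endpoint_graph")
}

#' Build a graph from edge triples
#'
#' Convenience constructor: `kind` is `"undir"` (tail--tail), `"dir"`
#' (`from` is the cause, arrow at `to`) or `"conf"` (arrow--arrow).
#'
#' @param nodes Node names.
#' @param from,to Endpoint vectors.
#' @param kind Edge kind per edge, recycled.
#' @return An `endpoint_graph`.
#' @export
graph_from_edges <- function(nodes, from = character(), to = character(),
                             kind = "undir") {
  kind <- rep_len(kind, length(from))
  ma <- ifelse(kind == "conf", "arrow", "tail")
  mb <- ifelse(kind == "undir", "tail", "arrow")
  endpoint_graph(nodes, data.frame(a = from, b = to,
                                   mark_a = ma, mark_b = mb,
                                   stringsAsFactors = FALSE))
}

#' @export
print.endpoint_graph <- function(x, ...) {
  k <- edge_kinds(x)
  cat("endpoint_graph: ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges (", sum(k == "undir"), " undirected, ", sum(k == "dir"),
      " directed, ", sum(k == "conf"), " conflicted)\n", sep = "")
  invisible(x)
}

# Kind of each edge: undir / dir / conf.
edge_kinds <- function(graph) {
  e <- graph$edges
  ifelse(e$mark_a == "tail" & e$mark_b == "tail", "undir",
         ifelse(e$mark_a == "arrow" & e$mark_b == "arrow", "conf", "dir"))
}

edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Test whether two nodes are adjacent
#' @param graph An `endpoint_graph`.
#' @param a,b Node names.
#' @return Logical.
#' @export
has_edge <- function(graph, a, b) {
  edge_key(a, b) %in% edge_key(graph$edges$a, graph$edges$b)
}

#' Neighbors of a node (any edge kind)
#' @param graph An `endpoint_graph`.
#' @param node Node name.
#' @return Sorted character vector of adjacent node names.
#' @export
neighbors_of <- function(graph, node) {
  e <- graph$edges
  sort(c(e$b[e$a == node], e$a[e$b == node]))
}

# Adjacency list keyed by node name (sorted neighbor vectors).
adjacency_list <- function(graph) {
  out <- stats::setNames(vector("list", length(graph$nodes)), graph$nodes)
  for (nm in graph$nodes) out[[nm]] <- character()
  e <- graph$edges
  for (i in seq_len(nrow(e))) {
    out[[e$a[i]]] <- c(out[[e$a[i]]], e$b[i])
    out[[e$b[i]]] <- c(out[[e$b[i]]], e$a[i])
  }
  lapply(out, sort)
}

remove_edge <- function(graph, a, b) {
  keep <- edge_key(graph$edges$a, graph$edges$b) != edge_key(a, b)
  endpoint_graph(graph$nodes, graph$edges[keep, , drop = FALSE])
}

# Replace marks of the a--b edge; endpoints given in any order.
set_edge_marks <- function(graph, a, b, mark_at_a, mark_at_b) {
  e <- graph$edges
  i <- which(edge_key(e$a, e$b) == edge_key(a, b))
  if (length(i) != 1L) stop("no edge ", a, " -- ", b)
  if (e$a[i] == a) {
    e$mark_a[i] <- mark_at_a; e$mark_b[i] <- mark_at_b
  } else {
    e$mark_a[i] <- mark_at_b; e$mark_b[i] <- mark_at_a
  }
  endpoint_graph(graph$nodes, e)
}

#' Endpoint mark of an edge
#'
#' Returns the mark (`"tail"` or `"arrow"`) the a--b edge carries at the
#' `at` endpoint, or `NA` if the edge is absent.
#' @param graph An `endpoint_graph`.
#' @param a,b Edge endpoints (any order).
#' @param at The endpoint whose mark is requested.
#' @return `"tail"`, `"arrow"`, or `NA_character_`.
#' @export
mark_at <- function(graph, a, b, at) {
  e <- graph$edges
  i <- which(edge_key(e$a, e$b) == edge_key(a, b))
  if (length(i) != 1L) return(NA_character_)
  if (e$a[i] == at) e$mark_a[i] else e$mark_b[i]
}

#' Undirected skeleton of a graph
#'
#' Drops all endpoint marks, returning the same adjacency structure with
#' every edge tail--tail.
#' @param graph An `endpoint_graph`.
#' @return An `endpoint_graph` with only undirected edges.
#' @export
skeleton_of <- function(graph) {
  e <- graph$edges
  if (nrow(e)) { e$mark_a <- "tail"; e$mark_b <- "tail" }
  endpoint_graph(graph$nodes, e)
}

#' Structural equality of endpoint graphs
#'
#' Same node set (order ignored) and identical edge sets with identical
#' endpoint marks.
#' @param g1,g2 `endpoint_graph` objects.
#' @return Logical.
#' @export
graphs_equal <- function(g1, g2) {
  if (!setequal(g1$nodes, g2$nodes)) return(FALSE)
  f <- function(g) {
    e <- g$edges
    sort(paste(e$a, e$mark_a, e$mark_b, e$b))
  }
  identical(f(g1), f(g2))
}

#' Directed part of a graph as an edge list
#'
#' Returns the tail--arrow edges as a two-column matrix (cause, effect);
#' undirected and conflicted edges are excluded.
#' @param graph An `endpoint_graph`.
#' @return Character matrix with columns `from`, `to`.
#' @export
directed_edges <- function(graph) {
  e <- graph$edges
  k <- edge_kinds(graph)
  d <- e[k == "dir", , drop = FALSE]
  from <- ifelse(d$mark_a == "tail", d$a, d$b)
  to <- ifelse(d$mark_a == "tail", d$b, d$a)
  cbind(from = from, to = to)
}

#' Relabel graph nodes
#'
#' Renames every node through a named map (`old name -> new name`);
#' edges are re-canonicalized under the new names.
#' @param graph An `endpoint_graph`.
#' @param map Named character vector keyed by the current node names.
#' @return The relabeled `endpoint_graph`.
#' @export
relabel_graph <- function(graph, map) {
  e <- graph$edges
  e$a <- unname(map[e$a]); e$b <- unname(map[e$b])
  endpoint_graph(unname(map[graph$nodes]), e)
}
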