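#' PC configuration
#'
#' @param alpha P-value threshold for the conditional-independence tests
#'   (default 0.05).
#' @param max_depth Largest conditioning-set size (default `Inf`).
#' @param initial_graph Optional [endpoint_graph()] to start from
#'   (typically the MGM graph); `NULL` means the complete graph.
#' @return A `pc_config` list.
#' @export
pc_config <- function(alpha = 0.05, max_depth = Inf, initial_graph = NULL) {
  stopifnot(alpha > 0, alpha < 1, max_depth >= 0)
  structure(list(alpha = alpha, max_depth = max_depth,
                 initial_graph = initial_graph), class = "pc_config")
}

complete_graph <- function(nodes) {
  nodes <- sort(nodes)
  p <- length(nodes)
  if (p < 2L) return(endpoint_graph(nodes))
  idx <- utils::combn(p, 2L)
  graph_from_edges(nodes, nodes[idx[1L, ]], nodes[idx[2L, ]], "undir")
}

sepset_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

# Subsets of size d of a sorted vector, in lexicographic order.
subsets_of <- function(v, d) {
  if (d == 0L) return(list(character(0)))
  if (length(v) < d) return(list())
  cm <- utils::combn(v, d, simplify = FALSE)
  cm
}

#' PC-Stable skeleton search
#'
#' Order-independent edge pruning: at each depth d every node's adjacency
#' set is snapshotted before any removal, and for each remaining edge X--Y
#' conditioning subsets of size d are enumerated (lexicographically) from
#' the snapshot adjacencies of X (minus Y) and of Y (minus X). The edge
#' is removed, and the first separating subset recorded, as soon as a test
#' accepts independence at `alpha`. The loop stops when no node has d+1
#' snapshot neighbors or `max_depth` is exceeded.
#'
#' @param dataset A [mixed_dataset()].
#' @param config A [pc_config()]; its `initial_graph` (complete graph if
#'   `NULL`) must cover exactly the dataset's variables.
#' @return A list with `graph` (undirected skeleton), `sepsets` (named
#'   list keyed by node pair), and `n_tests`.
#' @export
pcs_skeleton <- function(dataset, config = pc_config()) {
  vars <- variable_names(dataset)
  graph <- config$initial_graph %||% complete_graph(vars)
  if (!all(graph$nodes %in% vars))
    stop("initial graph nodes must be dataset variables")
  graph <- skeleton_of(graph)
  sepsets <- list()
  n_tests <- 0L
  d <- 0L
  repeat {
    adj <- adjacency_list(graph)
    if (d > config$max_depth) break
    if (!any(vapply(adj, length, integer(1)) >= d + 1L)) break
    snap_edges <- graph$edges[, c("a", "b"), drop = FALSE]
    for (i in seq_len(nrow(snap_edges))) {
      xa <- snap_edges$a[i]; xb <- snap_edges$b[i]
      if (!has_edge(graph, xa, xb)) next
      cand <- c(subsets_of(setdiff(adj[[xa]], xb), d),
                subsets_of(setdiff(adj[[xb]], xa), d))
      seen <- character(0)
      for (S in cand) {
        key <- paste(S, collapse = "\r")
        if (key %in% seen) next
        seen <- c(seen, key)
        res <- suppressWarnings(ci_test(dataset, xa, xb, S,
                                        alpha = config$alpha))
        n_tests <- n_tests + 1L
        if (res$independent) {
          graph <- remove_edge(graph, xa, xb)
          sepsets[[sepset_key(xa, xb)]] <- S
          break
        }
      }
    }
    d <- d + 1L
  }
  list(graph = graph, sepsets = sepsets, n_tests = n_tests)
}

#' Orient colliders on a skeleton
#'
#' For every unshielded triple X--Z--Y (X and Y nonadjacent), orients
#' X -> Z <- Y exactly when Z is not in the recorded separating set of
#' (X, Y). When two triples propose arrowheads at both ends of the same
#' edge, that edge is marked conflicted (arrow--arrow) instead of one
#' orientation overwriting the other. A nonadjacent pair missing from the
#' sepset table is treated as separated by the empty set, with a warning.
#'
#' @param skeleton An undirected [endpoint_graph()].
#' @param sepsets Sepset table from [pcs_skeleton()].
#' @return An [endpoint_graph()] with collider orientations applied.
#' @export
orient_colliders <- function(skeleton, sepsets) {
  graph <- skeleton
  adj <- adjacency_list(graph)
  # proposals[[edge key]] = set of endpoints proposed to carry an arrowhead
  proposals <- list()
  missing_pairs <- character(0)
  for (z in sort(graph$nodes)) {
    nb <- adj[[z]]
    if (length(nb) < 2L) next
    pairs <- utils::combn(nb, 2L)
    for (k in seq_len(ncol(pairs))) {
      x <- pairs[1L, k]; y <- pairs[2L, k]
      if (has_edge(graph, x, y)) next  # shielded
      key <- sepset_key(x, y)
      S <- sepsets[[key]]
      if (is.null(S) && !key %in% names(sepsets)) {
        missing_pairs <- union(missing_pairs, paste(x, y, sep = "--"))
        S <- character(0)
      }
      if (!(z %in% S)) {
        for (e in list(c(x, z), c(y, z))) {
          ek <- sepset_key(e[1L], e[2L])
          proposals[[ek]] <- union(proposals[[ek]], z)
        }
      }
    }
  }
  if (length(missing_pairs))
    warning(length(missing_pairs), " nonadjacent pair(s) without a ",
            "recorded separating set treated as separated by the empty ",
            "set (e.g. ", missing_pairs[1L], ")")
  for (ek in names(proposals)) {
    ends <- strsplit(ek, "\r", fixed = TRUE)[[1L]]
    heads <- proposals[[ek]]
    if (length(heads) == 2L) {
      graph <- set_edge_marks(graph, ends[1L], ends[2L], "arrow", "arrow")
    } else {
      tailend <- setdiff(ends, heads)
      graph <- set_edge_marks(graph, tailend, heads, "tail", "arrow")
    }
  }
  graph
}

# Orient a--b as a -> b unless the edge is conflicted or already carries
# an opposing arrowhead (then mark conflicted).
meek_orient <- function(graph, a, b) {
  ma <- mark_at(graph, a, b, a)
  mb <- mark_at(graph, a, b, b)
  if (ma == "arrow" && mb == "arrow") return(list(graph = graph, changed = FALSE))
  if (ma == "tail" && mb == "arrow") return(list(graph = graph, changed = FALSE))
  if (ma == "arrow" && mb == "tail")  # opposing direction exists
    return(list(graph = set_edge_marks(graph, a, b, "arrow", "arrow"),
                changed = TRUE))
  list(graph = set_edge_marks(graph, a, b, "tail", "arrow"), changed = TRUE)
}

is_directed_edge <- function(graph, from, to) {
  identical(mark_at(graph, from, to, from), "tail") &&
    identical(mark_at(graph, from, to, to), "arrow")
}

is_undirected_edge <- function(graph, a, b) {
  identical(mark_at(graph, a, b, a), "tail") &&
    identical(mark_at(graph, a, b, b), "tail")
}

#' Apply Meek orientation propagation rules
#'
#' Repeats rules R1–R3 to a fixed point: R1 orients B--C as B -> C when
#' A -> B and A, C are nonadjacent (avoiding a new collider); R2 orients
#' A--C as A -> C when A -> B -> C (avoiding a directed cycle); R3 orients
#' A--B as A -> B when A--C, A--D, C -> B, D -> B and C, D are
#' nonadjacent. Conflicted (arrow--arrow) edges are never reoriented, and
#' a rule firing against an existing opposite orientation marks the edge
#' conflicted.
#'
#' @param graph An [endpoint_graph()] (typically from
#'   [orient_colliders()]).
#' @return The graph with orientations propagated.
#' @export
apply_meek_rules <- function(graph) {
  repeat {
    changed <- FALSE
    adj <- adjacency_list(graph)
    e <- graph$edges
    k <- edge_kinds(graph)
    # R1
    dd <- directed_edges(graph)
    for (i in seq_len(nrow(dd))) {
      a <- dd[i, "from"]; b <- dd[i, "to"]
      for (cc in adj[[b]]) {
        if (cc == a || has_edge(graph, a, cc)) next
        if (is_undirected_edge(graph, b, cc)) {
          out <- meek_orient(graph, b, cc)
          graph <- out$graph; changed <- changed || out$changed
        }
      }
    }
    # R2
    dd <- directed_edges(graph)
    for (i in seq_len(nrow(dd))) {
      a <- dd[i, "from"]; b <- dd[i, "to"]
      for (j in seq_len(nrow(dd))) {
        if (dd[j, "from"] != b) next
        cc <- dd[j, "to"]
        if (cc == a) next
        if (has_edge(graph, a, cc) && is_undirected_edge(graph, a, cc)) {
          out <- meek_orient(graph, a, cc)
          graph <- out$graph; changed <- changed || out$changed
        }
      }
    }
    # R3
    for (a in sort(graph$nodes)) {
      und <- Filter(function(nb) is_undirected_edge(graph, a, nb),
                    adj[[a]])
      if (length(und) < 3L) next
      for (b in und) {
        others <- setdiff(und, b)
        if (length(others) < 2L) next
        prs <- utils::combn(others, 2L)
        for (q in seq_len(ncol(prs))) {
          cc <- prs[1L, q]; dd2 <- prs[2L, q]
          if (has_edge(graph, cc, dd2)) next
          if (is_directed_edge(graph, cc, b) &&
              is_directed_edge(graph, dd2, b)) {
            out <- meek_orient(graph, a, b)
            graph <- out$graph; changed <- changed || out$changed
            break
          }
        }
      }
    }
    if (!changed) break
  }
  graph
}

#' Run MGM followed by PC-Stable
#'
#' The full causal-discovery step: fit the undirected mixed graphical
#' model (with [steps_select()] when `lambdas_or_steps` is a
#' `steps_config`, or at a fixed [lambda_triple()]), extract its graph,
#' then prune it with [pcs_skeleton()], orient colliders and propagate
#' Meek rules. Provenance (the lambda triple, alpha and test count) is
#' attached to the returned graph as attributes.
#'
#' @param dataset A [mixed_dataset()].
#' @param lambdas_or_steps A [lambda_triple()] or a [steps_config()].
#' @param config A [pc_config()]; its `initial_graph` is ignored (the
#'   MGM graph is used).
#' @return The oriented [endpoint_graph()] with attributes `lambdas`,
#'   `alpha`, `n_tests` and `undirected` (the MGM graph).
#' @export
mgm_pcstable <- function(dataset, lambdas_or_steps = lambda_triple(0.25),
                         config = pc_config()) {
  if (inherits(lambdas_or_steps, "steps_config")) {
    prof <- steps_select(dataset, config = lambdas_or_steps)
    lambdas <- prof$chosen
  } else {
    stopifnot(inherits(lambdas_or_steps, "lambda_triple"))
    lambdas <- lambdas_or_steps
  }
  fit <- fit_mgm(dataset, lambdas)
  undirected <- extract_graph(fit)
  sk <- pcs_skeleton(dataset, pc_config(alpha = config$alpha,
                                        max_depth = config$max_depth,
                                        initial_graph = undirected))
  graph <- orient_colliders(sk$graph, sk$sepsets)
  graph <- apply_meek_rules(graph)
  attr(graph, "lambdas") <- lambdas
  attr(graph, "alpha") <- config$alpha
  attr(graph, "n_tests") <- sk$n_tests
  attr(graph, "undirected") <- undirected
  graph
}
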