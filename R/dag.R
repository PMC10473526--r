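#' Directed acyclic trait graph
#'
#' Constructs a `trait_dag`: a directed acyclic graph over trait identifiers,
#' optionally annotated with per-edge arc probabilities (the bootstrap
#' frequency with which each trait-trait link is recovered).
#'
#' @param nodes character vector of trait identifiers (unique).
#' @param edges two-column object (`parent`, `child`); a data.frame, matrix or
#'   NULL for an empty graph.
#' @param arc_prob optional numeric vector in `[0, 1]`, one entry per edge.
#' @return An object of class `trait_dag` with elements `nodes`, `edges`
#'   (data.frame with columns `parent`, `child`) and `arc_prob`.
#' @examples
#' g <- trait_dag(c("a", "b", "c"), data.frame(parent = "a", child = "b"))
#' dag_descendants(g, "a")
#' @export
trait_dag <- function(nodes, edges = NULL, arc_prob = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  edges <- normalize_edges(edges)
  if (nrow(edges)) {
    bad <- setdiff(c(edges$parent, edges$child), nodes)
    if (length(bad)) stop("edge endpoints not in node set: ", paste(bad, collapse = ", "))
    if (any(edges$parent == edges$child)) stop("self-loop edge")
    if (anyDuplicated(paste(edges$parent, edges$child, sep = "\r"))) {
      stop("duplicate edges")
    }
  }
  if (!is.null(arc_prob)) {
    arc_prob <- as.numeric(arc_prob)
    if (length(arc_prob) != nrow(edges)) stop("arc_prob length must equal edge count")
    if (any(arc_prob < 0 | arc_prob > 1)) stop("arc probabilities must lie in [0, 1]")
  }
  g <- structure(list(nodes = nodes, edges = edges, arc_prob = arc_prob),
                 class = "trait_dag")
  if (is.null(topological_order(g))) stop("edge set contains a cycle")
  g
}

normalize_edges <- function(edges) {
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0L) ||
      (is.matrix(edges) && nrow(edges) == 0L)) {
    return(data.frame(parent = character(), child = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("parent", "child") %in% names(edges))) {
    names(edges)[1:2] <- c("parent", "child")
  }
  data.frame(parent = as.character(edges$parent),
             child = as.character(edges$child), stringsAsFactors = FALSE)
}

#' @export
print.trait_dag <- function(x, ...) {
  cat("trait_dag:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    lab <- paste0(x$edges$parent, " -> ", x$edges$child)
    if (!is.null(x$arc_prob)) lab <- paste0(lab, " (", format(x$arc_prob, digits = 2), ")")
    cat(paste0("  ", lab, collapse = "\n"), "\n")
  }
  invisible(x)
}

# adjacency matrix (logical, rows = parents)
dag_adjacency <- function(dag) {
  m <- length(dag$nodes)
  A <- matrix(FALSE, m, m, dimnames = list(dag$nodes, dag$nodes))
  if (nrow(dag$edges)) A[cbind(dag$edges$parent, dag$edges$child)] <- TRUE
  A
}

adjacency_to_edges <- function(A) {
  idx <- which(A, arr.ind = TRUE)
  data.frame(parent = rownames(A)[idx[, 1L]], child = colnames(A)[idx[, 2L]],
             stringsAsFactors = FALSE)
}

# Kahn topological sort on a logical adjacency matrix; NULL if cyclic.
topo_order_adjacency <- function(A) {
  m <- nrow(A)
  indeg <- colSums(A)
  order <- integer(0)
  avail <- which(indeg == 0)
  indeg[avail] <- NA_real_
  while (length(avail)) {
    v <- avail[1L]; avail <- avail[-1L]
    order <- c(order, v)
    ch <- which(A[v, ])
    for (w in ch) {
      indeg[w] <- indeg[w] - 1
      if (!is.na(indeg[w]) && indeg[w] == 0) {
        avail <- c(avail, w)
        indeg[w] <- NA_real_
      }
    }
  }
  if (length(order) < m) NULL else order
}

#' Topological node ordering of a trait DAG
#'
#' @param dag a [trait_dag()].
#' @return Character vector of node names in a parent-before-child order, or
#'   NULL if the edge set is cyclic (cannot happen for a validated object).
#' @export
topological_order <- function(dag) {
  A <- dag_adjacency(dag)
  ord <- topo_order_adjacency(A)
  if (is.null(ord)) NULL else dag$nodes[ord]
}

adjacency_is_acyclic <- function(A) !is.null(topo_order_adjacency(A))

# topological order with lexicographic tie-breaking: invariant to the order
# in which nodes were declared
canonical_topological_order <- function(dag) {
  A <- dag_adjacency(dag)
  nodes <- dag$nodes
  indeg <- colSums(A)
  out <- character(0)
  avail <- nodes[indeg == 0]
  placed <- structure(logical(length(nodes)), names = nodes)
  while (length(avail)) {
    v <- sort(avail)[1L]
    avail <- setdiff(avail, v)
    placed[v] <- TRUE
    out <- c(out, v)
    for (w in nodes[A[v, ]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L && !placed[w]) avail <- c(avail, w)
    }
  }
  out
}

#' Parents and descendants of a node
#'
#' `dag_parents()` returns the direct parents of a node; `dag_descendants()`
#' returns every node reachable by following directed links starting at the
#' node (excluding the node itself) — the set of traits whose values can
#' change when the node is experimentally modified.
#'
#' @param dag a [trait_dag()].
#' @param node a node name present in `dag`.
#' @return Character vector of node names.
#' @export
dag_descendants <- function(dag, node) {
  if (!node %in% dag$nodes) stop("unknown node: ", node)
  A <- dag_adjacency(dag)
  seen <- structure(logical(length(dag$nodes)), names = dag$nodes)
  frontier <- node
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(v) dag$nodes[A[v, ]])))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  dag$nodes[seen]
}

#' @rdname dag_descendants
#' @export
dag_parents <- function(dag, node) {
  if (!node %in% dag$nodes) stop("unknown node: ", node)
  dag$edges$parent[dag$edges$child == node]
}

#' Write / read a trait DAG as JSON, or render as DOT
#'
#' JSON carries nodes, edges and arc probabilities and round-trips exactly.
#' The DOT output is Graphviz-compatible text for network figures, with edge
#' labels showing arc probabilities when present.
#'
#' @param dag a [trait_dag()].
#' @param path output file path (for `dag_to_dot`, NULL returns the text).
#' @return `read_dag_json` returns a `trait_dag`; the writers return their
#'   path (or DOT text) invisibly.
#' @export
write_dag_json <- function(dag, path) {
  obj <- list(nodes = dag$nodes,
              edges = dag$edges,
              arc_prob = if (is.null(dag$arc_prob)) NULL else dag$arc_prob)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dag_json
#' @export
read_dag_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- if (is.null(obj$edges) || length(obj$edges) == 0L) NULL else
    as.data.frame(obj$edges, stringsAsFactors = FALSE)
  trait_dag(obj$nodes, edges, arc_prob = obj$arc_prob)
}

#' @rdname write_dag_json
#' @export
dag_to_dot <- function(dag, path = NULL) {
  esc <- function(x) gsub('"', '\\"', x, fixed = TRUE)
  lines <- c("digraph traits {", "  rankdir=TB;")
  lines <- c(lines, paste0('  "', esc(dag$nodes), '";'))
  if (nrow(dag$edges)) {
    lab <- if (!is.null(dag$arc_prob)) {
      paste0(' [label="', formatC(dag$arc_prob, digits = 2, format = "f"),
             '", penwidth=', formatC(0.5 + 2.5 * dag$arc_prob, digits = 2, format = "f"), ']')
    } else ""
    lines <- c(lines, paste0('  "', esc(dag$edges$parent), '" -> "',
                             esc(dag$edges$child), '"', lab, ";"))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}
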