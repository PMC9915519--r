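# Core directed-multigraph model. Nodes are opaque integers 1..n; optional
# character payloads (k-mer strings, oriented segment names) are attached as
# `node_names` but never used for graph semantics. Arcs are identified by
# their position in the tail/head vectors, so parallel arcs and self-loops
# are first-class.

#' Construct a directed multigraph
#'
#' Creates the graph container used by all walk and tig algorithms in this
#' package. Nodes are the integers `1..n`; arc `i` runs from `tails[i]` to
#' `heads[i]`. Parallel arcs and self-loops are allowed and preserved.
#'
#' @param n Number of nodes (non-negative integer).
#' @param tails,heads Integer vectors of equal length giving, per arc, the
#'   tail and head node. Must lie in `1..n`.
#' @param node_names Optional character vector of length `n` with unique
#'   node payloads (e.g. \eqn{(k-1)}-mers or `"seg+"`/`"seg-"` labels).
#' @param arc_labels Optional character vector, one payload per arc (e.g.
#'   the k-mer an arc represents in a de Bruijn graph).
#' @return An object of class `omni_graph` with precomputed degree tables
#'   and adjacency lists.
#' @examples
#' g <- omni_graph(3, tails = c(1, 2), heads = c(2, 3),
#'                 node_names = c("a", "b", "c"))
#' n_nodes(g); n_arcs(g)
#' @export
omni_graph <- function(n, tails = integer(), heads = integer(),
                       node_names = NULL, arc_labels = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, !is.na(n), n >= 0)
  n <- as.integer(n)
  tails <- as.integer(tails)
  heads <- as.integer(heads)
  if (length(tails) != length(heads)) {
    stop("`tails` and `heads` must have equal length")
  }
  if (length(tails) > 0L) {
    rng <- range(c(tails, heads))
    if (is.na(rng[1L]) || rng[1L] < 1L || rng[2L] > n) {
      stop("arc endpoint outside the node set 1..", n)
    }
  }
  if (!is.null(node_names)) {
    node_names <- as.character(node_names)
    if (length(node_names) != n) stop("`node_names` must have length n")
    if (anyDuplicated(node_names)) stop("`node_names` must be unique")
  }
  if (!is.null(arc_labels)) {
    arc_labels <- as.character(arc_labels)
    if (length(arc_labels) != length(tails)) {
      stop("`arc_labels` must have one entry per arc")
    }
  }
  g <- list(
    n = n,
    tails = tails,
    heads = heads,
    node_names = node_names,
    arc_labels = arc_labels,
    out_deg = tabulate(tails, nbins = n),
    in_deg = tabulate(heads, nbins = n),
    out_arcs = split(seq_along(tails), factor(tails, levels = seq_len(n))),
    in_arcs = split(seq_along(heads), factor(heads, levels = seq_len(n)))
  )
  class(g) <- "omni_graph"
  g
}

#' @export
print.omni_graph <- function(x, ...) {
  cat("omni_graph with", x$n, "nodes and", length(x$tails), "arcs\n")
  if (!is.null(x$node_names)) {
    shown <- utils::head(x$node_names, 8L)
    cat("  node payloads:", paste(shown, collapse = " "),
        if (x$n > 8L) "..." else "", "\n")
  }
  invisible(x)
}

#' Number of nodes / arcs
#'
#' Constant-time accessors for the node count \eqn{n} and arc count \eqn{m}.
#'
#' @param g An `omni_graph`.
#' @return A single integer.
#' @export
n_nodes <- function(g) {
  stopifnot(inherits(g, "omni_graph"))
  g$n
}

#' @rdname n_nodes
#' @export
n_arcs <- function(g) {
  stopifnot(inherits(g, "omni_graph"))
  length(g$tails)
}

# Resolve node references given as integers or as payload names.
resolve_node <- function(g, v) {
  if (is.character(v)) {
    if (is.null(g$node_names)) stop("graph has no node payloads to match")
    idx <- match(v, g$node_names)
    if (anyNA(idx)) stop("unknown node payload: ", v[which(is.na(idx))[1L]])
    return(idx)
  }
  idx <- as.integer(v)
  if (length(idx) == 0L || anyNA(idx) || any(idx < 1L) || any(idx > g$n)) {
    stop("unknown node: outside 1..", g$n)
  }
  idx
}

#' Node degrees and branching predicates
#'
#' `out_degree()`/`in_degree()` count arcs leaving/entering a node; a
#' self-loop counts once in each direction. `is_split()` tests for at least
#' two outgoing arcs and `is_join()` for at least two incoming arcs.
#'
#' @param g An `omni_graph`.
#' @param v Node id(s), as integers in `1..n` or payload names.
#' @return An integer (degrees) or logical (predicates) vector along `v`.
#' @examples
#' g <- omni_graph(2, tails = c(1, 1, 2), heads = c(2, 2, 2))
#' out_degree(g, 1)   # 2
#' is_split(g, 1)     # TRUE
#' is_join(g, 2)      # TRUE: two parallel arcs plus a self-loop
#' @export
out_degree <- function(g, v) {
  stopifnot(inherits(g, "omni_graph"))
  g$out_deg[resolve_node(g, v)]
}

#' @rdname out_degree
#' @export
in_degree <- function(g, v) {
  stopifnot(inherits(g, "omni_graph"))
  g$in_deg[resolve_node(g, v)]
}

#' @rdname out_degree
#' @export
is_split <- function(g, v) {
  out_degree(g, v) >= 2L
}

#' @rdname out_degree
#' @export
is_join <- function(g, v) {
  in_degree(g, v) >= 2L
}

#' Construct a walk in a graph
#'
#' A walk is a sequence of adjacent nodes \eqn{(w_1, \dots, w_\ell)}; the
#' arc sequence (length \eqn{\ell - 1}) is stored explicitly so that
#' parallel arcs are unambiguous. When `arcs` is omitted it is inferred,
#' which fails if any consecutive node pair is joined by zero or by several
#' arcs. A circular walk must satisfy \eqn{w_1 = w_\ell} and \eqn{\ell \ge 2}.
#'
#' @param g An `omni_graph`.
#' @param nodes Node sequence (ids or payload names), length \eqn{\ell \ge 1}.
#' @param arcs Optional integer vector of arc ids, length \eqn{\ell - 1}.
#' @param circular Logical flag marking a circular walk.
#' @return An object of class `omni_walk` with fields `nodes`, `arcs`,
#'   `circular`.
#' @examples
#' g <- omni_graph(3, tails = c(1, 2), heads = c(2, 3))
#' w <- omni_walk(g, c(1, 2, 3))
#' walk_length(w)
#' @export
omni_walk <- function(g, nodes, arcs = NULL, circular = FALSE) {
  stopifnot(inherits(g, "omni_graph"), length(nodes) >= 1L)
  nodes <- resolve_node(g, nodes)
  l <- length(nodes)
  if (is.null(arcs)) {
    arcs <- integer(l - 1L)
    if (l >= 2L) {
      for (p in seq_len(l - 1L)) {
        cand <- g$out_arcs[[nodes[p]]]
        cand <- cand[g$heads[cand] == nodes[p + 1L]]
        if (length(cand) == 0L) {
          stop("no arc from node ", nodes[p], " to node ", nodes[p + 1L])
        }
        if (length(cand) > 1L) {
          stop("ambiguous parallel arcs from node ", nodes[p], " to node ",
               nodes[p + 1L], "; pass `arcs` explicitly")
        }
        arcs[p] <- cand
      }
    }
  } else {
    arcs <- as.integer(arcs)
    if (length(arcs) != l - 1L) stop("`arcs` must have length ", l - 1L)
    if (l >= 2L) {
      ok <- g$tails[arcs] == nodes[-l] & g$heads[arcs] == nodes[-1L]
      if (anyNA(ok) || !all(ok)) {
        stop("stored arc sequence does not connect consecutive walk nodes")
      }
    }
  }
  if (circular && (l < 2L || nodes[1L] != nodes[l])) {
    stop("a circular walk requires w1 = w_l and l >= 2")
  }
  structure(list(nodes = nodes, arcs = arcs, circular = isTRUE(circular)),
            class = "omni_walk")
}

#' @export
print.omni_walk <- function(x, ...) {
  cat(if (x$circular) "circular walk:" else "walk:",
      paste(x$nodes, collapse = " -> "), "\n")
  invisible(x)
}

#' Walk accessors
#'
#' `walk_tail()` and `walk_head()` return \eqn{w_1} and \eqn{w_\ell};
#' `walk_length()` returns the number of nodes \eqn{\ell}.
#'
#' @param w An `omni_walk`.
#' @return A single integer.
#' @export
walk_tail <- function(w) w$nodes[1L]

#' @rdname walk_tail
#' @export
walk_head <- function(w) w$nodes[length(w$nodes)]

#' @rdname walk_tail
#' @export
walk_length <- function(w) length(w$nodes)

#' Concatenate two walks
#'
#' Joins walks `w1` and `w2` with `HEAD(w1) == TAIL(w2)` into the walk
#' consisting of `w1` followed by `w2` without its first node; the arc
#' sequences are concatenated. Associative wherever defined.
#'
#' @param w1,w2 `omni_walk` objects in the same graph.
#' @return An `omni_walk`.
#' @export
walk_concat <- function(w1, w2) {
  stopifnot(inherits(w1, "omni_walk"), inherits(w2, "omni_walk"))
  if (walk_head(w1) != walk_tail(w2)) {
    stop("cannot concatenate: HEAD(w1) != TAIL(w2)")
  }
  structure(list(nodes = c(w1$nodes, w2$nodes[-1L]),
                 arcs = c(w1$arcs, w2$arcs),
                 circular = FALSE),
            class = "omni_walk")
}

# Canonical string key for set comparisons of walks. Single-node walks have
# no arcs, so the first node disambiguates them; longer walks are uniquely
# identified by their arc sequence (arcs determine nodes).
walk_key <- function(w) {
  paste0(if (w$circular) "c:" else "", "n", w$nodes[1L], "|",
         paste(w$arcs, collapse = ","))
}

# Is `a` a contiguous subwalk of `b`? Compares arc sequences; a single-node
# walk is a subwalk iff its node occurs in b.
is_subwalk <- function(a, b) {
  la <- length(a$arcs)
  lb <- length(b$arcs)
  if (la == 0L) return(a$nodes[1L] %in% b$nodes)
  if (la > lb) return(FALSE)
  for (s in 0:(lb - la)) {
    if (all(b$arcs[s + seq_len(la)] == a$arcs)) return(TRUE)
  }
  FALSE
}

#' Map walk nodes to their payload names
#'
#' @param g An `omni_graph` with `node_names`.
#' @param w An `omni_walk` in `g`.
#' @return Character vector of node payloads along the walk.
#' @export
walk_node_names <- function(g, w) {
  stopifnot(inherits(g, "omni_graph"), inherits(w, "omni_walk"))
  if (is.null(g$node_names)) stop("graph has no node payloads")
  g$node_names[w$nodes]
}
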