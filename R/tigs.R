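# Maximal unitigs, the core characterization of maximal simple omnitigs,
# univocal extension, and the output-sensitive enumeration algorithm.
#
# A unitig is a walk whose inner nodes have in- and out-degree one; the
# maximal ones partition the arc set. A simple omnitig is a walk with a
# core: letting w_i be its first inner join (or w_l) and w_j its last inner
# split (or w_1), the core is the subwalk w_j..w_i when j < i. Maximal
# simple omnitigs are exactly the univocal extensions of maximal unitigs
# whose endpoints satisfy two local degree conditions, which is what makes
# the O(m + out) enumeration possible.

# internal: nodes traversable inside a unitig
unitig_internal <- function(g) g$in_deg == 1L & g$out_deg == 1L

#' Enumerate all maximal unitigs
#'
#' Every arc belongs to exactly one maximal unitig. Non-circular maximal
#' unitigs start and end at branching nodes (splits, joins, sources,
#' sinks); components in which every node has in- and out-degree one are
#' isolated cycles and are returned once each as a circular walk broken at
#' their smallest node id. Output order is deterministic: sorted by first
#' node id, then walk length, then first arc id.
#'
#' @param g An `omni_graph`.
#' @return A list of `omni_walk` objects (circular ones flagged via their
#'   `circular` field).
#' @examples
#' g <- omni_graph(3, tails = c(1, 2), heads = c(2, 3))
#' maximal_unitigs(g)   # single unitig 1 -> 2 -> 3
#' @export
maximal_unitigs <- function(g) {
  stopifnot(inherits(g, "omni_graph"))
  m <- n_arcs(g)
  internal <- unitig_internal(g)
  visited <- logical(m)
  out <- list()
  # path sweep: start from arcs whose tail is not internal
  start_arcs <- which(!internal[g$tails])
  for (a in start_arcs) {
    if (visited[a]) next
    nodes <- c(g$tails[a], g$heads[a])
    arcs <- a
    visited[a] <- TRUE
    v <- g$heads[a]
    while (internal[v]) {
      e <- g$out_arcs[[v]][1L]
      if (visited[e]) break  # guards closed lassos re-entering the start
      visited[e] <- TRUE
      arcs <- c(arcs, e)
      v <- g$heads[e]
      nodes <- c(nodes, v)
    }
    out[[length(out) + 1L]] <-
      structure(list(nodes = nodes, arcs = arcs, circular = FALSE),
                class = "omni_walk")
  }
  # remaining arcs lie on isolated degree-(1,1) cycles
  for (a in seq_len(m)) {
    if (visited[a]) next
    cyc_arcs <- a
    visited[a] <- TRUE
    v <- g$heads[a]
    while (v != g$tails[a]) {
      e <- g$out_arcs[[v]][1L]
      visited[e] <- TRUE
      cyc_arcs <- c(cyc_arcs, e)
      v <- g$heads[e]
    }
    cyc_nodes <- g$tails[cyc_arcs]
    rot <- which.min(cyc_nodes)  # break at smallest node id
    ord <- c(seq(rot, length(cyc_arcs)), seq_len(rot - 1L))
    cyc_arcs <- cyc_arcs[ord]
    nodes <- c(g$tails[cyc_arcs], g$tails[cyc_arcs[1L]])
    out[[length(out) + 1L]] <-
      structure(list(nodes = nodes, arcs = cyc_arcs, circular = TRUE),
                class = "omni_walk")
  }
  sort_walks(out)
}

# deterministic ordering shared by all enumerations
sort_walks <- function(walks) {
  if (length(walks) <= 1L) return(walks)
  key <- vapply(walks, function(w) {
    sprintf("%09d|%09d|%s", w$nodes[1L], length(w$nodes),
            paste(sprintf("%09d", w$arcs), collapse = ","))
  }, character(1L))
  walks[order(key)]
}

#' Core decomposition of a walk
#'
#' Let \eqn{w_i} be the first inner join of the walk (or \eqn{w_\ell} if
#' none) and \eqn{w_j} its last inner split (or \eqn{w_1} if none). The
#' core is the subwalk \eqn{w_j..w_i} when \eqn{j < i}; otherwise the walk
#' has no core. A walk with a core is a simple omnitig. Single-node walks
#' have no core.
#'
#' @param g An `omni_graph`.
#' @param w A non-circular `omni_walk` in `g`.
#' @return A list with elements `j`, `i`, `has_core` and (when present)
#'   `core`, an `omni_walk`.
#' @examples
#' g <- omni_graph(3, tails = c(1, 2), heads = c(2, 3))
#' core_decomposition(g, omni_walk(g, c(1, 2, 3)))$has_core  # TRUE
#' @export
core_decomposition <- function(g, w) {
  stopifnot(inherits(g, "omni_graph"), inherits(w, "omni_walk"))
  if (w$circular) stop("core decomposition is defined on non-circular walks")
  l <- length(w$nodes)
  if (l < 2L) {
    return(list(j = 1L, i = l, has_core = FALSE, core = NULL))
  }
  inner <- if (l >= 3L) w$nodes[2:(l - 1L)] else integer(0)
  joins <- which(g$in_deg[inner] >= 2L)
  splits <- which(g$out_deg[inner] >= 2L)
  i <- if (length(joins)) joins[1L] + 1L else l
  j <- if (length(splits)) splits[length(splits)] + 1L else 1L
  if (j < i) {
    core <- structure(list(nodes = w$nodes[j:i], arcs = w$arcs[j:(i - 1L)],
                           circular = FALSE), class = "omni_walk")
    list(j = j, i = i, has_core = TRUE, core = core)
  } else {
    list(j = j, i = i, has_core = FALSE, core = NULL)
  }
}

# is w a unitig (inner nodes all degree (1,1))?
is_unitig_walk <- function(g, w) {
  l <- length(w$nodes)
  if (l < 3L) return(TRUE)
  inner <- w$nodes[2:(l - 1L)]
  all(g$in_deg[inner] == 1L & g$out_deg[inner] == 1L)
}

#' Test whether a unitig is the core of a maximal simple omnitig
#'
#' A maximal non-circular unitig \eqn{W = (w_1..w_\ell)} is the core of a
#' maximal simple omnitig if and only if (a) the core of \eqn{W} is
#' \eqn{W} itself, (b) if \eqn{w_1} has exactly one outgoing arc then it
#' has no incoming arcs, and (c) if \eqn{w_\ell} has exactly one incoming
#' arc then it has no outgoing arcs. For unitigs with \eqn{\ell \ge 2},
#' (a) holds automatically. A single-node unitig is accepted only when (b)
#' and (c) hold and its univocal extension has length at least two and
#' itself possesses a core.
#'
#' @param g An `omni_graph`.
#' @param u A maximal non-circular unitig of `g` (an `omni_walk`).
#' @return Logical scalar.
#' @export
is_core_of_maximal <- function(g, u) {
  stopifnot(inherits(g, "omni_graph"), inherits(u, "omni_walk"))
  if (u$circular) stop("core test is defined on non-circular unitigs")
  if (!is_unitig_walk(g, u)) stop("walk is not a unitig")
  w1 <- u$nodes[1L]
  wl <- u$nodes[length(u$nodes)]
  cond_b <- g$out_deg[w1] != 1L || g$in_deg[w1] == 0L
  cond_c <- g$in_deg[wl] != 1L || g$out_deg[wl] == 0L
  if (!(cond_b && cond_c)) return(FALSE)
  if (length(u$nodes) >= 2L) return(TRUE)
  # l = 1: require the extension to be a genuine simple omnitig
  ext <- univocal_extension(g, u)
  length(ext$nodes) >= 2L && core_decomposition(g, ext)$has_core
}

#' Univocal extension of a walk
#'
#' Extends a walk forward while its head has exactly one outgoing arc and
#' backward while its tail has exactly one incoming arc. To guarantee
#' termination on cyclic degree-one regions, each direction stops before
#' appending an arc it has already added (the guard cannot trigger on
#' graphs arising from error-free genomes whose repeats have branching
#' flanks). The input walk is a subwalk of the result.
#'
#' @param g An `omni_graph`.
#' @param w An `omni_walk` in `g`.
#' @return An `omni_walk`.
#' @examples
#' g <- omni_graph(4, tails = c(1, 2, 3), heads = c(2, 3, 4))
#' univocal_extension(g, omni_walk(g, c(2, 3)))  # 1 -> 2 -> 3 -> 4
#' @export
univocal_extension <- function(g, w) {
  stopifnot(inherits(g, "omni_graph"), inherits(w, "omni_walk"))
  nodes <- w$nodes
  arcs <- w$arcs
  # forward: append the unique out-arc of the head
  fwd <- integer(0)
  v <- nodes[length(nodes)]
  while (g$out_deg[v] == 1L) {
    e <- g$out_arcs[[v]][1L]
    if (e %in% fwd) break
    fwd <- c(fwd, e)
    v <- g$heads[e]
    nodes <- c(nodes, v)
    arcs <- c(arcs, e)
  }
  # backward: prepend the unique in-arc of the tail
  bwd <- integer(0)
  v <- nodes[1L]
  while (g$in_deg[v] == 1L) {
    e <- g$in_arcs[[v]][1L]
    if (e %in% bwd) break
    bwd <- c(bwd, e)
    v <- g$tails[e]
    nodes <- c(v, nodes)
    arcs <- c(e, arcs)
  }
  structure(list(nodes = nodes, arcs = arcs, circular = FALSE),
            class = "omni_walk")
}

#' Enumerate all maximal simple omnitigs
#'
#' Iterates over the maximal unitigs, keeps those passing the core test of
#' [is_core_of_maximal()], and outputs their univocal extensions. Runs in
#' time linear in the graph size plus the total output length. Isolated
#' circular unitigs are passed through unchanged and keep their circular
#' flag; they are excluded from the core test. On doubled graphs,
#' `collapse_mirror = TRUE` keeps only the lexicographically smaller of
#' each walk / mirror-walk pair, so bidirected inputs are not reported
#' twice.
#'
#' @param g An `omni_graph`.
#' @param collapse_mirror Collapse reverse-complement walk pairs (requires
#'   a graph built by [double_graph()]).
#' @return A list of records, each a list with elements `walk`
#'   (`omni_walk`), `core` (`omni_walk` or `NULL` for circular walks) and
#'   `circular` (logical).
#' @examples
#' g <- omni_graph(3, tails = c(1, 2), heads = c(2, 3))
#' maximal_simple_omnitigs(g)[[1]]$walk
#' @export
maximal_simple_omnitigs <- function(g, collapse_mirror = FALSE) {
  stopifnot(inherits(g, "omni_graph"))
  if (collapse_mirror && is.null(g$mirror_node)) {
    stop("collapse_mirror requires a doubled graph")
  }
  units <- maximal_unitigs(g)
  recs <- list()
  seen <- character(0)
  for (u in units) {
    if (u$circular) {
      key <- walk_key(u)
      if (key %in% seen) next
      seen <- c(seen, key)
      recs[[length(recs) + 1L]] <- list(walk = u, core = NULL, circular = TRUE)
    } else {
      if (!is_core_of_maximal(g, u)) next
      w <- univocal_extension(g, u)
      key <- walk_key(w)
      if (key %in% seen) next
      seen <- c(seen, key)
      recs[[length(recs) + 1L]] <- list(walk = w, core = u, circular = FALSE)
    }
  }
  if (collapse_mirror && length(recs) > 0L) {
    keep <- logical(length(recs))
    keys <- vapply(recs, function(r) walk_key(r$walk), character(1L))
    for (idx in seq_along(recs)) {
      mk <- walk_key(mirror_walk(g, recs[[idx]]$walk))
      # keep self-mirror walks and the smaller key of each proper pair
      keep[idx] <- !(mk %in% keys) || keys[idx] <= mk
    }
    recs <- recs[keep]
  }
  ord <- order(vapply(recs, function(r) {
    w <- r$walk
    sprintf("%09d|%09d|%s", w$nodes[1L], length(w$nodes),
            paste(sprintf("%09d", w$arcs), collapse = ","))
  }, character(1L)))
  recs[ord]
}

#' Extract the walks from a simple-omnitig record list
#'
#' @param recs Result of [maximal_simple_omnitigs()].
#' @return A list of `omni_walk` objects.
#' @export
so_walks <- function(recs) lapply(recs, `[[`, "walk")
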