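# Exhaustive reference enumeration of maximal simple omnitigs, used as an
# independent oracle in tests. It never calls the maximal-unitig /
# core-test path: walks are grown arc by arc from every single-arc walk
# (every two-node walk trivially has a core), each candidate is accepted
# or rejected directly from the core definition, and maximality is decided
# by subwalk containment over the whole accepted set.

# Guard matching the univocal-extension termination rule. Relative to the
# walk's own core decomposition (j, i), the arcs of the backward phase
# together with the core (positions 1..i-1) must be duplicate-free, and so
# must the core together with the forward phase (positions j..l-1); only
# the two extension phases may share an arc (a repeat traversed once on
# each side of its core, as in the planted-repeat fixture). Walks whose
# phases wind around a cycle re-using an arc on the same side correspond
# to unbounded univocal extensions and are never maximal.
guarded_omnitig <- function(g, w) {
  cd <- core_decomposition(g, w)
  if (!cd$has_core) return(FALSE)
  l <- length(w$nodes)
  left <- w$arcs[seq_len(cd$i - 1L)]
  right <- w$arcs[cd$j:(l - 1L)]
  !anyDuplicated(left) && !anyDuplicated(right)
}

#' Brute-force enumeration of maximal simple omnitigs
#'
#' Reference implementation for small graphs: grows walks arc by arc in
#' both directions from every single-arc walk, keeping exactly the walks
#' that have a core (the defining property of a simple omnitig) and whose
#' extension phases repeat no arc, and finally discards every walk that is
#' strictly contained as a contiguous subwalk of another kept walk.
#' Isolated degree-(1,1) cycle components, which no finite walk can cover
#' maximally, are reported once each as a circular walk broken at their
#' smallest node id. Intended only for testing
#' [maximal_simple_omnitigs()] on small instances.
#'
#' @param g An `omni_graph` (small; enumeration must be feasible).
#' @param max_len Maximum number of nodes per enumerated walk; defaults to
#'   `2 * n_arcs(g) + 2`, which no guarded walk can exceed.
#' @param max_walks Enumeration budget; exceeding it raises an error
#'   advising a smaller instance.
#' @return A list of `omni_walk` objects in deterministic order.
#' @export
brute_force_simple_omnitigs <- function(g, max_len = NULL, max_walks = 200000L) {
  stopifnot(inherits(g, "omni_graph"))
  m <- n_arcs(g)
  if (m == 0L) return(list())
  if (is.null(max_len)) max_len <- 2L * m + 2L

  # isolated cycle components: every node reachable along them has
  # in-degree one and out-degree one, so no walk through them ever meets a
  # branching node
  internal <- g$in_deg == 1L & g$out_deg == 1L
  on_path <- logical(m)
  for (a in seq_len(m)) {
    if (!internal[g$tails[a]]) {
      e <- a
      repeat {
        if (on_path[e]) break
        on_path[e] <- TRUE
        v <- g$heads[e]
        if (!internal[v]) break
        e <- g$out_arcs[[v]][1L]
      }
    }
  }
  cycles <- list()
  cyc_done <- logical(m)
  for (a in seq_len(m)) {
    if (on_path[a] || cyc_done[a]) next
    cyc_arcs <- a
    cyc_done[a] <- TRUE
    v <- g$heads[a]
    while (v != g$tails[a]) {
      e <- g$out_arcs[[v]][1L]
      cyc_done[e] <- TRUE
      cyc_arcs <- c(cyc_arcs, e)
      v <- g$heads[e]
    }
    rot <- which.min(g$tails[cyc_arcs])
    ord <- c(seq(rot, length(cyc_arcs)), seq_len(rot - 1L))
    cyc_arcs <- cyc_arcs[ord]
    cycles[[length(cycles) + 1L]] <-
      structure(list(nodes = c(g$tails[cyc_arcs], g$tails[cyc_arcs[1L]]),
                     arcs = cyc_arcs, circular = TRUE),
                class = "omni_walk")
  }

  # breadth-first growth over walks with cores, on the non-cycle arcs
  mk_walk <- function(nodes, arcs) {
    structure(list(nodes = nodes, arcs = arcs, circular = FALSE),
              class = "omni_walk")
  }
  pool <- new.env(parent = emptyenv())
  pool_size <- 0L
  frontier <- list()
  for (a in which(on_path)) {
    w <- mk_walk(c(g$tails[a], g$heads[a]), a)
    assign(walk_key(w), w, envir = pool)
    pool_size <- pool_size + 1L
    frontier[[length(frontier) + 1L]] <- w
  }
  while (length(frontier) > 0L) {
    nxt <- list()
    for (w in frontier) {
      l <- length(w$nodes)
      if (l >= max_len) next
      cand <- list()
      for (e in g$out_arcs[[w$nodes[l]]]) {
        cand[[length(cand) + 1L]] <- mk_walk(c(w$nodes, g$heads[e]),
                                             c(w$arcs, e))
      }
      for (e in g$in_arcs[[w$nodes[1L]]]) {
        cand[[length(cand) + 1L]] <- mk_walk(c(g$tails[e], w$nodes),
                                             c(e, w$arcs))
      }
      for (x in cand) {
        key <- walk_key(x)
        if (exists(key, envir = pool, inherits = FALSE)) next
        if (!guarded_omnitig(g, x)) next
        assign(key, x, envir = pool)
        pool_size <- pool_size + 1L
        nxt[[length(nxt) + 1L]] <- x
        if (pool_size > max_walks) {
          stop("enumeration budget exceeded; use a smaller instance")
        }
      }
    }
    frontier <- nxt
  }
  kept <- mget(ls(pool), envir = pool)

  # the core of a maximal simple omnitig is a *maximal* unitig, i.e. its
  # endpoints are not degree-(1,1) nodes (otherwise the unitig extends).
  # Walks failing this are winding phases of an unbounded extension inside
  # an entered cycle and are never maximal.
  if (length(kept) > 0L) {
    ok <- vapply(kept, function(w) {
      cd <- core_decomposition(g, w)
      e1 <- cd$core$nodes[1L]
      e2 <- cd$core$nodes[length(cd$core$nodes)]
      !(g$in_deg[e1] == 1L && g$out_deg[e1] == 1L) &&
        !(g$in_deg[e2] == 1L && g$out_deg[e2] == 1L)
    }, logical(1L))
    kept <- kept[ok]
  }

  # maximality: drop walks strictly contained in another kept walk
  if (length(kept) > 1L) {
    lens <- vapply(kept, function(w) length(w$arcs), integer(1L))
    ord <- order(-lens)
    kept <- kept[ord]
    lens <- lens[ord]
    maximal <- logical(length(kept))
    for (idx in seq_along(kept)) {
      contained <- FALSE
      for (jdx in seq_along(kept)) {
        if (lens[jdx] <= lens[idx]) break  # sorted: no longer walks follow
        if (is_subwalk(kept[[idx]], kept[[jdx]])) {
          contained <- TRUE
          break
        }
      }
      maximal[idx] <- !contained
    }
    kept <- kept[maximal]
  }
  sort_walks(c(kept, cycles))
}
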