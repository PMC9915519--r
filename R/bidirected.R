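# Bidirected (GFA-style) graphs and their conversion to doubled plain
# directed graphs. Each segment contributes a forward ("+") and a reverse
# ("-") node; each link contributes an arc and its mirror arc, so that the
# doubled graph is closed under reverse-complement symmetry.

#' Construct a bidirected segment graph
#'
#' The GFA1 view of an assembly graph: sequence segments plus oriented
#' links. Orientations are `"+"` or `"-"`; the `overlap` column stores the
#' GFA overlap field verbatim (it is parsed but never interpreted, since
#' tig enumeration is topology-only).
#'
#' @param segments Character vector of segment names, or a data.frame with
#'   columns `name` and optionally `sequence`.
#' @param links A data.frame with columns `from`, `from_orient`, `to`,
#'   `to_orient` and optionally `overlap` (default `"*"`).
#' @return An object of class `bidigraph`.
#' @examples
#' bg <- bidigraph(c("x", "y"),
#'                 data.frame(from = "x", from_orient = "+",
#'                            to = "y", to_orient = "+"))
#' double_graph(bg)
#' @export
bidigraph <- function(segments, links = NULL) {
  if (is.character(segments)) {
    segments <- data.frame(name = segments,
                           sequence = NA_character_,
                           stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(segments), "name" %in% names(segments))
  segments$name <- as.character(segments$name)
  if (anyDuplicated(segments$name)) stop("duplicate segment names")
  if (is.null(segments$sequence)) segments$sequence <- NA_character_
  if (is.null(links)) {
    links <- data.frame(from = character(), from_orient = character(),
                        to = character(), to_orient = character(),
                        overlap = character(), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(links),
            all(c("from", "from_orient", "to", "to_orient") %in% names(links)))
  if (is.null(links$overlap)) links$overlap <- rep("*", nrow(links))
  for (col in c("from", "from_orient", "to", "to_orient", "overlap")) {
    links[[col]] <- as.character(links[[col]])
  }
  if (nrow(links) > 0L) {
    if (!all(links$from_orient %in% c("+", "-")) ||
        !all(links$to_orient %in% c("+", "-"))) {
      stop("link orientations must be '+' or '-'")
    }
    missing <- setdiff(c(links$from, links$to), segments$name)
    if (length(missing) > 0L) {
      stop("link references unknown segment: ", missing[1L])
    }
  }
  structure(list(segments = segments, links = links), class = "bidigraph")
}

#' @export
print.bidigraph <- function(x, ...) {
  cat("bidigraph with", nrow(x$segments), "segments and",
      nrow(x$links), "links\n")
  invisible(x)
}

flip_orient <- function(o) ifelse(o == "+", "-", "+")

#' Convert a bidirected graph to a doubled plain graph
#'
#' Each segment `s` becomes two nodes `s+` and `s-`. Each link
#' `(a, oa, b, ob)` becomes the arc `a^oa -> b^ob` together with its mirror
#' arc `b^flip(ob) -> a^flip(oa)`; a palindromic link whose mirror is itself
#' contributes a single arc. Duplicate arcs arising from links already
#' stated in both orientations are emitted once. The result carries the
#' node mirror map and the arc mirror pairing, which downstream code uses
#' to collapse reverse-complement walk pairs.
#'
#' @param bg A `bidigraph`.
#' @return An `omni_graph` with `node_names` `"<seg>+"`/`"<seg>-"` and extra
#'   fields `mirror_node` (integer vector mapping each node to its mirror)
#'   and `mirror_arc` (integer vector pairing each arc with its mirror).
#' @export
double_graph <- function(bg) {
  stopifnot(inherits(bg, "bidigraph"))
  segs <- bg$segments$name
  ns <- length(segs)
  # segment i -> nodes 2i-1 ("+") and 2i ("-")
  node_names <- as.vector(rbind(paste0(segs, "+"), paste0(segs, "-")))
  node_id <- function(seg, orient) {
    i <- match(seg, segs)
    2L * i - ifelse(orient == "+", 1L, 0L)
  }
  tails <- integer(0)
  heads <- integer(0)
  overlaps <- character(0)
  mirror_arc <- integer(0)
  seen <- character(0)
  ln <- bg$links
  if (nrow(ln) > 0L) {
    for (r in seq_len(nrow(ln))) {
      u <- node_id(ln$from[r], ln$from_orient[r])
      v <- node_id(ln$to[r], ln$to_orient[r])
      mu <- node_id(ln$to[r], flip_orient(ln$to_orient[r]))
      mv <- node_id(ln$from[r], flip_orient(ln$from_orient[r]))
      ov <- ln$overlap[r]
      k1 <- paste(u, v, ov, sep = "/")
      k2 <- paste(mu, mv, ov, sep = "/")
      if (k1 %in% seen || k2 %in% seen) next  # redundant restatement
      if (k1 == k2) {
        # palindromic link: the mirror arc coincides with the arc itself
        tails <- c(tails, u); heads <- c(heads, v)
        overlaps <- c(overlaps, ov)
        mirror_arc <- c(mirror_arc, length(tails))
        seen <- c(seen, k1)
      } else {
        tails <- c(tails, u, mu); heads <- c(heads, v, mv)
        overlaps <- c(overlaps, ov, ov)
        a <- length(tails)
        mirror_arc <- c(mirror_arc, a, a - 1L)
        seen <- c(seen, k1, k2)
      }
    }
  }
  g <- omni_graph(2L * ns, tails, heads, node_names = node_names,
                  arc_labels = if (length(overlaps)) overlaps else NULL)
  # mirror of node 2i-1 (s+) is 2i (s-) and vice versa
  g$mirror_node <- ifelse(seq_len(2L * ns) %% 2L == 1L,
                          seq_len(2L * ns) + 1L,
                          seq_len(2L * ns) - 1L)
  g$mirror_arc <- mirror_arc
  g$doubled <- TRUE
  g
}

#' Mirror (reverse-complement) of a walk in a doubled graph
#'
#' Reverses the walk and maps every node and arc to its mirror. A
#' mirrored circular walk is rotated back to the canonical break point
#' (its smallest node id), so mirrors of enumeration output compare
#' directly against enumeration output. Only defined on graphs produced
#' by [double_graph()].
#'
#' @param g An `omni_graph` from [double_graph()].
#' @param w An `omni_walk` in `g`.
#' @return The mirrored `omni_walk`.
#' @export
mirror_walk <- function(g, w) {
  stopifnot(inherits(g, "omni_graph"), inherits(w, "omni_walk"))
  if (is.null(g$mirror_node)) stop("graph is not a doubled graph")
  nodes <- rev(g$mirror_node[w$nodes])
  arcs <- rev(g$mirror_arc[w$arcs])
  if (w$circular && length(arcs) > 0L) {
    open <- nodes[-length(nodes)]
    rot <- which.min(open)
    ord <- c(seq(rot, length(arcs)), seq_len(rot - 1L))
    arcs <- arcs[ord]
    nodes <- c(open[ord], open[ord][1L])
  }
  structure(list(nodes = nodes, arcs = arcs, circular = w$circular),
            class = "omni_walk")
}
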