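# k-spectrum extraction and the arc-centric de Bruijn graph. The model is
# single-stranded: no reverse complements are added, matching the setting
# in which simple-omnitig safety is proved. Double-stranded inputs enter
# through double_graph() instead.

#' Construct a genome object
#'
#' A genome is a set of chromosomes, each a DNA sequence over `{A,C,G,T}`
#' with linear or circular topology. Internally a data.frame with columns
#' `name`, `sequence`, `circular`.
#'
#' @param sequences Character vector of chromosome sequences.
#' @param names Chromosome names; defaults to `chr1`, `chr2`, ...
#' @param circular Logical, recycled along chromosomes.
#' @return A data.frame of class `genome`.
#' @examples
#' genome(c("ACGGT", "TTACG"))
#' genome("ACGTACGT", circular = TRUE)
#' @export
genome <- function(sequences, names = NULL, circular = FALSE) {
  sequences <- toupper(as.character(sequences))
  if (length(sequences) > 0L && any(grepl("[^ACGT]", sequences))) {
    stop("chromosome sequences must be over the alphabet {A,C,G,T}")
  }
  if (is.null(names)) {
    names <- if (length(sequences)) paste0("chr", seq_along(sequences)) else character(0)
  }
  if (anyDuplicated(names)) stop("duplicate chromosome names")
  circular <- rep_len(as.logical(circular), length(sequences))
  structure(data.frame(name = as.character(names), sequence = sequences,
                       circular = circular, stringsAsFactors = FALSE),
            class = c("genome", "data.frame"))
}

as_genome <- function(x) {
  if (inherits(x, "genome")) return(x)
  if (is.data.frame(x)) {
    return(genome(x$sequence, names = x$name,
                  circular = if (is.null(x$circular)) FALSE else x$circular))
  }
  genome(x)
}

# All k-substrings of one chromosome, respecting topology. A circular
# chromosome of length n contributes n wrap-around positions.
chrom_kmers <- function(seq, k, circ, name) {
  n <- nchar(seq)
  if (circ) {
    if (n < 1L) stop("empty circular chromosome: ", name)
    s2 <- paste0(seq, substr(seq, 1L, min(k - 1L, n)))
    if (nchar(s2) < k) {
      # very short circular chromosome: keep wrapping
      s2 <- paste0(strrep(seq, ceiling(k / n) + 1L))
      s2 <- substr(s2, 1L, n + k - 1L)
    }
    starts <- seq_len(n)
  } else {
    if (n < k) {
      stop("linear chromosome '", name, "' is shorter than k = ", k)
    }
    starts <- seq_len(n - k + 1L)
    s2 <- seq
  }
  substring(s2, starts, starts + k - 1L)
}

#' k-spectrum of a genome
#'
#' The k-spectrum is the set (multiplicity discarded) of all length-`k`
#' substrings of the chromosomes. Linear chromosomes of length `n`
#' contribute their `n - k + 1` substrings; circular chromosomes wrap
#' around, contributing one substring per position.
#'
#' @param gen A [genome()] (or coercible data.frame / character vector).
#' @param k Integer word size, at least 2.
#' @return An object of class `k_spectrum`: a list with elements `k` and
#'   `kmers` (sorted character vector).
#' @examples
#' k_spectrum(genome("ACGGT"), 3)$kmers           # ACG CGG GGT
#' k_spectrum(genome("ACG", circular = TRUE), 2)  # wrap-around adds GA
#' @export
k_spectrum <- function(gen, k) {
  gen <- as_genome(gen)
  stopifnot(is.numeric(k), length(k) == 1L, k >= 2L)
  k <- as.integer(k)
  kmers <- character(0)
  for (i in seq_len(nrow(gen))) {
    kmers <- c(kmers, chrom_kmers(gen$sequence[i], k, gen$circular[i],
                                  gen$name[i]))
  }
  structure(list(k = k, kmers = sort(unique(kmers))), class = "k_spectrum")
}

#' @export
print.k_spectrum <- function(x, ...) {
  cat("k-spectrum: k =", x$k, "with", length(x$kmers), "k-mers\n")
  invisible(x)
}

#' Boundary set of a genome
#'
#' The set `L` of \eqn{(k-1)}-mers that begin or end some linear
#' chromosome: for each linear chromosome `s`, its length-\eqn{(k-1)}
#' prefix and suffix. Circular chromosomes contribute nothing, so `L` is
#' empty for an all-circular genome. Simple omnitigs whose inner nodes
#' avoid `L` are guaranteed safe on the error-free de Bruijn graph.
#'
#' @inheritParams k_spectrum
#' @return Sorted character vector of \eqn{(k-1)}-mers.
#' @examples
#' boundary_set(genome(c("AACT", "GACTT")), 3)  # AA CT GA TT
#' boundary_set(genome("ACGTT", circular = TRUE), 3)  # empty
#' @export
boundary_set <- function(gen, k) {
  gen <- as_genome(gen)
  stopifnot(is.numeric(k), length(k) == 1L, k >= 2L)
  k <- as.integer(k)
  members <- character(0)
  for (i in seq_len(nrow(gen))) {
    if (gen$circular[i]) next
    s <- gen$sequence[i]
    n <- nchar(s)
    if (n < k) stop("linear chromosome '", gen$name[i],
                    "' is shorter than k = ", k)
    members <- c(members, substr(s, 1L, k - 1L), substr(s, n - k + 2L, n))
  }
  sort(unique(members))
}

#' Build the arc-centric de Bruijn graph of a k-spectrum
#'
#' Nodes are the \eqn{(k-1)}-mers occurring as prefix or suffix of some
#' spectrum k-mer; each k-mer contributes exactly one arc from its
#' \eqn{(k-1)}-prefix to its \eqn{(k-1)}-suffix. Arcs carry their k-mer as
#' payload and nodes carry their \eqn{(k-1)}-mer, so walks can be spelled.
#'
#' @param spectrum A [k_spectrum()].
#' @return An `omni_graph` with an attached field `k`.
#' @examples
#' g <- build_dbg(k_spectrum(genome("ACGGT"), 3))
#' n_nodes(g); n_arcs(g)   # path AC -> CG -> GG -> GT
#' @export
build_dbg <- function(spectrum) {
  stopifnot(inherits(spectrum, "k_spectrum"))
  kmers <- spectrum$kmers
  if (length(kmers) == 0L) stop("empty k-spectrum")
  k <- spectrum$k
  pref <- substr(kmers, 1L, k - 1L)
  suf <- substr(kmers, 2L, k)
  nodes <- sort(unique(c(pref, suf)))
  g <- omni_graph(length(nodes),
                  tails = match(pref, nodes),
                  heads = match(suf, nodes),
                  node_names = nodes,
                  arc_labels = kmers)
  g$k <- k
  g
}

#' Spell the string of a walk in a de Bruijn graph
#'
#' A walk spells its first node's \eqn{(k-1)}-mer followed by the last
#' character of each subsequent node, giving a string of length
#' \eqn{(k-1) + (\ell-1)}. For a circular walk (closed, \eqn{w_1 = w_\ell})
#' the spelled string duplicates the \eqn{(k-1)}-long wrap;
#' [spell_cyclic()] returns the length-\eqn{(\ell-1)} cyclic
#' representative instead.
#'
#' @param g A de Bruijn graph from [build_dbg()].
#' @param w An `omni_walk` in `g`.
#' @return A character scalar.
#' @examples
#' g <- build_dbg(k_spectrum(genome("ACGGT"), 3))
#' spell(g, omni_walk(g, c("AC", "CG", "GG", "GT")))  # "ACGGT"
#' @export
spell <- function(g, w) {
  stopifnot(inherits(g, "omni_graph"), inherits(w, "omni_walk"))
  if (is.null(g$node_names)) stop("graph nodes carry no (k-1)-mer payloads")
  names <- g$node_names[w$nodes]
  if (length(names) == 1L) return(names)
  paste0(names[1L],
         paste(substr(names[-1L], nchar(names[-1L]), nchar(names[-1L])),
               collapse = ""))
}

#' @rdname spell
#' @export
spell_cyclic <- function(g, w) {
  if (!w$circular) stop("spell_cyclic() requires a circular walk")
  s <- spell(g, w)
  substr(s, g$k, nchar(s))  # drop the duplicated (k-1)-prefix
}
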