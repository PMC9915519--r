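# Seeded generators for test instances: random genomes, genomes with
# planted repeats and bubbles, random multigraphs and bidirected graphs,
# and the two small worked-example graphs used throughout the test suite.
# Every generator is a pure function of its arguments: the seed is part of
# the specification, never taken from the session RNG state.

# Run code under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Specify a synthetic genome
#'
#' Collects the parameters of a synthetic genome into a specification
#' object; [generate_genome()] is a pure function of this object, so the
#' same spec always yields the same genome. Plain chromosomes are drawn
#' uniformly over `{A,C,G,T}`; planted features add extra chromosomes with
#' a recorded structure.
#'
#' @param n_chromosomes Number of plain random chromosomes.
#' @param length_range Length range (min, max) for plain chromosomes; a
#'   single value fixes the length.
#' @param circular Topology of plain chromosomes.
#' @param features List of planted features built with [repeat_feature()]
#'   or [bubble_feature()].
#' @param k Word size used to verify flank uniqueness of planted features
#'   by rejection sampling (ignored when no features are given).
#' @param seed Integer seed (mandatory; defaults to 0).
#' @return A list of class `genome_spec`.
#' @export
genome_spec <- function(n_chromosomes = 1L, length_range = c(200L, 200L),
                        circular = FALSE, features = list(), k = 7L,
                        seed = 0L) {
  if (length(length_range) == 1L) length_range <- rep(length_range, 2L)
  stopifnot(n_chromosomes >= 0L, length(length_range) == 2L,
            length_range[1L] <= length_range[2L], k >= 2L)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 length_range = as.integer(length_range),
                 circular = isTRUE(circular),
                 features = features,
                 k = as.integer(k),
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' Planted features for synthetic genomes
#'
#' `repeat_feature()` plants `copies` exact copies of a random repeat unit
#' separated and flanked by random spacers (structure `X R Y R Z` for two
#' copies). `bubble_feature()` plants a diploid-style bubble: two
#' chromosomes `A B C` and `A D C` sharing their flanks, with the arms `B`
#' and `D` differing in at least one position. Flank uniqueness at the
#' spec's `k` is enforced by rejection sampling (at most 1000 attempts).
#'
#' @param copies Number of repeat copies (at least 2).
#' @param unit_length Length of the repeat unit.
#' @param flank_length Length of each flanking / separating spacer.
#' @param arm_length Length of each bubble arm.
#' @return A feature description list.
#' @export
repeat_feature <- function(copies = 2L, unit_length = 30L,
                           flank_length = 50L) {
  stopifnot(copies >= 2L, unit_length >= 1L, flank_length >= 1L)
  list(type = "repeat", copies = as.integer(copies),
       unit_length = as.integer(unit_length),
       flank_length = as.integer(flank_length))
}

#' @rdname repeat_feature
#' @export
bubble_feature <- function(arm_length = 20L, flank_length = 50L) {
  stopifnot(arm_length >= 1L, flank_length >= 1L)
  list(type = "bubble", arm_length = as.integer(arm_length),
       flank_length = as.integer(flank_length))
}

# positions (1-based starts) of all (k-1)-mers of s
kmer_starts <- function(s, km1) {
  n <- nchar(s)
  if (n < km1) return(character(0))
  substring(s, seq_len(n - km1 + 1L), seq_len(n - km1 + 1L) + km1 - 1L)
}

# Clean-repeat check: every duplicated (k-1)-mer must be explained by the
# planted unit copies, i.e. all of its occurrences overlap a unit span.
repeat_clean <- function(s, km1, unit_starts, unit_len) {
  kk <- kmer_starts(s, km1)
  tab <- table(kk)
  dup <- names(tab)[tab > 1L]
  lo <- unit_starts - km1 + 1L
  hi <- unit_starts + unit_len - 1L
  for (d in dup) {
    pos <- which(kk == d)
    for (p in pos) {
      if (!any(p >= lo & p <= hi)) return(FALSE)
    }
  }
  TRUE
}

# Clean-bubble check: a duplicated (k-1)-mer is acceptable only when it is
# explained by the shared flanks, i.e. it occurs exactly once in each
# haplotype at the same position, and that occurrence overlaps a flank.
# Within-flank repeats (four occurrences) or flank-to-flank duplicates are
# rejected: they introduce extra repeat structure beyond the bubble.
bubble_clean <- function(s1, s2, km1, fl, al) {
  k1 <- kmer_starts(s1, km1)
  k2 <- kmer_starts(s2, km1)
  if (anyDuplicated(k1) || anyDuplicated(k2)) return(FALSE)
  shared <- intersect(k1, k2)
  for (d in shared) {
    p1 <- which(k1 == d)
    p2 <- which(k2 == d)
    if (p1 != p2) return(FALSE)
    overlaps_flank <- p1 <= fl || p1 >= fl + al + 2L - km1
    if (!overlaps_flank) return(FALSE)
  }
  TRUE
}

#' Generate a synthetic genome from a specification
#'
#' Deterministic under the spec's seed. Planted repeat units are exact
#' copies; bubble arms differ in at least one position. The manifest
#' records, per feature part, its chromosome and 0-based half-open
#' coordinates. For planted features the flanks are re-sampled (up to 1000
#' times) until the only \eqn{(k-1)}-mers occurring more than once are
#' those explained by the feature itself, so the feature appears in the de
#' Bruijn graph exactly as designed.
#'
#' @param spec A [genome_spec()].
#' @return A list with elements `genome` (a [genome()]) and `manifest`
#'   (data.frame with columns `chrom`, `feature`, `part`, `start`, `end`).
#' @examples
#' gs <- genome_spec(n_chromosomes = 0,
#'                   features = list(repeat_feature()), k = 7, seed = 1)
#' generate_genome(gs)$manifest
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    seqs <- character(0)
    names <- character(0)
    circ <- logical(0)
    manifest <- data.frame(chrom = character(0), feature = character(0),
                           part = character(0), start = integer(0),
                           end = integer(0), stringsAsFactors = FALSE)
    km1 <- spec$k - 1L
    for (i in seq_len(spec$n_chromosomes)) {
      len <- if (spec$length_range[1L] == spec$length_range[2L]) {
        spec$length_range[1L]
      } else {
        sample(spec$length_range[1L]:spec$length_range[2L], 1L)
      }
      if (!spec$circular && len < spec$k) {
        stop("infeasible spec: chromosome length below k")
      }
      seqs <- c(seqs, random_dna(len))
      names <- c(names, paste0("chr", length(names) + 1L))
      circ <- c(circ, spec$circular)
    }
    fi <- 0L
    for (f in spec$features) {
      fi <- fi + 1L
      fname <- paste0(f$type, fi)
      if (f$type == "repeat") {
        nspacer <- f$copies + 1L
        for (attempt in seq_len(1000L)) {
          unit <- random_dna(f$unit_length)
          spacers <- vapply(seq_len(nspacer), function(i)
            random_dna(f$flank_length), character(1L))
          parts <- character(0)
          for (ci in seq_len(f$copies)) {
            parts <- c(parts, spacers[ci], unit)
          }
          parts <- c(parts, spacers[nspacer])
          s <- paste(parts, collapse = "")
          # starts of the repeat copies (1-based)
          starts <- cumsum(c(1L, nchar(parts)))[seq_len(length(parts))]
          unit_idx <- seq(2L, by = 2L, length.out = f$copies)
          if (repeat_clean(s, km1, starts[unit_idx], f$unit_length)) break
          if (attempt == 1000L) stop("could not plant repeat with unique flanks")
        }
        cname <- paste0("chr", length(names) + 1L)
        seqs <- c(seqs, s)
        names <- c(names, cname)
        circ <- c(circ, FALSE)
        starts0 <- cumsum(c(0L, nchar(parts)))
        labels <- c(rbind(paste0("flank", seq_len(f$copies)),
                          paste0("unit", seq_len(f$copies))),
                    paste0("flank", nspacer))
        manifest <- rbind(manifest, data.frame(
          chrom = cname, feature = fname, part = labels,
          start = starts0[seq_along(parts)],
          end = starts0[seq_along(parts) + 1L], stringsAsFactors = FALSE))
      } else if (f$type == "bubble") {
        for (attempt in seq_len(1000L)) {
          a <- random_dna(f$flank_length)
          c_ <- random_dna(f$flank_length)
          b <- random_dna(f$arm_length)
          d <- random_dna(f$arm_length)
          if (b == d) next
          s1 <- paste0(a, b, c_)
          s2 <- paste0(a, d, c_)
          fl <- f$flank_length; al <- f$arm_length
          if (bubble_clean(s1, s2, km1, fl, al)) break
          if (attempt == 1000L) stop("could not plant bubble with unique flanks")
        }
        c1 <- paste0("chr", length(names) + 1L)
        c2 <- paste0("chr", length(names) + 2L)
        seqs <- c(seqs, s1, s2)
        names <- c(names, c1, c2)
        circ <- c(circ, FALSE, FALSE)
        fl <- f$flank_length; al <- f$arm_length
        manifest <- rbind(manifest, data.frame(
          chrom = c(c1, c1, c1, c2, c2, c2), feature = fname,
          part = c("flankA", "armB", "flankC", "flankA", "armD", "flankC"),
          start = c(0L, fl, fl + al, 0L, fl, fl + al),
          end = c(fl, fl + al, 2L * fl + al, fl, fl + al, 2L * fl + al),
          stringsAsFactors = FALSE))
      } else {
        stop("unknown feature type: ", f$type)
      }
    }
    list(genome = genome(seqs, names = names, circular = circ),
         manifest = manifest)
  })
}

#' Generate a seeded random directed multigraph
#'
#' Samples `m` arcs uniformly with replacement over ordered node pairs;
#' self-loops and parallel arcs are allowed. Deterministic under `seed`.
#'
#' @param n Number of nodes (at least 1).
#' @param m Number of arcs (non-negative).
#' @param seed Integer seed.
#' @return An `omni_graph`.
#' @export
generate_random_graph <- function(n, m, seed = 0L) {
  stopifnot(n >= 1L, m >= 0L)
  with_seed(seed, {
    omni_graph(n,
               tails = sample.int(n, m, replace = TRUE),
               heads = sample.int(n, m, replace = TRUE))
  })
}

#' Generate a seeded random bidirected graph
#'
#' Samples links uniformly over (segment, orientation) pairs; duplicate
#' links are kept (doubling deduplicates them). Deterministic under
#' `seed`.
#'
#' @param n_segments Number of segments (at least 1).
#' @param n_links Number of links to sample.
#' @param seed Integer seed.
#' @return A `bidigraph`.
#' @export
generate_random_bidigraph <- function(n_segments, n_links, seed = 0L) {
  stopifnot(n_segments >= 1L, n_links >= 0L)
  with_seed(seed, {
    segs <- paste0("s", seq_len(n_segments))
    links <- data.frame(
      from = segs[sample.int(n_segments, n_links, replace = TRUE)],
      from_orient = sample(c("+", "-"), n_links, replace = TRUE),
      to = segs[sample.int(n_segments, n_links, replace = TRUE)],
      to_orient = sample(c("+", "-"), n_links, replace = TRUE),
      stringsAsFactors = FALSE)
    bidigraph(segs, links)
  })
}

#' Worked-example graphs: planted repeat and bubble
#'
#' Returns the two 8-node graphs used as fixtures throughout: `G1` models
#' a genome with two occurrences of a repeat `R` between unique context
#' (`A R B R C` at the sequence level, each labelled block drawn as a
#' length-two path), and `G2` models a bubble where `A B C` coexists with
#' the variant `A D C`. `G1` yields the three maximal simple omnitigs
#' spelling `AR`, `RBR` and `RC`; `G2` yields the two spelling `ABC` and
#' `ADC`.
#'
#' @return A list with elements `G1` and `G2`, each an `omni_graph` with
#'   named nodes.
#' @export
fixtures <- function() {
  g1_nodes <- c("a1", "a2", "r1", "r2", "b1", "b2", "c1", "c2")
  g1 <- omni_graph(8,
    tails = match(c("a1", "a2", "r1", "r2", "b1", "b2", "r2", "c1"), g1_nodes),
    heads = match(c("a2", "r1", "r2", "b1", "b2", "r1", "c1", "c2"), g1_nodes),
    node_names = g1_nodes)
  g2_nodes <- c("a1", "a2", "b1", "b2", "c1", "c2", "d1", "d2")
  g2 <- omni_graph(8,
    tails = match(c("a1", "a2", "a2", "b1", "b2", "d1", "d2", "c1"), g2_nodes),
    heads = match(c("a2", "b1", "d1", "b2", "c1", "d2", "c1", "c2"), g2_nodes),
    node_names = g2_nodes)
  list(G1 = g1, G2 = g2)
}
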