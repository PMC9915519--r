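# Summary statistics comparing unitig and simple-omnitig output on the de
# Bruijn graph of a genome.

#' Spelled lengths of a list of walks
#'
#' @param g A de Bruijn graph from [build_dbg()].
#' @param walks List of `omni_walk` objects.
#' @return Integer vector of spelled string lengths.
#' @export
spelled_lengths <- function(g, walks) {
  vapply(walks, function(w) nchar(spell(g, w)), integer(1L))
}

#' Unitig versus simple-omnitig contiguity on a genome's de Bruijn graph
#'
#' Builds the de Bruijn graph of the genome's k-spectrum, enumerates
#' maximal unitigs and maximal simple omnitigs, and summarises their
#' counts and total spelled lengths. Because every maximal unitig is a
#' subwalk of some maximal simple omnitig, the summed omnitig length is
#' never below the summed unitig length; it is strictly larger whenever a
#' repeat or bubble with unique flanks lets an extension continue past a
#' branching node.
#'
#' @param gen A [genome()] (or coercible object).
#' @param k Integer word size.
#' @return A list with `n_unitigs`, `n_simple_omnitigs`,
#'   `unitig_total_length`, `omnitig_total_length` and `gain` (ratio of
#'   the two totals).
#' @examples
#' gs <- genome_spec(n_chromosomes = 0,
#'                   features = list(repeat_feature()), k = 7, seed = 4)
#' tig_stats(generate_genome(gs)$genome, 7)$gain  # > 1
#' @export
tig_stats <- function(gen, k) {
  gen <- as_genome(gen)
  g <- build_dbg(k_spectrum(gen, k))
  u <- maximal_unitigs(g)
  so <- so_walks(maximal_simple_omnitigs(g))
  ul <- sum(spelled_lengths(g, u))
  sl <- sum(spelled_lengths(g, so))
  list(n_unitigs = length(u),
       n_simple_omnitigs = length(so),
       unitig_total_length = ul,
       omnitig_total_length = sl,
       gain = sl / ul)
}
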