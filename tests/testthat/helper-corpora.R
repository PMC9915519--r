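# Shared helpers: canonical walk keys for set comparisons and the seeded
# corpora used by the property and acceptance tests.

walk_keys <- function(walks) {
  sort(unname(vapply(walks, omnitigs:::walk_key, character(1L))))
}

node_names_of <- function(g, walks) {
  unname(vapply(walks, function(w)
    paste(walk_node_names(g, w), collapse = ","), character(1L)))
}

# random-multigraph corpus for oracle equivalence (n <= 12, m <= 25)
oracle_corpus_graph <- function(seed) {
  generate_random_graph(3L + (seed %% 10L), 5L + (seed %% 21L), seed = seed)
}

# random linear multi-chromosome genomes: 2-4 chromosomes, lengths
# 100-500, k cycling over {5, 7, 11}
linear_genome_case <- function(seed) {
  spec <- genome_spec(n_chromosomes = 2L + (seed %% 3L),
                      length_range = c(100L, 500L), seed = seed)
  list(genome = generate_genome(spec)$genome,
       k = c(5L, 7L, 11L)[1L + (seed %% 3L)])
}

circular_case <- function(seed) {
  spec <- genome_spec(n_chromosomes = 1L, length_range = c(100L, 500L),
                      circular = TRUE, seed = seed)
  generate_genome(spec)$genome
}

# seeded random EAxmax instances: G <= 1e4, up to 50 records
eaxmax_case <- function(seed) {
  set.seed(seed)
  G <- sample(10:10000, 1L)
  nrec <- sample(0:50, 1L)
  starts <- integer(0); ends <- integer(0)
  if (nrec > 0L) {
    starts <- sample(0:(G - 1L), nrec, replace = TRUE)
    ends <- pmin(G, starts + sample(1:G, nrec, replace = TRUE))
  }
  list(G = G, starts = starts, ends = ends)
}
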