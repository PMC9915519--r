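test_that("k-spectrum enumerates substrings with circular wrap-around", {
  expect_setequal(k_spectrum(genome("ACGGT"), 3)$kmers,
                  c("ACG", "CGG", "GGT"))
  expect_setequal(k_spectrum(genome("ACG", circular = TRUE), 2)$kmers,
                  c("AC", "CG", "GA"))
  expect_setequal(k_spectrum(genome(c("AACT", "GACTT")), 3)$kmers,
                  c("AAC", "ACT", "GAC", "CTT"))
  expect_error(k_spectrum(genome("AC"), 3), "chr1")
})

test_that("the de Bruijn graph has one arc per k-mer from prefix to suffix", {
  g1 <- build_dbg(k_spectrum(genome("ACG"), 3))
  expect_equal(g1$node_names, c("AC", "CG"))
  expect_equal(n_arcs(g1), 1L)
  expect_equal(g1$node_names[g1$tails], "AC")
  expect_equal(g1$node_names[g1$heads], "CG")

  gp <- build_dbg(k_spectrum(genome("ACGGT"), 3))
  arcs <- paste(gp$node_names[gp$tails], gp$node_names[gp$heads], sep = ">")
  expect_setequal(arcs, c("AC>CG", "CG>GG", "GG>GT"))

  g2 <- build_dbg(k_spectrum(genome(c("AACT", "GACTT")), 3))
  expect_setequal(g2$node_names, c("AA", "AC", "CT", "GA", "TT"))
  arcs2 <- paste(g2$node_names[g2$tails], g2$node_names[g2$heads], sep = ">")
  expect_setequal(arcs2, c("AA>AC", "AC>CT", "GA>AC", "CT>TT"))
})

test_that("arc count always equals the spectrum size", {
  for (s in 1:10) {
    gen <- generate_genome(genome_spec(n_chromosomes = 2,
                                       length_range = c(50, 120),
                                       seed = s))$genome
    sp <- k_spectrum(gen, 5)
    expect_equal(n_arcs(build_dbg(sp)), length(sp$kmers))
  }
})

test_that("walks spell their strings, including single nodes and cycles", {
  g <- build_dbg(k_spectrum(genome("ACGGT"), 3))
  expect_equal(spell(g, omni_walk(g, "AC")), "AC")
  expect_equal(spell(g, omni_walk(g, c("AC", "CG", "GG", "GT"))), "ACGGT")
  g2 <- build_dbg(k_spectrum(genome(c("AACT", "GACTT")), 3))
  expect_equal(spell(g2, omni_walk(g2, c("AA", "AC", "CT", "TT"))), "AACTT")

  gc <- build_dbg(k_spectrum(genome("ACGT", circular = TRUE), 3))
  w <- omni_walk(gc, c("AC", "CG", "GT", "TA", "AC"), circular = TRUE)
  expect_equal(nchar(spell(gc, w)), 2L + 4L)
  expect_equal(spell_cyclic(gc, w), "GTAC")
})

test_that("every chromosome is spelled by a walk in its own de Bruijn graph", {
  for (s in 1:8) {
    k <- c(5L, 7L)[1L + s %% 2L]
    gen <- generate_genome(genome_spec(n_chromosomes = 3,
                                       length_range = c(80, 200),
                                       seed = 100 + s))$genome
    g <- build_dbg(k_spectrum(gen, k))
    for (i in seq_len(nrow(gen))) {
      s_chr <- gen$sequence[i]
      n <- nchar(s_chr)
      nodes <- substring(s_chr, 1:(n - k + 2L), (k - 1L):n)
      w <- omni_walk(g, nodes)
      expect_equal(spell(g, w), s_chr)
    }
  }
})

test_that("boundary set holds the terminal (k-1)-mers of linear chromosomes", {
  expect_equal(boundary_set(genome("ACGTT", circular = TRUE), 3),
               character(0))
  expect_setequal(boundary_set(genome(c("AACT", "GACTT")), 3),
                  c("AA", "CT", "GA", "TT"))
  expect_setequal(boundary_set(genome("ACG"), 3), c("AC", "CG"))
})
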