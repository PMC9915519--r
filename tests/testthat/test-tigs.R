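test_that("maximal unitigs partition arcs and break at branching nodes", {
  gp <- omni_graph(3, tails = c(1, 2), heads = c(2, 3))
  us <- maximal_unitigs(gp)
  expect_length(us, 1L)
  expect_equal(us[[1L]]$nodes, c(1L, 2L, 3L))

  g1 <- fixtures()$G1
  us1 <- maximal_unitigs(g1)
  expect_setequal(node_names_of(g1, us1),
                  c("a1,a2,r1", "r1,r2", "r2,b1,b2,r1", "r2,c1,c2"))
  # partition property: every arc in exactly one unitig
  all_arcs <- sort(unlist(lapply(us1, `[[`, "arcs")))
  expect_equal(all_arcs, seq_len(n_arcs(g1)))

  cyc <- omni_graph(3, tails = c(1, 2, 3), heads = c(2, 3, 1))
  uc <- maximal_unitigs(cyc)
  expect_length(uc, 1L)
  expect_true(uc[[1L]]$circular)
  expect_equal(uc[[1L]]$nodes, c(1L, 2L, 3L, 1L))
})

test_that("arc partition by maximal unitigs holds on random multigraphs", {
  for (s in 1:25) {
    g <- oracle_corpus_graph(s)
    us <- maximal_unitigs(g)
    expect_equal(sort(unlist(lapply(us, `[[`, "arcs"))), seq_len(n_arcs(g)))
    for (u in us) {
      expect_true(omnitigs:::is_unitig_walk(g, u))
    }
  }
})

test_that("core decomposition finds the last split / first join window", {
  g1 <- fixtures()$G1
  # a unitig of length >= 2 is its own core
  u <- omni_walk(g1, c("r1", "r2"))
  cd <- core_decomposition(g1, u)
  expect_true(cd$has_core)
  expect_equal(cd$core$nodes, u$nodes)

  # first inner join precedes last inner split: no core
  w <- omni_walk(g1, c("a1", "a2", "r1", "r2", "b1"))
  cd <- core_decomposition(g1, w)
  expect_false(cd$has_core)
  expect_equal(cd$i, 3L)
  expect_equal(cd$j, 4L)

  # the repeat-spanning walk has core R
  w2 <- omni_walk(g1, c("r1", "r2", "b1", "b2", "r1", "r2"))
  cd2 <- core_decomposition(g1, w2)
  expect_true(cd2$has_core)
  expect_equal(cd2$i, 5L)
  expect_equal(cd2$j, 2L)
  expect_equal(walk_node_names(g1, cd2$core), c("r2", "b1", "b2", "r1"))

  # single-node walks have no core
  expect_false(core_decomposition(g1, omni_walk(g1, "r1"))$has_core)
})

test_that("the core test accepts exactly the cores of maximal simple omnitigs", {
  g1 <- fixtures()$G1
  expect_true(is_core_of_maximal(g1, omni_walk(g1, c("a1", "a2", "r1"))))
  expect_false(is_core_of_maximal(g1, omni_walk(g1, c("r1", "r2"))))
  g2 <- fixtures()$G2
  expect_false(is_core_of_maximal(g2, omni_walk(g2, c("a1", "a2"))))
  expect_error(
    is_core_of_maximal(g1, omni_walk(g1, c("a2", "r1", "r2", "b1"))),
    "not a unitig")
})

test_that("univocal extension follows unique arcs and terminates on cycles", {
  g1 <- fixtures()$G1
  e1 <- univocal_extension(g1, omni_walk(g1, c("a1", "a2", "r1")))
  expect_equal(walk_node_names(g1, e1), c("a1", "a2", "r1", "r2"))
  e2 <- univocal_extension(g1, omni_walk(g1, c("r2", "b1", "b2", "r1")))
  expect_equal(walk_node_names(g1, e2),
               c("r1", "r2", "b1", "b2", "r1", "r2"))

  # isolated 2-cycle: the repeated-arc guard bounds each direction
  gc <- omni_graph(2, tails = c(1, 2), heads = c(2, 1))
  ext <- univocal_extension(gc, omni_walk(gc, 1))
  expect_lte(length(ext$arcs), 2L * n_arcs(gc))
  expect_true(1L %in% ext$nodes)
})

test_that("fixture G1 yields the AR, RBR, RC simple omnitigs with their cores", {
  g1 <- fixtures()$G1
  so <- maximal_simple_omnitigs(g1)
  expect_setequal(node_names_of(g1, so_walks(so)),
                  c("a1,a2,r1,r2",
                    "r1,r2,b1,b2,r1,r2",
                    "r1,r2,c1,c2"))
  for (r in so) {
    cd <- core_decomposition(g1, r$walk)
    expect_identical(walk_keys(list(cd$core)), walk_keys(list(r$core)))
  }
})

test_that("fixture G2 recovers both bubble variants in full", {
  g2 <- fixtures()$G2
  so <- maximal_simple_omnitigs(g2)
  expect_setequal(node_names_of(g2, so_walks(so)),
                  c("a1,a2,b1,b2,c1,c2", "a1,a2,d1,d2,c1,c2"))
})

test_that("every maximal unitig is subsumed by a simple omnitig", {
  for (s in 1:40) {
    g <- oracle_corpus_graph(s)
    us <- maximal_unitigs(g)
    sow <- so_walks(maximal_simple_omnitigs(g))
    for (u in us) {
      expect_true(any(vapply(sow, function(w)
        omnitigs:::is_subwalk(u, w), logical(1L))))
    }
    # subsumption implies the longest walk never shrinks
    expect_gte(max(vapply(sow, walk_length, integer(1L))),
               max(vapply(us, walk_length, integer(1L))))
  }
})

test_that("each maximal simple omnitig has exactly one core among its unitigs", {
  for (s in 1:20) {
    g <- oracle_corpus_graph(s)
    us <- maximal_unitigs(g)
    for (r in maximal_simple_omnitigs(g)) {
      if (r$circular) next
      contained <- Filter(function(u) !u$circular &&
                            omnitigs:::is_subwalk(u, r$walk), us)
      cores <- Filter(function(u) is_core_of_maximal(g, u), contained)
      # exactly one contained maximal unitig passes the core test and it
      # is the recorded core
      expect_length(walk_keys(cores), 1L)
      expect_identical(walk_keys(cores), walk_keys(list(r$core)))
    }
  }
})

test_that("enumeration equals the brute-force oracle on random multigraphs", {
  for (s in 1:40) {
    g <- oracle_corpus_graph(1000L + s)
    expect_identical(walk_keys(so_walks(maximal_simple_omnitigs(g))),
                     walk_keys(brute_force_simple_omnitigs(g)))
  }
})

test_that("brute force handles edge cases", {
  expect_identical(brute_force_simple_omnitigs(omni_graph(3)), list())
  g <- omni_graph(3, tails = c(1, 2), heads = c(2, 3))
  expect_identical(walk_keys(brute_force_simple_omnitigs(g)),
                   walk_keys(list(omni_walk(g, c(1, 2, 3)))))
})

test_that("mirror collapse halves proper reverse-complement pairs", {
  dg <- double_graph(generate_random_bidigraph(8, 12, seed = 7))
  so <- so_walks(maximal_simple_omnitigs(dg))
  keys <- walk_keys(so)
  mirrored <- walk_keys(lapply(so, function(w) mirror_walk(dg, w)))
  expect_identical(keys, mirrored)  # closure under mirroring
  col <- maximal_simple_omnitigs(dg, collapse_mirror = TRUE)
  n_self <- sum(vapply(so, function(w)
    omnitigs:::walk_key(w) == omnitigs:::walk_key(mirror_walk(dg, w)),
    logical(1L)))
  expect_equal(length(col), (length(so) - n_self) / 2L + n_self)
  expect_error(maximal_simple_omnitigs(fixtures()$G1, collapse_mirror = TRUE),
               "doubled")
})
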