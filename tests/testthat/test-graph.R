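test_that("degrees count self-loops once per direction and reject unknown nodes", {
  g0 <- omni_graph(1)
  expect_equal(c(out_degree(g0, 1), in_degree(g0, 1)), c(0L, 0L))

  gl <- omni_graph(1, tails = 1, heads = 1)  # one self-loop
  expect_equal(c(out_degree(gl, 1), in_degree(gl, 1)), c(1L, 1L))

  g1 <- fixtures()$G1
  expect_equal(in_degree(g1, "r1"), 2L)
  expect_equal(out_degree(g1, "r1"), 1L)
  expect_true(is_join(g1, "r1"))
  expect_false(is_split(g1, "r1"))
  expect_true(is_split(g1, "r2"))
  expect_false(is_join(g1, "r2"))
  expect_false(is_split(g1, "b1"))
  expect_false(is_join(g1, "b1"))

  expect_error(out_degree(g1, 99), "unknown node")
  expect_error(in_degree(g1, "zz"), "unknown node")
})

test_that("graph construction validates arcs and preserves parallels", {
  expect_error(omni_graph(2, tails = 1, heads = 3), "outside the node set")
  g <- omni_graph(2, tails = c(1, 1), heads = c(2, 2))
  expect_equal(n_arcs(g), 2L)
  expect_equal(out_degree(g, 1), 2L)
})

test_that("walk concatenation joins at matching endpoints and is associative", {
  g <- omni_graph(4, tails = c(1, 2, 3), heads = c(2, 3, 4))
  ab <- omni_walk(g, c(1, 2))
  bc <- omni_walk(g, c(2, 3))
  cd <- omni_walk(g, c(3, 4))
  expect_equal(walk_concat(ab, bc)$nodes, c(1L, 2L, 3L))
  expect_equal(walk_concat(omni_walk(g, 1), ab)$nodes, c(1L, 2L))
  expect_equal(walk_concat(ab, omni_walk(g, 2))$nodes, c(1L, 2L))
  expect_error(walk_concat(ab, cd), "HEAD")
  left <- walk_concat(walk_concat(ab, bc), cd)
  right <- walk_concat(ab, walk_concat(bc, cd))
  expect_identical(left, right)
})

test_that("walks store arcs disambiguating parallels and validate adjacency", {
  g <- omni_graph(2, tails = c(1, 1), heads = c(2, 2))
  expect_error(omni_walk(g, c(1, 2)), "ambiguous")
  w <- omni_walk(g, c(1, 2), arcs = 2)
  expect_equal(w$arcs, 2L)
  expect_error(omni_walk(g, c(2, 1)), "no arc")
  expect_error(omni_walk(g, c(1, 2), arcs = 1, circular = TRUE), "circular")
})

test_that("doubling produces mirror nodes and arcs with palindrome dedup", {
  bg0 <- bidigraph("x")
  d0 <- double_graph(bg0)
  expect_equal(n_nodes(d0), 2L)
  expect_equal(n_arcs(d0), 0L)

  bg <- bidigraph(c("x", "y"),
                  data.frame(from = "x", from_orient = "+",
                             to = "y", to_orient = "+"))
  d <- double_graph(bg)
  arcs <- paste(d$node_names[d$tails], d$node_names[d$heads], sep = ">")
  expect_setequal(arcs, c("x+>y+", "y->x-"))

  pal <- bidigraph("x", data.frame(from = "x", from_orient = "+",
                                   to = "x", to_orient = "-"))
  dp <- double_graph(pal)
  expect_equal(n_arcs(dp), 1L)
  expect_equal(dp$node_names[dp$tails], "x+")
  expect_equal(dp$node_names[dp$heads], "x-")

  expect_error(
    bidigraph("x", data.frame(from = "x", from_orient = "+",
                              to = "q", to_orient = "-")),
    "unknown segment")
})

test_that("doubled graphs satisfy mirror symmetry on random bidirected graphs", {
  for (s in 1:10) {
    dg <- double_graph(generate_random_bidigraph(6, 10, seed = s))
    for (a in seq_len(n_arcs(dg))) {
      ma <- dg$mirror_arc[a]
      expect_equal(dg$tails[ma], dg$mirror_node[dg$heads[a]])
      expect_equal(dg$heads[ma], dg$mirror_node[dg$tails[a]])
    }
    # in-degree of s+ equals out-degree of s-
    plus <- seq(1, n_nodes(dg), by = 2)
    expect_equal(dg$in_deg[plus], dg$out_deg[dg$mirror_node[plus]])
  }
})
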