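test_that("homopolymer compression collapses runs and is idempotent", {
  expect_equal(hpc_compress("AAATTTGGGC"), "ATGC")
  expect_equal(hpc_compress("ACGT"), "ACGT")
  expect_equal(hpc_compress(""), "")
  for (s in 1:20) {
    set.seed(s)
    x <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE,
                      prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
    h <- hpc_compress(x)
    expect_identical(hpc_compress(h), h)
    expect_lte(nchar(h), nchar(x))
  }
})

test_that("the homopolymer coordinate map is a run-start bijection", {
  m <- hpc_coordinate_map("AAATTG")
  expect_equal(m$comp_to_raw, c(0L, 3L, 5L))
  expect_equal(m$comp_to_raw[2L], 3L)  # compressed index 1 <-> raw index 3
  expect_equal(m$raw_to_comp[m$comp_to_raw + 1L],
               seq_along(m$comp_to_raw) - 1L)
  id <- hpc_coordinate_map("ACGT")
  expect_equal(id$comp_to_raw, 0:3)
  expect_equal(id$raw_to_comp, 0:3)
  empty <- hpc_coordinate_map("")
  expect_length(empty$comp_to_raw, 0L)
})

test_that("EAxmax reproduces the hand-worked per-base example", {
  aln <- alignment_records("r", c(0, 5), c(8, 10))
  prof <- eaxmax(aln, c(r = 10), x = c(50, 75, 90))
  expect_equal(prof$per_base$r, c(8, 8, 8, 8, 8, 8, 8, 8, 5, 5))
  expect_equal(prof$values$value, c(8, 8, 5))
})

test_that("EAxmax boundary behaviour: full coverage, no coverage, bad input", {
  full <- alignment_records("r", 0, 50)
  vals <- eaxmax(full, c(r = 50), x = c(0, 25, 50, 75, 99))$values$value
  expect_true(all(vals == 50))

  none <- eaxmax(alignment_records(character(0), integer(0), integer(0))[0, ],
                 c(r = 20), x = c(0, 50, 100))
  expect_true(all(none$values$value == 0))

  expect_error(eaxmax(alignment_records("r", 5, 30), c(r = 10)), "outside")
  expect_error(alignment_records("r", 5, 5), "start < end")
  expect_error(eaxmax(alignment_records("r", 0, 1), c(r = 0)), "positive")
})

test_that("eaxmax agrees with the literal per-base oracle on random instances", {
  xs <- c(0, 10, 25, 50, 75, 90, 100)
  for (s in 1:40) {
    case <- eaxmax_case(s)
    aln <- if (length(case$starts)) {
      alignment_records("r", case$starts, case$ends)
    } else {
      alignment_records(character(0), integer(0), integer(0))[0, ]
    }
    fast <- eaxmax(aln, c(r = case$G), x = xs)$values$value
    slow <- vapply(xs, function(x)
      eaxmax_bruteforce(case$starts, case$ends, case$G, x), numeric(1L))
    expect_equal(fast, slow)
    # monotone non-increasing in x
    expect_true(all(diff(fast) <= 0))
  }
})

test_that("adding a fully-overlapped shorter alignment never lowers EAxmax", {
  xs <- c(10, 50, 90)
  for (s in 1:10) {
    case <- eaxmax_case(100 + s)
    if (length(case$starts) == 0L) next
    base <- eaxmax(alignment_records("r", case$starts, case$ends),
                   c(r = case$G), x = xs)$values$value
    # duplicate the first record and add a shorter contained block
    st <- case$starts[1L]; en <- case$ends[1L]
    mid <- st + max(1L, (en - st) %/% 2L)
    aug <- eaxmax(alignment_records("r", c(case$starts, st, st),
                                    c(case$ends, en, mid)),
                  c(r = case$G), x = xs)$values$value
    expect_true(all(aug >= base))
    expect_equal(aug, base)  # max-based: duplicates change nothing
  }
})

test_that("misassembly merging respects the span guard and strict threshold", {
  cl1 <- merge_misassemblies(c(100, 2000, 5000, 5100), X = 3000)
  expect_equal(nrow(cl1), 2L)
  expect_equal(cl1$representative, c(100, 5000))
  expect_equal(cl1$n_members, c(2L, 2L))

  # non-transitive merging: 4000 is < 3000 from 2000 but >= 3000 from 0
  cl2 <- merge_misassemblies(c(0, 2000, 4000), X = 3000)
  expect_equal(nrow(cl2), 2L)
  expect_equal(cl2$representative, c(0, 4000))

  # strict inequality at the threshold
  cl3 <- merge_misassemblies(c(0, 3000), X = 3000)
  expect_equal(nrow(cl3), 2L)

  expect_true(all(cl1$span < 3000), all(cl2$span < 3000))
  expect_error(merge_misassemblies(c(-5, 10), X = 100), "non-negative")

  # unsorted input is sorted internally; references cluster separately
  df <- data.frame(ref = c("b", "a", "a"), pos = c(10, 500, 20))
  cl4 <- merge_misassemblies(df, X = 1000)
  expect_equal(nrow(cl4), 2L)
  expect_equal(sort(cl4$ref), c("a", "b"))
})

test_that("cluster spans stay below X on random position sets", {
  for (s in 1:15) {
    set.seed(s)
    pos <- sort(sample(0:100000, 60, replace = TRUE))
    cl <- merge_misassemblies(pos, X = 3000)
    expect_true(all(cl$span < 3000))
    expect_lte(nrow(cl), length(pos))
    expect_equal(sum(cl$n_members), length(pos))
  }
})
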