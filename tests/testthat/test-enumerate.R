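test_that("enumeration counts match brute-force isomorphism dedup", {
  expect_length(enumerate_connected(2), 1)
  expect_length(enumerate_connected(3), 2)
  expect_length(enumerate_connected(4), oracle_count_connected(4))
  expect_length(enumerate_connected(5), oracle_count_connected(5))
})

test_that("enumeration yields no duplicates and agrees with counting", {
  for (N in 4:6) {
    gs <- enumerate_connected(N)
    ids <- vapply(gs, canonical_id, 0)
    expect_false(anyDuplicated(ids) > 0)
    expect_length(gs, count_connected_unlabeled(N))
  }
  expect_error(enumerate_connected(9), "2 <= N <= 8")
})

test_that("closed-form counts reproduce the known sequence", {
  expect_equal(vapply(1:8, count_connected_unlabeled, 0),
               c(1, 1, 2, 6, 21, 112, 853, 11117))
})

test_that("canonical ids are isomorphism invariants that decode back", {
  expect_equal(canonical_id(moran_graph(rbind(c(1, 2)))), 3)
  expect_equal(canonical_id(graph_clique(3)), 15)
  set.seed(11)
  for (k in 1:12) {
    n <- sample(4:8, 1)
    g <- random_moran_graph(n)
    id <- canonical_id(g)
    for (rep in 1:8) { # random relabellings map to the same id
      p <- sample(n)
      h <- moran_graph(cbind(p[g$edges[, 1]], p[g$edges[, 2]]), n = n)
      expect_equal(canonical_id(h), id)
    }
    back <- graph_from_id(id)
    expect_equal(back$n, n)
    expect_true(igraph::isomorphic(evofix:::.as_igraph(back),
                                   evofix:::.as_igraph(g)))
  }
  expect_error(canonical_id(graph_cycle(11)), "orders up to 10")
})

test_that("a path on three vertices has exactly two pair-bits set", {
  id <- canonical_id(moran_graph(rbind(c(1, 2), c(2, 3))))
  bits <- as.integer(intToBits(id - 8))[1:3]
  expect_equal(sum(bits), 2)
})
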