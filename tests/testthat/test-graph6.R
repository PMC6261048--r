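test_that("graph6 encoding matches the standard format", {
  # reference strings computed with an independent implementation
  expect_equal(graph6_encode(graph_cycle(5)), "Dhc")
  expect_equal(graph6_encode(graph_clique(4)), "C~")
  expect_equal(graph6_encode(graph_star(6)), "Esa?")
  expect_equal(graph6_encode(graph_ell(6, 2, 2)), "E~ow")
  expect_equal(graph6_encode(moran_graph(rbind(c(1, 2), c(2, 3)))), "Bg")
})

test_that("graph6 round-trips arbitrary small graphs", {
  set.seed(7)
  for (k in 1:25) {
    g <- random_moran_graph(sample(2:12, 1))
    h <- graph6_decode(graph6_encode(g))
    expect_equal(h$edges, g$edges)
    expect_equal(h$n, g$n)
  }
})

test_that("graph6 and edge-list files round-trip", {
  gs <- list(graph_cycle(4), graph_ell(6, 2, 2), graph_star(3))
  f <- tempfile()
  write_graph6(gs, f)
  back <- read_graph6(f)
  expect_equal(lapply(back, `[[`, "edges"), lapply(gs, `[[`, "edges"))

  f2 <- tempfile()
  write_edgelist(gs[[2]], f2)
  cat("# a comment\n\n", file = f2, append = TRUE)
  g2 <- read_edgelist(f2)
  expect_equal(g2$edges, gs[[2]]$edges)
})

test_that("malformed input is rejected", {
  expect_error(graph6_decode("~~~"), "malformed|unsupported")
  f <- tempfile()
  writeLines("1 2 3", f)
  expect_error(read_edgelist(f), "malformed")
})
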