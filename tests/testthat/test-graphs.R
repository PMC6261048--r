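test_that("graph construction validates simplicity and connectivity", {
  expect_error(moran_graph(rbind(c(1, 1))), "self-loops")
  expect_error(moran_graph(rbind(c(1, 2), c(2, 1))), "multi-edges")
  expect_error(moran_graph(rbind(c(1, 2), c(3, 4))), "disconnected")
  expect_error(moran_graph(rbind(c(1, 2)), n = 3), "disconnected")
  g <- moran_graph(rbind(c(2, 1), c(3, 2)))
  expect_equal(g$edges, cbind(c(1L, 2L), c(2L, 3L)))
  expect_equal(degrees(g), c(1L, 2L, 1L))
})

test_that("family constructors produce the documented structures", {
  ell6 <- graph_ell(6, 2, 2)
  expect_equal(nrow(ell6$edges), 11)
  # u and v: adjacent to each other and to their disjoint pairs
  expect_equal(sort(ell6$adj[[5]]), c(1, 2, 6))
  expect_equal(sort(ell6$adj[[6]]), c(3, 4, 5))

  fc <- graph_friendship_cycle(7, 2)
  expect_equal(nrow(fc$edges), 10)
  expect_equal(degrees(fc)[7], 4) # centre joined to two disjoint pairs
  # the two centre-attached pairs are opposite on the 6-cycle
  expect_equal(sort(fc$adj[[7]]), c(1, 2, 4, 5))

  st <- graph_star(3)
  expect_equal(st$edges, cbind(c(1L, 1L), c(2L, 3L)))

  kb <- graph_complete_bipartite(2, 3)
  expect_equal(nrow(kb$edges), 6)
  expect_true(all(degrees(kb) == c(3, 3, 2, 2, 2)))

  fr <- graph_friendship_ribbon(10, 6)
  expect_equal(fr$n, 10)
  # no vertex lies in more than two triangles
  A <- matrix(0, 10, 10); A[fr$edges] <- 1; A <- A + t(A)
  per_vertex <- vapply(1:10, function(v) {
    nb <- which(A[v, ] > 0)
    sum(A[nb, nb]) / 2
  }, 0)
  expect_true(all(per_vertex <= 2))
  expect_equal(sum(diag(A %*% A %*% A)) / 6, 6) # exactly m = 6 triangles
})

test_that("invalid family parameters are rejected with the constraint named", {
  expect_error(graph_ell(6, 3, 2), "n \\+ m <= N - 2")
  expect_error(graph_ell(4, 1, 1), "N >= 5")
  expect_error(graph_ell(6, 0, 2), "n >= 1")
  expect_error(graph_friendship_cycle(7, 4), "2m <= N - 1")
  expect_error(graph_friendship_star(7, 3), "even")
  expect_error(graph_friendship_star(8, 4), "N = 3m/2 \\+ 1")
  expect_error(graph_friendship_ribbon(10, 5), "even")
})

test_that("ell-graph attachment choice does not matter up to isomorphism", {
  # attach u and v to different disjoint pairs of the clique: the clique is
  # vertex-transitive, so the result must be isomorphic to the standard one
  k <- t(combn(4, 2))
  alt <- moran_graph(rbind(k, c(5, 6), c(5, 2), c(5, 4), c(6, 1), c(6, 3)))
  expect_equal(canonical_id(alt), canonical_id(graph_ell(6, 2, 2)))
})

test_that("temperatures are exact and sum to the order", {
  st <- temperatures(graph_star(5))
  expect_equal(format(st), c("4", "1/4", "1/4", "1/4", "1/4"))
  expect_true(all(as.numeric(temperatures(graph_cycle(6))) == 1))
  # ell7 vertex u: neighbours v (degree 3) and two K5 vertices (degree 5)
  tu <- temperatures(graph_ell(7, 2, 2))[6]
  expect_true(tu == rational(11, 15)) # 1/3 + 2/5
  # ell6 vertex u: neighbour v (degree 3) and two K4 vertices (degree 4)
  expect_true(temperatures(graph_ell(6, 2, 2))[5] == rational(5, 6))
  set.seed(42)
  for (k in 1:20) {
    g <- random_moran_graph(sample(3:9, 1))
    expect_true(sum(temperatures(g)) == rational(g$n))
  }
})

test_that("isothermal detection equals regularity", {
  expect_true(is_isothermal(graph_cycle(7)))
  expect_true(is_isothermal(graph_clique(5)))
  expect_false(is_isothermal(graph_star(4)))
  expect_false(is_isothermal(graph_ell(6, 2, 2)))
  # order-7 4-regular graphs: brute-force enumeration finds exactly two
  quartic <- Filter(function(g) all(degrees(g) == 4), enumerate_connected(7))
  expect_length(quartic, 2)
  expect_true(all(vapply(quartic, is_isothermal, TRUE)))
})

test_that("weight matrix rows are stochastic", {
  g <- graph_ell(6, 2, 2)
  W <- weight_matrix(g)
  expect_equal(rowSums(W), rep(1, 6))
  We <- weight_matrix(g, exact = TRUE)
  expect_equal(We[1, 2], "1/4") # clique vertices of ell6 have degree 4
  expect_equal(weight_matrix(graph_ell(7, 2, 2), exact = TRUE)[1, 2], "1/5")
})

test_that("exact rational vectors behave arithmetically", {
  x <- rational(c(1, 2), c(3, 4))
  expect_equal(format(x + rational(1, 12)), c("5/12", "7/12"))
  expect_true(rational(2, 4) == rational(1, 2))
  expect_equal(as.numeric(rational(-3, -6)), 0.5)
  expect_error(rational(1, 0), "zero denominator")
  # doubles are accepted when a small fraction reproduces them bit-exactly
  expect_true(as.numeric(as_rational(1 / 3)) == 1 / 3)
  expect_true(as_rational("7/3") / as_rational(7) == rational(1, 3))
})
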