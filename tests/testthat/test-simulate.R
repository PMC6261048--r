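test_that("simulation is reproducible under a fixed seed", {
  g <- graph_ell(6, 2, 2)
  a <- estimate_fixation(g, 2, runs = 3000, seed = 42)
  b <- estimate_fixation(g, 2, runs = 3000, seed = 42)
  expect_identical(a$fixations, b$fixations)
  expect_identical(a$per_vertex, b$per_vertex)
  c_ <- estimate_fixation(g, 2, runs = 3000, seed = 43)
  expect_false(identical(a$fixations, c_$fixations))
})

test_that("estimates agree with closed forms within 3.29 standard errors", {
  g2 <- moran_graph(rbind(c(1, 2)))
  est <- estimate_fixation(g2, 2, runs = 1e5, seed = 1)
  expect_lt(abs(est$estimate - 2 / 3), 3.29 * est$std_error)

  # neutral drift on an arbitrary graph fixes with probability 1/N
  set.seed(2)
  g <- random_moran_graph(5)
  est <- estimate_fixation(g, 1, runs = 4e4, seed = 3)
  expect_lt(abs(est$estimate - 1 / 5), 3.29 * est$std_error)
})

test_that("estimates agree with the exact solver", {
  g <- graph_ell(6, 2, 2)
  exact <- solve_fixation(g, 2)$average
  est <- estimate_fixation(g, 2, runs = 1e5, seed = 7)
  expect_lt(abs(est$estimate - exact), 3.29 * est$std_error)
})

test_that("per-vertex conditional frequencies match solver singletons", {
  g <- graph_star(3)
  sol <- solve_fixation(g, 2)
  est <- estimate_fixation(g, 2, runs = 6e4, seed = 11)
  for (v in 1:3) {
    pv <- est$per_vertex[v, ]
    se <- sqrt(sol$singles[v] * (1 - sol$singles[v]) / pv$runs)
    expect_lt(abs(pv$estimate - sol$singles[v]), 3.29 * se)
  }
})

test_that("fixed initial subsets are honoured", {
  # two mutants in K3: classical birth-death gives (1 - r^-2)/(1 - r^-3)
  g <- graph_clique(3)
  est <- estimate_fixation(g, 2, runs = 4e4, seed = 5, initial = c(1, 2))
  expect_null(est$per_vertex)
  expect_lt(abs(est$estimate - 6 / 7), 3.29 * est$std_error)
  expect_error(estimate_fixation(g, 2, initial = 1:3), "at least one resident")
  expect_error(estimate_fixation(g, 2, initial = 5), "out of range")
  expect_error(estimate_fixation(g, -1), "positive")
})
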