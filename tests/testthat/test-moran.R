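test_that("transition rows implement the replacement rule exactly", {
  # K2 from {1}: gain with r/(r+1), extinction with 1/(r+1)
  tr <- transition_row(moran_graph(rbind(c(1, 2))), S = 1, r = "2")
  expect_equal(tr$prob[tr$change == "gain 2"], 2 / 3)
  expect_equal(tr$prob[tr$change == "loss 1"], 1 / 3)
  expect_false("self" %in% tr$change)

  # star on 3 vertices from the centre at r = 2: each leaf gained with 1/4,
  # extinction 1/2, no self-loop (leaves are not adjacent)
  tr <- transition_row(graph_star(3), S = 1, r = 2)
  expect_equal(tr$num[grepl("gain", tr$change)] / tr$den[grepl("gain", tr$change)],
               c(1 / 4, 1 / 4))
  expect_equal(tr$prob[tr$change == "loss 1"], 1 / 2)
  expect_false("self" %in% tr$change)

  expect_error(transition_row(graph_star(3), S = 1, r = "-1"), "positive")
})

test_that("transition rows are exactly stochastic for random configurations", {
  set.seed(101)
  for (k in 1:60) {
    n <- sample(3:7, 1)
    g <- random_moran_graph(n)
    s <- sample(1:(2^n - 2), 1)
    r <- rational(sample(1:9, 1), sample(1:4, 1))
    tr <- transition_row(g, S = which(bitwAnd(s, 2^(0:(n - 1))) > 0), r = r)
    expect_true(sum(rational(tr$num, tr$den)) == rational(1))
  }
})

test_that("the cleared polynomial system satisfies row-stochasticity", {
  set.seed(5)
  for (k in 1:10) {
    g <- random_moran_graph(sample(3:7, 1))
    expect_true(evofix:::.check_system(build_polynomial_system(g)))
    expect_true(evofix:::.check_system(build_polynomial_system(g, subset_orbits(g))))
  }
  # K2: the orbit-reduced cleared system is 1 x 1, (r + 1) Phi = r
  g2 <- moran_graph(rbind(c(1, 2)))
  sys <- build_polynomial_system(g2, subset_orbits(g2))
  expect_equal(unname(sys$A0[1, 1]), 1)
  expect_equal(unname(sys$A1[1, 1]), 1)
  expect_equal(sys$c0, 0)
  expect_equal(sys$c1, 1)
})

test_that("K2 fixation matches the closed form r/(r+1)", {
  g <- moran_graph(rbind(c(1, 2)))
  for (r in c("2", "3", "1/2", "7/5")) {
    got <- solve_fixation(g, r, mode = "exact")$average_frac
    rr <- as_rational(r)
    want <- as.character(rr / (rr + 1))
    expect_rat_equal(got, want)
  }
})

test_that("neutral mutants fix with probability 1/N exactly", {
  set.seed(9)
  gs <- c(list(graph_star(5), graph_ell(6, 2, 2)),
          lapply(1:5, function(k) random_moran_graph(sample(3:7, 1))))
  for (g in gs) {
    got <- solve_fixation(g, "1", mode = "exact")$average_frac
    expect_rat_equal(got, sprintf("1/%d", g$n))
  }
})

test_that("regular graphs have exactly the homogeneous fixation probability", {
  regs <- list(graph_cycle(5), graph_cycle(8), graph_clique(5),
               graph_clique(7), graph_complete_bipartite(3, 3))
  regs <- c(regs, Filter(function(g) all(degrees(g) == 4),
                         enumerate_connected(7)))
  for (g in regs) {
    for (r in c("2", "3", "1/2")) {
      got <- solve_fixation(g, r, mode = "exact", reduce = TRUE)$average_frac
      expect_rat_equal(got, phi0(g$n, r))
    }
  }
})

test_that("solver agrees with an independently built chain", {
  st <- solve_fixation(graph_star(3), 2)
  or <- oracle_fixation(graph_star(3), 2)
  expect_equal(st$average, or$average, tolerance = 1e-12)
  expect_equal(st$singles, or$singles, tolerance = 1e-12)
  set.seed(31)
  for (k in 1:6) {
    g <- random_moran_graph(sample(3:6, 1))
    r <- runif(1, 0.3, 6)
    expect_equal(solve_fixation(g, r)$average, oracle_fixation(g, r)$average,
                 tolerance = 1e-10)
  }
})

test_that("exact and float modes agree closely across orders and fitnesses", {
  for (g in enumerate_connected(4)) {
    for (r in c(0.25, 0.5, 2, 10)) {
      rf <- c("0.25" = "1/4", "0.5" = "1/2", "2" = "2", "10" = "10")[as.character(r)]
      ex <- solve_fixation(g, unname(rf), mode = "exact")$average
      fl <- solve_fixation(g, r)$average
      expect_equal(fl, ex, tolerance = 1e-10)
    }
  }
  set.seed(77)
  for (k in 1:4) {
    g <- random_moran_graph(6)
    ex <- solve_fixation(g, "7/2", mode = "exact")$average
    expect_equal(solve_fixation(g, 3.5)$average, ex, tolerance = 1e-10)
  }
})

test_that("high-precision mode renders exact decimals", {
  out <- solve_fixation(moran_graph(rbind(c(1, 2))), "2", mode = "highprec",
                        digits = 40)
  expect_match(out$average_decimal, "^6\\.6{30,}7e-1$")
})

test_that("invalid fitness and sizes error cleanly", {
  g <- graph_star(3)
  expect_error(solve_fixation(g, 0), "positive")
  expect_error(solve_fixation(g, "0"), "positive")
  expect_error(build_polynomial_system(graph_cycle(13)), "too large")
})
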