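test_that("interpolated curves reproduce closed forms", {
  f <- interpolate_fixation(moran_graph(rbind(c(1, 2))))
  expect_equal(f$num, c("0", "1")) # r / (1 + r)
  expect_equal(f$den, c("1", "1"))
  for (N in 3:5)
    expect_true(rf_equal(interpolate_fixation(graph_clique(N)), phi0_fun(N)))
  for (N in c(4, 6, 8))
    expect_true(rf_equal(interpolate_fixation(graph_cycle(N)), phi0_fun(N)))
})

test_that("interpolants agree with exact solves at held-out points", {
  gs <- list(graph_star(3), graph_star(5), graph_ell(6, 2, 2),
             graph_complete_bipartite(2, 3))
  for (g in gs) {
    f <- interpolate_fixation(g)
    for (r in c("13/3", "29/2", "101")) {
      expect_rat_equal(rf_eval(f, r, exact = TRUE),
                       solve_fixation(g, r, mode = "exact")$average_frac)
    }
  }
})

test_that("curve degree is bounded by the orbit count and limits are right", {
  set.seed(23)
  gs <- c(list(graph_star(4), graph_ell(6, 2, 2)),
          lapply(1:3, function(k) random_moran_graph(5)))
  for (g in gs) {
    f <- interpolate_fixation(g)
    expect_lte(f$degree, orbit_reduce(g)$n_orbits)
    expect_lte(f$degree, 2^g$n - 2)
    # Phi(1) = 1/N and Phi -> 1 as r -> Inf (equal leading coefficients)
    expect_rat_equal(rf_eval(f, "1", exact = TRUE), sprintf("1/%d", g$n))
    expect_length(f$num, f$degree + 1)
    expect_length(f$den, f$degree + 1)
    expect_rat_equal(f$num[f$degree + 1], f$den[f$degree + 1])
    # denominator has no poles on (0, Inf)
    expect_equal(evofix:::cpp_count_roots_pos(f$den), 0)
  }
})

test_that("rational-function arithmetic is exact and canonical", {
  f <- ratfun(c(0, 1), c(1, 1)) # r/(1+r)
  expect_true(rf_is_zero(rf_sub(f, f)))
  expect_rat_equal(rf_eval(f, "1", exact = TRUE), "1/2")
  # (r/(1+r))' = 1/(1+r)^2
  expect_true(rf_equal(rf_deriv(f), ratfun(1, c(1, 2, 1))))
  # products reduce to coprime canonical form
  g <- rf_mul(f, ratfun(c(1, 1), 1)) # (r/(1+r)) * (1+r) = r
  expect_equal(g$num, c("0", "1"))
  expect_equal(g$den, "1")
  # second derivative of the N = 3 homogeneous curve is negative at r = 2
  d2 <- rf_deriv(phi0_fun(3), 2)
  expect_lt(rf_eval(d2, 2), 0)
  expect_error(rf_eval(ratfun(1, c(-2, 1)), "2"), "pole")
})

test_that("a supplied degree bound that is too large still converges", {
  f <- interpolate_fixation(graph_clique(4), degree_bound = 9)
  expect_true(rf_equal(f, phi0_fun(4)))
  expect_equal(f$degree, 3)
})
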