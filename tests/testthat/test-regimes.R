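test_that("reference curves take their known values", {
  expect_equal(phi0(3, 2), 4 / 7)
  expect_rat_equal(phi0(3, "2"), "4/7")
  expect_equal(phi0(2, 2), 2 / 3)
  expect_equal(phi0(c(5), 1), 1 / 5)
  expect_equal(phi2(4, 3), phi0(4, 9))
  expect_rat_equal(rf_eval(phi0_fun(2), "2", exact = TRUE), "2/3")
  # phi2 as a rational function equals phi0 evaluated at r^2
  expect_equal(rf_eval(phi2_fun(5), 1.7), phi0(5, 1.7^2), tolerance = 1e-12)
  expect_true(all(diff(phi0(6, seq(0.2, 8, 0.2))) > 0)) # strictly increasing
})

test_that("isothermal and family classifications are certified", {
  expect_equal(classify(graph_cycle(5))$classification, "isothermal")
  expect_equal(classify(graph_clique(6))$classification, "isothermal")

  p6 <- classify(graph_ell(6, 2, 2))
  expect_equal(p6$classification, "suppressor")
  expect_equal(p6$method, "exact")
  expect_equal(nrow(p6$transitions), 0)

  p <- classify(graph_ell(7, 2, 2))
  expect_equal(p$classification, "S/A")
  expect_equal(p$transitions$r_c, 5.1761, tolerance = 1e-4)

  expect_equal(classify(graph_star(4))$classification, "amplifier")
})

test_that("friendship graphs of order 7 lose their amplification at the known fitnesses", {
  p <- classify(graph_friendship_cycle(7, 2))
  expect_equal(p$classification, "A/S")
  expect_equal(p$transitions$r_c, 4.9881, tolerance = 1e-4)
  p <- classify(graph_friendship_star(7, 4))
  expect_equal(p$classification, "A/S")
  expect_equal(p$transitions$r_c, 24.797, tolerance = 1e-4)
})

test_that("transition isolation separates odd and even multiplicity", {
  D <- rf_sub(phi0_fun(5), phi0_fun(5))
  tr <- isolate_transitions(D)
  expect_equal(nrow(tr), 0)
  expect_true(attr(tr, "isothermal"))

  # numerator (r-2)^2 (r^2+1): a tangency at 2, no transition
  num <- evofix:::cpp_poly_arith(
    evofix:::cpp_poly_arith(c("4", "-4", "1"), c("1", "0", "1"), "*"),
    "1", "*")
  tr <- isolate_transitions(ratfun(num, "1"))
  expect_equal(nrow(tr), 0)
  roots <- attr(tr, "all_roots")
  expect_equal(nrow(roots), 1)
  expect_equal(roots$r_c, 2, tolerance = 1e-6)
  expect_false(roots$transition)

  # numerator (r-2)(r-3): two genuine alternating transitions
  tr <- isolate_transitions(ratfun(c("6", "-5", "1"), "1"))
  expect_equal(round(tr$r_c, 6), c(2, 3))
  expect_equal(tr$direction, c("A/S", "S/A"))
})

test_that("numeric scan matches exact signs on random graphs", {
  set.seed(19)
  for (k in 1:8) {
    g <- random_moran_graph(sample(4:6, 1))
    if (is_isothermal(g)) next
    D <- rf_sub(interpolate_fixation(g), phi0_fun(g$n))
    sys <- build_polynomial_system(g, subset_orbits(g))
    for (r in round(runif(5, 1.1, 9.9), 3)) {
      dv <- evofix:::.solve_sys(sys, r)$average - phi0(g$n, r)
      exact_sign <- evofix:::cpp_poly_eval(D$num, evofix:::.rationalize(r))$sign
      if (abs(dv) > 1e-11) expect_equal(sign(dv), exact_sign)
    }
  }
})

test_that("scan classification flags apparent results but finds transitions", {
  p <- classify(graph_ell(7, 1, 4), method = "scan")
  expect_match(p$method, "numeric-scan")
  expect_equal(p$classification, "S/A")
  expect_equal(p$transitions$r_c, 1.8046, tolerance = 1e-3)
})

test_that("star and bipartite fixation sits strictly between phi0 and phi2", {
  for (N in 3:12) {
    g <- graph_star(N)
    for (r in c(1.5, 2, 5, 10)) {
      phi <- solve_fixation(g, r, reduce = TRUE)$average
      expect_gt(phi, phi0(N, r))
      expect_lt(phi, phi2(N, r))
    }
  }
  for (ab in list(c(2, 3), c(3, 4), c(2, 5))) {
    g <- graph_complete_bipartite(ab[1], ab[2])
    for (r in c(1.5, 2, 5)) {
      phi <- solve_fixation(g, r, reduce = TRUE)$average
      expect_gt(phi, phi0(g$n, r))
      expect_lt(phi, phi2(g$n, r))
    }
  }
})

test_that("fixation increases with fitness on every tested graph", {
  set.seed(3)
  gs <- c(list(graph_ell(6, 2, 2), graph_star(5)),
          lapply(1:4, function(k) random_moran_graph(sample(4:6, 1))))
  rs <- seq(0.25, 10, 0.25)
  for (g in gs) {
    sys <- build_polynomial_system(g, subset_orbits(g))
    vals <- vapply(rs, function(r) evofix:::.solve_sys(sys, r)$average, 0)
    expect_true(all(diff(vals) > 0))
  }
})

test_that("phi0 is concave on (1, Inf) exactly for N <= 5", {
  for (N in 2:5) {
    cc <- phi0_concavity(N)
    expect_true(cc$concave)
    expect_null(cc$witness)
  }
  for (N in 6:8) {
    cc <- phi0_concavity(N)
    expect_false(cc$concave)
    # the witness certifies convexity near r = 1
    d2 <- rf_deriv(phi0_fun(N), 2)
    expect_equal(evofix:::cpp_poly_eval(d2$num, cc$witness)$sign, 1)
    expect_lt(evofix:::cpp_rat_to_double(cc$witness), 1.6)
  }
})
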