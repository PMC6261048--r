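test_that("orbit counts match the known structure of symmetric families", {
  # star: orbits are (centre occupied?, number of occupied leaves)
  for (N in 3:6)
    expect_equal(orbit_reduce(graph_star(N))$n_orbits, 2 * N - 2)
  # clique: orbits are the subset sizes
  for (N in 3:6)
    expect_equal(orbit_reduce(graph_clique(N))$n_orbits, N - 1)
  # cycle: orbits are binary necklaces (dihedral), minus the two absorbers
  for (N in 4:7)
    expect_equal(orbit_reduce(graph_cycle(N))$n_orbits,
                 oracle_dihedral_orbits(N) - 2)
})

test_that("the orbit partition is lumpable for the transition polynomials", {
  set.seed(13)
  gs <- c(list(graph_ell(6, 2, 2), graph_star(5), graph_friendship_cycle(7, 2)),
          lapply(1:4, function(k) random_moran_graph(sample(4:6, 1))))
  for (g in gs)
    expect_true(evofix:::.check_lumpable(g, subset_orbits(g)))
})

test_that("reduced and full solves agree exactly", {
  gs <- list(graph_star(6), graph_cycle(6), graph_ell(6, 2, 2),
             graph_friendship_cycle(7, 2), graph_ell(7, 2, 3))
  for (g in gs) {
    for (r in c("2", "7/3")) {
      full <- solve_fixation(g, r, mode = "exact", reduce = FALSE)
      red <- solve_fixation(g, r, mode = "exact", reduce = TRUE)
      expect_rat_equal(full$average_frac, red$average_frac)
      expect_rat_equal(full$singles_frac, red$singles_frac)
    }
  }
  # every subset's fixation probability expands correctly from its orbit
  g <- graph_star(4)
  ored <- orbit_reduce(g)
  full <- solve_fixation(g, "3", mode = "exact", reduce = FALSE)
  red <- evofix:::.solve_sys(ored$system, "3", "exact")
  for (s in 1:(2^g$n - 2)) {
    expect_rat_equal(full$psi_frac[s],
                     red$psi_frac[ored$system$col_of[s + 1]])
  }
})

test_that("trivial automorphism groups leave the system unreduced", {
  # an asymmetric graph: orbit count equals the full state count
  g <- moran_graph(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6),
                         c(1, 3), c(3, 6), c(2, 6)))
  expect_length(graph_automorphisms(g), 0)
  expect_equal(orbit_reduce(g)$n_orbits, 2^g$n - 2)
})
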