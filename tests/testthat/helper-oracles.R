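# Independent oracles used across the test files.  These deliberately avoid
# the package's cleared-polynomial machinery: the chain is built directly
# from its probabilistic definition in plain floating point.

# random connected graph on n vertices (random spanning tree plus extra
# edges), as an edge matrix
random_connected_edges <- function(n, extra = n) {
  e <- cbind(2:n, vapply(2:n, function(v) sample.int(v - 1, 1), 0L))
  all_pairs <- t(combn(n, 2))
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  pool <- all_pairs[!(key(all_pairs) %in% key(e)), , drop = FALSE]
  if (extra > 0 && nrow(pool) > 0) {
    take <- sample.int(nrow(pool), min(extra, nrow(pool)))
    e <- rbind(e, pool[take, , drop = FALSE])
  }
  e
}

random_moran_graph <- function(n, extra = n) {
  moran_graph(random_connected_edges(n, extra), n = n)
}

# brute-force average fixation probability: build the full 2^n transition
# matrix straight from the replacement rule and solve the hitting system
oracle_fixation <- function(g, r) {
  n <- g$n
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, g$adj[[i]]] <- 1 / g$degree[i]
  ns <- 2^n
  P <- matrix(0, ns, ns)
  for (s in 0:(ns - 1)) {
    memb <- bitwAnd(s, 2^(0:(n - 1))) > 0
    k <- sum(memb)
    if (k == 0 || k == n) { P[s + 1, s + 1] <- 1; next }
    wS <- r * k + n - k
    for (j in which(!memb)) # gain j
      P[s + 1, s + 2^(j - 1) + 1] <- r * sum(W[memb, j]) / wS
    for (j in which(memb)) # lose j
      P[s + 1, s - 2^(j - 1) + 1] <- sum(W[!memb, j]) / wS
    P[s + 1, s + 1] <- (r * sum(W[memb, memb]) + sum(W[!memb, !memb])) / wS
  }
  trans <- 2:(ns - 1)
  Q <- P[trans, trans]
  cvec <- P[trans, ns]
  psi <- solve(diag(length(trans)) - Q, cvec)
  singles <- psi[match(2^(0:(n - 1)), trans - 1)]
  list(average = mean(singles), singles = singles, psi = psi)
}

# brute-force dedup of all connected labeled graphs on n vertices with
# igraph isomorphism tests (independent of the package's augmentation)
oracle_count_connected <- function(n) {
  pairs <- t(combn(n, 2))
  reps <- list()
  for (mask in 1:(2^nrow(pairs) - 1)) {
    sel <- bitwAnd(mask, 2^(0:(nrow(pairs) - 1))) > 0
    ig <- igraph::graph_from_edgelist(pairs[sel, , drop = FALSE],
                                      directed = FALSE)
    if (igraph::vcount(ig) < n)
      ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
    if (!igraph::is_connected(ig)) next
    found <- FALSE
    for (h in reps) if (igraph::isomorphic(ig, h)) { found <- TRUE; break }
    if (!found) reps[[length(reps) + 1]] <- ig
  }
  length(reps)
}

# number of binary necklaces of length n under the dihedral group, counted
# by brute force over all bitmasks (independent orbit oracle for cycles)
oracle_dihedral_orbits <- function(n) {
  seen <- rep(FALSE, 2^n)
  count <- 0
  rot <- function(s, k) bitwOr(bitwShiftL(s, k) %% 2^n, bitwShiftR(s, n - k))
  refl <- function(s) { # reverse bit order
    b <- as.integer(bitwAnd(s, 2^(0:(n - 1))) > 0)
    sum(rev(b) * 2^(0:(n - 1)))
  }
  for (s in 0:(2^n - 1)) {
    if (seen[s + 1]) next
    count <- count + 1
    for (k in 0:(n - 1)) {
      t1 <- rot(s, k)
      seen[t1 + 1] <- TRUE
      seen[refl(t1) + 1] <- TRUE
    }
  }
  count
}

rat_cmp <- function(a, b) evofix:::cpp_rat_cmp(a, b)

expect_rat_equal <- function(a, b) {
  expect_true(all(rat_cmp(a, b) == 0L), label = paste(a, "==", b))
}
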