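# Automorphism-orbit reduction of the subset state space.
#
# The automorphism group of the graph acts on mutant configurations; the
# Moran chain is lumpable with respect to the orbit partition (vertex
# permutations commute with the transition kernel), so the fixation system
# can be solved on orbit representatives and expanded back exactly.

#' Automorphism group generators
#'
#' @param g a [moran_graph].
#' @return A list of vertex permutations (integer vectors) generating the
#'   automorphism group (empty for the trivial group).
#' @export
graph_automorphisms <- function(g) {
  stopifnot(inherits(g, "moran_graph"))
  gens <- igraph::automorphism_group(.as_igraph(g))
  lapply(gens, function(p) as.integer(p))
}

#' Orbits of mutant configurations
#'
#' Partitions all `2^n` subset encodings into orbits under the
#' automorphism group acting vertexwise.
#'
#' @param g a [moran_graph] (or a list of permutations from
#'   [graph_automorphisms()] via `gens`).
#' @param gens optional generator list, computed from `g` if missing.
#' @return Integer vector of length `2^n`: the orbit label (1-based, dense)
#'   of each subset encoding `0 .. 2^n - 1`, in encoding order.
#' @export
subset_orbits <- function(g, gens = NULL) {
  stopifnot(inherits(g, "moran_graph"))
  n <- g$n
  if (n > 16) stop("subset orbits supported up to order 16")
  if (is.null(gens)) gens <- graph_automorphisms(g)
  full <- 2^n - 1
  ids <- 0:full
  B <- matrix(0, 2^n, n)
  for (i in 1:n) B[, i] <- bitwAnd(ids, 2^(i - 1)) > 0
  imgs <- lapply(gens, function(p) as.vector(B %*% 2^(p - 1)))
  lab <- ids
  repeat {
    old <- lab
    for (img in imgs) {
      lab <- pmin(lab, lab[img + 1])
      lab[img + 1] <- pmin(lab[img + 1], lab)
    }
    lab <- lab[lab + 1] # path compression
    if (identical(lab, old)) break
  }
  match(lab, sort(unique(lab)))
}

#' Orbit reduction of the fixation system
#'
#' Builds the fixation system on subset orbits.  Solving the reduced system
#' and expanding by orbit membership reproduces the full solution exactly.
#'
#' @param g a [moran_graph].
#' @return A list with `orbit_of` (label per subset encoding),
#'   `representatives` (minimal encoding per non-absorbing orbit),
#'   `n_orbits` (non-absorbing count) and `system` (the reduced
#'   [build_polynomial_system()] output).
#' @examples
#' orbit_reduce(graph_star(5))$n_orbits # 2 * 5 - 2 orbits
#' @export
orbit_reduce <- function(g) {
  orbit_of <- subset_orbits(g)
  sys <- build_polynomial_system(g, orbit_of)
  list(orbit_of = orbit_of, representatives = sys$states,
       n_orbits = length(sys$states), system = sys)
}

# internal test hook: verify lumpability of the transition polynomials --
# any two states of an orbit must have identical summed transition
# polynomials into every other orbit
.check_lumpable <- function(g, orbit_of, max_orbits = Inf) {
  n <- g$n
  full <- 2^n - 1
  sysf <- build_polynomial_system(g)
  labs <- sort(unique(orbit_of))
  for (o in head(labs, max_orbits)) {
    members <- which(orbit_of == o) - 1
    members <- members[members != 0 & members != full]
    if (length(members) < 2) next
    rowsum_of <- function(s) {
      row <- sysf$col_of[s + 1]
      t0 <- tapply(c(sysf$A0[row, ], sysf$b0[row], sysf$c0[row]),
                   c(orbit_of[sysf$states + 1], orbit_of[1], orbit_of[full + 1]), sum)
      t1 <- tapply(c(sysf$A1[row, ], sysf$b1[row], sysf$c1[row]),
                   c(orbit_of[sysf$states + 1], orbit_of[1], orbit_of[full + 1]), sum)
      list(t0, t1)
    }
    ref <- rowsum_of(members[1])
    for (s in members[-1])
      if (!identical(ref, rowsum_of(s))) return(FALSE)
  }
  TRUE
}
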