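# The subset-state Moran chain and its fixation linear system.
#
# States are vertex subsets encoded as N-bit integers (bit i-1 <=> vertex i
# mutant).  For a state S the total reproductive weight is
# w_S(r) = r|S| + N - |S|; multiplying the hitting-probability equation of
# each non-absorbing state by w_S(r) clears all denominators, leaving a
# square system whose entries are degree-one polynomials in r.  Scaling
# every row by L = lcm of the vertex degrees makes all coefficients
# integers, so the system is stored as two integer matrices:
#   (A0 + r A1) Psi = c0 + r c1,
# with b0 + r b1 (the extinction column) kept for validation.

.lcm_vec <- function(x) Reduce(function(a, b) a * b / .gcd2(a, b), x)

.state_members <- function(s, n) which(bitwAnd(s, 2^(0:(n - 1))) > 0)

.encode_subset <- function(vertices, n) {
  if (any(vertices < 1 | vertices > n)) stop("vertex out of range")
  sum(2^(unique(vertices) - 1))
}

#' Build the cleared polynomial fixation system
#'
#' Assembles the linear system for the fixation probabilities of all
#' non-absorbing mutant configurations (or of their automorphism orbits
#' when `orbit_of` is supplied).  All entries are degree-one polynomials in
#' the fitness with integer coefficients.
#'
#' @param g a [moran_graph].
#' @param orbit_of optional integer vector of length `2^n` assigning an
#'   orbit label to every subset encoding (from [subset_orbits()]); rows
#'   and columns then index orbits instead of subsets.
#' @return An object of class `moran_system` with integer matrices `A0`,
#'   `A1`, vectors `c0`, `c1` (fixation column), `b0`, `b1` (extinction
#'   column), the row representative encodings `states`, and `col_of`
#'   mapping every subset encoding (offset by one) to its column.
#' @export
build_polynomial_system <- function(g, orbit_of = NULL) {
  stopifnot(inherits(g, "moran_graph"))
  n <- g$n
  if (is.null(orbit_of) && n > 12)
    stop("full state space 2^", n, " is too large; ",
         "use orbit reduction (orbit_reduce) or the numeric scan")
  full <- 2^n - 1
  L <- .lcm_vec(g$degree)
  invdeg <- L / g$degree
  A <- matrix(0, n, n)
  A[g$edges] <- 1
  A <- A + t(A)
  WA <- invdeg * A                      # WA[i, j] = L * w_ij for i ~ j
  B <- matrix(0, 2^n, n)
  for (i in 1:n) B[, i] <- bitwAnd(0:full, 2^(i - 1)) > 0
  Gm <- B %*% WA                        # Gm[s+1, j] = sum_{i in S, i~j} L/d_i
  colT <- colSums(WA)                   # L * temperature of j
  sizes <- rowSums(B)

  if (is.null(orbit_of)) {
    states <- 1:(full - 1)
    col_of <- c(NA, seq_len(full - 1), NA)
  } else {
    if (length(orbit_of) != 2^n) stop("orbit_of must have length 2^n")
    non_abs <- setdiff(unique(orbit_of[-c(1, full + 1)]),
                       orbit_of[c(1, full + 1)])
    non_abs <- sort(non_abs)
    col_of <- match(orbit_of, non_abs)  # NA for absorbing orbits
    states <- vapply(non_abs, function(o) min(which(orbit_of == o)) - 1, 0)
  }
  K <- length(states)
  if (K > 4096)
    stop(K, " states exceed the dense-solver bound (4096); ",
         "use orbit reduction or the numeric scan")
  A0 <- matrix(0, K, K); A1 <- matrix(0, K, K)
  c0 <- c1 <- b0 <- b1 <- numeric(K)

  for (row in seq_len(K)) {
    s <- states[row]
    memb <- B[s + 1, ] > 0
    sz <- sizes[s + 1]
    gain <- Gm[s + 1, ]
    selfmut <- sum(gain[memb])
    selfres <- sum(colT[!memb] - gain[!memb])
    # diagonal: w_S(r) L minus the self-loop polynomial
    cs <- col_of[s + 1]
    A0[row, cs] <- A0[row, cs] + L * (n - sz) - selfres
    A1[row, cs] <- A1[row, cs] + L * sz - selfmut
    for (j in which(!memb & gain > 0)) {       # mutant gains vertex j
      t <- s + 2^(j - 1)
      if (t == full) c1[row] <- c1[row] + gain[j]
      else A1[row, col_of[t + 1]] <- A1[row, col_of[t + 1]] - gain[j]
    }
    for (j in which(memb)) {                   # mutant loses vertex j
      h <- colT[j] - gain[j]
      if (h == 0) next
      t <- s - 2^(j - 1)
      if (t == 0) b0[row] <- b0[row] + h
      else A0[row, col_of[t + 1]] <- A0[row, col_of[t + 1]] - h
    }
  }
  structure(list(n = n, L = L, A0 = A0, A1 = A1, c0 = c0, c1 = c1,
                 b0 = b0, b1 = b1, states = states, col_of = col_of,
                 reduced = !is.null(orbit_of), orbit_of = orbit_of,
                 sizes = sizes[states + 1]),
            class = "moran_system")
}

#' @export
print.moran_system <- function(x, ...) {
  cat(sprintf("<moran_system> order %d, %d %s rows, row scale L = %d\n",
              x$n, length(x$states),
              if (x$reduced) "orbit" else "state", x$L))
  invisible(x)
}

# internal: solve a prebuilt system at fitness r
.solve_sys <- function(sys, r, mode = c("float", "exact", "highprec"),
                       digits = 50) {
  mode <- match.arg(mode)
  n <- sys$n
  if (mode == "float") {
    r_num <- if (is.character(r)) cpp_rat_to_double(r) else r
    if (r_num <= 0) stop("fitness must be positive")
    psi <- solve(sys$A0 + r_num * sys$A1, sys$c0 + r_num * sys$c1)
    psi_frac <- NULL
  } else {
    rr <- as_rational(r)
    if (length(rr) != 1 || as.numeric(rr) <= 0) stop("fitness must be a positive rational")
    sol <- cpp_exact_solve(sys$A0, sys$A1, sys$c0, sys$c1,
                           sprintf("%.0f", rr$num), sprintf("%.0f", rr$den))
    psi <- sol$value
    psi_frac <- sol$frac
  }
  singles_cols <- sys$col_of[2^(0:(n - 1)) + 1]
  singles <- psi[singles_cols]
  if (!is.null(psi_frac)) {
    singles_frac <- psi_frac[singles_cols]
    avg_frac <- Reduce(function(a, b) cpp_rat_arith(a, b, "+"), singles_frac)
    avg_frac <- cpp_rat_arith(avg_frac, as.character(n), "/")
    average <- cpp_rat_to_double(avg_frac)
  } else {
    singles_frac <- avg_frac <- NULL
    average <- mean(singles)
  }
  out <- structure(list(n = n, r = r, mode = mode,
                        psi = as.numeric(psi), psi_frac = psi_frac,
                        states = sys$states,
                        singles = as.numeric(singles),
                        singles_frac = singles_frac,
                        average = average, average_frac = avg_frac,
                        reduced = sys$reduced),
                   class = "fixation_vector")
  if (mode == "highprec") {
    out$average_decimal <- cpp_rat_to_decimal(avg_frac, digits)
    out$singles_decimal <- vapply(singles_frac, cpp_rat_to_decimal, "",
                                  digits = digits)
  }
  out
}

#' Fixation probabilities of the Moran process
#'
#' Solves the fixation linear system of the Birth-Death Moran process on
#' `g` at fitness `r`, returning per-configuration, per-initial-vertex and
#' average (uniform single-mutant) fixation probabilities.
#'
#' @param g a [moran_graph].
#' @param r fitness of the mutant (positive).  For the exact modes pass an
#'   exact value: an integer-valued numeric, a fraction string like
#'   `"5/2"`, or a [rational].
#' @param mode `"float"` (LAPACK LU on the cleared system evaluated at
#'   `r`), `"exact"` (fraction-free elimination over the rationals), or
#'   `"highprec"` (exact solve rendered to `digits` significant decimals).
#' @param reduce use automorphism-orbit reduction of the state space
#'   (`NULL`: automatic — reduce when the full space exceeds 1022 states).
#' @param digits significant digits for `mode = "highprec"`.
#' @return A `fixation_vector` with components `psi` (per state or orbit),
#'   `singles` (per initial vertex), `average`, and exact fraction strings
#'   (`*_frac`) in the exact modes.
#' @examples
#' solve_fixation(graph_clique(4), 2)$average # 8/15
#' solve_fixation(graph_star(5), "2", mode = "exact")$average_frac
#' @export
solve_fixation <- function(g, r, mode = c("float", "exact", "highprec"),
                           reduce = NULL, digits = 50) {
  stopifnot(inherits(g, "moran_graph"))
  mode <- match.arg(mode)
  if (is.null(reduce)) reduce <- 2^g$n - 2 > 1022
  sys <- if (reduce) build_polynomial_system(g, subset_orbits(g))
         else build_polynomial_system(g)
  .solve_sys(sys, r, mode, digits)
}

#' @export
print.fixation_vector <- function(x, ...) {
  cat(sprintf("<fixation_vector> order %d, r = %s, mode = %s%s\n",
              x$n, format(x$r), x$mode,
              if (x$reduced) " (orbit-reduced)" else ""))
  cat(sprintf("  average fixation probability: %.12g", x$average))
  if (!is.null(x$average_frac)) cat("  = ", x$average_frac, sep = "")
  cat("\n  per-vertex:", sprintf("%.6g", x$singles), "\n")
  invisible(x)
}

#' One row of the Moran transition matrix
#'
#' Exact transition probabilities out of a mutant configuration `S`: the
#' chain can gain a vertex adjacent to a mutant, lose a mutant adjacent to
#' a resident, or stay put.  Probabilities are exact rationals over the
#' common denominator `L * (p|S| + q(N - |S|))` for \eqn{r = p/q}.
#'
#' @param g a [moran_graph].
#' @param S mutant configuration: vector of vertices, or a single subset
#'   encoding (bitmask).
#' @param r fitness (exact: integer, fraction string or [rational]).
#' @return A data frame with the target encoding `subset`, a `change`
#'   label, exact `num`/`den`, and the numeric `prob`; rows sum to one
#'   exactly.
#' @examples
#' transition_row(graph_star(3), S = 1, r = 2)
#' @export
transition_row <- function(g, S, r) {
  stopifnot(inherits(g, "moran_graph"))
  n <- g$n
  s <- if (length(S) == 1 && (S > n || S == 0)) S else .encode_subset(S, n)
  if (s <= 0 || s >= 2^n - 1)
    if (s != 0 && s != 2^n - 1) stop("invalid configuration encoding")
  rr <- as_rational(r)
  if (as.numeric(rr) <= 0) stop("fitness must be positive")
  p <- rr$num; q <- rr$den
  L <- .lcm_vec(g$degree)
  invdeg <- L / g$degree
  memb <- bitwAnd(s, 2^(0:(n - 1))) > 0
  sz <- sum(memb)
  if (sz == 0 || sz == n) { # absorbing: stays put with probability one
    return(data.frame(subset = s, change = "self", num = 1, den = 1, prob = 1))
  }
  gain <- vapply(1:n, function(j) sum(invdeg[intersect(g$adj[[j]], which(memb))]), 0)
  den <- L * (p * sz + q * (n - sz))
  out <- NULL
  for (j in which(!memb)) if (gain[j] > 0)
    out <- rbind(out, data.frame(subset = s + 2^(j - 1),
                                 change = sprintf("gain %d", j),
                                 num = p * gain[j], den = den))
  for (j in which(memb)) {
    h <- sum(invdeg[setdiff(g$adj[[j]], which(memb))])
    if (h > 0)
      out <- rbind(out, data.frame(subset = s - 2^(j - 1),
                                   change = sprintf("loss %d", j),
                                   num = q * h, den = den))
  }
  selfnum <- p * sum(gain[memb]) +
    q * sum(vapply(which(!memb), function(j)
      sum(invdeg[setdiff(g$adj[[j]], which(memb))]), 0))
  if (selfnum > 0)
    out <- rbind(out, data.frame(subset = s, change = "self",
                                 num = selfnum, den = den))
  .check_exact(out$num); .check_exact(out$den)
  g2 <- .gcd2(out$num, out$den)
  out$num <- out$num / g2; out$den <- out$den / g2
  out$prob <- out$num / out$den
  out
}

# internal: polynomial identity check of cleared row-stochasticity.  The
# transition polynomials of a row sum to w_S(r) * L, which is equivalent to
# the matrix rows (diagonal w_S L minus transitions) summing to the
# absorbing columns: rowSums(A0) == b0 and rowSums(A1) == c1.
.check_system <- function(sys) {
  all(rowSums(sys$A0) == sys$b0) && all(rowSums(sys$A1) == sys$c1)
}
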