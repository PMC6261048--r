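# Exact rational-function fixation curves.
#
# The solution of the cleared polynomial system is, by Cramer's rule, a
# ratio of determinants of matrices with degree-one polynomial entries, so
# the average fixation probability is a rational function
# Phi(r) = Phi'(r) / Phi''(r) with rational coefficients whose degree is
# bounded by the number of non-absorbing orbit rows.  The curve is
# recovered from exact point evaluations at r in {1, ..., d+1} and
# {1/2, ..., 1/d} by solving the 2d linear interpolation conditions with
# leading coefficients pinned to one (Phi -> 1 as r -> Inf); if the system
# is rank-deficient the numerator and denominator share a factor and the
# degree bound is lowered until the solution is unique.

#' Rational functions with exact coefficients
#'
#' Constructs a rational function from numerator and denominator
#' coefficient vectors (constant term first; fraction strings or numerics).
#' The result is normalised to the canonical form: numerator and
#' denominator coprime, denominator monic.
#'
#' @param num,den coefficient vectors.
#' @return An object of class `ratfun`.
#' @examples
#' ratfun(c(0, 1), c(1, 1)) # r / (1 + r)
#' @export
ratfun <- function(num, den) {
  num <- .as_coef(num); den <- .as_coef(den)
  if (all(cpp_rat_to_double(den) == 0)) stop("zero denominator")
  if (!all(cpp_rat_to_double(num) == 0)) {
    g <- cpp_poly_gcd(num, den)
    if (length(g) > 1) {
      num <- cpp_poly_divexact(num, g)
      den <- cpp_poly_divexact(den, g)
    }
  } else num <- "0"
  lead <- den[length(den)]
  den <- cpp_rat_arith(den, lead, "/")
  num <- cpp_rat_arith(num, lead, "/")
  structure(list(num = num, den = den,
                 degree = max(length(num), length(den)) - 1L),
            class = "ratfun")
}

.as_coef <- function(x) {
  if (is.numeric(x)) {
    rr <- as_rational(x)
    x <- as.character(rr)
  }
  x <- as.character(x)
  # strip trailing zero coefficients
  nz <- which(cpp_rat_to_double(x) != 0)
  if (length(nz) == 0) return("0")
  x[seq_len(max(nz))]
}

#' @export
print.ratfun <- function(x, ...) {
  fmt <- function(cf) {
    d <- length(cf) - 1
    lab <- c("", if (d >= 1) " r", if (d >= 2) sprintf(" r^%d", 2:d))
    terms <- cf != "0"
    paste(sprintf("%s%s", cf[terms], lab[terms]), collapse = " + ")
  }
  cat("<ratfun> degree", x$degree, "\n  num:", fmt(x$num),
      "\n  den:", fmt(x$den), "\n")
  invisible(x)
}

#' Operations on rational functions
#'
#' Exact arithmetic on [ratfun] objects: `rf_add`, `rf_sub`, `rf_mul`,
#' differentiation `rf_deriv`, and evaluation `rf_eval` (exact at rational
#' points).  Results are renormalised to canonical coprime form.
#'
#' @param f,g [ratfun] objects.
#' @return A [ratfun]; for `rf_eval` a numeric, or a fraction string when
#'   `exact = TRUE`.
#' @export
rf_add <- function(f, g) .rf_combine(f, g, "+")

#' @rdname rf_add
#' @export
rf_sub <- function(f, g) .rf_combine(f, g, "-")

#' @rdname rf_add
#' @export
rf_mul <- function(f, g) {
  stopifnot(inherits(f, "ratfun"), inherits(g, "ratfun"))
  ratfun(cpp_poly_arith(f$num, g$num, "*"), cpp_poly_arith(f$den, g$den, "*"))
}

.rf_combine <- function(f, g, op) {
  stopifnot(inherits(f, "ratfun"), inherits(g, "ratfun"))
  num <- cpp_poly_arith(cpp_poly_arith(f$num, g$den, "*"),
                        cpp_poly_arith(g$num, f$den, "*"), op)
  ratfun(num, cpp_poly_arith(f$den, g$den, "*"))
}

#' @rdname rf_add
#' @param order derivative order.
#' @export
rf_deriv <- function(f, order = 1) {
  stopifnot(inherits(f, "ratfun"))
  for (k in seq_len(order)) {
    num <- cpp_poly_arith(
      cpp_poly_arith(cpp_poly_deriv(f$num), f$den, "*"),
      cpp_poly_arith(f$num, cpp_poly_deriv(f$den), "*"), "-")
    f <- ratfun(num, cpp_poly_arith(f$den, f$den, "*"))
  }
  f
}

#' @rdname rf_add
#' @param r evaluation point: numeric vector, or fraction string(s) for
#'   exact evaluation.
#' @param exact return exact fraction strings instead of doubles.
#' @export
rf_eval <- function(f, r, exact = FALSE) {
  stopifnot(inherits(f, "ratfun"))
  rs <- if (is.character(r)) r else as.character(as_rational(r))
  out <- vapply(rs, function(p) {
    nv <- cpp_poly_eval(f$num, p)
    dv <- cpp_poly_eval(f$den, p)
    if (dv$sign == 0) stop("evaluation at a pole of the rational function")
    cpp_rat_arith(nv$frac, dv$frac, "/")
  }, "")
  if (exact) unname(out) else cpp_rat_to_double(out)
}

#' @rdname rf_add
#' @export
rf_is_zero <- function(f) {
  stopifnot(inherits(f, "ratfun"))
  all(cpp_rat_to_double(f$num) == 0)
}

#' @rdname rf_add
#' @export
rf_equal <- function(f, g) rf_is_zero(rf_sub(f, g))

#' Exact fixation curve by evaluation and interpolation
#'
#' Computes the average fixation probability of `g` as an exact rational
#' function of the fitness.  Exact solves of the (orbit-reduced) fixation
#' system at the sample fitnesses `1, ..., d+1` and `1/2, ..., 1/d` provide
#' the interpolation conditions; the two leading coefficients are pinned to
#' one, and the degree bound `d` starts at the number of non-absorbing
#' orbits and is lowered on rank deficiency until the canonical coprime
#' solution is unique.  The result is validated against a fresh exact solve
#' at a held-out point.
#'
#' @param g a [moran_graph].
#' @param degree_bound optional starting degree bound (defaults to the
#'   non-absorbing orbit count).
#' @param reduce use orbit reduction for the exact solves (default TRUE).
#' @return A [ratfun] with attribute `"n"` (graph order).
#' @examples
#' interpolate_fixation(graph_clique(3)) # r^2 / (1 + r + r^2)
#' @export
interpolate_fixation <- function(g, degree_bound = NULL, reduce = TRUE) {
  stopifnot(inherits(g, "moran_graph"))
  sys <- if (reduce) orbit_reduce(g)$system else build_polynomial_system(g)
  d <- if (is.null(degree_bound)) length(sys$states) else degree_bound
  cache <- new.env(parent = emptyenv())
  phi_at <- function(pt) { # exact average fixation at rational point pt
    if (is.null(cache[[pt]]))
      cache[[pt]] <- .solve_sys(sys, pt, "exact")$average_frac
    cache[[pt]]
  }
  repeat {
    if (d < 1) stop("internal: degree bound exhausted")
    pts <- c(as.character(1:(d + 1)),
             if (d >= 2) sprintf("1/%d", 2:d))
    phis <- vapply(pts, phi_at, "")
    # unknowns a_0..a_{d-1}, b_0..b_{d-1}; a_d = b_d = 1
    A <- matrix("0", length(pts), 2 * d)
    rhs <- character(length(pts))
    for (k in seq_along(pts)) {
      pw <- "1"
      pows <- character(d + 1)
      for (i in 0:d) {
        pows[i + 1] <- pw
        pw <- cpp_rat_arith(pw, pts[k], "*")
      }
      A[k, 1:d] <- pows[1:d]
      A[k, d + (1:d)] <- cpp_rat_arith(cpp_rat_arith("0", phis[k], "-"),
                                       pows[1:d], "*")
      rhs[k] <- cpp_rat_arith(cpp_rat_arith(phis[k], "1", "-"), pows[d + 1], "*")
    }
    sol <- cpp_rat_solve(A, rhs)
    if (sol$status == "unique") {
      f <- ratfun(c(sol$frac[1:d], "1"), c(sol$frac[d + (1:d)], "1"))
      break
    }
    if (sol$status == "inconsistent")
      stop("internal: inconsistent interpolation system (solver bug?)")
    # a rank deficiency of k means numerator and denominator share a
    # degree-k factor, so the canonical coprime degree is d - k
    d_new <- d - (2 * d - sol$rank)
    if (d_new < 1 || d_new >= d) d_new <- d - 1
    d <- d_new
  }
  # validation at a held-out point
  probe <- as.character(d + 2)
  while (probe %in% pts) probe <- as.character(as.numeric(probe) + 1)
  stopifnot(rf_eval(f, probe, exact = TRUE) == phi_at(probe))
  attr(f, "n") <- g$n
  f
}
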