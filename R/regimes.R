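# Reference curves, regime classification and transition isolation.
#
# A non-isothermal graph is an amplifier (suppressor) of selection on a
# fitness interval when its average fixation probability lies above (below)
# the homogeneous-population curve Phi0 there.  Sign analysis of
# D(r) = Phi(r) - Phi0(r) on (1, Inf) yields the regime sequence; the
# critical fitnesses where D changes sign are the regime transitions.

#' The homogeneous Moran fixation probability
#'
#' \eqn{\Phi_0(r) = (1 - r^{-1}) / (1 - r^{-N}) = r^{N-1}(r-1)/(r^N-1)},
#' the fixation probability of a single mutant of fitness `r` in an
#' unstructured population of size `N` (value `1/N` at \eqn{r = 1}).
#' `phi2(N, r) = phi0(N, r^2)` is the classical upper bound for star and
#' complete bipartite graphs.  `phi0_fun()` and `phi2_fun()` return the
#' curves as exact [ratfun] objects.
#'
#' @param N population size (graph order), `N >= 2`.
#' @param r fitness vector (numeric), or fraction strings for exact
#'   evaluation.
#' @return Numeric vector of probabilities (fraction strings if `r` is
#'   character).
#' @examples
#' phi0(3, 2) # 4/7
#' phi0(10, 1) # 1/10
#' @export
phi0 <- function(N, r) {
  stopifnot(N >= 2)
  if (is.character(r)) return(rf_eval(phi0_fun(N), r, exact = TRUE))
  ifelse(r == 1, 1 / N, r^(N - 1) * (r - 1) / (r^N - 1))
}

#' @rdname phi0
#' @export
phi2 <- function(N, r) {
  if (is.character(r)) return(rf_eval(phi2_fun(N), r, exact = TRUE))
  phi0(N, r^2)
}

#' @rdname phi0
#' @export
phi0_fun <- function(N) {
  stopifnot(N >= 2)
  ratfun(c(rep(0, N - 1), 1), rep(1, N))
}

#' @rdname phi0
#' @export
phi2_fun <- function(N) {
  stopifnot(N >= 2)
  num <- rep(0, 2 * N - 1); num[2 * N - 1] <- 1
  den <- rep(0, 2 * N - 1); den[2 * (0:(N - 1)) + 1] <- 1
  ratfun(num, den)
}

# internal: check that a ratfun denominator is positive on (0, Inf), as it
# must be for a difference of fixation curves
.check_pos_den <- function(f) {
  if (cpp_count_roots_pos(f$den) != 0 || cpp_poly_eval(f$den, "1")$sign <= 0)
    stop("internal: rational-function denominator is not positive on (0, Inf)")
  invisible(TRUE)
}

#' Isolate regime transitions of a fixation-curve difference
#'
#' Finds all odd-multiplicity real roots of the numerator of `D` in the
#' open interval `(1, Inf)` by square-free reduction and Descartes-rule
#' bisection, each refined to an isolating interval narrower than `tol`.
#' Even-multiplicity roots (tangencies without regime change) are reported
#' but not counted as transitions.
#'
#' @param D a [ratfun], typically `Phi - Phi0`.
#' @param tol isolating-interval width.
#' @return A data frame of transitions (`r_c`, `direction`, exact interval
#'   strings `lo`/`hi`), with all distinct roots (including tangencies) in
#'   attribute `"all_roots"`.  Zero rows with attribute `"isothermal"` set
#'   when `D` is identically zero.
#' @export
isolate_transitions <- function(D, tol = 1e-6) {
  stopifnot(inherits(D, "ratfun"))
  empty <- data.frame(r_c = numeric(0), direction = character(0),
                      lo = character(0), hi = character(0))
  if (rf_is_zero(D)) {
    attr(empty, "isothermal") <- TRUE
    return(empty)
  }
  .check_pos_den(D)
  iso <- cpp_isolate_roots_gt1(D$num, tol)
  if (iso$n_roots == 0) {
    attr(empty, "isothermal") <- FALSE
    attr(empty, "sign") <- iso$sign_tail
    return(empty)
  }
  roots <- data.frame(r_c = iso$root, lo = iso$lo_str, hi = iso$hi_str,
                      sign_before = iso$sign_before,
                      sign_after = iso$sign_after,
                      transition = iso$sign_change)
  tr <- roots[roots$transition, , drop = FALSE]
  out <- data.frame(r_c = tr$r_c,
                    direction = ifelse(tr$sign_before < 0, "S/A", "A/S"),
                    lo = tr$lo, hi = tr$hi)
  attr(out, "isothermal") <- FALSE
  attr(out, "all_roots") <- roots
  attr(out, "sign") <- if (nrow(out)) NULL else iso$sign_before[1]
  out
}

.profile <- function(classification, sequence, transitions, method, n,
                     scan = NULL, inconclusive = FALSE) {
  structure(list(classification = classification, sequence = sequence,
                 transitions = transitions, method = method, n = n,
                 scan = scan, inconclusive = inconclusive),
            class = "regime_profile")
}

# two-decimal display of critical fitnesses (truncated, the convention of
# the published tables; full precision stays in the transition records)
.fmt_rc <- function(x) sprintf("%.2f", floor(x * 100) / 100)

#' @export
print.regime_profile <- function(x, ...) {
  cat(sprintf("<regime_profile> order %d: %s (method: %s)\n",
              x$n, x$classification, x$method))
  if (nrow(x$transitions))
    cat(sprintf("  transition %s at r_c ~ %s\n",
                x$transitions$direction, .fmt_rc(x$transitions$r_c)), sep = "")
  if (x$inconclusive) cat("  WARNING: classification inconclusive\n")
  invisible(x)
}

# sequence of regime labels from the sign before/after each transition
.sequence_from_transitions <- function(transitions, lone_sign) {
  if (nrow(transitions) == 0)
    return(if (lone_sign > 0) "A" else "S")
  first <- if (transitions$direction[1] == "S/A") "S" else "A"
  seqs <- first
  for (d in transitions$direction) seqs <- c(seqs, if (d == "S/A") "A" else "S")
  seqs
}

#' Classify the evolutionary regime of a graph
#'
#' Determines whether `g` is isothermal, an amplifier, a suppressor, or a
#' graph with regime transitions, on the advantageous-fitness domain
#' `(1, Inf)`.
#'
#' With `method = "exact"` the fixation curve is computed symbolically
#' ([interpolate_fixation()]) and the sign of `Phi - Phi0` is analysed by
#' exact root isolation: the classification is certified for all \eqn{r > 1}.
#' With `method = "scan"` the difference is evaluated numerically on a
#' fitness grid (plus an extended, coarser grid up to \eqn{r = 2000}), sign
#' changes are bisected, and the result is an *apparent* classification:
#' transitions outside the scan range or sign excursions between grid
#' points cannot be excluded.  Regularity is always checked first and
#' certifies the isothermal class without any solve.
#'
#' @param g a [moran_graph].
#' @param method `"exact"` or `"scan"`.
#' @param grid main scan grid (fitnesses > 1 are used for classification).
#' @param extended extended scan grid.
#' @param tol isolating-interval width for exact transitions.
#' @param zero_tol numeric-scan threshold: grid values with `|D|` below
#'   this are treated as ties and flagged for exact confirmation.
#' @return A `regime_profile`.
#' @examples
#' classify(graph_ell(6, 2, 2)) # certified global suppressor
#' @export
classify <- function(g, method = c("exact", "scan"),
                     grid = NULL, extended = NULL,
                     tol = 1e-6, zero_tol = 1e-9) {
  stopifnot(inherits(g, "moran_graph"))
  method <- match.arg(method)
  n <- g$n
  empty <- data.frame(r_c = numeric(0), direction = character(0),
                      lo = character(0), hi = character(0))
  if (is_isothermal(g))
    return(.profile("isothermal", character(0), empty, "exact", n))
  if (method == "exact") {
    f <- interpolate_fixation(g)
    D <- rf_sub(f, phi0_fun(n))
    if (rf_is_zero(D)) # cannot happen for non-regular undirected graphs
      return(.profile("isothermal", character(0), empty, "exact", n))
    tr <- isolate_transitions(D, tol)
    lone <- attr(tr, "sign")
    seqs <- .sequence_from_transitions(tr, if (is.null(lone)) 0 else lone)
    cls <- if (nrow(tr) == 0) {
      if (lone > 0) "amplifier" else "suppressor"
    } else paste(seqs, collapse = "/")
    return(.profile(cls, seqs, tr, "exact", n))
  }
  # numeric scan
  sys <- build_polynomial_system(g, subset_orbits(g))
  scan <- .scan_profile(sys, n, grid, extended, zero_tol)
  .profile(scan$classification, scan$sequence, scan$transitions,
           sprintf("numeric-scan[%g..%g]", scan$range[1], scan$range[2]),
           n, scan = scan$data, inconclusive = scan$inconclusive)
}

.default_grid <- function() c(seq(0.25, 10, 0.25),
                              1.0005, 1.001, 1.002, 1.005, 1.01, 1.015,
                              seq(1.02, 1.2, 0.02), seq(1.3, 4, 0.1))

.default_extended <- function()
  unique(c(seq(10.5, 30, 0.5), seq(32.5, 100, 2.5),
           round(exp(seq(log(104), log(2000), length.out = 30)))))

# numeric-scan classification of a prebuilt (reduced) system
.scan_profile <- function(sys, n, grid = NULL, extended = NULL,
                          zero_tol = 1e-9) {
  if (is.null(grid)) grid <- .default_grid()
  if (is.null(extended)) extended <- .default_extended()
  rs <- sort(unique(c(grid, extended)))
  rs <- rs[rs > 1]
  scols <- sys$col_of[2^(0:(n - 1)) + 1]
  avg_at <- function(r)
    mean(solve(sys$A0 + r * sys$A1, sys$c0 + r * sys$c1)[scols])
  D <- vapply(rs, function(r) avg_at(r) - phi0(n, r), 0)
  sgn <- ifelse(abs(D) < zero_tol, 0L, ifelse(D > 0, 1L, -1L))
  ties <- rs[sgn == 0L]
  # sign changes between consecutive decided points
  dec <- which(sgn != 0L)
  trans <- NULL
  if (length(dec) >= 2) {
    ch <- which(diff(sgn[dec]) != 0)
    for (k in ch) {
      lo <- rs[dec[k]]; hi <- rs[dec[k + 1]]
      s_lo <- sgn[dec[k]]
      # numeric bisection of the sign change
      for (it in 1:60) {
        if (hi - lo < 1e-9) break
        mid <- (lo + hi) / 2
        dm <- avg_at(mid) - phi0(n, mid)
        if (sign(dm) == s_lo) lo <- mid else hi <- mid
      }
      trans <- rbind(trans, data.frame(
        r_c = (lo + hi) / 2,
        direction = if (s_lo < 0) "S/A" else "A/S",
        lo = as.character(lo), hi = as.character(hi)))
    }
  }
  if (is.null(trans))
    trans <- data.frame(r_c = numeric(0), direction = character(0),
                        lo = character(0), hi = character(0))
  lone <- if (length(dec)) sgn[dec[1]] else 0L
  seqs <- .sequence_from_transitions(trans, lone)
  cls <- if (nrow(trans) == 0) {
    if (lone > 0) "amplifier" else if (lone < 0) "suppressor" else "inconclusive"
  } else paste(seqs, collapse = "/")
  list(classification = cls, sequence = seqs, transitions = trans,
       range = range(rs), inconclusive = length(ties) > 0 && nrow(trans) == 0 &&
         lone == 0L,
       data = data.frame(r = rs, D = D, sign = sgn), ties = ties)
}

#' Concavity of the homogeneous fixation curve
#'
#' Reports whether \eqn{\Phi_0} is concave on all of `(1, Inf)` for
#' population size `N` (true exactly for `N <= 5`); for larger `N` the
#' curve is convex just above \eqn{r = 1}, and a certified rational witness
#' point with positive second derivative is returned.
#'
#' @param N population size.
#' @return A list with `N`, `concave`, the sign-change points of the second
#'   derivative (`inflections`), and `witness` (fraction string where
#'   \eqn{\Phi_0'' > 0}, or NULL).
#' @examples
#' phi0_concavity(3)$concave # TRUE
#' phi0_concavity(6)$concave # FALSE
#' @export
phi0_concavity <- function(N) {
  stopifnot(N >= 2)
  f2 <- rf_deriv(phi0_fun(N), 2)
  .check_pos_den(f2)
  iso <- cpp_isolate_roots_gt1(f2$num, 1e-6)
  if (iso$zero) stop("internal: second derivative cannot vanish identically")
  changes <- if (iso$n_roots) iso$root[iso$sign_change] else numeric(0)
  concave <- length(changes) == 0 &&
    (if (iso$n_roots) all(iso$sign_before < 0) && iso$sign_tail < 0
     else iso$sign_tail < 0)
  witness <- NULL
  if (!concave) {
    for (k in 1:10000) {
      pt <- sprintf("%d/%d", k + 1, k) # 1 + 1/k, walking towards 1
      if (cpp_poly_eval(f2$num, pt)$sign > 0) { witness <- pt; break }
    }
    if (is.null(witness)) stop("internal: no convexity witness found near 1")
  }
  list(N = N, concave = concave, inflections = changes, witness = witness)
}
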