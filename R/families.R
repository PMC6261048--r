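# Constructors for the graph families used in the study of amplification
# and suppression mechanisms.

#' Graph family constructors
#'
#' `make_family()` dispatches on a family name; the individual constructors
#' are also exported.  Families:
#'
#' * `clique`: the complete graph \eqn{K_N}.
#' * `cycle`: the cycle \eqn{C_N}.
#' * `star`: the star \eqn{K_{1,N-1}} with centre 1.
#' * `complete_bipartite`: \eqn{K_{a,b}}.
#' * `ell`: the ell-graph \eqn{\ell_N^{n,m}} — a clique \eqn{K_{N-2}} plus
#'   two adjacent extra vertices \eqn{u, v}, with \eqn{u} joined to `n` and
#'   \eqn{v} to `m` disjoint clique vertices.  Balanced (`n == m`) ell-graphs
#'   of order \eqn{2n+2} are the classical global suppressors of selection.
#' * `friendship_cycle`: a cycle \eqn{C_{N-1}} plus a central vertex joined
#'   to `m` disjoint adjacent pairs on the cycle (`m` 3-cliques through the
#'   centre), pairs spaced as evenly as possible around the cycle.
#' * `friendship_star`: `m` 3-cliques arranged as `m/2` base edges, each
#'   joined to a private apex and to one apex shared by every base edge, so
#'   the shared vertex belongs to more than two 3-cliques (see Details).
#' * `friendship_ribbon`: a chain of `m` 3-cliques in which pairs of
#'   3-cliques share a base edge and consecutive pairs share an apex, so no
#'   vertex lies in more than two 3-cliques.
#'
#' @details
#' The friendship star and ribbon layouts in the literature are schematic;
#' both conventions here use "diamonds" (two 3-cliques on a shared base
#' edge, the apexes not adjacent): the star glues `m/2` diamonds at a
#' common apex (`N = 3m/2 + 1`), while the ribbon chains them through
#' distinct shared apexes (also `N = 3m/2 + 1`); the two coincide for
#' `m = 4` and diverge from `m = 6` on.  The star convention is calibrated
#' so that FS(7, 4) is exactly the order-7 graph whose amplifier regime
#' ends at the largest critical fitness in the order-7 census; conventions
#' should be treated as provisional beyond the cases with a checkable
#' critical value.
#'
#' @param family one of `"clique"`, `"cycle"`, `"star"`,
#'   `"complete_bipartite"`, `"ell"`, `"friendship_cycle"`,
#'   `"friendship_star"`, `"friendship_ribbon"`.
#' @param N graph order.
#' @param ... family parameters passed on (`n`, `m`, `a`, `b`).
#' @return A [moran_graph].
#' @examples
#' make_family("ell", N = 6, n = 2, m = 2) # the order-6 global suppressor
#' graph_friendship_cycle(7, 2)
#' @export
make_family <- function(family, N, ...) {
  family <- match.arg(family, c("clique", "cycle", "star",
                                "complete_bipartite", "ell",
                                "friendship_cycle", "friendship_star",
                                "friendship_ribbon"))
  switch(family,
    clique = graph_clique(N),
    cycle = graph_cycle(N),
    star = graph_star(N),
    complete_bipartite = graph_complete_bipartite(N = N, ...),
    ell = graph_ell(N, ...),
    friendship_cycle = graph_friendship_cycle(N, ...),
    friendship_star = graph_friendship_star(N, ...),
    friendship_ribbon = graph_friendship_ribbon(N, ...))
}

#' @rdname make_family
#' @export
graph_clique <- function(N) {
  if (N < 2) stop("clique requires N >= 2")
  moran_graph(t(utils::combn(N, 2)), n = N)
}

#' @rdname make_family
#' @export
graph_cycle <- function(N) {
  if (N < 3) stop("cycle requires N >= 3")
  moran_graph(cbind(1:N, c(2:N, 1)), n = N)
}

#' @rdname make_family
#' @export
graph_star <- function(N) {
  if (N < 2) stop("star requires N >= 2")
  moran_graph(cbind(1L, 2:N), n = N)
}

#' @rdname make_family
#' @param a,b part sizes for the complete bipartite graph (alternatively
#'   give `N` and `a`; then `b = N - a`).
#' @export
graph_complete_bipartite <- function(a, b, N = NULL) {
  if (missing(b)) {
    if (is.null(N)) stop("give both part sizes, or N and a")
    b <- N - a
  }
  if (a < 1 || b < 1) stop("part sizes must be positive")
  moran_graph(as.matrix(expand.grid(1:a, a + (1:b))), n = a + b)
}

#' @rdname make_family
#' @param n,m family parameters: for ell-graphs the number of clique
#'   vertices joined to each extra vertex (`n >= 1`, `m >= 1`,
#'   `n + m <= N - 2`, `N >= 5`); for friendship families the number of
#'   3-cliques.
#' @export
graph_ell <- function(N, n, m) {
  if (N < 5) stop("ell-graph requires N >= 5")
  if (n < 1 || m < 1) stop("ell-graph requires n >= 1 and m >= 1")
  if (n + m > N - 2) stop("ell-graph requires n + m <= N - 2")
  k <- N - 2 # clique size
  u <- N - 1; v <- N
  e <- rbind(t(utils::combn(k, 2)),
             c(u, v),
             cbind(u, seq_len(n)),
             cbind(v, n + seq_len(m)))
  moran_graph(e, n = N)
}

#' @rdname make_family
#' @export
graph_friendship_cycle <- function(N, m) {
  cyc <- N - 1
  if (cyc < 3) stop("friendship cycle requires a cycle of length >= 3 (N >= 4)")
  if (m < 1) stop("friendship cycle requires m >= 1")
  if (2 * m > cyc) stop("friendship cycle requires 2m <= N - 1 (disjoint pairs)")
  centre <- N
  # place the m centre-connected cycle edges with maximal spacing
  starts <- unique(1L + floor((0:(m - 1)) * cyc / m))
  if (length(starts) < m || any(diff(c(starts, starts[1] + cyc)) < 2))
    stop("cannot place ", m, " disjoint pairs on a cycle of length ", cyc)
  e <- cbind(1:cyc, c(2:cyc, 1))
  for (s in starts) e <- rbind(e, c(centre, s), c(centre, s %% cyc + 1))
  moran_graph(e, n = N)
}

#' @rdname make_family
#' @export
graph_friendship_star <- function(N, m) {
  if (m < 2 || m %% 2 != 0)
    stop("friendship star requires an even number of 3-cliques (m >= 2)")
  k <- m / 2 # number of base edges, each carrying two 3-cliques
  if (N != 3 * k + 1)
    stop("friendship star FS(N, m) requires N = 3m/2 + 1 ",
         "(", 3 * k + 1, " for m = ", m, ")")
  centre <- N
  # base edge i = {x, y} is joined to its private apex i and to the common
  # centre, giving two 3-cliques per base edge; the centre lies in all of
  # them, so a single vertex belongs to more than two 3-cliques when k >= 3
  e <- NULL
  for (i in seq_len(k)) {
    x <- k + 2 * i - 1; y <- x + 1
    e <- rbind(e, c(x, y), c(x, i), c(y, i), c(x, centre), c(y, centre))
  }
  moran_graph(e, n = N)
}

#' @rdname make_family
#' @export
graph_friendship_ribbon <- function(N, m) {
  if (m < 2 || m %% 2 != 0)
    stop("friendship ribbon requires an even number of 3-cliques (m >= 2)")
  k <- m / 2 # number of diamonds (pairs of 3-cliques on a shared base edge)
  if (N != 3 * k + 1)
    stop("friendship ribbon FR(N, m) requires N = 3m/2 + 1 ",
         "(", 3 * k + 1, " for m = ", m, ")")
  # corner vertices 1..k+1; diamond i has base edge {x_i, y_i} joined to
  # corners i and i+1, so no vertex lies in more than two 3-cliques
  e <- NULL
  for (i in seq_len(k)) {
    x <- k + 1 + 2 * i - 1; y <- x + 1
    e <- rbind(e, c(x, y), c(x, i), c(y, i), c(x, i + 1), c(y, i + 1))
  }
  moran_graph(e, n = N)
}
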