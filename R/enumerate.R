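# Canonical identification and exhaustive enumeration of small connected
# graphs up to isomorphism.  Canonical labellings come from igraph (BLISS);
# enumeration proceeds by vertex augmentation: every connected graph on N
# vertices arises from a connected graph on N-1 vertices (delete a non-cut
# vertex, e.g. a leaf of a spanning tree) by attaching a new vertex to a
# non-empty neighbourhood, so extending every order-(N-1) representative by
# all non-empty subsets and deduplicating canonically is exhaustive.

# canonical edge matrix under the BLISS canonical labelling
.canonical_edges <- function(g) {
  ig <- .as_igraph(g)
  perm <- igraph::canonical_permutation(ig)$labeling
  e <- cbind(perm[g$edges[, 1]], perm[g$edges[, 2]])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

.canonical_key <- function(g) {
  e <- .canonical_edges(g)
  paste(g$n, paste(e[, 1], e[, 2], sep = "-", collapse = ","), sep = ":")
}

#' Canonical 64-bit graph identifier
#'
#' Maps a graph (up to isomorphism) to a unique integer: a sentinel bit
#' `2^choose(N,2)` plus the upper-triangle bits of the canonically labelled
#' adjacency matrix in row-major pair order ((1,2), (1,3), ..., (N-1,N),
#' with the (1,2) bit most significant).  The order and edge list can be
#' recovered from the id with [graph_from_id()].  Supported for `N <= 10`
#' (ids stay below 2^46 and are exactly representable); this scheme is
#' self-contained and its values are not comparable to ids from external
#' databases.
#'
#' @param g a [moran_graph] with at most 10 vertices.
#' @return A double holding the exact integer id.
#' @examples
#' canonical_id(graph_clique(3)) # 2^3 + 7 = 15
#' @export
canonical_id <- function(g) {
  stopifnot(inherits(g, "moran_graph"))
  if (g$n > 10) stop("canonical ids support orders up to 10 only")
  n <- g$n
  e <- .canonical_edges(g)
  C <- n * (n - 1) / 2
  # row-major pair index of (i,j), i < j
  k <- (e[, 1] - 1) * n - e[, 1] * (e[, 1] - 1) / 2 + (e[, 2] - e[, 1])
  sum(2^(C - k)) + 2^C
}

#' @rdname canonical_id
#' @param id an id produced by `canonical_id()`.
#' @export
graph_from_id <- function(id) {
  if (id < 3 || id != round(id)) stop("malformed graph id")
  C <- floor(log2(id))
  n <- (1 + sqrt(1 + 8 * C)) / 2
  if (n != round(n)) stop("malformed graph id: no order with choose(N,2) = ", C)
  rest <- id - 2^C
  e <- NULL
  k <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    k <- k + 1
    if (rest %/% 2^(C - k) %% 2 == 1) e <- rbind(e, c(i, j))
  }
  moran_graph(e, n = n)
}

#' Enumerate connected graphs up to isomorphism
#'
#' Returns one representative per isomorphism class of connected simple
#' graphs on `N` vertices, built by vertex augmentation from the
#' order-`N - 1` classes with canonical-form deduplication.  Practical up
#' to `N = 8` (11,117 classes); larger orders should be ingested from
#' external graph6 lists instead.
#'
#' @param N graph order, between 2 and 8.
#' @return A list of [moran_graph] objects, sorted by [canonical_id()] when
#'   `N <= 10`.
#' @examples
#' length(enumerate_connected(5)) # 21
#' @export
enumerate_connected <- function(N) {
  if (N < 2 || N > 8) stop("built-in enumeration supports 2 <= N <= 8")
  reps <- list(moran_graph(rbind(c(1, 2)), n = 2))
  if (N == 2) return(reps)
  for (n in 3:N) {
    seen <- new.env(parent = emptyenv(), hash = TRUE)
    out <- vector("list", 0)
    for (g in reps) {
      base <- g$edges
      for (mask in 1:(2^(n - 1) - 1)) {
        nb <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
        cand <- moran_graph(rbind(base, cbind(n, nb)), n = n)
        key <- .canonical_key(cand)
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          out[[length(out) + 1]] <- cand
        }
      }
    }
    reps <- out
  }
  if (N <= 10) reps[order(vapply(reps, canonical_id, 0))] else reps
}

# ---- counting by cycle index + connected-graph transform ----

.partitions <- function(n) {
  # all integer partitions of n as decreasing vectors
  rec <- function(n, maxpart) {
    if (n == 0) return(list(integer(0)))
    out <- list()
    for (k in min(n, maxpart):1)
      for (p in rec(n - k, k)) out[[length(out) + 1]] <- c(k, p)
    out
  }
  rec(n, n)
}

# number of unlabeled simple graphs on n vertices (Burnside over the pair
# action of the symmetric group)
.count_graphs_unlabeled <- function(n) {
  if (n == 0) return(1)
  total <- 0
  for (p in .partitions(n)) {
    # class size n! / (prod l_i * prod mult_j!)
    tab <- table(p)
    csize <- factorial(n) / (prod(p) * prod(factorial(tab)))
    # cycles of the induced action on unordered pairs
    cyc <- sum(floor(p / 2))
    if (length(p) > 1) {
      pairs <- utils::combn(length(p), 2)
      cyc <- cyc + sum(apply(pairs, 2, function(ij) .gcd2(p[ij[1]], p[ij[2]])))
    }
    total <- total + csize * 2^cyc
  }
  cnt <- total / factorial(n)
  if (cnt >= .INT_MAX_EXACT) stop("count exceeds exact double range")
  cnt
}

#' Count connected graphs up to isomorphism
#'
#' Computes the number of isomorphism classes of connected simple graphs on
#' `N` vertices without listing them: orbit counting over the pair action
#' of the symmetric group gives the number of unlabeled graphs, and the
#' connected classes are extracted with the inverse Euler transform.
#' Agrees with [enumerate_connected()] wherever both apply, and supports
#' the orders (up to 10) that are far beyond desk-scale enumeration.
#'
#' @param N graph order, between 1 and 10.
#' @return The exact class count as a double.
#' @examples
#' count_connected_unlabeled(6) # 112
#' sum(sapply(2:10, count_connected_unlabeled)) # 11989763
#' @export
count_connected_unlabeled <- function(N) {
  if (N < 1 || N > 10) stop("counting supports 1 <= N <= 10")
  a <- vapply(1:N, .count_graphs_unlabeled, 0) # all unlabeled graphs
  # inverse Euler transform: 1 + sum a_n x^n = prod (1 - x^n)^(-c_n)
  b <- numeric(N) # b_n = sum_{d | n} d c_d
  for (n in 1:N) {
    s <- 0
    if (n > 1) for (k in 1:(n - 1)) s <- s + b[k] * a[n - k]
    b[n] <- n * a[n] - s
  }
  mobius <- function(n) {
    if (n == 1) return(1)
    f <- c(); m <- n
    for (p in 2:n) if (m %% p == 0) {
      cnt <- 0
      while (m %% p == 0) { m <- m / p; cnt <- cnt + 1 }
      if (cnt > 1) return(0)
      f <- c(f, p)
    }
    (-1)^length(f)
  }
  divs <- which(N %% seq_len(N) == 0)
  sum(vapply(divs, function(d) mobius(N / d) * b[d], 0)) / N
}
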