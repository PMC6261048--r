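# Undirected connected simple graphs with 1-based vertices.

#' Construct an undirected graph for the Moran process
#'
#' Builds a simple, connected, undirected graph on vertices `1..n` from an
#' edge list.  Self-loops, multi-edges and disconnected graphs are rejected:
#' the Moran model studied here assumes a connected population, and fixation
#' from a single mutant is impossible on a disconnected graph.
#'
#' @param edges two-column matrix (or data frame) of vertex pairs, 1-based.
#' @param n number of vertices; defaults to the largest endpoint.
#' @return An object of class `moran_graph` with components `n`, `edges`
#'   (canonicalised `i < j`, sorted), `adj` (adjacency lists) and `degree`.
#' @examples
#' g <- moran_graph(rbind(c(1, 2), c(2, 3), c(1, 3)))
#' degrees(g)
#' @export
moran_graph <- function(edges, n = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0) stop("a graph needs at least one edge")
  if (ncol(edges) != 2) stop("edges must have two columns")
  storage.mode(edges) <- "integer"
  if (any(is.na(edges)) || any(edges < 1)) stop("vertices must be positive integers")
  if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
  if (is.null(n)) n <- max(edges)
  n <- as.integer(n)
  if (n < 2) stop("graph order must be at least 2")
  if (any(edges > n)) stop("edge endpoint exceeds the vertex count")
  if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
  e <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  if (anyDuplicated(paste(e[, 1], e[, 2]))) stop("multi-edges are not allowed")

  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    adj[[e[k, 1]]] <- c(adj[[e[k, 1]]], e[k, 2])
    adj[[e[k, 2]]] <- c(adj[[e[k, 2]]], e[k, 1])
  }
  adj <- lapply(adj, function(v) sort(as.integer(v)))
  deg <- vapply(adj, length, 0L)
  if (any(deg == 0)) stop("graph is disconnected (isolated vertex)")

  # connectivity by BFS
  seen <- logical(n); seen[1] <- TRUE; queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]][!seen[adj[[v]]]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (!all(seen)) stop("graph is disconnected")

  structure(list(n = n, edges = e, adj = adj, degree = deg),
            class = "moran_graph")
}

#' @export
print.moran_graph <- function(x, ...) {
  cat(sprintf("<moran_graph> order %d, size %d, degrees %s%s\n",
              x$n, nrow(x$edges),
              if (length(unique(x$degree)) == 1) sprintf("all %d", x$degree[1])
              else paste0(min(x$degree), "..", max(x$degree)),
              if (is_isothermal(x)) " (isothermal)" else ""))
  invisible(x)
}

#' Vertex degrees
#' @param g a `moran_graph`.
#' @return Integer vector of neighbour counts.
#' @export
degrees <- function(g) {
  stopifnot(inherits(g, "moran_graph"))
  g$degree
}

#' Vertex temperatures
#'
#' The temperature of a vertex is the sum of the inverse degrees of its
#' neighbours, \eqn{T_i = \sum_{j \sim i} 1/d_j}.  It measures how often the
#' vertex is replaced per Moran step; the temperatures of any graph sum
#' exactly to its order.
#'
#' @param g a `moran_graph`.
#' @return A [rational] vector of exact temperatures, one per vertex.
#' @examples
#' temperatures(graph_star(4)) # hot centre, cold leaves
#' @export
temperatures <- function(g) {
  stopifnot(inherits(g, "moran_graph"))
  num <- den <- numeric(g$n)
  for (i in seq_len(g$n)) {
    d <- g$degree[g$adj[[i]]]
    # sum of 1/d over neighbours with an exact common denominator
    L <- Reduce(function(a, b) a * b / .gcd2(a, b), d, accumulate = FALSE)
    num[i] <- sum(L / d)
    den[i] <- L
  }
  rational(num, den)
}

#' Is the graph isothermal?
#'
#' A graph is isothermal when all vertex temperatures are equal; for
#' undirected graphs this is equivalent to being regular.  Isothermal graphs
#' have exactly the homogeneous-population fixation probability [phi0] for
#' every fitness (the Isothermal Theorem).
#'
#' @param g a `moran_graph`.
#' @return TRUE if all degrees are equal.
#' @export
is_isothermal <- function(g) {
  stopifnot(inherits(g, "moran_graph"))
  length(unique(g$degree)) == 1L
}

# internal: igraph view of a moran_graph
.as_igraph <- function(g) {
  igraph::graph_from_edgelist(g$edges, directed = FALSE)
}

#' Weight matrix of the Moran process
#'
#' The replacement weights \eqn{w_{ij} = 1/d_i} for neighbours \eqn{j} of
#' \eqn{i} (0 otherwise); every row sums to one.
#'
#' @param g a `moran_graph`.
#' @param exact if TRUE return fraction strings, else a numeric matrix.
#' @return An `n x n` matrix.
#' @export
weight_matrix <- function(g, exact = FALSE) {
  stopifnot(inherits(g, "moran_graph"))
  n <- g$n
  if (exact) {
    W <- matrix("0", n, n)
    for (i in seq_len(n)) W[i, g$adj[[i]]] <- sprintf("1/%d", g$degree[i])
  } else {
    W <- matrix(0, n, n)
    for (i in seq_len(n)) W[i, g$adj[[i]]] <- 1 / g$degree[i]
  }
  W
}
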