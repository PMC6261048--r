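# graph6: the standard compact ASCII encoding of small undirected graphs.
# Bits run over the upper triangle column by column: (1,2), (1,3), (2,3),
# (1,4), ... padded with zeros to a multiple of six; each 6-bit group is
# printed as its value plus 63.

#' Encode / decode graphs in graph6 format
#'
#' @param g a [moran_graph] (orders up to 62 are supported).
#' @return `graph6_encode()` returns a single graph6 string;
#'   `graph6_decode()` returns a [moran_graph].
#' @examples
#' graph6_decode(graph6_encode(graph_cycle(5)))
#' @export
graph6_encode <- function(g) {
  stopifnot(inherits(g, "moran_graph"))
  n <- g$n
  if (n > 62) stop("graph6 encoding beyond order 62 is not supported")
  A <- matrix(FALSE, n, n)
  A[g$edges] <- TRUE
  bits <- logical(n * (n - 1) / 2)
  k <- 0
  for (j in 2:n) for (i in 1:(j - 1)) {
    k <- k + 1
    bits[k] <- A[i, j] || A[j, i]
  }
  pad <- (6 - length(bits) %% 6) %% 6
  bits <- c(bits, rep(FALSE, pad))
  groups <- matrix(bits, nrow = 6)
  vals <- as.integer(2^(5:0) %*% groups)
  rawToChar(as.raw(c(n + 63L, vals + 63L)))
}

#' @rdname graph6_encode
#' @param s a graph6 string.
#' @export
graph6_decode <- function(s) {
  v <- as.integer(charToRaw(s)) - 63L
  if (length(v) < 1 || v[1] < 1 || v[1] == 63)
    stop("unsupported or malformed graph6 string")
  n <- v[1]
  nb <- n * (n - 1) / 2
  need <- ceiling(nb / 6)
  if (length(v) - 1 < need) stop("graph6 string too short for its order")
  bits <- as.logical(unlist(lapply(v[-1][seq_len(need)],
                                   function(x) bitwAnd(x, 2^(5:0)) > 0)))
  e <- NULL
  k <- 0
  for (j in 2:n) for (i in 1:(j - 1)) {
    k <- k + 1
    if (bits[k]) e <- rbind(e, c(i, j))
  }
  if (is.null(e)) stop("graph6 string encodes an empty (disconnected) graph")
  moran_graph(e, n = n)
}

#' Read or write graph lists
#'
#' `write_graph6()`/`read_graph6()` handle one graph6 string per line;
#' `write_edgelist()`/`read_edgelist()` handle plain 1-based "i j" pairs,
#' one per line, with blank lines and `#` comments ignored.
#'
#' @param graphs a [moran_graph] or list of them.
#' @param path file path.
#' @return Readers return a list of [moran_graph] (a single graph for
#'   `read_edgelist`); writers return the path invisibly.
#' @export
write_graph6 <- function(graphs, path) {
  if (inherits(graphs, "moran_graph")) graphs <- list(graphs)
  writeLines(vapply(graphs, graph6_encode, ""), path)
  invisible(path)
}

#' @rdname write_graph6
#' @export
read_graph6 <- function(path) {
  lines <- readLines(path)
  lapply(lines[nzchar(lines)], graph6_decode)
}

#' @rdname write_graph6
#' @param g a [moran_graph].
#' @export
write_edgelist <- function(g, path) {
  stopifnot(inherits(g, "moran_graph"))
  writeLines(sprintf("%d %d", g$edges[, 1], g$edges[, 2]), path)
  invisible(path)
}

#' @rdname write_graph6
#' @param n optional order for `read_edgelist` (defaults to the largest
#'   endpoint).
#' @export
read_edgelist <- function(path, n = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- vapply(parts, length, 0L) != 2
  if (any(bad)) stop("malformed edge list line: ", lines[bad][1])
  e <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE)
  moran_graph(e, n = n)
}
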