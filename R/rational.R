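# Light-weight exact rational vectors for small quantities (temperatures,
# transition probabilities).  Numerators and denominators are kept as exact
# integers in doubles; every operation checks that intermediates stay below
# 2^53 so results are exact.  Heavy exact arithmetic (solves, polynomials)
# lives in the GMP-backed C++ layer instead.

.INT_MAX_EXACT <- 2^53

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b > 0)) {
    r <- ifelse(b > 0, a %% b, 0)
    a <- ifelse(b > 0, b, a) # keep finished elements fixed
    b <- r
  }
  a
}

.check_exact <- function(x) {
  if (any(abs(x) >= .INT_MAX_EXACT))
    stop("exact integer overflow in rational arithmetic; ",
         "use the exact (GMP) solver interface instead", call. = FALSE)
  x
}

#' Exact rational vectors
#'
#' Creates a vector of exact rationals `num/den`, reduced to lowest terms
#' with positive denominators.  Used for vertex temperatures and transition
#' probabilities, where exactness matters but magnitudes are small.
#'
#' @param num integer-valued numerators.
#' @param den integer-valued denominators (recycled).
#' @return An object of class `moran_rational`.
#' @examples
#' rational(c(1, 2), c(3, 4)) + rational(1, 12)
#' @export
rational <- function(num, den = 1) {
  if (length(den) != length(num)) den <- rep_len(den, length(num))
  if (any(den == 0)) stop("zero denominator")
  if (any(num != round(num)) || any(den != round(den)))
    stop("numerators and denominators must be integers")
  .check_exact(num); .check_exact(den)
  s <- ifelse(den < 0, -1, 1)
  num <- num * s; den <- den * s
  g <- .gcd2(num, den)
  g[g == 0] <- 1
  structure(list(num = num / g, den = den / g), class = "moran_rational")
}

.rat <- function(num, den) rational(num, den) # internal alias

#' @export
length.moran_rational <- function(x) length(x$num)

#' @export
`[.moran_rational` <- function(x, i) rational(x$num[i], x$den[i])

#' @export
format.moran_rational <- function(x, ...) {
  ifelse(x$den == 1, sprintf("%.0f", x$num),
         sprintf("%.0f/%.0f", x$num, x$den))
}

#' @export
print.moran_rational <- function(x, ...) {
  cat("<exact rationals> ", paste(format(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.moran_rational <- function(x, ...) format(x)

#' @export
as.double.moran_rational <- function(x, ...) x$num / x$den

#' @export
as.numeric.moran_rational <- function(x, ...) x$num / x$den

#' @export
c.moran_rational <- function(...) {
  xs <- lapply(list(...), as_rational)
  rational(unlist(lapply(xs, function(x) x$num)),
           unlist(lapply(xs, function(x) x$den)))
}

#' @export
sum.moran_rational <- function(..., na.rm = FALSE) {
  x <- c.moran_rational(...)
  acc <- rational(0)
  for (i in seq_along(x)) acc <- acc + x[i]
  acc
}

#' Coerce to an exact rational vector
#'
#' Integer-valued numerics become exact integers; fraction strings like
#' `"3/7"` are parsed; other numerics are reconstructed by a continued
#' fraction with denominator at most `1e9`, which errors unless some such
#' fraction reproduces the double bit-exactly (grid values like `0.25` or
#' `1/3` stored as a double do; arbitrary reals need not).
#'
#' @param x numeric, character, or `moran_rational`.
#' @return A `moran_rational` vector.
#' @export
as_rational <- function(x) {
  if (inherits(x, "moran_rational")) return(x)
  if (is.character(x)) {
    parts <- strsplit(x, "/", fixed = TRUE)
    num <- vapply(parts, function(p) as.numeric(p[1]), 0)
    den <- vapply(parts, function(p) if (length(p) > 1) as.numeric(p[2]) else 1, 0)
    return(rational(num, den))
  }
  if (!is.numeric(x)) stop("cannot coerce to rational")
  num <- den <- numeric(length(x))
  for (i in seq_along(x)) {
    if (x[i] == round(x[i])) {
      num[i] <- x[i]; den[i] <- 1
    } else {
      cf <- .approx_fraction(x[i])
      if (is.null(cf))
        stop("numeric value ", x[i], " is not an exact small rational; ",
             "pass it as a fraction string like \"1/3\"")
      num[i] <- cf[1]; den[i] <- cf[2]
    }
  }
  rational(num, den)
}

# Exact small-denominator reconstruction of a double, or NULL.
.approx_fraction <- function(x, max_den = 1e9) {
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; y <- x
  for (k in 1:64) {
    a <- floor(y)
    p <- a * p1 + p0; q <- a * q1 + q0
    if (q > max_den) return(NULL)
    if (p / q == x) return(c(p, q))
    if (y == a) return(NULL)
    y <- 1 / (y - a)
    p0 <- p1; q0 <- q1; p1 <- p; q1 <- q
  }
  NULL
}

#' @export
Ops.moran_rational <- function(e1, e2) {
  if (nargs() == 1L) {
    if (.Generic == "-") return(rational(-e1$num, e1$den))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not supported")
  }
  e1 <- as_rational(e1); e2 <- as_rational(e2)
  n <- max(length(e1), length(e2))
  i1 <- rep_len(seq_along(e1), n); i2 <- rep_len(seq_along(e2), n)
  a <- e1$num[i1]; b <- e1$den[i1]; c_ <- e2$num[i2]; d <- e2$den[i2]
  switch(.Generic,
    "+" = rational(.check_exact(a * d + c_ * b), .check_exact(b * d)),
    "-" = rational(.check_exact(a * d - c_ * b), .check_exact(b * d)),
    "*" = rational(.check_exact(a * c_), .check_exact(b * d)),
    "/" = {
      if (any(c_ == 0)) stop("division by zero")
      rational(.check_exact(a * d), .check_exact(b * c_))
    },
    "==" = .check_exact(a * d) == .check_exact(c_ * b),
    "!=" = .check_exact(a * d) != .check_exact(c_ * b),
    "<"  = .check_exact(a * d) < .check_exact(c_ * b),
    ">"  = .check_exact(a * d) > .check_exact(c_ * b),
    "<=" = .check_exact(a * d) <= .check_exact(c_ * b),
    ">=" = .check_exact(a * d) >= .check_exact(c_ * b),
    stop(.Generic, " not supported for rationals")
  )
}
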