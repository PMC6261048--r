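# Batch classification of all small connected graphs: the regime census.
#
# Strategy per graph (method "hybrid", the default): regular graphs are
# certified isothermal outright; graphs whose orbit-reduced system is small
# enough are classified fully symbolically; the remainder are classified by
# a numeric scan whose findings are then confirmed with exact rational
# solves — the sign of Phi - Phi0 is certified exactly at the grid points
# flanking every detected transition, at every near-tie grid point, and at
# a spread of representative fitnesses for every graph whose scan shows a
# suppression regime anywhere.  "exact" forces full symbolic
# classification; "scan" skips all exact confirmation.

.BARCODE_GRID <- seq(0.25, 10, 0.25)

# exact sign of D(r) = Phi(r) - Phi0(r) at a rational point, via an exact
# solve of the (reduced) system
.exact_D_sign <- function(sys, n, pt) {
  rr <- as_rational(pt)
  avg <- .solve_sys(sys, as.character(rr), "exact")$average_frac
  ref <- phi0(n, as.character(rr))
  cpp_rat_cmp(avg, ref)
}

# classification record for one graph
.census_classify <- function(g, method = "hybrid", exact_limit = 16,
                             zero_tol = 1e-9, grid = NULL, extended = NULL,
                             confirm_points = c("3/2", "2", "5", "20", "100", "1000")) {
  n <- g$n
  if (is_isothermal(g)) {
    prof <- .profile("isothermal", character(0),
                     data.frame(r_c = numeric(0), direction = character(0),
                                lo = character(0), hi = character(0)),
                     "exact", n)
    return(list(profile = prof, signs = rep(0L, length(.BARCODE_GRID))))
  }
  orbit_of <- subset_orbits(g)
  K <- length(unique(orbit_of)) - 2L
  if (method == "exact" || (method == "hybrid" && K <= exact_limit)) {
    prof <- classify(g, "exact")
    D <- rf_sub(interpolate_fixation(g), phi0_fun(n))
    dv <- rf_eval(D, .BARCODE_GRID)
    return(list(profile = prof,
                signs = ifelse(dv > 0, 1L, ifelse(dv < 0, -1L, 0L))))
  }
  sys <- build_polynomial_system(g, orbit_of)
  scan <- .scan_profile(sys, n, grid, extended, zero_tol)
  meth <- sprintf("numeric-scan[%g..%g]", scan$range[1], scan$range[2])
  inconclusive <- scan$inconclusive
  if (method == "hybrid") {
    ok <- TRUE
    n_confirm <- 0L
    # certify the flanks of every detected transition
    for (k in seq_len(nrow(scan$transitions))) {
      lo <- max(scan$transitions$r_c[k] - 0.01, (1 + scan$transitions$r_c[k]) / 2)
      hi <- scan$transitions$r_c[k] + 0.01
      want <- if (scan$transitions$direction[k] == "S/A") c(-1L, 1L) else c(1L, -1L)
      got <- c(.exact_D_sign(sys, n, .rationalize(lo)),
               .exact_D_sign(sys, n, .rationalize(hi)))
      n_confirm <- n_confirm + 2L
      if (!identical(got, want)) { ok <- FALSE; break }
    }
    # certify suppression regimes at representative points
    if (ok && any(scan$sequence == "S")) {
      expected <- .expected_signs(scan$transitions, scan$sequence, confirm_points)
      for (k in seq_along(confirm_points)) {
        if (is.na(expected[k])) next # too close to a transition
        n_confirm <- n_confirm + 1L
        if (.exact_D_sign(sys, n, confirm_points[k]) != expected[k]) {
          ok <- FALSE; break
        }
      }
    }
    # spot-certify a pure amplification regime at one interior fitness
    if (ok && identical(scan$sequence, "A")) {
      n_confirm <- n_confirm + 1L
      if (.exact_D_sign(sys, n, "2") != 1L) ok <- FALSE
    }
    # re-decide every near-tie grid point exactly
    if (ok && length(scan$ties)) {
      for (tie in scan$ties) {
        s <- .exact_D_sign(sys, n, .rationalize(tie))
        n_confirm <- n_confirm + 1L
        if (s == 0) { ok <- FALSE; break } # a true tie needs full symbolics
      }
    }
    if (ok && n_confirm > 0) meth <- paste0(meth, "+exact-confirm")
    else { # escalate: full symbolic classification
      prof <- classify(g, "exact")
      D <- rf_sub(interpolate_fixation(g), phi0_fun(n))
      dv <- rf_eval(D, .BARCODE_GRID)
      return(list(profile = prof,
                  signs = ifelse(dv > 0, 1L, ifelse(dv < 0, -1L, 0L))))
    }
  }
  prof <- .profile(scan$classification, scan$sequence, scan$transitions,
                   meth, n, inconclusive = inconclusive)
  std <- match(round(.BARCODE_GRID, 10), round(scan$data$r, 10))
  signs <- ifelse(is.na(std), NA_integer_, scan$data$sign[std])
  # fill sub-unit fitnesses absent from a custom grid with fresh solves
  miss <- which(is.na(signs))
  for (k in miss) {
    d <- .solve_sys(sys, .BARCODE_GRID[k])$average - phi0(n, .BARCODE_GRID[k])
    signs[k] <- if (abs(d) < zero_tol) 0L else if (d > 0) 1L else -1L
  }
  list(profile = prof, signs = signs)
}

# exact small rational representation of a scan point
.rationalize <- function(x) {
  f <- .approx_fraction(x)
  if (is.null(f)) f <- c(round(x * 2^20), 2^20)
  sprintf("%.0f/%.0f", f[1], f[2])
}

# expected sign of D at given points from the scanned transition structure;
# NA when a point is within 0.05 of a transition
.expected_signs <- function(transitions, sequence, points) {
  pts <- cpp_rat_to_double(points)
  out <- integer(length(pts))
  for (k in seq_along(pts)) {
    if (nrow(transitions) && any(abs(transitions$r_c - pts[k]) < 0.05)) {
      out[k] <- NA_integer_
    } else {
      idx <- if (nrow(transitions)) sum(transitions$r_c < pts[k]) + 1 else 1
      out[k] <- if (sequence[idx] == "A") 1L else -1L
    }
  }
  out
}

#' Run the regime census over all small connected graphs
#'
#' Enumerates every connected graph of the requested orders up to
#' isomorphism (ascending canonical id) and classifies each one.  Records
#' are appended to `out` (tab-separated, one header line) as soon as each
#' graph is finished, so an interrupted run can be resumed with
#' `resume = TRUE`; output is deterministic regardless of interruptions.
#'
#' @param orders integer vector of graph orders (2..8).
#' @param method `"hybrid"` (scan prefilter with exact confirmation and
#'   full symbolics for small orbit systems — the default), `"exact"`
#'   (full symbolic classification of every graph) or `"scan"` (numeric
#'   only, apparent classifications).
#' @param out optional path of the census table.
#' @param resume skip graphs already present in `out`.
#' @param exact_limit orbit-count bound below which hybrid classification
#'   goes fully symbolic.
#' @param zero_tol scan tie threshold on `|Phi - Phi0|`.
#' @param grid,extended scan grids (see [classify()]).
#' @param progress print one line per 100 graphs.
#' @return A data frame of census records (invisibly if `out` is given):
#'   canonical `id`, canonical `graph6`, `order`, `size`, `classification`,
#'   `n_transitions`, `transitions` (`dir@r_c` separated by `;`),
#'   `method`, `signs` (barcode over the standard grid 0.25..10).
#' @export
run_census <- function(orders, method = c("hybrid", "exact", "scan"),
                       out = NULL, resume = FALSE, exact_limit = 16,
                       zero_tol = 1e-9, grid = NULL, extended = NULL,
                       progress = FALSE) {
  method <- match.arg(method)
  cols <- c("id", "graph6", "order", "size", "classification",
            "n_transitions", "transitions", "method", "signs")
  done <- character(0)
  if (!is.null(out) && file.exists(out) && resume) {
    prev <- read.delim(out, colClasses = "character")
    done <- prev$id
  } else if (!is.null(out)) {
    writeLines(paste(cols, collapse = "\t"), out)
  }
  rows <- list()
  for (N in sort(orders)) {
    graphs <- enumerate_connected(N)
    for (i in seq_along(graphs)) {
      g <- graphs[[i]]
      id <- sprintf("%.0f", canonical_id(g))
      if (id %in% done) next
      res <- .census_classify(g, method, exact_limit, zero_tol, grid, extended)
      prof <- res$profile
      rec <- data.frame(
        id = id,
        graph6 = graph6_encode(moran_graph(.canonical_edges(g), n = N)),
        order = N, size = nrow(g$edges),
        classification = prof$classification,
        n_transitions = nrow(prof$transitions),
        transitions = paste(sprintf("%s@%.6f", prof$transitions$direction,
                                    prof$transitions$r_c), collapse = ";"),
        method = prof$method,
        signs = paste(c("-", "0", "+")[res$signs + 2L], collapse = ""))
      rows[[length(rows) + 1]] <- rec
      if (!is.null(out))
        write.table(rec, out, append = TRUE, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
      if (progress && i %% 100 == 0)
        message(sprintf("order %d: %d/%d", N, i, length(graphs)))
    }
  }
  res <- do.call(rbind, rows)
  if (!is.null(out)) {
    full <- read.delim(out, colClasses = "character")
    full$order <- as.integer(full$order)
    return(invisible(full))
  }
  res
}

#' Summarise a census in the standard taxonomy
#'
#' Counts, per order: isothermal graphs, global suppressors and amplifiers
#' (no transition), and graphs by transition pattern (S/A, A/S, S/A/S,
#' ...).  Percentages are always recomputed from the counts.
#'
#' @param census a data frame from [run_census()] or the path of a census
#'   table.
#' @return A `census_summary` data frame with one row per order.
#' @export
summarize_census <- function(census) {
  if (is.character(census)) {
    census <- read.delim(census, colClasses = "character")
    census$order <- as.integer(census$order)
  }
  pats <- c("S/A", "A/S", "S/A/S", "A/S/A", "S/A/S/A")
  out <- NULL
  for (N in sort(unique(census$order))) {
    sub <- census[census$order == N, ]
    row <- data.frame(order = N, total = nrow(sub),
                      isothermal = sum(sub$classification == "isothermal"),
                      suppressor = sum(sub$classification == "suppressor"),
                      amplifier = sum(sub$classification == "amplifier"))
    for (p in pats)
      row[[gsub("/", "", p)]] <- sum(sub$classification == p)
    row$other <- row$total - row$isothermal - row$suppressor -
      row$amplifier - sum(unlist(row[gsub("/", "", pats)]))
    # "exact": every graph fully symbolically classified; "confirmed":
    # scans backed by exact sign confirmations; "apparent": scan only
    row$guarantee <- if (all(sub$method == "exact")) "exact"
      else if (all(grepl("exact", sub$method))) "confirmed" else "apparent"
    out <- rbind(out, row)
  }
  structure(out, class = c("census_summary", "data.frame"))
}

#' @export
print.census_summary <- function(x, ...) {
  cat("Regime census summary (percentages recomputed):\n")
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    pct <- function(k) sprintf("%d (%.2f%%)", k, 100 * k / r$total)
    cat(sprintf(
      "  N=%d  #%d  iso %s  sup %s  S/A %s  A/S %s  S/A/S %s  amp %d  [%s]\n",
      r$order, r$total, pct(r$isothermal), pct(r$suppressor), pct(r$SA),
      pct(r$AS), pct(r$SAS), r$amplifier, r$guarantee))
  }
  invisible(x)
}

#' Export a regime barcode
#'
#' One row per graph, one column per fitness of the standard grid
#' (0.25 to 10 by 0.25); entries are -1 (suppression), 0 (tie /
#' isothermal) or +1 (amplification).  With `sort = "by-pattern"` rows are
#' ordered lexicographically by sign pattern, which groups equal regime
#' structures into visible bands.
#'
#' @param census a census data frame or table path (see
#'   [summarize_census()]).
#' @param sort `"unsorted"` (canonical id order) or `"by-pattern"`.
#' @param out optional path for a tab-separated export.
#' @return The sign matrix (graphs x grid), invisibly when `out` is given.
#' @export
barcode_export <- function(census, sort = c("unsorted", "by-pattern"),
                           out = NULL) {
  sort <- match.arg(sort)
  if (is.character(census)) census <- read.delim(census, colClasses = "character")
  sgn <- census$signs
  if (sort == "by-pattern") {
    o <- order(sgn)
    census <- census[o, ]; sgn <- sgn[o]
  }
  M <- t(vapply(strsplit(sgn, ""), function(ch)
    c("-" = -1L, "0" = 0L, "+" = 1L)[ch], integer(nchar(sgn[1]))))
  dimnames(M) <- list(census$id, sprintf("r%.2f", .BARCODE_GRID))
  if (!is.null(out)) {
    write.table(cbind(id = census$id, as.data.frame(M)), out, sep = "\t",
                quote = FALSE, row.names = FALSE)
    return(invisible(M))
  }
  M
}
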