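# Monte-Carlo estimation of fixation probabilities, used exclusively as an
# independent stochastic check of the exact and numeric solvers.

#' Estimate a fixation probability by simulation
#'
#' Runs independent Birth-Death Moran trajectories until extinction or
#' fixation.  Each step selects a reproducing individual with probability
#' proportional to fitness (`r` for mutants, 1 for residents) and replaces
#' a uniformly chosen neighbour — the same transition kernel the solvers
#' use, sampled instead of solved.  By default each trajectory starts from
#' a uniformly chosen single mutant vertex.
#'
#' @param g a [moran_graph].
#' @param r mutant fitness (positive numeric).
#' @param runs number of independent trajectories.
#' @param seed optional RNG seed (`set.seed()`), making the estimate
#'   reproducible.
#' @param initial optional fixed initial mutant set (vector of vertices);
#'   default: uniform random single mutant.
#' @return A `sim_estimate` with the `estimate`, its binomial standard
#'   error `std_error`, counts, and (for uniform initialisation) the
#'   per-initial-vertex conditional fixation frequencies.
#' @examples
#' estimate_fixation(graph_clique(3), r = 2, runs = 2000, seed = 1)
#' @export
estimate_fixation <- function(g, r, runs = 1e5, seed = NULL, initial = NULL) {
  stopifnot(inherits(g, "moran_graph"))
  if (!is.numeric(r) || length(r) != 1 || r <= 0) stop("fitness must be positive")
  if (runs < 1) stop("runs must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  init <- if (is.null(initial)) integer(0) else as.integer(unique(initial))
  if (length(init) && (any(init < 1) || any(init > g$n)))
    stop("initial vertices out of range")
  if (length(init) == g$n) stop("initial set must leave at least one resident")
  res <- cpp_simulate_fixation(g$adj, r, as.integer(runs), init)
  est <- res$fixations / runs
  per_vertex <- NULL
  if (length(init) == 0)
    per_vertex <- data.frame(vertex = seq_len(g$n),
                             runs = res$initial_runs,
                             fixations = res$initial_fixations,
                             estimate = ifelse(res$initial_runs > 0,
                                               res$initial_fixations /
                                                 pmax(res$initial_runs, 1), NA))
  structure(list(estimate = est,
                 std_error = sqrt(est * (1 - est) / runs),
                 fixations = res$fixations, runs = runs, seed = seed,
                 r = r, per_vertex = per_vertex),
            class = "sim_estimate")
}

#' @export
print.sim_estimate <- function(x, ...) {
  cat(sprintf(
    "<sim_estimate> r = %g: %d/%d fixed, estimate %.5f (SE %.5f)\n",
    x$r, x$fixations, x$runs, x$estimate, x$std_error))
  invisible(x)
}
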