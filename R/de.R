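# Differential evolution (DE/rand/1/bin) minimiser for the noisy,
# simulation-based G2 objective. Standard scheme: population NP = np_factor
# * dim, mutation factor drawn per mutant from f_range (dither), binomial
# crossover with rate cr, candidates clipped to bounds. Stops when the best
# objective has not improved by at least tol_rel (relatively) over the last
# tol_window iterations, or at max_iter.

#' Differential-evolution settings
#'
#' @param np_factor Population size as a multiple of the number of free
#'   parameters (population = `np_factor * dim`, at least 15).
#' @param cr Crossover rate.
#' @param f_range Range of the mutation factor (dithered per mutant).
#' @param max_iter Maximum number of iterations.
#' @param tol_window,tol_rel Stopping rule: terminate when the last
#'   `tol_window` iterations did not reduce the best objective by at least
#'   `tol_rel` (a 1% improvement window of 50 iterations by default).
#' @param crn Use common random numbers: evaluate every candidate with the
#'   same simulation noise (a fixed RNG substream), trading objective bias
#'   for reduced optimizer chatter. Off by default.
#' @param restarts Number of independent search runs the iteration budget is
#'   split across (each with its own noise substream when `crn = TRUE`);
#'   the final re-evaluation selects among all runs' best candidates. More
#'   than one restart decorrelates the noise-induced bias of a single run
#'   along weakly identified parameter directions.
#' @return A list of class `dmc_de_options`.
#' @export
de_options <- function(np_factor = 10, cr = 0.9, f_range = c(0.5, 1),
                       max_iter = 500, tol_window = 50, tol_rel = 0.01,
                       crn = FALSE, restarts = 1) {
  structure(list(np_factor = np_factor, cr = cr, f_range = f_range,
                 max_iter = max_iter, tol_window = tol_window,
                 tol_rel = tol_rel, crn = crn,
                 restarts = max(1L, as.integer(restarts))),
            class = "dmc_de_options")
}

de_optim <- function(fn, lower, upper, control = de_options()) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(lower < upper))
  np <- max(15L, ceiling(control$np_factor * d))
  pop <- matrix(stats::runif(np * d, rep(lower, each = np),
                             rep(upper, each = np)), nrow = np)
  cost <- apply(pop, 1, fn)
  # archive of every evaluated candidate; the caller's final re-evaluation
  # stage selects among these, so diversity lost during convergence is not
  # lost to the fit
  arch_par <- matrix(NA_real_, np * (control$max_iter + 1L), d)
  arch_cost <- rep(NA_real_, np * (control$max_iter + 1L))
  arch_par[seq_len(np), ] <- pop
  arch_cost[seq_len(np)] <- cost
  n_arch <- np
  best_hist <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(control$max_iter)) {
    for (i in seq_len(np)) {
      r <- sample(seq_len(np)[-i], 3L)
      f <- stats::runif(1, control$f_range[1], control$f_range[2])
      v <- pop[r[1], ] + f * (pop[r[2], ] - pop[r[3], ])
      mask <- stats::runif(d) < control$cr
      mask[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(mask, v, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      ct <- fn(trial)
      n_arch <- n_arch + 1L
      arch_par[n_arch, ] <- trial
      arch_cost[n_arch] <- ct
      if (ct <= cost[i]) {
        pop[i, ] <- trial
        cost[i] <- ct
      }
    }
    best_hist[iter] <- min(cost)
    w <- control$tol_window
    if (iter > w) {
      ref <- best_hist[iter - w]
      if (ref - best_hist[iter] < control$tol_rel * abs(ref)) {
        converged <- TRUE
        break
      }
    }
  }
  i_best <- which.min(cost)
  list(par = pop[i_best, ], value = cost[i_best], pop = pop, cost = cost,
       archive = arch_par[seq_len(n_arch), , drop = FALSE],
       archive_cost = arch_cost[seq_len(n_arch)],
       iterations = iter, converged = converged, trace = best_hist)
}
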