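#' Fit the eight-model ladder
#'
#' Fits every model in the power set of the conflict parameters (see
#' [model_spec()]) to the same data and ranks them by mean BIC across the
#' two object conditions. With several participants in the table, each model
#' is fitted per participant, BIC values are averaged across participants
#' and conditions, and the participants' condition-specific estimates of
#' every free parameter are compared by paired t-tests (as in the customary
#' ladder tables).
#'
#' A failing fit for one model is caught and reported as an `NA` row;
#' partial results are retained.
#'
#' @param trials Trial table; may contain a `participant` column.
#' @param specs List of [model_spec()]s (default all eight).
#' @param profile Passed to [dmc_fit()]; off by default here — BIC ranking
#'   compares whole models and is insensitive to position along the A-tau
#'   ridge, so the profile stage's extra final-size evaluations are not
#'   worth their cost across eight models.
#' @param ... Passed to [dmc_fit()] (`n_sim`, `de`, `seed`, ...).
#' @return An object of class `dmc_ladder`: a data frame with one row per
#'   model (label, k, mean G2, mean BIC, rank), ordered by mean BIC, with
#'   the underlying fits in `attr(, "fits")` and paired-comparison p-values
#'   in `attr(, "comparisons")` when participants > 1.
#' @export
model_ladder <- function(trials, specs = all_model_specs(),
                         profile = FALSE, ...) {
  by_pp <- if ("participant" %in% names(trials))
    split(trials, trials$participant) else list(`1` = trials)
  labels <- vapply(specs, function(s) s$label, "")
  fits <- lapply(specs, function(spec) {
    lapply(by_pp, function(tt)
      tryCatch(dmc_fit(tt, spec = spec, profile = profile, ...),
               error = function(e) e))
  })
  names(fits) <- labels

  row_of <- function(spec, fl) {
    ok <- Filter(function(f) inherits(f, "dmc_fit"), fl)
    if (length(ok) == 0)
      return(data.frame(model = spec$label, k = spec$k, g2 = NA_real_,
                        mean_bic = NA_real_, n_fits = 0L,
                        stringsAsFactors = FALSE))
    data.frame(model = spec$label, k = spec$k,
               g2 = mean(vapply(ok, function(f) f$g2_total, 0)),
               mean_bic = mean(vapply(ok, function(f) f$mean_bic, 0)),
               n_fits = length(ok), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, Map(row_of, specs, fits))
  tab <- tab[order(tab$mean_bic), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL

  comparisons <- NULL
  if (length(by_pp) > 1) {
    comparisons <- list()
    for (i in seq_along(specs)) {
      spec <- specs[[i]]
      ok <- Filter(function(f) inherits(f, "dmc_fit"), fits[[i]])
      if (length(ok) < 3 || length(spec$free) == 0) next
      for (p in spec$free) {
        vals <- t(vapply(ok, function(f) coef(f)[, p], numeric(2)))
        pv <- tryCatch(paired_t(vals[, 1], vals[, 2])$p_value,
                       error = function(e) NA_real_)
        comparisons[[length(comparisons) + 1L]] <-
          data.frame(model = spec$label, parameter = p, p_value = pv,
                     stringsAsFactors = FALSE)
      }
    }
    comparisons <- if (length(comparisons))
      do.call(rbind, comparisons) else NULL
  }
  structure(tab, fits = fits, comparisons = comparisons,
            class = c("dmc_ladder", "data.frame"))
}

#' @export
print.dmc_ladder <- function(x, ...) {
  cat("Eight-model BIC ladder (lower mean BIC is better)\n")
  print.data.frame(cbind(x["model"], round(x[c("g2", "mean_bic")], 2),
                         x[c("k", "n_fits", "rank")]), row.names = FALSE)
  cmp <- attr(x, "comparisons")
  if (!is.null(cmp)) {
    cat("\nPaired comparisons of condition-specific estimates:\n")
    print.data.frame(cmp, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Parameter-recovery study
#'
#' Simulates data from known parameter values, refits the generating model,
#' and summarises how well each parameter is recovered across replicates:
#' the standard simulate-and-refit check of estimator bias and precision.
#'
#' @param true_params List with one [dmc_params()] per condition (names are
#'   the condition labels).
#' @param spec The generating [model_spec()] to refit.
#' @param n_trials Simulated trials per congruency and condition in each
#'   generated data set.
#' @param n_reps Number of replicates.
#' @param seed Optional seed for the whole study.
#' @param ... Passed to [dmc_fit()].
#' @return An object of class `dmc_recovery`: a long data frame with one
#'   row per replicate, condition and parameter (`true`, `recovered`), with
#'   a per-parameter bias/RMSE summary in `attr(, "summary")`.
#' @export
recovery_study <- function(true_params, spec = model_spec("mu_t"),
                           n_trials = 10000, n_reps = 5, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  conditions <- names(true_params)
  kinds <- c("mu_t", "A", "tau", "b", "mu_r", "sigma_r")
  truth <- t(vapply(true_params, function(p) unlist(p[kinds]),
                    numeric(length(kinds))))
  opts <- list(...)
  sim_opts <- if (!is.null(opts$sim_opts)) opts$sim_opts else sim_options()
  rows <- list()
  for (rep in seq_len(n_reps)) {
    dat <- do.call(rbind, lapply(conditions, function(cond)
      cbind(object = cond,
            simulate_both(true_params[[cond]], n_trials, sim_opts),
            stringsAsFactors = FALSE)))
    fit <- dmc_fit(dat, spec = spec, conditions = conditions, ...)
    est <- coef(fit)
    for (cond in conditions)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = rep, condition = cond, parameter = kinds,
        true = truth[cond, kinds], recovered = est[cond, kinds],
        stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  err <- out$recovered - out$true
  summ <- do.call(rbind, lapply(split(seq_len(nrow(out)), out$parameter),
                                function(ix) data.frame(
    parameter = out$parameter[ix[1]],
    bias = mean(err[ix]), rmse = sqrt(mean(err[ix]^2)),
    rel_rmse = sqrt(mean((err[ix] / out$true[ix])^2)),
    stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  structure(out, summary = summ, class = c("dmc_recovery", "data.frame"))
}

#' @export
print.dmc_recovery <- function(x, ...) {
  cat("Parameter recovery over", max(x$rep), "replicate data set(s)\n")
  print.data.frame(attr(x, "summary"), row.names = FALSE, digits = 3)
  invisible(x)
}
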