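#' Model specification for the eight-model ladder
#'
#' Every model estimates six parameter kinds: the three conflict parameters
#' (`mu_t`, `A`, `tau`) and the three shared nuisance parameters (`b`,
#' `mu_r`, `sigma_r`, which cannot produce a condition-specific congruency
#' effect and are therefore always constrained equal across conditions).
#' A specification names which of the conflict parameters may take different
#' values in the two object conditions; the power set of \{`mu_t`, `A`,
#' `tau`\} gives eight models, from the null model (nothing varies) to the
#' full model (all three vary). The number of estimated values is
#' `k = 6 + |free|`. `sigma`, `alpha_s` and `a_shape` stay at their fixed
#' conventional values (4, 3, 2).
#'
#' @param free Character subset of `c("mu_t", "A", "tau")`.
#' @return An object of class `dmc_model_spec` with fields `free`, `k` and
#'   `label`.
#' @examples
#' model_spec("mu_t")
#' length(all_model_specs())  # 8
#' @export
model_spec <- function(free = character()) {
  conflict <- c("mu_t", "A", "tau")
  free <- unique(as.character(free))
  if (!all(free %in% conflict))
    stop("'free' must be a subset of {mu_t, A, tau}", call. = FALSE)
  free <- conflict[conflict %in% free]   # canonical order
  label <- if (length(free) == 0) "M_0" else
    paste0("M_", paste(free, collapse = "+"))
  structure(list(free = free, k = 6L + length(free), label = label),
            class = "dmc_model_spec")
}

#' @export
print.dmc_model_spec <- function(x, ...) {
  cat(x$label, ": free across conditions {",
      paste(x$free, collapse = ", "), "}, k =", x$k, "\n")
  invisible(x)
}

#' @rdname model_spec
#' @export
all_model_specs <- function() {
  conflict <- c("mu_t", "A", "tau")
  sets <- unlist(lapply(0:3, function(m) utils::combn(conflict, m,
                                                      simplify = FALSE)),
                 recursive = FALSE)
  lapply(sets, model_spec)
}

#' Parameter search bounds
#'
#' Lower and upper limits of the estimated parameters used by the
#' differential-evolution search: `mu_t` in \[0.1, 1.5\], `A` in \[0, 40\],
#' `tau` in \[1, 500\] ms, `b` in \[20, 100\], `mu_r` in \[200, 500\] ms,
#' `sigma_r` in \[5, 50\] ms.
#'
#' @param ... Named numeric length-2 vectors overriding individual bounds,
#'   e.g. `tau = c(1, 400)`.
#' @return An object of class `dmc_bounds`: a named list of `c(low, high)`.
#' @export
dmc_bounds <- function(...) {
  b <- list(mu_t = c(0.1, 1.5), A = c(0, 40), tau = c(1, 500),
            b = c(20, 100), mu_r = c(200, 500), sigma_r = c(5, 50))
  ov <- list(...)
  if (!all(names(ov) %in% names(b)))
    stop("unknown bound name(s): ",
         paste(setdiff(names(ov), names(b)), collapse = ", "), call. = FALSE)
  for (nm in names(ov)) {
    v <- ov[[nm]]
    if (length(v) != 2 || v[1] >= v[2])
      stop("bound '", nm, "' must be c(low, high) with low < high",
           call. = FALSE)
    b[[nm]] <- v
  }
  structure(b, class = "dmc_bounds")
}

# Layout of the DE search vector for a spec: free conflict parameters get one
# entry per condition, shared parameters one entry.
vector_layout <- function(spec, conditions) {
  nm <- character(0)
  for (p in c("mu_t", "A", "tau"))
    nm <- c(nm, if (p %in% spec$free) paste(p, conditions, sep = ".") else p)
  c(nm, "b", "mu_r", "sigma_r")
}

layout_bounds <- function(layout, bounds) {
  base <- sub("\\..*$", "", layout)
  list(lower = vapply(base, function(p) bounds[[p]][1], 0),
       upper = vapply(base, function(p) bounds[[p]][2], 0))
}

# Expand a search vector into one dmc_params object per condition.
vector_to_params <- function(vec, spec, conditions,
                             fixed = list(sigma = 4, alpha_s = 3,
                                          a_shape = 2)) {
  names(vec) <- vector_layout(spec, conditions)
  out <- list()
  for (cond in conditions) {
    val <- function(p) {
      key <- if (p %in% spec$free) paste(p, cond, sep = ".") else p
      unname(vec[[key]])
    }
    out[[cond]] <- do.call(dmc_params, c(
      list(mu_t = val("mu_t"), A = val("A"), tau = max(val("tau"), 1),
           b = val("b"), mu_r = val("mu_r"), sigma_r = val("sigma_r")),
      fixed))
  }
  out
}

#' Fit the conflict diffusion model to trial data
#'
#' Jointly fits one model specification to the two object conditions of a
#' trial table by minimising the summed G-squared discrepancy between
#' observed and simulated RT-quantile and conditional-accuracy summaries
#' with differential evolution. Parameters listed as free in `spec` take a
#' value per condition; all others take a single shared value — the equality
#' constraints are what make the fit joint.
#'
#' During the search each candidate is evaluated on `n_sim` freshly
#' simulated trials per congruency and condition; after the search the best
#' members of the final population are re-evaluated on `n_sim_final` trials
#' and the winner is reported, which de-biases the selection among noisy
#' objective values. Per-condition BIC uses the model's total number of
#' estimated parameters `k` and that condition's included trial count.
#'
#' @param trials Trial table with columns `object` (two conditions),
#'   `congruency`, `rt`, `accuracy`, `status`.
#' @param spec A [model_spec()].
#' @param bounds A [dmc_bounds()] object.
#' @param n_sim Simulated trials per congruency and condition per candidate
#'   evaluation during the search.
#' @param n_sim_final Simulated trials for the final re-evaluation.
#' @param final_top Number of best search candidates entering the final
#'   re-evaluation.
#' @param final_reps Independent `n_sim_final` evaluations averaged per
#'   candidate in the final selection (fresh simulation noise even when the
#'   search uses common random numbers).
#' @param profile Re-resolve the distractor block (`A`, `tau`) by a
#'   coarse-then-fine grid scored at `n_sim_final` before the final
#'   selection. At the search's simulation size the Monte-Carlo noise floor
#'   flattens the A-tau trade-off ridge, so the search cannot place the
#'   distractor timing; the profile stage can. Adds a few hundred
#'   final-size evaluations; disable for quick exploratory fits.
#' @param sim_opts A [sim_options()] object (deadline/floor handling must
#'   match the data's).
#' @param de A [de_options()] object.
#' @param seed Optional integer seed making the whole fit reproducible.
#' @param conditions Names of the two object conditions (default
#'   `c("same", "different")`, taken from the data if absent).
#' @return An object of class `dmc_fit`; see [coef.dmc_fit()],
#'   [summary.dmc_fit()], [simulate.dmc_fit()], [predict.dmc_fit()],
#'   [plot.dmc_fit()].
#' @export
dmc_fit <- function(trials, spec = model_spec("mu_t"), bounds = dmc_bounds(),
                    n_sim = 2000, n_sim_final = 10000, final_top = 10,
                    final_reps = 3, profile = TRUE,
                    sim_opts = sim_options(), de = de_options(),
                    seed = NULL, conditions = c("same", "different")) {
  stopifnot(inherits(spec, "dmc_model_spec"), inherits(bounds, "dmc_bounds"))
  if (!all(conditions %in% unique(trials$object)))
    conditions <- sort(unique(trials$object))
  if (length(conditions) != 2)
    stop("dmc_fit expects exactly two object conditions", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  observed <- lapply(conditions, function(cond)
    summarize_observed(trials[trials$object == cond, , drop = FALSE]))
  names(observed) <- conditions
  n_obs <- vapply(observed, function(o)
    o$congruent$n_included + o$incongruent$n_included, 0)

  layout <- vector_layout(spec, conditions)
  lb <- layout_bounds(layout, bounds)
  crn_seed <- NULL

  objective <- function(vec, n_per_cell, use_crn = TRUE) {
    params <- vector_to_params(vec, spec, conditions)
    if (de$crn && use_crn && !is.null(crn_seed)) {
      saved <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", saved, envir = globalenv()))
      set.seed(crn_seed)
    }
    total <- 0
    for (cond in conditions) {
      pred <- simulate_both(params[[cond]], n_per_cell, sim_opts)
      total <- total + g2(observed[[cond]], pred)
    }
    total
  }

  # The iteration budget is split across independent search runs; with
  # common random numbers each run gets its own noise substream, so the
  # substream-induced bias along weakly identified directions (the A-tau
  # ridge) decorrelates across runs.
  de_run <- de
  de_run$max_iter <- ceiling(de$max_iter / de$restarts)
  runs <- vector("list", de$restarts)
  for (s in seq_len(de$restarts)) {
    if (de$crn) crn_seed <- sample.int(.Machine$integer.max, 1L)
    runs[[s]] <- de_optim(function(v) objective(v, n_sim), lb$lower,
                          lb$upper, control = de_run)
  }

  # Final selection at the final simulation size. At the search's
  # simulation size the Monte-Carlo noise floor flattens the objective
  # along the weakly identified A-tau ridge, so where the population
  # converges on that ridge is arbitrary; only final-size evaluations can
  # resolve it, and even those carry per-evaluation noise comparable to the
  # G2 differences along the ridge. All final-stage scores are therefore
  # PAIRED: every candidate is evaluated on the same small set of fixed
  # noise substreams (common random numbers across candidates), so the
  # simulation noise largely cancels out of score differences.
  n_extra <- 3L * final_reps
  sel_seeds <- sample.int(.Machine$integer.max, final_reps + n_extra)
  score <- function(v, idx = seq_len(final_reps)) {
    mean(vapply(sel_seeds[idx], function(s) {
      saved <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", saved, envir = globalenv()))
      set.seed(s)
      objective(v, n_sim_final, use_crn = FALSE)
    }, 0))
  }

  arch <- do.call(rbind, lapply(runs, `[[`, "archive"))
  arch_cost <- do.call(c, lapply(runs, `[[`, "archive_cost"))
  ord <- order(arch_cost)
  top <- lapply(ord[seq_len(min(final_top, length(ord)))],
                function(i) arch[i, ])

  # Ridge profile of the distractor block: the well-identified parameters
  # (mu_t, b, mu_r, sigma_r) of the best vector are kept fixed while
  # (A, tau) is re-resolved by a coarse-then-fine grid scored with the
  # paired evaluations above.
  if (profile && length(grep("^tau", layout))) {
    base_vec <- arch[ord[1], ]
    a_cols <- grep("^A", layout)
    t_cols <- grep("^tau", layout)
    splice <- function(a, t) {
      v <- base_vec
      v[a_cols] <- a
      v[t_cols] <- t
      v
    }
    coarse <- expand.grid(
      A = seq(bounds$A[1], bounds$A[2], length.out = 6),
      tau = seq(bounds$tau[1], bounds$tau[2], length.out = 8))
    cost1 <- vapply(seq_len(nrow(coarse)), function(i)
      score(splice(coarse$A[i], coarse$tau[i]),
            seq_len(min(2L, final_reps))), 0)
    w <- which.min(cost1)
    fine <- expand.grid(
      A = pmin(pmax(coarse$A[w] + seq(-4, 4, by = 2), bounds$A[1]),
               bounds$A[2]),
      tau = pmin(pmax(coarse$tau[w] + seq(-36, 36, by = 18),
                      bounds$tau[1]), bounds$tau[2]))
    cand_fine <- lapply(seq_len(nrow(fine)), function(i)
      splice(fine$A[i], fine$tau[i]))
    top <- c(top, cand_fine)
  }
  top <- unique(top)
  # two-round tournament: triage every candidate with final_reps paired
  # evaluations, then separate the leaders with 3x more paired evaluations
  # so that the small G2 differences between neighbouring ridge candidates
  # are resolved rather than drawn by lot
  round1 <- vapply(top, function(v) score(v), 0)
  keep <- order(round1)[seq_len(min(6L, length(top)))]
  round2 <- vapply(top[keep], function(v)
    score(v, final_reps + seq_len(n_extra)), 0)
  combined <- (final_reps * round1[keep] + n_extra * round2) /
    (final_reps + n_extra)
  final_cost <- combined
  best <- top[[keep[which.min(combined)]]]
  res <- list(iterations = sum(vapply(runs, `[[`, 0L, "iterations")),
              converged = all(vapply(runs, `[[`, TRUE, "converged")),
              trace = do.call(c, lapply(runs, `[[`, "trace")))

  params <- vector_to_params(best, spec, conditions)
  g2_cond <- vapply(conditions, function(cond)
    g2(observed[[cond]], simulate_both(params[[cond]], n_sim_final,
                                       sim_opts)), 0)
  bic_cond <- vapply(conditions, function(cond)
    bic(g2_cond[[cond]], spec$k, n_obs[[cond]]), 0)

  structure(list(spec = spec, conditions = conditions, par = best,
                 par_names = layout, params = params,
                 g2 = g2_cond, g2_total = sum(g2_cond),
                 bic = bic_cond, mean_bic = mean(bic_cond),
                 n_obs = n_obs, iterations = res$iterations,
                 converged = res$converged, trace = res$trace,
                 seed = seed, n_sim = n_sim, n_sim_final = n_sim_final,
                 observed = observed, bounds = bounds, sim_opts = sim_opts,
                 de = de, call = match.call()),
            class = "dmc_fit")
}

#' @export
print.dmc_fit <- function(x, ...) {
  cat("Conflict diffusion model fit —", x$spec$label, "\n")
  print(round(coef(x), 3))
  cat(sprintf("G2 = %.2f (per condition: %s)\n", x$g2_total,
              paste(sprintf("%s %.2f", x$conditions, x$g2), collapse = ", ")))
  cat(sprintf("mean BIC = %.2f, k = %d, iterations = %d, converged = %s\n",
              x$mean_bic, x$spec$k, x$iterations, x$converged))
  invisible(x)
}

#' Extract fitted parameters
#'
#' @param object A [dmc_fit()] object.
#' @param ... Unused.
#' @return Matrix with one row per object condition and one column per
#'   estimated parameter kind.
#' @export
coef.dmc_fit <- function(object, ...) {
  kinds <- c("mu_t", "A", "tau", "b", "mu_r", "sigma_r")
  t(vapply(object$params,
           function(p) unlist(p[kinds]), numeric(length(kinds))))
}

#' @export
summary.dmc_fit <- function(object, ...) {
  out <- list(spec = object$spec, coef = coef(object), g2 = object$g2,
              g2_total = object$g2_total, bic = object$bic,
              mean_bic = object$mean_bic, n_obs = object$n_obs,
              iterations = object$iterations, converged = object$converged)
  class(out) <- "summary.dmc_fit"
  out
}

#' @export
print.summary.dmc_fit <- function(x, ...) {
  cat("Model:", x$spec$label, "(free:",
      paste(x$spec$free, collapse = ", "), ")\n")
  print(round(x$coef, 3))
  tab <- rbind(`G2` = x$g2, BIC = x$bic, N = x$n_obs)
  print(round(tab, 2))
  cat(sprintf("mean BIC = %.2f after %d iterations (converged: %s)\n",
              x$mean_bic, x$iterations, x$converged))
  invisible(x)
}

#' Simulate trials from a fitted model
#'
#' @param object A [dmc_fit()] object.
#' @param nsim Trials per congruency and condition.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A trial table with an `object` column.
#' @export
simulate.dmc_fit <- function(object, nsim = 1000, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  do.call(rbind, lapply(object$conditions, function(cond) {
    tab <- simulate_both(object$params[[cond]], nsim, object$sim_opts)
    cbind(object = cond, tab, stringsAsFactors = FALSE)
  }))
}

#' Model-predicted distributional summaries
#'
#' Simulates from the fitted parameters and returns the predicted CDF
#' percentiles, conditional accuracy functions and RT delta function per
#' condition, for comparison with the observed summaries.
#'
#' @param object A [dmc_fit()] object.
#' @param nsim Simulated trials per congruency and condition.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list per condition with elements `cdf` (predicted percentile
#'   cuts per congruency), `caf` and `delta`.
#' @export
predict.dmc_fit <- function(object, nsim = 10000, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  probs <- attr(object$observed[[1]], "probs")
  out <- lapply(object$conditions, function(cond) {
    tab <- simulate_both(object$params[[cond]], nsim, object$sim_opts)
    ok <- tab[tab$status == "ok", ]
    con <- ok[ok$congruency == "congruent", ]
    inc <- ok[ok$congruency == "incongruent", ]
    list(cdf = list(
           congruent = stats::quantile(con$rt[con$accuracy == 1], probs,
                                       type = 7, names = FALSE),
           incongruent = stats::quantile(inc$rt[inc$accuracy == 1], probs,
                                         type = 7, names = FALSE)),
         caf = list(congruent = caf(con), incongruent = caf(inc)),
         delta = delta_function_rt(con$rt[con$accuracy == 1],
                                   inc$rt[inc$accuracy == 1]))
  })
  names(out) <- object$conditions
  out
}

#' Plot observed against model-predicted summaries
#'
#' Three panels per object condition: cumulative RT percentiles, conditional
#' accuracy functions and the RT delta function, observed (points) against
#' model-predicted (lines).
#'
#' @param x A [dmc_fit()] object.
#' @param nsim Simulated trials per congruency and condition for the
#'   predictions.
#' @param ... Passed to plotting functions.
#' @return Invisibly, the predictions.
#' @export
plot.dmc_fit <- function(x, nsim = 10000, ...) {
  pred <- predict(x, nsim = nsim)
  probs <- attr(x$observed[[1]], "probs")
  op <- graphics::par(mfrow = c(length(x$conditions), 3),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (cond in x$conditions) {
    obs <- x$observed[[cond]]
    prd <- pred[[cond]]
    rng <- range(obs$congruent$cuts, obs$incongruent$cuts,
                 prd$cdf$congruent, prd$cdf$incongruent)
    graphics::plot(obs$congruent$cuts, probs, xlim = rng, ylim = c(0, 1),
                   xlab = "RT (ms)", ylab = "cumulative probability",
                   main = paste(cond, "- CDF"), pch = 1, ...)
    graphics::points(obs$incongruent$cuts, probs, pch = 16)
    graphics::lines(prd$cdf$congruent, probs, lty = 1)
    graphics::lines(prd$cdf$incongruent, probs, lty = 2)
    obs_caf_c <- obs$congruent$caf_correct / obs$congruent$caf_n
    obs_caf_i <- obs$incongruent$caf_correct / obs$incongruent$caf_n
    graphics::plot(1:5, obs_caf_c, ylim = c(0.5, 1), xlab = "RT bin",
                   ylab = "accuracy", main = paste(cond, "- CAF"),
                   pch = 1, ...)
    graphics::points(1:5, obs_caf_i, pch = 16)
    graphics::lines(1:5, prd$caf$congruent$accuracy_per_bin, lty = 1)
    graphics::lines(1:5, prd$caf$incongruent$accuracy_per_bin, lty = 2)
    obs_delta <- obs$incongruent$cuts - obs$congruent$cuts
    obs_mid <- (obs$incongruent$cuts + obs$congruent$cuts) / 2
    graphics::plot(obs_mid, obs_delta, xlab = "mean RT (ms)",
                   ylab = "delta (ms)", main = paste(cond, "- delta"),
                   pch = 16, ...)
    graphics::lines(pred[[cond]]$delta$xmid, pred[[cond]]$delta$delta)
  }
  invisible(pred)
}
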