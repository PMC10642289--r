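#' Study design of a flanker experiment
#'
#' Captures the within-subject design emulated by the cohort generator:
#' congruency crossed with object membership (flankers grouped with the
#' target vs. with the outer lines), 112 trials per cell per participant, a
#' 2000 ms response deadline and a 150 ms fast-response floor.
#'
#' @param n_participants Number of participants.
#' @param trials_per_cell Trials per design cell per participant.
#' @param deadline,rt_floor Response window (ms).
#' @param proximity Value written to the trial table's `proximity` column;
#'   the generator simulates the near-flanker regime in which conflict
#'   effects arise.
#' @return An object of class `dmc_study_design`.
#' @export
study_design <- function(n_participants = 40, trials_per_cell = 112,
                         deadline = 2000, rt_floor = 150,
                         proximity = "near") {
  stopifnot(n_participants >= 1, trials_per_cell >= 1)
  structure(list(n_participants = n_participants,
                 trials_per_cell = trials_per_cell,
                 deadline = deadline, rt_floor = rt_floor,
                 proximity = proximity),
            class = "dmc_study_design")
}

#' Population-level specification of a synthetic cohort
#'
#' Defines the group-level mean parameters per object condition, the
#' between-participant variability, and which parameters actually differ
#' between conditions. Participant-level parameters are drawn independently
#' per parameter from normal distributions truncated to the fitting bounds
#' (coefficient of variation `cv`, default 15%); parameters outside the
#' effect structure use the same-condition mean and a single shared draw per
#' participant, so the generated conditions truly differ only in the listed
#' parameters.
#'
#' @param means List with a [dmc_params()] per condition (default the
#'   package's reference parameter sets, [dmc_defaults()]).
#' @param cv Coefficient of variation of the between-participant truncated
#'   normals (0 gives identical participants).
#' @param effect Character subset of `c("mu_t", "A", "tau")` naming the
#'   parameters that differ between conditions (default `"mu_t"` only).
#' @param bounds A [dmc_bounds()] object used for truncation.
#' @return An object of class `dmc_population_spec`.
#' @export
population_spec <- function(means = dmc_defaults("exp1"), cv = 0.15,
                            effect = "mu_t", bounds = dmc_bounds()) {
  stopifnot(length(means) == 2, !is.null(names(means)),
            all(vapply(means, inherits, TRUE, "dmc_params")))
  effect <- unique(as.character(effect))
  if (!all(effect %in% c("mu_t", "A", "tau")))
    stop("'effect' must be a subset of {mu_t, A, tau}", call. = FALSE)
  if (cv < 0) stop("'cv' must be nonnegative", call. = FALSE)
  structure(list(means = means, cv = cv, effect = effect, bounds = bounds),
            class = "dmc_population_spec")
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (sd == 0) return(min(max(mean, lo), hi))
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

#' Draw participant-level parameters
#'
#' @param pop A [population_spec()].
#' @return A list with one [dmc_params()] per condition for one simulated
#'   participant.
#' @export
sample_participant_params <- function(pop) {
  stopifnot(inherits(pop, "dmc_population_spec"))
  conditions <- names(pop$means)
  kinds <- c("mu_t", "A", "tau", "b", "mu_r", "sigma_r")
  base <- pop$means[[1]]
  shared <- list()
  for (p in setdiff(kinds, pop$effect)) {
    bb <- pop$bounds[[p]]
    shared[[p]] <- rtruncnorm1(base[[p]], pop$cv * abs(base[[p]]),
                               bb[1], bb[2])
  }
  out <- list()
  for (cond in conditions) {
    vals <- shared
    for (p in pop$effect) {
      bb <- pop$bounds[[p]]
      m <- pop$means[[cond]][[p]]
      vals[[p]] <- rtruncnorm1(m, pop$cv * abs(m), bb[1], bb[2])
    }
    out[[cond]] <- do.call(dmc_params, c(vals, list(
      sigma = base$sigma, alpha_s = base$alpha_s, a_shape = base$a_shape)))
  }
  out
}

#' Generate a synthetic cohort
#'
#' Simulates a full experiment: for every participant, parameters are drawn
#' from the population specification and every design cell (object condition
#' x congruency) is filled with diffusion-simulated trials, including
#' deadline/floor/nonresponse statuses. Reproducible via `seed`.
#'
#' @param design A [study_design()].
#' @param pop A [population_spec()].
#' @param seed Optional integer seed.
#' @return A trial table with columns `participant`, `proximity`, `object`,
#'   `congruency`, `rt`, `accuracy`, `status`.
#' @examples
#' coh <- generate_cohort(study_design(n_participants = 2,
#'                                     trials_per_cell = 30),
#'                        population_spec(), seed = 1)
#' table(coh$object, coh$congruency)
#' @export
generate_cohort <- function(design = study_design(),
                            pop = population_spec(), seed = NULL) {
  stopifnot(inherits(design, "dmc_study_design"),
            inherits(pop, "dmc_population_spec"))
  if (!is.null(seed)) set.seed(seed)
  opts <- sim_options(deadline = design$deadline,
                      rt_floor = design$rt_floor)
  conditions <- names(pop$means)
  pieces <- vector("list", design$n_participants)
  for (i in seq_len(design$n_participants)) {
    pars <- sample_participant_params(pop)
    cell <- list()
    for (cond in conditions)
      for (cg in c("congruent", "incongruent"))
        cell[[paste(cond, cg)]] <- cbind(
          participant = i, proximity = design$proximity, object = cond,
          simulate_condition(pars[[cond]], cg, design$trials_per_cell,
                             opts),
          stringsAsFactors = FALSE)
    pieces[[i]] <- do.call(rbind, cell)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[, c("participant", "proximity", "object", "congruency", "rt",
          "accuracy", "status")]
}

#' Apply trial exclusions
#'
#' Removes responses outside the response window from all analyses:
#' `too_slow` (beyond the deadline), `too_fast` (below the floor) and
#' `nonresponse`. Statuses are (re)derived from the RT thresholds so that
#' ingested tables without simulator statuses are handled identically.
#' Choice errors are retained — they enter accuracy analyses — and are
#' reported so downstream RT analyses can exclude them.
#'
#' @param trials A trial table.
#' @param deadline,rt_floor Response window (ms).
#' @return A list with `trials` (included rows only) and `report`, a data
#'   frame of exclusion categories with counts and percentages (error rate
#'   computed among included trials).
#' @export
apply_exclusions <- function(trials, deadline = 2000, rt_floor = 150) {
  status <- if ("status" %in% names(trials)) trials$status
            else rep("ok", nrow(trials))
  status[is.na(trials$rt)] <- "nonresponse"
  slow <- !is.na(trials$rt) & trials$rt > deadline
  fast <- !is.na(trials$rt) & trials$rt < rt_floor
  status[slow & status != "nonresponse"] <- "too_slow"
  status[fast & status != "nonresponse"] <- "too_fast"
  status[!slow & !fast & !is.na(trials$rt)] <- "ok"
  keep <- status == "ok"
  n <- nrow(trials)
  included <- trials[keep, , drop = FALSE]
  included$status <- "ok"
  n_err <- sum(included$accuracy == 0, na.rm = TRUE)
  report <- data.frame(
    category = c("too_slow", "too_fast", "nonresponse", "errors"),
    n = c(sum(status == "too_slow"), sum(status == "too_fast"),
          sum(status == "nonresponse"), n_err),
    pct = 100 * c(sum(status == "too_slow") / n,
                  sum(status == "too_fast") / n,
                  sum(status == "nonresponse") / n,
                  if (nrow(included)) n_err / nrow(included) else 0),
    stringsAsFactors = FALSE)
  list(trials = included, report = report)
}
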