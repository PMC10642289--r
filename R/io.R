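#' Read a trial table from CSV
#'
#' Expects the package's standard schema by column name (order free):
#' `participant, proximity, object, congruency, rt_ms, accuracy, status`.
#' RTs are in milliseconds. Malformed rows are reported with their row
#' numbers.
#'
#' @param path CSV file path.
#' @return A validated trial table (with `rt_ms` renamed to `rt`).
#' @export
read_trials <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("participant", "proximity", "object", "congruency",
                "rt_ms", "accuracy", "status")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  rt <- suppressWarnings(as.numeric(raw$rt_ms))
  bad <- which(is.na(rt) & !(raw$rt_ms %in% c("", "NA")))
  if (length(bad))
    stop("non-numeric rt_ms in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  acc <- suppressWarnings(as.integer(raw$accuracy))
  bad <- which(is.na(acc) & !(raw$accuracy %in% c("", "NA")))
  if (length(bad))
    stop("non-integer accuracy in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  bad <- which(!raw$congruency %in% c("congruent", "incongruent"))
  if (length(bad))
    stop("unknown congruency level in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  bad <- which(!raw$status %in% c("ok", "too_slow", "too_fast",
                                  "nonresponse"))
  if (length(bad))
    stop("unknown status in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  data.frame(participant = raw$participant, proximity = raw$proximity,
             object = raw$object, congruency = raw$congruency,
             rt = rt, accuracy = acc, status = raw$status,
             stringsAsFactors = FALSE)
}

#' Write a trial table to CSV
#'
#' Inverse of [read_trials()]: writes the standard header with `rt` renamed
#' to `rt_ms`.
#'
#' @param trials Trial table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  out <- trials
  names(out)[names(out) == "rt"] <- "rt_ms"
  cols <- c("participant", "proximity", "object", "congruency", "rt_ms",
            "accuracy", "status")
  utils::write.csv(out[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' A fully serialisable description of one analysis run: where the data come
#' from (a built-in experiment template to simulate, or an ingested CSV),
#' the seed, and which stages to run. A run is exactly reproducible from its
#' configuration.
#'
#' @param experiment `"exp1"`, `"exp2"` or `"custom"` (template for the
#'   synthetic cohort and reference parameters).
#' @param n_participants,trials_per_cell Cohort size when simulating.
#' @param seed Integer seed for the whole run.
#' @param input_csv Optional path to an existing trial CSV; when given, no
#'   simulation stage runs.
#' @param fit,ladder,recovery Stage toggles.
#' @param fit_n_sim,fit_max_iter,fit_n_sim_final Fitting budget.
#' @param output_dir Optional directory for CSV/JSON outputs.
#' @return An object of class `dmc_config`.
#' @export
run_config <- function(experiment = c("exp2", "exp1", "custom"),
                       n_participants = 8, trials_per_cell = 112,
                       seed = 1, input_csv = NULL,
                       fit = FALSE, ladder = FALSE, recovery = FALSE,
                       fit_n_sim = 2000, fit_max_iter = 150,
                       fit_n_sim_final = 10000, output_dir = NULL) {
  experiment <- match.arg(experiment)
  structure(list(experiment = experiment, n_participants = n_participants,
                 trials_per_cell = trials_per_cell, seed = seed,
                 input_csv = input_csv, fit = fit, ladder = ladder,
                 recovery = recovery, fit_n_sim = fit_n_sim,
                 fit_max_iter = fit_max_iter,
                 fit_n_sim_final = fit_n_sim_final,
                 output_dir = output_dir),
            class = "dmc_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config[order(names(unclass(config)))], tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Ties the stages together: cohort generation (or CSV ingestion), trial
#' exclusions, cell summaries and congruency effects, distributional
#' analyses (delta functions, delta regressions, CAFs, accuracy deltas),
#' and optionally model fitting, the eight-model ladder and a recovery
#' study. Failures in one stage are isolated: the stage is reported in the
#' log with its error and downstream stages that depend on it are skipped.
#'
#' @param config A [run_config()] object.
#' @return A report bundle: a list with `config`, `config_hash`,
#'   `seed_manifest`, `log` (per-stage counts and errors), `exclusions`,
#'   `cells`, `ce`, `tests`, `distributional`, `fit`/`ladder`/`recovery`
#'   (when enabled) and `metrics` (flat named list of headline numbers,
#'   written as JSON when `output_dir` is set).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "dmc_config"))
  set.seed(config$seed)
  log <- list()
  note <- function(stage, ...) {
    log[[stage]] <<- list(...)
  }
  metrics <- list()
  report <- list(config = config, config_hash = config_hash(config),
                 seed_manifest = list(seed = config$seed))

  # --- data stage
  trials <- tryCatch({
    if (!is.null(config$input_csv)) {
      tt <- read_trials(config$input_csv)
      note("data", source = "csv", n = nrow(tt))
      tt
    } else {
      means <- dmc_defaults(if (config$experiment == "exp1") "exp1" else
                              "exp2")
      coh <- generate_cohort(
        study_design(n_participants = config$n_participants,
                     trials_per_cell = config$trials_per_cell),
        population_spec(means = means), seed = config$seed)
      note("data", source = "simulated", n = nrow(coh))
      coh
    }
  }, error = function(e) {
    note("data", error = conditionMessage(e))
    NULL
  })
  if (is.null(trials)) {
    report$log <- log
    return(report)
  }

  # --- exclusions
  excl <- apply_exclusions(trials)
  note("exclusions", n_in = nrow(trials), n_out = nrow(excl$trials))
  report$exclusions <- excl$report
  included <- excl$trials

  # --- behavioural summaries
  report$cells <- cell_summaries(included)
  report$ce <- congruency_effect(report$cells)
  ce_by_obj <- split(report$ce$ce_rt, report$ce$object)
  if (length(ce_by_obj) == 2 && all(lengths(ce_by_obj) >= 2)) {
    tt <- tryCatch(paired_t(ce_by_obj$same, ce_by_obj$different),
                   error = function(e) NULL)
    report$tests <- list(ce_rt_object = tt)
    if (!is.null(tt)) metrics$ce_object_p <- tt$p_value
  }
  metrics$mean_rt <- mean(included$rt[included$accuracy == 1])
  metrics$error_rate <- 1 - mean(included$accuracy)
  metrics$ce_rt_same <- mean(ce_by_obj$same)
  metrics$ce_rt_different <- mean(ce_by_obj$different)
  note("summaries", cells = nrow(report$cells))

  # --- distributional
  report$distributional <- tryCatch({
    dist <- pipeline_distributional(included)
    note("distributional", participants = length(unique(included$participant)))
    metrics$delta_slope_same <- dist$mean_slope[["same"]]
    metrics$delta_slope_different <- dist$mean_slope[["different"]]
    metrics$delta_intercept_same <- dist$mean_intercept[["same"]]
    metrics$delta_intercept_different <- dist$mean_intercept[["different"]]
    dist
  }, error = function(e) {
    note("distributional", error = conditionMessage(e))
    NULL
  })

  # --- fitting stages
  if (isTRUE(config$fit)) {
    report$fit <- tryCatch({
      f <- dmc_fit(included, spec = model_spec("mu_t"),
                   n_sim = config$fit_n_sim,
                   n_sim_final = config$fit_n_sim_final,
                   de = de_options(max_iter = config$fit_max_iter),
                   seed = config$seed + 1L)
      note("fit", iterations = f$iterations, g2 = f$g2_total)
      metrics$fit_g2 <- f$g2_total
      metrics$fit_mean_bic <- f$mean_bic
      f
    }, error = function(e) {
      note("fit", error = conditionMessage(e))
      NULL
    })
  }
  if (isTRUE(config$ladder)) {
    report$ladder <- tryCatch({
      l <- model_ladder(included, n_sim = config$fit_n_sim,
                        n_sim_final = config$fit_n_sim_final,
                        de = de_options(max_iter = config$fit_max_iter),
                        seed = config$seed + 2L)
      note("ladder", best = l$model[1])
      metrics$ladder_best <- l$model[1]
      l
    }, error = function(e) {
      note("ladder", error = conditionMessage(e))
      NULL
    })
  }
  if (isTRUE(config$recovery)) {
    report$recovery <- tryCatch({
      r <- recovery_study(dmc_defaults(if (config$experiment == "exp1")
        "exp1" else "exp2"), n_trials = 2000, n_reps = 2,
        n_sim = config$fit_n_sim,
        de = de_options(max_iter = config$fit_max_iter),
        seed = config$seed + 3L)
      note("recovery", reps = max(r$rep))
      r
    }, error = function(e) {
      note("recovery", error = conditionMessage(e))
      NULL
    })
  }

  report$log <- log
  report$metrics <- metrics

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report$cells,
                     file.path(config$output_dir, "cell_summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(report$ce,
                     file.path(config$output_dir, "congruency_effects.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      c(list(config_hash = report$config_hash, seed = config$seed), metrics),
      file.path(config$output_dir, "metrics.json"),
      auto_unbox = TRUE, digits = NA)
  }
  report
}

# Per-participant delta functions, regressions and CAFs for the two object
# conditions; centring RT is the participant's mean correct RT over the two
# congruency cells entering each delta function.
pipeline_distributional <- function(included) {
  by_pp <- split(included, included$participant)
  conds <- sort(unique(included$object))
  rows <- list()
  for (pp in names(by_pp)) {
    tt <- by_pp[[pp]]
    for (cond in conds) {
      sub <- tt[tt$object == cond, ]
      con <- sub[sub$congruency == "congruent", ]
      inc <- sub[sub$congruency == "incongruent", ]
      df <- delta_function_rt(con$rt[con$accuracy == 1],
                              inc$rt[inc$accuracy == 1])
      center <- mean(sub$rt[sub$accuracy == 1])
      reg <- delta_regression(df, center)
      pcd <- delta_function_pc(con, inc)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = pp, object = cond, slope = reg$slope,
        intercept = reg$intercept, center_rt = center,
        pc_delta_first = pcd[1], pc_delta_last = pcd[5],
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(per_participant = tab,
       mean_slope = tapply(tab$slope, tab$object, mean),
       mean_intercept = tapply(tab$intercept, tab$object, mean))
}
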