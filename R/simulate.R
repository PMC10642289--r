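#' Draw diffusion starting points
#'
#' Starting-point variability follows a symmetric beta distribution with
#' shape `alpha_s` on both sides, rescaled from (0, 1) to the open interval
#' `(-b, b)`. Larger `alpha_s` concentrates starts near zero.
#'
#' @param n Number of draws.
#' @param params A [dmc_params()] object.
#' @return Numeric vector of starting points strictly inside `(-b, b)`.
#' @export
sample_starting_point <- function(n, params) {
  stopifnot(inherits(params, "dmc_params"))
  params$b * (2 * stats::rbeta(n, params$alpha_s, params$alpha_s) - 1)
}

#' Simulate one condition of the conflict diffusion process
#'
#' Runs `n` independent Euler-Maruyama walks with superimposed target and
#' distractor drift between absorbing boundaries at `+b` (correct) and `-b`
#' (error), adds normally distributed residual (nondecision) time, and
#' applies the behavioural response window: RTs above the deadline are
#' flagged `too_slow`, RTs below the floor `too_fast`, walks unabsorbed by
#' `t_max_decision` `nonresponse`; all remaining trials are `ok`.
#'
#' Negative residual draws are redrawn until nonnegative; for `mu_r` well
#' above `sigma_r` this truncation is negligible.
#'
#' @param params A [dmc_params()] object.
#' @param congruency `"congruent"` or `"incongruent"`.
#' @param n Number of trials (0 gives an empty table).
#' @param options A [sim_options()] object.
#' @return A data frame (trial table) with columns `congruency`, `rt` (ms),
#'   `accuracy` (1 correct / 0 error, `NA` for nonresponses) and `status`.
#' @examples
#' set.seed(1)
#' head(simulate_condition(dmc_defaults("exp1")$same, "incongruent", 5))
#' @export
simulate_condition <- function(params, congruency, n,
                               options = sim_options()) {
  stopifnot(inherits(params, "dmc_params"), inherits(options, "dmc_sim_options"))
  congruency <- if (is.numeric(congruency)) {
    if (congruency_sign(congruency) > 0) "congruent" else "incongruent"
  } else match.arg(congruency, c("congruent", "incongruent"))
  if (n < 1)
    return(data.frame(congruency = character(), rt = numeric(),
                      accuracy = integer(), status = character(),
                      stringsAsFactors = FALSE))
  drift <- drift_schedule(params, congruency, options)
  z0 <- sample_starting_point(n, params)
  n_steps <- length(drift)
  walk <- .dmc_walk(drift, params$b, params$sigma, options$dt, z0, n_steps)
  resid <- stats::rnorm(n, params$mu_r, params$sigma_r)
  while (any(bad <- resid < 0))
    resid[bad] <- stats::rnorm(sum(bad), params$mu_r, params$sigma_r)
  rt <- walk$decision_time + resid
  absorbed <- walk$response != 0L
  status <- rep("ok", n)
  status[!absorbed] <- "nonresponse"
  status[absorbed & rt > options$deadline] <- "too_slow"
  status[absorbed & rt < options$rt_floor] <- "too_fast"
  accuracy <- ifelse(absorbed, as.integer(walk$response == 1L), NA_integer_)
  rt[!absorbed] <- NA_real_
  data.frame(congruency = congruency, rt = rt, accuracy = accuracy,
             status = status, stringsAsFactors = FALSE)
}

#' Simulate a single trial
#'
#' Convenience wrapper around [simulate_condition()] with `n = 1`.
#'
#' @inheritParams simulate_condition
#' @return A one-row trial table.
#' @export
simulate_trial <- function(params, congruency, options = sim_options()) {
  simulate_condition(params, congruency, 1L, options)
}

# Simulate both congruencies for one condition's parameter set; used by the
# fitting objective and by predict/simulate methods.
simulate_both <- function(params, n, options) {
  rbind(simulate_condition(params, "congruent", n, options),
        simulate_condition(params, "incongruent", n, options))
}
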