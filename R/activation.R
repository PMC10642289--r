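#' Expected distractor activation
#'
#' The automatic (distractor-driven) channel contributes an expected
#' activation shaped as a rescaled gamma density,
#' \deqn{E[X_d](t) = A \, e^{-t/\tau} \left(\frac{t e}{(a-1)\tau}\right)^{a-1},}
#' which rises to its single maximum `A` at `t = (a_shape - 1) * tau`
#' (see [peak_time()]) and then decays toward zero.
#'
#' @param t Time since stimulus onset (ms); strictly positive, vectorised.
#' @param params A [dmc_params()] object.
#' @return Expected activation (evidence units), same length as `t`.
#' @examples
#' p <- dmc_params(A = 13.8, tau = 249, a_shape = 2)
#' automatic_activation_mean(249, p)  # equals A at the peak
#' @export
automatic_activation_mean <- function(t, params) {
  stopifnot(inherits(params, "dmc_params"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0))
    stop("'t' must be strictly positive", call. = FALSE)
  a <- params$a_shape
  params$A * exp(-t / params$tau) *
    (t * exp(1) / ((a - 1) * params$tau))^(a - 1)
}

#' Time-varying distractor drift
#'
#' The distractor's contribution to the drift rate is the time derivative of
#' the expected activation, signed by congruency: on congruent trials the
#' distractor initially pushes toward the correct boundary, on incongruent
#' trials toward the error boundary.
#' \deqn{\mu_d(t) = \pm E[X_d](t)\left(\frac{a-1}{t} - \frac{1}{\tau}\right).}
#' It is positive before the activation peak (congruent), crosses zero at the
#' peak, and reverses sign afterwards.
#'
#' @inheritParams automatic_activation_mean
#' @param congruency `"congruent"` or `"incongruent"` (alternatively `+1` /
#'   `-1`).
#' @return Drift contribution (evidence units per ms), same length as `t`.
#' @export
automatic_drift <- function(t, params, congruency = "congruent") {
  s <- congruency_sign(congruency)
  act <- automatic_activation_mean(t, params)
  s * act * ((params$a_shape - 1) / t - 1 / params$tau)
}

congruency_sign <- function(congruency) {
  if (is.numeric(congruency)) {
    if (!congruency %in% c(-1, 1)) stop("numeric congruency must be +1 or -1")
    return(congruency)
  }
  switch(match.arg(congruency, c("congruent", "incongruent")),
         congruent = 1, incongruent = -1)
}

# Superimposed drift mu_t + mu_d(t) at the midpoint of every integration
# step; evaluating at midpoints keeps t strictly positive for the first step.
drift_schedule <- function(params, congruency, options) {
  n_steps <- ceiling(options$t_max_decision / options$dt)
  t_mid <- (seq_len(n_steps) - 0.5) * options$dt
  params$mu_t + automatic_drift(t_mid, params, congruency)
}
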