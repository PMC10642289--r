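#' Parameters of the conflict diffusion process
#'
#' Bundles the nine parameters governing one experimental condition of the
#' diffusion model for conflict tasks (DMC): a single Wiener diffusion
#' process whose drift is the sum of a constant, target-driven component and
#' a pulse-like, gamma-shaped distractor-driven component.
#'
#' @param mu_t Target drift rate (evidence units per ms). The constant,
#'   controlled component of the drift.
#' @param A Peak amplitude of the expected distractor activation (evidence
#'   units). `A = 0` switches the distractor channel off.
#' @param tau Scale of the gamma-shaped distractor activation (ms). For
#'   `a_shape = 2` it equals the time at which the activation peaks.
#' @param a_shape Shape of the gamma-shaped distractor activation
#'   (dimensionless, must exceed 1 so a peak exists). Conventionally fixed
#'   at 2.
#' @param sigma Diffusion constant (evidence units per square-root ms).
#'   Conventionally fixed at 4.
#' @param b Correct decision boundary (evidence units); the error boundary
#'   sits symmetrically at `-b`.
#' @param alpha_s Shape of the symmetric beta distribution of the starting
#'   point, rescaled to `(-b, b)`. Conventionally fixed at 3.
#' @param mu_r Mean residual (nondecision) time (ms).
#' @param sigma_r Standard deviation of the residual time (ms).
#'
#' @return An object of class `dmc_params`: a named list of the nine values.
#' @examples
#' p <- dmc_params(mu_t = 0.6, A = 14, tau = 250)
#' peak_time(p)
#' @export
dmc_params <- function(mu_t = 0.5, A = 20, tau = 150, a_shape = 2,
                       sigma = 4, b = 75, alpha_s = 3,
                       mu_r = 300, sigma_r = 30) {
  p <- list(mu_t = mu_t, A = A, tau = tau, a_shape = a_shape, sigma = sigma,
            b = b, alpha_s = alpha_s, mu_r = mu_r, sigma_r = sigma_r)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (p$tau < 1) stop("'tau' must be at least 1 ms", call. = FALSE)
  if (p$A < 0) stop("'A' must be nonnegative", call. = FALSE)
  if (p$b <= 0) stop("'b' must be positive", call. = FALSE)
  if (p$sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  if (p$mu_r < 0) stop("'mu_r' must be nonnegative", call. = FALSE)
  if (p$sigma_r < 0) stop("'sigma_r' must be nonnegative", call. = FALSE)
  if (p$a_shape <= 1) stop("'a_shape' must exceed 1", call. = FALSE)
  if (p$alpha_s <= 0) stop("'alpha_s' must be positive", call. = FALSE)
  structure(p, class = "dmc_params")
}

#' @export
print.dmc_params <- function(x, digits = 4, ...) {
  cat("DMC parameters (one condition)\n")
  v <- unlist(x)
  print(round(v, digits))
  cat(sprintf("peak of distractor activation: %.1f ms\n", peak_time(x)))
  invisible(x)
}

#' Time of the distractor activation peak
#'
#' The expected distractor activation rises to its single maximum `A` at
#' `t_peak = (a_shape - 1) * tau` and then decays toward zero. For the
#' conventional `a_shape = 2` the peak time equals `tau`, so the scale
#' parameter can be read directly as the timing of distractor influence.
#'
#' @param params A [dmc_params()] object.
#' @return Peak time in ms.
#' @export
peak_time <- function(params) {
  stopifnot(inherits(params, "dmc_params"))
  (params$a_shape - 1) * params$tau
}

#' Simulation options for the trial-level simulator
#'
#' @param dt Integration step of the Euler-Maruyama scheme (ms).
#' @param t_max_decision Maximum simulated decision time (ms); walks not
#'   absorbed by then are flagged `nonresponse`.
#' @param deadline Total-RT deadline (ms); slower responses are flagged
#'   `too_slow`, mirroring the behavioural response window.
#' @param rt_floor Fast-response floor (ms); faster responses are flagged
#'   `too_fast` (anticipations).
#' @return An object of class `dmc_sim_options`.
#' @export
sim_options <- function(dt = 1, t_max_decision = 5000, deadline = 2000,
                        rt_floor = 150) {
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  if (t_max_decision < deadline)
    stop("'t_max_decision' must be at least 'deadline'", call. = FALSE)
  structure(list(dt = dt, t_max_decision = t_max_decision,
                 deadline = deadline, rt_floor = rt_floor),
            class = "dmc_sim_options")
}

#' Reference DMC parameter sets for the two object-membership conditions
#'
#' Group-level parameter sets representative of published flanker-task DMC
#' fits in which only the target drift rate differs between the same- and
#' different-object conditions (distractor amplitude, timing, boundary and
#' residual parameters shared). They serve as the package's default
#' generating truth for synthetic cohorts and recovery studies.
#'
#' @param experiment `"exp1"` (proximity manipulated, near conditions) or
#'   `"exp2"` (near conditions only, replication).
#' @return A list with elements `same` and `different`, each a
#'   [dmc_params()] object.
#' @export
dmc_defaults <- function(experiment = c("exp1", "exp2")) {
  experiment <- match.arg(experiment)
  if (experiment == "exp1") {
    shared <- list(A = 13.8, tau = 249, b = 74.5, mu_r = 408, sigma_r = 38)
    mu <- c(same = 0.58, different = 0.62)
  } else {
    shared <- list(A = 17.8, tau = 254, b = 72.8, mu_r = 413, sigma_r = 38)
    mu <- c(same = 0.58, different = 0.64)
  }
  mk <- function(m) do.call(dmc_params, c(list(mu_t = m), shared))
  list(same = mk(mu[["same"]]), different = mk(mu[["different"]]))
}
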