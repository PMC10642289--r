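#' Summarise observed trials into the fitting target
#'
#' Reduces the included (`status == "ok"`) trials of both congruencies to
#' the summaries the G-squared statistic compares: per congruency, the
#' correct-RT percentile cuts at probabilities 0.1, 0.3, 0.5, 0.7, 0.9 (six
#' induced CDF bins with observed counts) and a five-bin conditional
#' accuracy function over all included trials (bin edges at the sample's
#' quintiles, correct/error counts per bin).
#'
#' @param trials Trial table with columns `congruency`, `rt`, `accuracy`,
#'   `status`; at least 25 included trials and 10 correct trials per
#'   congruency.
#' @param probs CDF percentile probabilities (default the conventional five).
#' @return An object of class `dmc_observed`: a list with one entry per
#'   congruency, each holding `cuts`, `cdf_counts`, `n_correct`,
#'   `caf_edges`, `caf_n`, `caf_correct` and `n_included`.
#' @export
summarize_observed <- function(trials, probs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  out <- list()
  for (cg in c("congruent", "incongruent")) {
    sub <- trials[trials$congruency == cg & trials$status == "ok", ,
                  drop = FALSE]
    if (nrow(sub) < 25)
      stop("summarize_observed: fewer than 25 included trials in the ",
           cg, " cell (", nrow(sub), ")", call. = FALSE)
    correct_rt <- sub$rt[sub$accuracy == 1]
    if (length(correct_rt) < 10)
      stop("summarize_observed: fewer than 10 correct trials in the ",
           cg, " cell", call. = FALSE)
    cuts <- stats::quantile(correct_rt, probs = probs, type = 7,
                            names = FALSE)
    cdf_counts <- tabulate(.bincode(correct_rt, c(-Inf, cuts, Inf),
                                    right = TRUE),
                           nbins = length(cuts) + 1L)
    cf <- caf(sub)
    bin <- .bincode(sub$rt, c(-Inf, cf$bin_edges, Inf), right = TRUE)
    caf_correct <- vapply(1:5, function(b) sum(sub$accuracy[bin == b]), 0)
    out[[cg]] <- list(cuts = cuts, cdf_counts = cdf_counts,
                      n_correct = length(correct_rt),
                      caf_edges = cf$bin_edges,
                      caf_n = cf$counts_per_bin,
                      caf_correct = as.integer(caf_correct),
                      n_included = nrow(sub))
  }
  structure(out, probs = probs, class = "dmc_observed")
}

#' @export
print.dmc_observed <- function(x, ...) {
  for (cg in names(x)) {
    s <- x[[cg]]
    cat(cg, ": N =", s$n_included, " correct =", s$n_correct, "\n")
    cat("  CDF cuts (ms):", paste(round(s$cuts), collapse = " "), "\n")
    cat("  CAF accuracy :",
        paste(round(s$caf_correct / s$caf_n, 3), collapse = " "), "\n")
  }
  invisible(x)
}

# Predicted bin proportions for one congruency given observed cut points,
# together with the simulated counts that determine their resolution.
predicted_props <- function(obs_cg, pred) {
  pred_ok <- pred[pred$status == "ok", , drop = FALSE]
  if (nrow(pred_ok) == 0)
    stop("g2: no included predicted trials", call. = FALSE)
  pred_correct <- pred_ok$rt[pred_ok$accuracy == 1]
  if (length(pred_correct) == 0)
    stop("g2: no correct predicted trials", call. = FALSE)
  p_cdf <- tabulate(.bincode(pred_correct, c(-Inf, obs_cg$cuts, Inf),
                             right = TRUE),
                    nbins = length(obs_cg$cuts) + 1L) / length(pred_correct)
  bin <- .bincode(pred_ok$rt, c(-Inf, obs_cg$caf_edges, Inf), right = TRUE)
  n_bin <- tabulate(bin, nbins = 5L)
  c_bin <- vapply(1:5, function(b) sum(pred_ok$accuracy[bin == b]), 0)
  p_caf <- ifelse(n_bin > 0, c_bin / n_bin, 0.5)
  list(p_cdf = p_cdf, n_cdf = length(pred_correct),
       p_caf = p_caf, n_caf = n_bin)
}

# x * log(x / y) with the convention 0 * log(0 / y) = 0.
xlogx <- function(x, ratio) ifelse(x == 0, 0, x * log(ratio))

#' Likelihood-ratio goodness-of-fit statistic G-squared
#'
#' Compares the observed summaries (six CDF bins of correct RTs, five
#' conditional-accuracy cells) with the corresponding proportions of a
#' predicted trial table, summed over the two congruencies:
#' \deqn{G^2 = 2 \sum \left[ \sum_6 n_j \ln(p_j / \hat p_j)
#'   + \sum_5 n_b \left( pc_b \ln \frac{pc_b}{\hat{pc}_b}
#'   + (1 - pc_b) \ln \frac{1 - pc_b}{1 - \hat{pc}_b} \right) \right].}
#' Predicted proportions are computed in the observed cut points and bin
#' edges (the predicted distribution is not re-quantiled). Every predicted
#' proportion entering a log denominator is floored at the simulation's
#' resolution, half a count: `1 / (2 m)` for a proportion estimated from `m`
#' simulated trials (with `eps` as an absolute backstop). A hard constant
#' floor would make the simulation-based objective severely biased wherever
#' the model predicts near-ceiling accuracy — a finite simulation then
#' returns a proportion of exactly 1 with appreciable probability and the
#' floored complement explodes the statistic, systematically penalising
#' good parameter regions; the half-count floor is the standard continuity
#' correction and leaves `G^2 = 0` exact when the predicted proportions
#' reproduce the observed ones.
#'
#' @param observed A [summarize_observed()] object.
#' @param predicted_trials Trial table of model-simulated trials, simulated
#'   under the same deadline/floor handling as the data.
#' @param eps Clipping bound for predicted proportions.
#' @return Nonnegative scalar.
#' @export
g2 <- function(observed, predicted_trials, eps = 1e-10) {
  stopifnot(inherits(observed, "dmc_observed"))
  total <- 0
  for (cg in c("congruent", "incongruent")) {
    obs <- observed[[cg]]
    pred <- predicted_trials[predicted_trials$congruency == cg, ,
                             drop = FALSE]
    pp <- predicted_props(obs, pred)
    p_obs <- obs$cdf_counts / obs$n_correct
    floor_cdf <- pmax(eps, 1 / (2 * pp$n_cdf))
    cdf_term <- sum(xlogx(obs$cdf_counts,
                          p_obs / pmax(pp$p_cdf, floor_cdf)))
    pc <- obs$caf_correct / obs$caf_n
    floor_caf <- pmax(eps, 1 / (2 * pmax(pp$n_caf, 1)))
    caf_term <- sum(obs$caf_n *
                      (xlogx(pc, pc / pmax(pp$p_caf, floor_caf)) +
                         xlogx(1 - pc,
                               (1 - pc) / pmax(1 - pp$p_caf, floor_caf))))
    total <- total + cdf_term + caf_term
  }
  2 * total
}

#' Bayesian information criterion for a G-squared fit
#'
#' `BIC = G^2 + k * log(n)`: the goodness-of-fit statistic plus a complexity
#' penalty growing with the number of estimated parameters `k` and the
#' number of trials `n`. Lower is better.
#'
#' @param g2_value Fitted G-squared value.
#' @param k Number of estimated parameters.
#' @param n Number of trials entering the fitted summaries.
#' @return Scalar BIC.
#' @export
bic <- function(g2_value, k, n) {
  if (n < 1) stop("'n' must be at least 1", call. = FALSE)
  g2_value + k * log(n)
}
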