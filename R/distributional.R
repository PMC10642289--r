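#' RT deciles
#'
#' The nine deciles (probabilities 0.1 to 0.9) of an RT sample, computed by
#' linear interpolation of order statistics (quantile type 7). Used as the
#' backbone of the RT delta functions.
#'
#' @param rts Numeric vector of RTs (ms); at least 10 observations.
#' @return Numeric vector of length 9.
#' @export
rt_deciles <- function(rts) {
  rts <- rts[!is.na(rts)]
  if (length(rts) < 10)
    stop("rt_deciles needs at least 10 observations, got ", length(rts),
         call. = FALSE)
  stats::quantile(rts, probs = seq(0.1, 0.9, by = 0.1), type = 7,
                  names = FALSE)
}

#' RT delta function
#'
#' The congruency effect at matched points of the RT distribution: deciles
#' are computed separately for correct congruent and correct incongruent
#' trials, and the delta function is their difference
#' (incongruent - congruent) plotted against the per-decile mean RT. An
#' increasing delta function signals distractor influence that grows with
#' response slowness; a vertical offset between two conditions signals a
#' change in conflict strength at every speed.
#'
#' @param congruent_rts,incongruent_rts Correct-trial RTs (ms) of the two
#'   congruency cells; each at least 10 observations.
#' @return An object of class `dmc_delta` with fields `probs`,
#'   `rt_congruent`, `rt_incongruent`, `delta` and `xmid` (per-decile mean
#'   RT).
#' @export
delta_function_rt <- function(congruent_rts, incongruent_rts) {
  qc <- rt_deciles(congruent_rts)
  qi <- rt_deciles(incongruent_rts)
  structure(list(probs = seq(0.1, 0.9, by = 0.1),
                 rt_congruent = qc, rt_incongruent = qi,
                 delta = qi - qc, xmid = (qi + qc) / 2),
            class = "dmc_delta")
}

#' @export
print.dmc_delta <- function(x, ...) {
  cat("RT delta function (9 deciles)\n")
  print(data.frame(p = x$probs, congruent = round(x$rt_congruent, 1),
                   incongruent = round(x$rt_incongruent, 1),
                   delta = round(x$delta, 1), xmid = round(x$xmid, 1)))
  invisible(x)
}

#' Conditional accuracy function
#'
#' Splits the included trials of one congruency (correct and error together)
#' into five equal-count RT bins at that sample's own quintiles and reports
#' the proportion correct per bin. Fast errors show up as depressed accuracy
#' in the fastest bin.
#'
#' @param trials Trial table for one congruency with columns `rt` and
#'   `accuracy`; at least 25 included trials.
#' @param edges Optional fixed bin edges (4 interior cut points, ms); by
#'   default the sample's own quintiles. Passing pooled edges gives the
#'   pooled-binning variant.
#' @return An object of class `dmc_caf` with fields `bin_edges`,
#'   `accuracy_per_bin` and `counts_per_bin`.
#' @export
caf <- function(trials, edges = NULL) {
  rt <- trials$rt
  acc <- trials$accuracy
  keep <- !is.na(rt) & !is.na(acc)
  rt <- rt[keep]; acc <- acc[keep]
  if (length(rt) < 25)
    stop("caf needs at least 25 included trials, got ", length(rt),
         call. = FALSE)
  if (is.null(edges))
    edges <- stats::quantile(rt, probs = c(0.2, 0.4, 0.6, 0.8), type = 7,
                             names = FALSE)
  bin <- .bincode(rt, c(-Inf, edges, Inf), right = TRUE)
  acc_bin <- tapply(acc, factor(bin, levels = 1:5), mean)
  n_bin <- tapply(acc, factor(bin, levels = 1:5), length)
  n_bin[is.na(n_bin)] <- 0L
  structure(list(bin_edges = edges,
                 accuracy_per_bin = as.numeric(acc_bin),
                 counts_per_bin = as.integer(n_bin)),
            class = "dmc_caf")
}

#' @export
print.dmc_caf <- function(x, ...) {
  cat("Conditional accuracy function (5 RT bins)\n")
  print(data.frame(bin = 1:5, n = x$counts_per_bin,
                   accuracy = round(x$accuracy_per_bin, 3)))
  invisible(x)
}

#' Accuracy (PC) delta function
#'
#' The congruency effect on proportion correct within five RT bins:
#' `PC_congruent - PC_incongruent` per bin, each congruency binned by its
#' own quintiles (see [caf()]). Typically largest for the fastest bin and
#' declining for slower responses.
#'
#' @param congruent,incongruent Trial tables of the two congruency cells
#'   (included trials, correct and error together).
#' @return Numeric vector of 5 PC differences.
#' @export
delta_function_pc <- function(congruent, incongruent) {
  caf(congruent)$accuracy_per_bin - caf(incongruent)$accuracy_per_bin
}

#' Line fit to the RT delta function
#'
#' Ordinary least squares of the nine delta values on the per-decile mean RT
#' centred at `center_rt`. The intercept is then the predicted congruency
#' effect at `center_rt` (conventionally the participant's mean RT), and the
#' slope the rate at which the effect grows per ms of response slowness.
#'
#' @param df A [delta_function_rt()] object.
#' @param center_rt Centring RT (ms), typically the participant's mean
#'   correct RT over the cells entering the delta function.
#' @return An object of class `dmc_delta_regression` with fields `slope`,
#'   `intercept` and `center_rt`.
#' @export
delta_regression <- function(df, center_rt) {
  stopifnot(inherits(df, "dmc_delta"))
  x <- df$xmid - center_rt
  if (isTRUE(all.equal(max(df$xmid), min(df$xmid))))
    stop("degenerate delta function: all per-decile mean RTs equal",
         call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), df$delta)
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 center_rt = center_rt),
            class = "dmc_delta_regression")
}

#' @export
print.dmc_delta_regression <- function(x, ...) {
  cat(sprintf("delta regression: intercept %.2f ms at RT = %.1f ms, slope %.4f\n",
              x$intercept, x$center_rt, x$slope))
  invisible(x)
}
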