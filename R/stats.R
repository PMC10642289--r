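#' Per-participant cell summaries
#'
#' One row per participant and design cell with the proportion of correct
#' responses (over all included trials) and the mean RT over correct trials
#' only — the standard summary table of a flanker experiment. Cells without
#' correct trials get `mean_rt = NA` rather than a silent zero.
#'
#' @param trials Included trial table (exclusions already applied), with a
#'   `participant` column and any of `proximity`, `object`, `congruency`.
#' @return Data frame with columns `participant`, the factor columns,
#'   `n_included`, `pc` and `mean_rt`.
#' @export
cell_summaries <- function(trials) {
  factors <- intersect(c("participant", "proximity", "object", "congruency"),
                       names(trials))
  if (!"participant" %in% factors)
    stop("cell_summaries needs a 'participant' column", call. = FALSE)
  key <- interaction(trials[factors], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(seq_len(nrow(trials)), key), function(ix) {
    sub <- trials[ix, , drop = FALSE]
    correct_rt <- sub$rt[sub$accuracy == 1]
    cbind(sub[1, factors, drop = FALSE],
          data.frame(n_included = nrow(sub),
                     pc = mean(sub$accuracy),
                     mean_rt = if (length(correct_rt)) mean(correct_rt)
                               else NA_real_))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Congruency effects per participant and cell pair
#'
#' The congruency effect (CE) is the RT cost and accuracy cost of
#' incongruent flankers: `CE_rt = RT_incongruent - RT_congruent` and
#' `CE_pc = PC_congruent - PC_incongruent`, computed per participant within
#' every combination of the remaining factors.
#'
#' @param summary A [cell_summaries()] table containing both congruencies.
#' @return Data frame with the non-congruency factors, `ce_rt` (ms) and
#'   `ce_pc` (proportion).
#' @export
congruency_effect <- function(summary) {
  if (!"congruency" %in% names(summary))
    stop("summary lacks a 'congruency' column", call. = FALSE)
  keyvars <- setdiff(names(summary),
                     c("congruency", "n_included", "pc", "mean_rt"))
  con <- summary[summary$congruency == "congruent", , drop = FALSE]
  inc <- summary[summary$congruency == "incongruent", , drop = FALSE]
  m <- merge(con, inc, by = keyvars, suffixes = c(".con", ".inc"))
  if (nrow(m) < max(nrow(con), nrow(inc)))
    stop("both congruencies must be present for every cell pair",
         call. = FALSE)
  out <- m[keyvars]
  out$ce_rt <- m$mean_rt.inc - m$mean_rt.con
  out$ce_pc <- m$pc.con - m$pc.inc
  out[do.call(order, out[keyvars]), , drop = FALSE]
}

#' Paired t-test with standardised effect size
#'
#' Two-sided paired t-test plus the paired effect size
#' `d_z = mean(diff) / sd(diff)`. If all differences are exactly zero the
#' test is reported as `t = 0, p = 1, d_z = 0`; a nonzero constant
#' difference (zero variance) is a degenerate case and raises an error.
#'
#' @param x,y Matched participant vectors (equal length, at least 2, no
#'   missing values).
#' @return An object of class `dmc_test` with `statistic`, `df`, `p_value`
#'   and `effect_size`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must match in length",
                                   call. = FALSE)
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(structure(list(statistic = 0, df = length(d) - 1L, p_value = 1,
                            effect_size = 0, method = "paired t"),
                       class = "dmc_test"))
    stop("degenerate pairing: constant nonzero difference (sd = 0)",
         call. = FALSE)
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  structure(list(statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 effect_size = mean(d) / stats::sd(d),
                 method = "paired t"),
            class = "dmc_test")
}

#' @export
print.dmc_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.3f, df = %.5g, p = %.4g, effect size = %.3f\n",
              x$method, x$statistic, x$df, x$p_value, x$effect_size))
  invisible(x)
}

#' Repeated-measures ANOVA for fully within-subject designs
#'
#' Standard univariate repeated-measures ANOVA via [stats::aov()] with an
#' `Error(participant/...)` stratum per effect, reporting F, degrees of
#' freedom, p and partial eta squared (`SS_effect / (SS_effect +
#' SS_error)`) for every main effect and interaction. The design must be
#' complete and balanced (one observation per participant and cell). All
#' factors in the motivating designs have two levels, where sphericity holds
#' exactly, so no sphericity correction is applied.
#'
#' @param data Data frame in long format, one row per participant x cell.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of within-subject factor columns.
#' @param id Name of the participant column.
#' @return Data frame with one row per effect: `effect`, `df1`, `df2`, `F`,
#'   `p_value`, `pes`.
#' @export
rm_anova <- function(data, dv, within, id = "participant") {
  stopifnot(all(c(dv, within, id) %in% names(data)))
  d <- data
  d[[id]] <- factor(d[[id]])
  for (f in within) d[[f]] <- factor(d[[f]])
  counts <- table(d[c(id, within)])
  if (any(counts != 1))
    stop("design must be complete and balanced: one observation per ",
         "participant and cell", call. = FALSE)
  rhs <- paste(within, collapse = " * ")
  fml <- stats::as.formula(paste0(
    "`", dv, "` ~ ", rhs, " + Error(`", id, "`/(", rhs, "))"))
  fit <- stats::aov(fml, data = d)
  out <- list()
  for (stratum in summary(fit)) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    eff <- terms[terms != "Residuals"]
    if (length(eff) == 0) next
    ss_err <- tab["Residuals", "Sum Sq"]
    for (e in eff) {
      out[[length(out) + 1L]] <- data.frame(
        effect = gsub(":", " x ", e),
        df1 = tab[e, "Df"], df2 = tab["Residuals", "Df"],
        F = tab[e, "F value"], p_value = tab[e, "Pr(>F)"],
        pes = tab[e, "Sum Sq"] / (tab[e, "Sum Sq"] + ss_err),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Within-subject standard errors (Cousineau-Morey)
#'
#' Removes between-participant variability by centring every participant's
#' condition profile on the grand mean, then rescales the condition SEs by
#' the Morey correction factor `sqrt(C / (C - 1))` for `C` conditions. A
#' cohort in which every participant shows the same condition profile (plus
#' an individual offset) yields SE = 0, the method's defining property.
#'
#' @param mat Numeric matrix, participants in rows, conditions in columns
#'   (complete, `C >= 2`).
#' @return Numeric vector of per-condition standard errors.
#' @export
within_subject_se <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("matrix must be complete", call. = FALSE)
  C <- ncol(mat)
  if (C < 2)
    stop("within-subject SE undefined for a single condition", call. = FALSE)
  centred <- mat - rowMeans(mat) + mean(mat)
  apply(centred, 2, stats::sd) / sqrt(nrow(mat)) * sqrt(C / (C - 1))
}
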