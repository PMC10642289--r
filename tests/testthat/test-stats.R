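make_summary_data <- function(n = 12, effect = 0, inter = 0, seed = 1) {
  set.seed(seed)
  d <- expand.grid(participant = seq_len(n),
                   object = c("same", "different"),
                   congruency = c("congruent", "incongruent"),
                   stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d), 500, 20) +
    effect * (d$congruency == "incongruent") +
    inter * (d$congruency == "incongruent") * (d$object == "same")
  d
}

test_that("cell summaries use all trials for PC and correct trials for RT", {
  tt <- data.frame(participant = 1,
                   object = "same",
                   congruency = rep(c("congruent", "incongruent"), each = 4),
                   rt = c(400, 500, 600, 700, 450, 550, 650, 750),
                   accuracy = c(1, 1, 0, 1, 1, 0, 0, 1),
                   status = "ok", stringsAsFactors = FALSE)
  cs <- cell_summaries(tt)
  con <- cs[cs$congruency == "congruent", ]
  inc <- cs[cs$congruency == "incongruent", ]
  expect_equal(con$mean_rt, mean(c(400, 500, 700)))
  expect_equal(con$pc, 3 / 4)
  expect_equal(inc$mean_rt, mean(c(450, 750)))
  expect_equal(inc$pc, 2 / 4)
  expect_equal(con$n_included, 4)

  # a cell with no correct responses yields an explicit missing RT
  tt2 <- tt
  tt2$accuracy[tt2$congruency == "incongruent"] <- 0L
  expect_true(is.na(cell_summaries(tt2)$mean_rt[2]))
})

test_that("congruency effects difference the two congruency cells", {
  tt <- expand.grid(participant = 1:3,
                    object = c("same", "different"),
                    congruency = c("congruent", "incongruent"),
                    stringsAsFactors = FALSE)
  tt$rt <- 500 + 30 * (tt$congruency == "incongruent")
  tt$accuracy <- 1L
  tt$status <- "ok"
  # several trials per cell via replication
  tt <- tt[rep(seq_len(nrow(tt)), 5), ]
  ce <- congruency_effect(cell_summaries(tt))
  expect_equal(ce$ce_rt, rep(30, 6))
  expect_equal(ce$ce_pc, rep(0, 6))
})

test_that("paired t reports d_z and guards degenerate input", {
  set.seed(14)
  x <- rnorm(20, 520, 30); y <- x + rnorm(20, 5, 10)
  r <- paired_t(x, y)
  d <- x - y
  expect_equal(r$statistic, mean(d) / (sd(d) / sqrt(20)), tolerance = 1e-12)
  expect_equal(r$effect_size, mean(d) / sd(d), tolerance = 1e-12)
  expect_equal(r$df, 19)

  same <- paired_t(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$effect_size, 0)
  expect_equal(same$p_value, 1)
  expect_error(paired_t(c(1, 2, 3, 4), c(2, 3, 4, 5)), "degenerate")
  expect_error(paired_t(1:3, 1:4), "length")
})

test_that("2x2 repeated-measures interaction equals the squared paired t on
           difference scores", {
  d <- make_summary_data(n = 14, effect = 12, inter = 8, seed = 15)
  res <- rm_anova(d, dv = "y", within = c("object", "congruency"))
  f_int <- res$F[res$effect == "object x congruency"]
  # difference-of-differences per participant
  wide <- tapply(d$y, d[c("participant", "object", "congruency")], mean)
  dd1 <- wide[, "same", "incongruent"] - wide[, "same", "congruent"]
  dd2 <- wide[, "different", "incongruent"] - wide[, "different", "congruent"]
  tt <- paired_t(dd1, dd2)
  expect_equal(f_int, tt$statistic^2, tolerance = 1e-8)
  # F statistics unaffected by adding a constant
  d2 <- d; d2$y <- d2$y + 1000
  res2 <- rm_anova(d2, dv = "y", within = c("object", "congruency"))
  expect_equal(res2$F, res$F, tolerance = 1e-8)
  expect_true(all(res$pes >= 0 & res$pes <= 1))
  expect_error(rm_anova(d[-1, ], "y", c("object", "congruency")),
               "balanced")
})

test_that("within-subject SE removes participant offsets", {
  profile <- c(480, 500, 520)
  mat <- matrix(rep(profile, each = 6), nrow = 6) +
    c(-30, -10, 0, 5, 15, 20)
  expect_equal(within_subject_se(mat), c(0, 0, 0))
  expect_error(within_subject_se(mat[, 1, drop = FALSE]), "single condition")

  # hand-computed 3x2 example
  m <- matrix(c(500, 520,
                480, 530,
                510, 540), nrow = 3, byrow = TRUE)
  centred <- m - rowMeans(m) + mean(m)
  manual <- apply(centred, 2, sd) / sqrt(3) * sqrt(2 / 1)
  expect_equal(within_subject_se(m), manual)
  expect_equal(within_subject_se(m)[1], within_subject_se(m)[2])
})
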