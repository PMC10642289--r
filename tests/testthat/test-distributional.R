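test_that("deciles use type-7 interpolation and are order invariant", {
  # hand-computed type-7 positions for n = 10: h = 9p + 1
  expect_equal(rt_deciles(1:10),
               c(1.9, 2.8, 3.7, 4.6, 5.5, 6.4, 7.3, 8.2, 9.1))
  expect_equal(rt_deciles(rep(400, 30)), rep(400, 9))
  set.seed(2)
  x <- runif(57, 300, 800)
  expect_equal(rt_deciles(x), rt_deciles(sample(x)))
  expect_true(all(diff(rt_deciles(x)) >= 0))
  expect_error(rt_deciles(1:9), "at least 10")
})

test_that("delta function records per-decile differences and midpoints", {
  x <- seq(310, 700, length.out = 40)
  d0 <- delta_function_rt(x, x)
  expect_equal(d0$delta, rep(0, 9))
  d30 <- delta_function_rt(x, x + 30)
  expect_equal(d30$delta, rep(30, 9))
  expect_equal(d30$xmid, rt_deciles(x) + 15)
  expect_equal(d30$rt_incongruent - d30$rt_congruent, d30$delta)
})

test_that("caf builds five equal-count bins on the sample's own quintiles", {
  set.seed(3)
  n <- 125
  tt <- toy_trials(runif(n, 300, 900), rbinom(n, 1, 0.9))
  cf <- caf(tt)
  expect_length(cf$accuracy_per_bin, 5)
  expect_true(all(abs(cf$counts_per_bin - n / 5) <= 1))
  expect_equal(sum(cf$counts_per_bin), n)
  expect_true(all(cf$accuracy_per_bin >= 0 & cf$accuracy_per_bin <= 1))
  all_correct <- caf(toy_trials(runif(60, 300, 900)))
  expect_equal(all_correct$accuracy_per_bin, rep(1, 5))
  expect_error(caf(toy_trials(runif(20, 300, 900))), "at least 25")
})

test_that("caf accuracy is flat when accuracy is independent of RT", {
  set.seed(4)
  n <- 4000
  p_true <- 0.92
  tt <- toy_trials(runif(n, 300, 900), rbinom(n, 1, p_true))
  cf <- caf(tt)
  # each bin is a binomial sample of size ~n/5 around the global mean
  half_width <- 3.29 * sqrt(p_true * (1 - p_true) / (n / 5))
  expect_true(all(abs(cf$accuracy_per_bin - mean(tt$accuracy)) <
                    half_width))
})

test_that("accuracy delta function is zero for matched processes", {
  set.seed(6)
  con <- toy_trials(runif(200, 300, 900), rbinom(200, 1, 0.93))
  inc <- toy_trials(runif(200, 320, 930), rbinom(200, 1, 0.93),
                    "incongruent")
  expect_lt(max(abs(delta_function_pc(con, inc))), 0.1)
  err_free <- delta_function_pc(toy_trials(runif(60, 300, 900)),
                                toy_trials(runif(60, 350, 950),
                                           congruency = "incongruent"))
  expect_equal(err_free, rep(0, 5))
})

test_that("delta regression recovers exact lines and is shift-equivariant", {
  x <- seq(320, 680, length.out = 40)
  dconst <- delta_function_rt(x, x + 12)
  r <- delta_regression(dconst, 500)
  expect_equal(r$slope, 0, tolerance = 1e-10)
  expect_equal(r$intercept, 12, tolerance = 1e-10)

  # construct delta = 0.5 * (xmid - center) + 10 exactly:
  # solve qi - qc = 0.5 * ((qi + qc)/2 - center) + 10 for qi decile-wise
  center <- 500
  qc <- rt_deciles(x)
  qi <- (1.25 * qc - 0.5 * center + 10) / 0.75
  df <- list(probs = seq(0.1, 0.9, 0.1), rt_congruent = qc,
             rt_incongruent = qi, delta = qi - qc, xmid = (qi + qc) / 2)
  class(df) <- "dmc_delta"
  r2 <- delta_regression(df, center)
  expect_equal(r2$slope, 0.5, tolerance = 1e-8)
  expect_equal(r2$intercept, 10, tolerance = 1e-6)

  # adding c to every RT moves xmid but not the slope; the intercept is
  # unchanged when the centring RT moves along
  set.seed(8)
  a <- runif(80, 350, 700); b <- runif(80, 380, 760)
  base <- delta_regression(delta_function_rt(a, b), 520)
  shift <- delta_regression(delta_function_rt(a + 40, b + 40), 560)
  expect_equal(shift$slope, base$slope, tolerance = 1e-10)
  expect_equal(shift$intercept, base$intercept, tolerance = 1e-8)

  dg <- delta_function_rt(rep(500, 20), rep(530, 20))
  expect_error(delta_regression(dg, 515), "degenerate")
})
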