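test_that("starting points follow the rescaled symmetric beta", {
  p <- dmc_params(alpha_s = 3, b = 75)
  set.seed(101)
  z <- sample_starting_point(1e5, p)
  expect_true(all(z > -75 & z < 75))
  # closed-form moments of z = b(2B - 1), B ~ beta(a, a):
  # E[z] = 0, Var[z] = b^2 / (2a + 1)
  v <- 75^2 / 7
  expect_lt(abs(mean(z)), 3 * sqrt(v / 1e5))
  expect_equal(var(z), v, tolerance = 0.03)
  # concentration limit: large alpha_s collapses toward 0
  zc <- sample_starting_point(1e4, dmc_params(alpha_s = 5000, b = 75))
  expect_lt(sd(zc), 2)
})

test_that("simulation is deterministic under a fixed seed", {
  p <- dmc_defaults("exp1")$same
  set.seed(7); a <- simulate_condition(p, "incongruent", 200)
  set.seed(7); b <- simulate_condition(p, "incongruent", 200)
  expect_identical(a, b)
  expect_equal(nrow(simulate_condition(p, "congruent", 0)), 0)
  expect_equal(nrow(simulate_trial(p, "congruent")), 1)
})

test_that("congruency is inert without distractor input", {
  p <- dmc_params(mu_t = 0.5, A = 0, b = 60, mu_r = 350, sigma_r = 30)
  set.seed(21)
  con <- simulate_condition(p, "congruent", 1e4)
  inc <- simulate_condition(p, "incongruent", 1e4)
  ks <- suppressWarnings(
    ks.test(con$rt[con$status == "ok"], inc$rt[inc$status == "ok"]))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(con$accuracy, na.rm = TRUE) -
                  mean(inc$accuracy, na.rm = TRUE)), 0.02)
})

test_that("strong target drift gives near-perfect fast decisions", {
  p <- dmc_params(mu_t = 5, A = 0, b = 60, mu_r = 300, sigma_r = 20)
  set.seed(31)
  tt <- simulate_condition(p, "congruent", 2000)
  expect_gt(mean(tt$accuracy, na.rm = TRUE), 0.999)
  expect_lt(mean(tt$rt, na.rm = TRUE) - 300, 60)  # decision time small
})

test_that("increasing mu_t speeds responses and raises accuracy", {
  mus <- c(0.3, 0.5, 0.7)
  stats_at <- lapply(mus, function(m) {
    set.seed(77)  # paired seeds across mu_t levels
    tt <- simulate_condition(dmc_params(mu_t = m, A = 15, tau = 200,
                                        b = 70, mu_r = 350, sigma_r = 30),
                             "incongruent", 1e4)
    ok <- tt[tt$status == "ok", ]
    c(rt = mean(ok$rt[ok$accuracy == 1]), pc = mean(ok$accuracy))
  })
  rts <- vapply(stats_at, `[[`, 0, "rt")
  pcs <- vapply(stats_at, `[[`, 0, "pc")
  expect_true(all(diff(rts) < 0))
  expect_true(all(diff(pcs) > 0))
})

test_that("published-style parameters give realistic included rates and a
           larger congruency effect in the smaller-mu_t condition", {
  p <- dmc_defaults("exp1")
  set.seed(41)
  ce <- vapply(c("same", "different"), function(cond) {
    con <- simulate_condition(p[[cond]], "congruent", 4e4)
    inc <- simulate_condition(p[[cond]], "incongruent", 4e4)
    expect_gt(mean(con$status == "ok"), 0.95)
    mean(inc$rt[inc$status == "ok" & inc$accuracy == 1]) -
      mean(con$rt[con$status == "ok" & con$accuracy == 1])
  }, 0)
  expect_gt(ce[["same"]], 0)
  expect_gt(ce[["different"]], 0)
  expect_gt(ce[["same"]], ce[["different"]])  # smaller mu_t, larger CE
})

test_that("two mu_t-only parameter sets shift the delta function, not its
           slope", {
  set.seed(51)
  slopes <- numeric(0); intercepts <- numeric(0)
  for (m in c(0.5, 0.65)) {
    p <- dmc_params(mu_t = m, A = 15, tau = 220, b = 70, mu_r = 380,
                    sigma_r = 35)
    con <- simulate_condition(p, "congruent", 3e4)
    inc <- simulate_condition(p, "incongruent", 3e4)
    df <- delta_function_rt(con$rt[con$status == "ok" & con$accuracy == 1],
                            inc$rt[inc$status == "ok" & inc$accuracy == 1])
    reg <- delta_regression(df, mean(c(con$rt, inc$rt), na.rm = TRUE))
    slopes <- c(slopes, reg$slope); intercepts <- c(intercepts, reg$intercept)
  }
  expect_gt(intercepts[1], intercepts[2])       # vertical offset
  expect_lt(abs(slopes[1] - slopes[2]), 0.08)   # near-parallel time course
})
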