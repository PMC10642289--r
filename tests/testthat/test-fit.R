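test_that("the model ladder enumerates the power set of conflict parameters", {
  specs <- all_model_specs()
  expect_length(specs, 8)
  ks <- vapply(specs, function(s) s$k, 0L)
  expect_equal(sort(unique(ks)), 6:9)
  expect_equal(sum(ks == 6), 1)  # null model
  expect_equal(sum(ks == 7), 3)  # one free parameter
  expect_equal(sum(ks == 8), 3)
  expect_equal(sum(ks == 9), 1)  # full model
  expect_equal(model_spec(c("tau", "mu_t"))$label, "M_mu_t+tau")
  expect_error(model_spec("sigma"), "subset")
})

test_that("bounds are validated", {
  b <- dmc_bounds()
  expect_equal(b$A, c(0, 40))
  expect_equal(b$tau, c(1, 500))
  expect_equal(b$b[2], 100)
  expect_equal(b$mu_r[2], 500)
  expect_equal(b$sigma_r[2], 50)
  b2 <- dmc_bounds(tau = c(1, 400))
  expect_equal(b2$tau, c(1, 400))
  expect_error(dmc_bounds(tau = c(5, 1)), "low < high")
  expect_error(dmc_bounds(zeta = c(0, 1)), "unknown")
})

test_that("fits are deterministic under a fixed seed", {
  dat <- toy_fit_data(n = 150)
  f1 <- dmc_fit(dat, spec = model_spec("mu_t"), n_sim = 150,
                n_sim_final = 400, de = de_options(max_iter = 4,
                                                   np_factor = 3),
                seed = 20)
  f2 <- dmc_fit(dat, spec = model_spec("mu_t"), n_sim = 150,
                n_sim_final = 400, de = de_options(max_iter = 4,
                                                   np_factor = 3),
                seed = 20)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$g2, f2$g2)
  expect_identical(coef(f1), coef(f2))
  expect_equal(dim(coef(f1)), c(2, 6))
  expect_false(f1$converged)  # cannot converge in 4 iterations
  expect_lte(f1$iterations, 4)
})

test_that("freeing the truly varying parameter improves the fit", {
  # data generated with a large mu_t difference between conditions
  dat <- toy_fit_data(n = 400, seed = 22, mu = c(same = 0.35,
                                                 different = 1.0))
  f_null <- dmc_fit(dat, spec = model_spec(), n_sim = 400,
                    n_sim_final = 2000,
                    de = de_options(max_iter = 25, np_factor = 5), seed = 23)
  f_mut <- dmc_fit(dat, spec = model_spec("mu_t"), n_sim = 400,
                   n_sim_final = 2000,
                   de = de_options(max_iter = 25, np_factor = 5), seed = 23)
  expect_gt(f_null$g2_total, f_mut$g2_total)
  # the freed parameter separates in the right direction
  expect_lt(coef(f_mut)["same", "mu_t"], coef(f_mut)["different", "mu_t"])
})

test_that("fit results carry BIC bookkeeping consistent with bic()", {
  dat <- toy_fit_data(n = 150)
  f <- dmc_fit(dat, spec = model_spec("mu_t"), n_sim = 100,
               n_sim_final = 300,
               de = de_options(max_iter = 3, np_factor = 3), seed = 24)
  for (cond in f$conditions)
    expect_equal(f$bic[[cond]], bic(f$g2[[cond]], f$spec$k, f$n_obs[[cond]]))
  expect_equal(f$mean_bic, mean(f$bic))
  ok <- dat[dat$status == "ok", ]
  expect_equal(unname(f$n_obs["same"]),
               sum(ok$object == "same"))
})

test_that("simulate and predict methods return usable objects", {
  dat <- toy_fit_data(n = 150)
  f <- dmc_fit(dat, spec = model_spec("mu_t"), n_sim = 100,
               n_sim_final = 300,
               de = de_options(max_iter = 3, np_factor = 3), seed = 25)
  sim <- simulate(f, nsim = 60, seed = 1)
  expect_equal(nrow(sim), 2 * 2 * 60)
  expect_setequal(unique(sim$object), c("same", "different"))
  pr <- predict(f, nsim = 2000, seed = 2)
  expect_length(pr$same$cdf$congruent, 5)
  expect_s3_class(pr$different$caf$incongruent, "dmc_caf")
  expect_s3_class(pr$same$delta, "dmc_delta")
})
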