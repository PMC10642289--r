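test_that("participant parameter draws respect the effect structure", {
  pop0 <- population_spec(cv = 0)
  pars <- sample_participant_params(pop0)
  means <- dmc_defaults("exp1")
  expect_equal(pars$same$mu_t, means$same$mu_t)
  expect_equal(pars$different$mu_t, means$different$mu_t)
  expect_equal(pars$same$A, means$same$A)

  # no effect structure: both conditions share every value
  pop_null <- population_spec(effect = character(), cv = 0.2)
  set.seed(16)
  p2 <- sample_participant_params(pop_null)
  expect_identical(unclass(p2$same), unclass(p2$different))

  # truncation: many draws all inside the fitting bounds
  set.seed(17)
  b <- dmc_bounds()
  draws <- replicate(1000, {
    pp <- sample_participant_params(population_spec())$same
    c(pp$mu_t, pp$A, pp$tau, pp$b, pp$mu_r, pp$sigma_r)
  })
  lims <- do.call(cbind, b[c("mu_t", "A", "tau", "b", "mu_r", "sigma_r")])
  expect_true(all(t(draws) >= lims[1, ][col(t(draws))] &
                    t(draws) <= lims[2, ][col(t(draws))]))
})

test_that("cohorts have exact design bookkeeping and are seed-reproducible", {
  des <- study_design(n_participants = 3, trials_per_cell = 40)
  coh <- generate_cohort(des, population_spec(), seed = 18)
  expect_equal(nrow(coh), 3 * 2 * 2 * 40)
  expect_equal(names(coh), c("participant", "proximity", "object",
                             "congruency", "rt", "accuracy", "status"))
  counts <- table(coh$participant, coh$object, coh$congruency)
  expect_true(all(counts == 40))
  coh2 <- generate_cohort(des, population_spec(), seed = 18)
  expect_identical(coh, coh2)
})

test_that("exclusions remove out-of-window trials and report rates", {
  ok_tab <- data.frame(participant = 1, proximity = "near", object = "same",
                       congruency = "congruent", rt = runif(50, 300, 700),
                       accuracy = rep(1L, 50), status = "ok",
                       stringsAsFactors = FALSE)
  r <- apply_exclusions(ok_tab)
  expect_equal(nrow(r$trials), 50)
  expect_equal(r$report$pct[r$report$category != "errors"], c(0, 0, 0))

  tab <- ok_tab
  tab$rt[1] <- 2500           # beyond the deadline
  tab$rt[2] <- 100            # below the floor
  tab$rt[3] <- NA             # nonresponse
  tab$accuracy[4] <- 0L
  r2 <- apply_exclusions(tab)
  expect_equal(nrow(r2$trials), 47)
  rep2 <- r2$report
  expect_equal(rep2$n[rep2$category == "too_slow"], 1)
  expect_equal(rep2$n[rep2$category == "too_fast"], 1)
  expect_equal(rep2$n[rep2$category == "nonresponse"], 1)
  expect_equal(rep2$pct[rep2$category == "errors"], 100 / 47)
})

test_that("default cohorts sit in the realistic behavioural regime", {
  coh <- generate_cohort(study_design(n_participants = 12,
                                      trials_per_cell = 112),
                         population_spec(), seed = 19)
  ex <- apply_exclusions(coh)
  err <- ex$report$pct[ex$report$category == "errors"]
  expect_gt(err, 2)           # a few percent choice errors ...
  expect_lt(err, 9)           # ... but far from guessing
  inc <- ex$trials
  mrt <- mean(inc$rt[inc$accuracy == 1])
  expect_gt(mrt, 450)
  expect_lt(mrt, 650)
  pc <- mean(inc$accuracy)
  expect_gt(pc, 0.90)
  expect_lt(pc, 0.98)
})

test_that("a zero-effect population yields no systematic condition difference", {
  pop <- population_spec(effect = character(), cv = 0.1)
  diffs <- vapply(1:4, function(i) {
    coh <- generate_cohort(study_design(n_participants = 6,
                                        trials_per_cell = 80),
                           pop, seed = 100 + i)
    ce <- congruency_effect(cell_summaries(apply_exclusions(coh)$trials))
    mean(ce$ce_rt[ce$object == "same"]) -
      mean(ce$ce_rt[ce$object == "different"])
  }, 0)
  # centred on zero: the mean difference is small relative to trial noise
  expect_lt(abs(mean(diffs)), 10)
})
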