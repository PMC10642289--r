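# Shared fixture builders; everything is generated in code.

# Deterministic trial table with prescribed RTs/accuracies for one congruency.
toy_trials <- function(rt, accuracy = rep(1L, length(rt)),
                       congruency = "congruent", status = "ok") {
  data.frame(congruency = congruency, rt = rt,
             accuracy = as.integer(accuracy), status = status,
             stringsAsFactors = FALSE)
}

# Two-congruency table around distinct RT ranges, errors sprinkled in.
toy_both <- function(n = 40, seed = 99) {
  set.seed(seed)
  rbind(
    toy_trials(runif(n, 300, 700), rbinom(n, 1, 0.95), "congruent"),
    toy_trials(runif(n, 320, 760), rbinom(n, 1, 0.9), "incongruent"))
}

# Small two-condition data set with a large drift-rate difference, for fast
# fitting tests.
toy_fit_data <- function(n = 400, seed = 5,
                         mu = c(same = 0.4, different = 0.9)) {
  set.seed(seed)
  do.call(rbind, lapply(names(mu), function(cond) {
    p <- dmc_params(mu_t = mu[[cond]], A = 15, tau = 200, b = 60,
                    mu_r = 350, sigma_r = 30)
    cbind(object = cond,
          rbind(simulate_condition(p, "congruent", n),
                simulate_condition(p, "incongruent", n)),
          stringsAsFactors = FALSE)
  }))
}

# mu_t-only condition contrast sized to the reported delta-function
# intercept dissociation (~9 ms at the participant mean RT, d_z ~ 0.44):
# other parameters at the same-object reference row.
dissociation_means <- function() {
  b <- dmc_defaults("exp1")$same
  list(same      = dmc_params(mu_t = 0.48, A = b$A, tau = b$tau, b = b$b,
                              mu_r = b$mu_r, sigma_r = b$sigma_r),
       different = dmc_params(mu_t = 0.67, A = b$A, tau = b$tau, b = b$b,
                              mu_r = b$mu_r, sigma_r = b$sigma_r))
}

# per-participant delta-regression slopes and intercepts for the two object
# conditions of an included trial table, in wide format
delta_wide <- function(included) {
  d <- flankdmc:::pipeline_distributional(included)$per_participant
  list(intercept = reshape(d[c("participant", "object", "intercept")],
                           idvar = "participant", timevar = "object",
                           direction = "wide"),
       slope = reshape(d[c("participant", "object", "slope")],
                       idvar = "participant", timevar = "object",
                       direction = "wide"))
}
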