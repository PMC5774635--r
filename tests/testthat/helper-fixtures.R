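# shared fixture builders: everything is generated in code

# four-patient toy trial with one binary covariate x = {0,0,1,1}
toy_trial <- function(outcome = c(0, 0, 1, 1)) {
  spec <- list(covariate_spec("x", "binary", "effect_modifier"))
  df <- data.frame(arm = c("A", "B", "A", "B"),
                   outcome = outcome,
                   x = c(0, 0, 1, 1))
  ipd_trial(df, spec)
}

toy_target <- function(mean = 0.75) list(covariate_summary("x", mean))

# random MAIC instance: one binary + one variance-matched continuous
# covariate (three moment columns), target drawn inside the support
random_instance <- function(n = 200L) {
  spec <- list(
    covariate_spec("b", "binary", "effect_modifier"),
    covariate_spec("z", "continuous", "effect_modifier",
                   match_moments = "mean_and_variance")
  )
  df <- data.frame(
    arm = rep(c("A", "B"), each = n / 2),
    outcome = rnorm(n),
    b = rbinom(n, 1, 0.5),
    z = rnorm(n, 0, 1)
  )
  trial <- ipd_trial(df, spec)
  target <- list(
    covariate_summary("b", runif(1, 0.3, 0.7)),
    covariate_summary("z", runif(1, -0.4, 0.4), sd = runif(1, 0.7, 1.2))
  )
  list(trial = trial, target = target, spec = spec)
}

# scenario with an imbalanced effect modifier (x1) and, optionally, an
# imbalanced purely prognostic covariate (x2)
em_imbalance_config <- function(n = 500L, with_prognostic = FALSE,
                                shared_em = FALSE, ...) {
  covs <- list(list(name = "x1", kind = "continuous", role = "both",
                    mean_ab = 0.2, mean_ac = 0.6, sd = 1))
  beta1 <- c(x1 = 1)
  if (with_prognostic) {
    covs <- c(covs, list(list(name = "x2", kind = "continuous",
                              role = "prognostic",
                              mean_ab = 0, mean_ac = 0.5, sd = 1)))
    beta1 <- c(beta1, x2 = 1)
  }
  scenario_config(
    n_ab = n, n_ac = n, covariates = covs,
    truth = list(beta0 = 0, beta1 = beta1, d_ab0 = 1, d_ac0 = 0.5,
                 gamma_b = c(x1 = 1),
                 gamma_c = c(x1 = if (shared_em) 1 else 0)),
    ...
  )
}

# hand-built relative effect (same shape trial_relative_effect returns)
new_effect_for_test <- function(t1, t0, scale, estimate, se,
                                population = "trial") {
  structure(
    list(contrast = c(t1, t0), population = population,
         scale = pa_scale(scale), estimate = estimate, se = se),
    class = "pa_effect"
  )
}

# relabel a B-vs-A effect as C-vs-A with identical numbers
d_ab_to_c <- function(d) {
  d$contrast[1] <- "C"
  d
}

expect_close <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)), tol)
}
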