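spec_em <- list(covariate_spec("x", "continuous", "both"))

# noise-free data generated exactly from the interaction model
linear_trial <- function(n = 40, beta0 = 1, beta1 = 2, betaB = 0.5,
                         beta2 = 1, noise = 0) {
  x <- seq(-1, 1, length.out = n)
  arm <- rep(c("A", "B"), each = n / 2)
  y <- beta0 + beta1 * x + (betaB + beta2 * x) * (arm == "B") +
    noise * rnorm(n)
  ipd_trial(data.frame(arm = arm, outcome = y, x = x), spec_em)
}

test_that("noise-free data reproduce the coefficients exactly", {
  fit <- fit_outcome_model(linear_trial(), spec_em, "identity")
  expect_equal(fit$beta0, 1, tolerance = 1e-8)
  expect_equal(unname(fit$beta1), 2, tolerance = 1e-8)
  expect_equal(fit$betaB, 0.5, tolerance = 1e-8)
  expect_equal(unname(fit$beta2), 1, tolerance = 1e-8)
})

test_that("null interactions are recovered as null across replicates", {
  set.seed(71)
  n_reps <- 400
  within3 <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    x <- rnorm(60)
    arm <- rep(c("A", "B"), 30)
    y <- 1 + x + 0.5 * (arm == "B") + rnorm(60)   # beta2 = 0
    tr <- ipd_trial(data.frame(arm = arm, outcome = y, x = x), spec_em)
    fit <- fit_outcome_model(tr, spec_em, "identity")
    se2 <- sqrt(fit$vcov[".treat:x", ".treat:x"])
    within3[r] <- abs(fit$beta2) < 3 * se2
  }
  expect_gte(mean(within3), 0.97)
})

test_that("separation in a binary outcome arm is a diagnosed error", {
  set.seed(72)
  x <- rnorm(40)
  arm <- rep(c("A", "B"), each = 20)
  y <- ifelse(arm == "A", 0, rbinom(40, 1, 0.5))
  tr <- ipd_trial(data.frame(arm = arm, outcome = y, x = x), spec_em,
                  outcome_type = "binary")
  expect_error(fit_outcome_model(tr, spec_em, "logit"), "separation")
})

test_that("small arms are refused (need K+2 patients per arm)", {
  tr <- linear_trial(n = 8)   # 4 per arm < 4 coefficients + 2
  expect_error(fit_outcome_model(tr, spec_em, "identity"), "at least")
})

test_that("plug-in prediction is linear arithmetic on the identity scale", {
  m <- outcome_model(beta0 = 1, beta1 = c(x = 2), betaB = 0.5,
                     beta2 = c(x = 1), scale = "identity")
  pred <- predict_plugin(m, list(covariate_summary("x", 0.6)))
  expect_equal(pred$A$ybar, 1 + 2 * 0.6)          # 2.2
  expect_equal(pred$B$ybar, 2.2 + 0.5 + 0.6)      # 3.3
  expect_length(attr(pred, "warnings"), 0)

  pred0 <- predict_plugin(m, list(covariate_summary("x", 0)))
  expect_equal(pred0$A$ybar, 1)
  expect_equal(pred0$B$ybar, 1.5)
})

test_that("plug-in prediction on a non-identity scale carries the bias warning", {
  m <- outcome_model(beta0 = 0, beta1 = c(x = 1), betaB = 1,
                     beta2 = numeric(0), scale = "logit")
  pred <- predict_plugin(m, list(covariate_summary("x", 0)))
  expect_match(attr(pred, "warnings"), "systematically biased")
  expect_equal(pred$A$ybar, 0.5)
})

test_that("prediction refuses unknown or missing covariates", {
  m <- outcome_model(beta0 = 1, beta1 = c(x = 2), betaB = 0.5,
                     beta2 = c(x = 1))
  expect_error(predict_plugin(m, list(covariate_summary("w", 1))),
               "unknown")
  expect_error(predict_plugin(m, list()), "missing")
})

test_that("simulation-based prediction matches plug-in under identity link", {
  m <- outcome_model(beta0 = 1, beta1 = c(x = 2), betaB = 0.5,
                     beta2 = c(x = 1), scale = "identity")
  dist <- covariate_distribution(
    list(covariate_summary("x", 0.6, sd = 1)), spec_em)
  pred <- predict_by_simulation(m, dist, n_draws = 5e4, seed = 9)
  mc <- attr(pred, "mc_se")
  expect_close(pred$A$ybar, 2.2, 3 * mc["A"])
  expect_close(pred$B$ybar, 3.3, 3 * mc["B"])
})

test_that("E[expit(X)] is 0.5 for standard normal X (MC oracle)", {
  m <- outcome_model(beta0 = 0, beta1 = c(x = 1), betaB = 1,
                     beta2 = numeric(0), scale = "logit")
  dist <- covariate_distribution(
    list(covariate_summary("x", 0, sd = 1)), spec_em)
  pred <- predict_by_simulation(m, dist, n_draws = 2e5, seed = 10)
  expect_close(pred$A$ybar, 0.5, 4 * attr(pred, "mc_se")["A"])
})

test_that("zero-variance covariates reproduce the plug-in exactly", {
  m <- outcome_model(beta0 = 0, beta1 = c(x = 1), betaB = 1,
                     beta2 = numeric(0), scale = "logit")
  dist <- covariate_distribution(
    list(covariate_summary("x", 0.4, sd = 1e-12)), spec_em)
  pred <- predict_by_simulation(m, dist, n_draws = 1e4, seed = 11)
  plug <- predict_plugin(m, list(covariate_summary("x", 0.4)))
  expect_equal(pred$A$ybar, plug$A$ybar, tolerance = 1e-9)
  expect_equal(pred$B$ybar, plug$B$ybar, tolerance = 1e-9)
})

test_that("simulation prediction enforces its floor and seed contract", {
  m <- outcome_model(beta0 = 0, beta1 = c(x = 1), betaB = 1)
  dist <- covariate_distribution(
    list(covariate_summary("x", 0, sd = 1)), spec_em)
  expect_error(predict_by_simulation(m, dist, n_draws = 100, seed = 1),
               "10\\^4")
  expect_error(predict_by_simulation(m, dist), "seed")
  p1 <- predict_by_simulation(m, dist, n_draws = 1e4, seed = 5)
  p2 <- predict_by_simulation(m, dist, n_draws = 1e4, seed = 5)
  expect_identical(p1$A$ybar, p2$A$ybar)
})

test_that("covariate distributions validate their correlation matrix", {
  specs2 <- list(covariate_spec("x", "continuous", "both"),
                 covariate_spec("b", "binary", "prognostic"))
  marg <- list(covariate_summary("x", 0, sd = 1),
               covariate_summary("b", 0.4))
  bad <- matrix(c(1, 2, 2, 1), 2, 2, dimnames = list(c("x", "b"),
                                                     c("x", "b")))
  expect_error(covariate_distribution(marg, specs2, correlation = bad),
               "positive semi-definite")
  ok <- covariate_distribution(marg, specs2)
  expect_equal(ok$correlation, diag(2), ignore_attr = TRUE)
})

test_that("IPD correlations are imputed into the joint draw", {
  set.seed(81)
  n <- 4000
  x <- rnorm(n)
  b <- as.numeric(runif(n) < pnorm(x * 0.8))  # correlated binary
  arm <- rep(c("A", "B"), n / 2)
  specs2 <- list(covariate_spec("x", "continuous", "both"),
                 covariate_spec("b", "binary", "prognostic"))
  tr <- ipd_trial(data.frame(arm = arm, outcome = rnorm(n), x = x, b = b),
                  specs2)
  dist <- covariate_distribution(
    list(covariate_summary("x", 0, sd = 1), covariate_summary("b", 0.5)),
    specs2, ipd = tr)
  expect_match(dist$source, "IPD")
  expect_gt(dist$correlation["x", "b"], 0.3)
})

test_that("parameter recovery is unbiased in noisy replicates", {
  set.seed(91)
  n_reps <- 300
  est <- matrix(NA_real_, n_reps, 4)
  for (r in seq_len(n_reps)) {
    tr <- linear_trial(n = 200, noise = 1)
    # jitter x to avoid identical design across reps
    tr$data$x <- tr$data$x + rnorm(200, 0, 0.3)
    tr$data$outcome <- 1 + 2 * tr$data$x +
      (0.5 + tr$data$x) * (tr$data$arm == "B") + rnorm(200)
    fit <- fit_outcome_model(tr, spec_em, "identity")
    est[r, ] <- c(fit$beta0, fit$beta1, fit$betaB, fit$beta2)
  }
  truth <- c(1, 2, 0.5, 1)
  mc <- apply(est, 2, sd) / sqrt(n_reps)
  expect_true(all(abs(colMeans(est) - truth) < 3 * mc))
})
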