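test_that("moment matrix centers at targets, including second moments", {
  tr <- toy_trial()
  Z <- build_moment_matrix(tr, toy_target(0.75), tr$spec)
  expect_equal(sort(drop(Z$Z)), sort(c(-0.75, -0.75, 0.25, 0.25)))

  spec_v <- list(covariate_spec("z", "continuous", "effect_modifier",
                                match_moments = "mean_and_variance"))
  df <- data.frame(arm = rep(c("A", "B"), 10), outcome = rnorm(20),
                   z = seq(40, 78, 2))
  tr2 <- ipd_trial(df, spec_v)
  Z2 <- build_moment_matrix(tr2, list(covariate_summary("z", 60, sd = 8)),
                            spec_v)
  expect_equal(Z2$column_labels, c("z.mean", "z.var"))
  expect_equal(Z2$Z[, "z.var"], df$z^2 - 3664)
})

test_that("targets outside the observed support are a diagnosed error", {
  tr <- toy_trial()
  expect_error(build_moment_matrix(tr, toy_target(2), tr$spec),
               "support")
  # degenerate binary covariate (all zero) with a different target
  spec_b <- list(covariate_spec("x", "binary", "effect_modifier"))
  df <- data.frame(arm = c("A", "B", "A", "B"), outcome = 1:4,
                   x = c(0, 0, 0, 0))
  expect_error(
    build_moment_matrix(ipd_trial(df, spec_b), toy_target(0.5), spec_b),
    "support")
})

test_that("collinear moment columns are dropped with a warning", {
  spec2 <- list(covariate_spec("u", "continuous", "effect_modifier"),
                covariate_spec("v", "continuous", "effect_modifier"))
  df <- data.frame(arm = rep(c("A", "B"), 5), outcome = rnorm(10),
                   u = 1:10, v = 2 * (1:10))
  tr <- ipd_trial(df, spec2)
  target <- list(covariate_summary("u", 5), covariate_summary("v", 10))
  expect_warning(Z <- build_moment_matrix(tr, target, spec2), "collinear")
  expect_equal(ncol(Z$Z), 1)
})

test_that("toy weights match the closed form: alpha = ln 3, ESS = 3.2", {
  tr <- toy_trial()
  Z <- build_moment_matrix(tr, toy_target(0.75), tr$spec)
  w <- fit_maic_weights(Z)
  expect_equal(unname(w$alpha), log(3), tolerance = 1e-8)
  expect_equal(w$weights[order(tr$data$x)], c(0.5, 0.5, 1.5, 1.5),
               tolerance = 1e-8)
  expect_equal(w$ess, 3.2, tolerance = 1e-8)
  wm <- sum(tr$data$x * w$weights) / sum(w$weights)
  expect_equal(wm, 0.75, tolerance = 1e-10)
})

test_that("targets equal to observed means give uniform weights", {
  set.seed(31)
  inst <- random_instance()
  s <- summarize_ipd(inst$trial)
  # targets = observed pooled moments (mean and sample-based 2nd moment)
  z <- inst$trial$data$z
  m2 <- mean(z^2)
  target <- list(
    covariate_summary("b", mean(inst$trial$data$b)),
    covariate_summary("z", mean(z), sd = sqrt(m2 - mean(z)^2))
  )
  Z <- build_moment_matrix(inst$trial, target, inst$spec)
  w <- fit_maic_weights(Z)
  expect_close(w$weights, 1, 1e-8)
  expect_equal(w$ess, nrow(inst$trial$data), tolerance = 1e-8)
})

test_that("method-of-moments weights exactly balance all matched moments", {
  set.seed(41)
  for (i in 1:50) {
    inst <- random_instance()
    Z <- build_moment_matrix(inst$trial, inst$target, inst$spec)
    w <- fit_maic_weights(Z)
    bal <- drop(crossprod(Z$Z, w$weights)) / sum(w$weights)
    expect_lt(max(abs(bal)), 1e-8)
    # balance on the raw scale: weighted means equal the targets
    d <- inst$trial$data
    wt <- w$weights
    expect_equal(sum(d$b * wt) / sum(wt), inst$target[[1]]$mean,
                 tolerance = 1e-8)
    expect_equal(sum(d$z * wt) / sum(wt), inst$target[[2]]$mean,
                 tolerance = 1e-8)
    m2 <- inst$target[[2]]$mean^2 + inst$target[[2]]$sd^2
    expect_equal(sum(d$z^2 * wt) / sum(wt), m2, tolerance = 1e-7)
  }
})

test_that("entropy balancing reproduces the method-of-moments weights", {
  set.seed(51)
  for (i in 1:50) {
    inst <- random_instance()
    Z <- build_moment_matrix(inst$trial, inst$target, inst$spec)
    wm <- fit_maic_weights(Z)
    we <- fit_entropy_weights(Z)
    expect_lt(max(abs(wm$weights - we$weights)), 1e-6)
  }
  expect_equal(fit_entropy_weights(
    build_moment_matrix(toy_trial(), toy_target(0.75),
                        toy_trial()$spec))$method, "entropy")
})

test_that("entropy weights are uniform when the target is already met", {
  tr <- toy_trial()
  Z <- build_moment_matrix(tr, toy_target(0.5), tr$spec)
  we <- fit_entropy_weights(Z)
  expect_close(we$weights, 1, 1e-8)
})

test_that("weighted arm estimates average outcomes with the weights", {
  tr <- toy_trial(outcome = c(5, 0, 7, 1))  # B outcomes 0,1 at x=0,1
  w <- structure(list(weights = rep(1, 4), arm = tr$data$arm,
                      ess = 4, ess_by_arm = c(A = 2, B = 2),
                      converged = TRUE, method = "moments"),
                 class = "pa_weights")
  est <- weighted_arm_estimates(tr, w)
  expect_equal(est$A$ybar, 6)
  expect_equal(est$B$ybar, 0.5)

  # B arm outcomes (0,0,1,1) with weights (0.5,0.5,1.5,1.5) -> 0.75
  spec <- list(covariate_spec("x", "binary", "effect_modifier"))
  df <- data.frame(arm = rep("B", 4), outcome = c(0, 0, 1, 1),
                   x = c(0, 0, 1, 1))
  df <- rbind(df, data.frame(arm = "A", outcome = 0, x = 0))
  tr2 <- ipd_trial(df, spec)
  w2 <- structure(list(weights = c(0.5, 0.5, 1.5, 1.5, 1),
                       arm = df$arm, converged = TRUE, method = "moments"),
                  class = "pa_weights")
  est2 <- weighted_arm_estimates(tr2, w2)
  expect_equal(est2$B$ybar, 0.75)
  expect_equal(est2$B$n, effective_sample_size(c(0.5, 0.5, 1.5, 1.5)))

  # single positive weight returns that patient's outcome
  w3 <- w2; w3$weights <- c(1, 0, 0, 0, 1)
  expect_equal(weighted_arm_estimates(tr2, w3)$B$ybar, 0)

  w4 <- w2; w4$weights <- c(0, 0, 0, 0, 1)
  expect_error(weighted_arm_estimates(tr2, w4), "effectively empty")
})

test_that("ESS follows (sum w)^2 / sum(w^2) and its invariances", {
  expect_equal(effective_sample_size(rep(2, 10)), 10)
  expect_equal(effective_sample_size(c(1, 1, 3, 3)), 3.2)
  expect_equal(effective_sample_size(c(1, 1, 2)), 16 / 6)
  # rescaling invariance and the Cauchy-Schwarz bound
  set.seed(61)
  for (i in 1:20) {
    w <- rexp(50)
    expect_equal(effective_sample_size(w), effective_sample_size(7.3 * w))
    expect_lte(effective_sample_size(w), 50 + 1e-12)
  }
  expect_error(effective_sample_size(c(0, 0)), "zero")
  expect_error(effective_sample_size(c(-1, 2)), "non-negative")
})

test_that("weight diagnostics report shares, ESS fraction, and flags", {
  tr <- toy_trial()
  Z <- build_moment_matrix(tr, toy_target(0.75), tr$spec)
  ws <- weight_summary(fit_maic_weights(Z))
  expect_equal(max(ws$top_shares), 0.375, tolerance = 1e-8)
  expect_equal(ws$ess, 3.2, tolerance = 1e-8)
  expect_match(ws$caveat, "understate")

  dom <- structure(list(weights = c(100, rep(1, 100)),
                        arm = rep(c("A", "B"), length.out = 101),
                        ess = effective_sample_size(c(100, rep(1, 100))),
                        ess_by_arm = c(A = 1, B = 1),
                        converged = TRUE, method = "moments"),
                   class = "pa_weights")
  ws2 <- weight_summary(dom)
  expect_equal(ws2$ess, 200^2 / 10100, tolerance = 1e-10)
  expect_true(any(grepl("ESS < 10%", ws2$flags)))
})
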