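asum <- function(arm, ybar, se = 0.1, n = 100) {
  arm_summary(arm, n = n, ybar = ybar, se_ybar = se)
}

test_that("within-trial effects difference link-transformed summaries", {
  d <- trial_relative_effect(asum("B", 5), asum("A", 2), "identity")
  expect_equal(d$estimate, 3)
  expect_equal(d$se, sqrt(2) * 0.1)

  d2 <- trial_relative_effect(asum("B", 0.5, 0.05), asum("A", 0.3, 0.05),
                              "logit")
  expect_equal(d2$estimate, 0 - log(0.3 / 0.7))
  expect_equal(round(d2$estimate, 5), 0.84730)
  # delta-method SE: dg(p) = 1/(p(1-p))
  expect_equal(d2$se, sqrt((4 * 0.05)^2 + (0.05 / 0.21)^2))

  d3 <- trial_relative_effect(asum("B", 2), asum("A", 2), "log")
  expect_equal(d3$estimate, 0)
})

test_that("zero-event binary arms get a continuity correction", {
  suppressMessages({
    d <- trial_relative_effect(arm_summary("B", n = 10, r = 0),
                               arm_summary("A", n = 10, r = 5), "logit")
  })
  expect_true(is.finite(d$estimate))
  expect_equal(d$estimate, log((0.5 / 11) / (1 - 0.5 / 11)) - 0)
})

test_that("the Bucher estimate differences contrasts and sums variances", {
  d_ab <- new_effect_for_test("B", "A", "identity", 0.5, 0.1)
  d_ac <- new_effect_for_test("C", "A", "identity", 0.8, 0.2)
  res <- bucher(d_ac, d_ab)
  expect_equal(res$estimate, 0.3)
  expect_equal(res$se, sqrt(0.05))
  expect_equal(round(res$se, 4), 0.2236)
  expect_equal(res$population, "assumed-constant")
  expect_true(res$anchored)

  res0 <- bucher(d_ab_to_c(d_ab), d_ab)
  expect_equal(res0$estimate, 0)

  d_log <- new_effect_for_test("C", "A", "log", 0.8, 0.2)
  expect_error(bucher(d_log, d_ab), "scale mismatch")
  d_noanchor <- new_effect_for_test("C", "B", "identity", 0.8, 0.2)
  expect_error(bucher(d_noanchor, d_ab), "anchor")
})

test_that("anchored comparisons combine observed and predicted contrasts", {
  res <- anchored_comparison(pred_A = asum("A", 1), pred_B = asum("B", 3),
                             obs_A = asum("A", 2), obs_C = asum("C", 5),
                             scale = "identity")
  expect_equal(res$estimate, (5 - 2) - (3 - 1))
  expect_true(res$anchored)
  expect_equal(res$population, "AC")

  # logit: obs (0.3, 0.5), pred (0.3, 0.4)
  res2 <- anchored_comparison(
    pred_A = asum("A", 0.3, 0.02), pred_B = asum("B", 0.4, 0.02),
    obs_A = asum("A", 0.3, 0.02), obs_C = asum("C", 0.5, 0.02),
    scale = "logit")
  expect_equal(res2$estimate,
               (log(0.5 / 0.5) - log(0.3 / 0.7)) -
                 (log(0.4 / 0.6) - log(0.3 / 0.7)))
  expect_equal(res2$estimate, log(1.5), tolerance = 1e-12)

  # null case: predicted contrast equals observed contrast
  res3 <- anchored_comparison(pred_A = asum("A", 2), pred_B = asum("B", 5),
                              obs_A = asum("A", 2), obs_C = asum("C", 5),
                              scale = "identity")
  expect_equal(res3$estimate, 0)
})

test_that("unanchored comparisons require a disconnected network", {
  expect_error(
    unanchored_comparison(asum("B", 3), asum("C", 5), "identity"),
    "anchored route is available|connected")
  res <- unanchored_comparison(asum("B", 3), asum("C", 5), "identity",
                               anchored_available = FALSE)
  expect_equal(res$estimate, 2)
  expect_false(res$anchored)
  expect_true(any(grepl("conditional constancy of absolute effects",
                        res$warnings)))
  res0 <- unanchored_comparison(asum("B", 5), asum("C", 5), "identity",
                                anchored_available = FALSE)
  expect_equal(res0$estimate, 0)
})

test_that("transport relabels only under the shared-EM assumption", {
  res <- anchored_comparison(pred_A = asum("A", 1), pred_B = asum("B", 3),
                             obs_A = asum("A", 2), obs_C = asum("C", 5),
                             scale = "identity")
  tgt <- target_population("registry-P")
  expect_error(transport_effect(res, tgt, shared_em = FALSE),
               "shared effect modifier")
  out <- transport_effect(res, tgt, shared_em = TRUE)
  expect_equal(out$population, "registry-P")
  expect_equal(out$estimate, res$estimate)
  expect_equal(out$se, res$se)
  expect_true(out$shared_em_used)
  # idempotence
  out2 <- transport_effect(out, tgt, shared_em = TRUE)
  expect_equal(out2$estimate, out$estimate)
  expect_equal(out2$population, out$population)
  # contrast must lie in the declared treatment set
  expect_error(transport_effect(res, tgt, shared_em = TRUE,
                                treatment_set = c("C", "D")),
               "not in the set")
})

test_that("absolute effects back-calculate from the target baseline", {
  tgt <- target_population(
    "P", baseline_A = arm_summary("A", n = 200, ybar = 0.3,
                                  se_ybar = 0.02))
  d_ab <- new_effect_for_test("B", "A", "logit", 0.5, 0.1, population = "P")
  abs_eff <- absolute_effects(tgt, d_ab = d_ab, scale = "logit")
  expect_equal(abs_eff$B$ybar, plogis(qlogis(0.3) + 0.5))
  expect_equal(round(abs_eff$B$ybar, 5), 0.41404)

  d0 <- new_effect_for_test("B", "A", "logit", 0, 0.1, population = "P")
  expect_equal(absolute_effects(tgt, d_ab = d0, scale = "logit")$B$ybar,
               0.3)

  tgt_id <- target_population(
    "P", baseline_A = arm_summary("A", n = 200, ybar = 2, se_ybar = 0.1))
  d_ac <- new_effect_for_test("C", "A", "identity", 3, 0.1,
                              population = "P")
  expect_equal(
    absolute_effects(tgt_id, d_ac = d_ac, scale = "identity")$C$ybar, 5)

  # population label must match
  d_wrong <- new_effect_for_test("B", "A", "logit", 0.5, 0.1,
                                 population = "AC")
  expect_error(absolute_effects(tgt, d_ab = d_wrong, scale = "logit"),
               "transport")
  # baseline required
  expect_error(absolute_effects(target_population("P"), d_ab = d_ab,
                                scale = "logit"), "baseline")
})

test_that("assumption checks implement the adjustment recommendations", {
  spec3 <- list(covariate_spec("em1", "continuous", "effect_modifier"),
                covariate_spec("pr1", "continuous", "prognostic"))
  # anchored weighting matching a prognostic-only covariate
  w1 <- check_assumptions("maic", spec3, anchored = TRUE,
                          adjusted = c("em1", "pr1"))
  expect_true(any(grepl("over-matching.*pr1", w1)))
  # anchored weighting omitting an effect modifier
  w2 <- check_assumptions("maic", spec3, anchored = TRUE, adjusted = "pr1")
  expect_true(any(grepl("effect modifier.*omitted.*em1", w2, TRUE)))
  # unanchored omitting a prognostic
  w3 <- check_assumptions("maic", spec3, anchored = FALSE,
                          adjusted = "em1")
  expect_true(any(grepl("unanchored.*pr1", w3)))
  # compliant anchored STC: only the mandatory statements remain
  w4 <- check_assumptions("stc", spec3, anchored = TRUE,
                          adjusted = c("em1", "pr1"),
                          scale = "logit", population = "AC")
  expect_equal(attr(w4, "n_warnings"), 0)
  expect_true(any(grepl("logit linear predictor", w4)))
  expect_true(any(grepl("target population: AC", w4)))
})

test_that("null adjustment: MAIC equals Bucher when targets match the IPD", {
  set.seed(101)
  cfg <- em_imbalance_config(n = 200)
  gen <- generate_scenario(cfg, 11)
  # replace aggregate covariate summary by the observed pooled IPD mean
  s <- summarize_ipd(gen$ab)
  agg <- gen$aggregate
  agg$covariate_summaries <- s$covariate_summaries
  res_maic <- maic_analysis(gen$ab, agg, gen$spec, "identity")
  res_bucher <- bucher_analysis(gen$ab, agg, "identity")
  expect_lt(abs(res_maic$estimate - res_bucher$estimate), 1e-12)
  w <- attr(res_maic, "weights")
  expect_close(w$weights, 1, 1e-9)
})

test_that("anchored and unanchored estimates coincide when the A arms agree", {
  # algebraic identity: g(Yhat_A) = g(Ybar_A) makes the two equal
  predA <- asum("A", 2); predB <- asum("B", 3.5)
  obsA <- asum("A", 2); obsC <- asum("C", 5)
  anc <- anchored_comparison(predA, predB, obsA, obsC, "identity")
  una <- unanchored_comparison(predB, obsC, "identity",
                               anchored_available = FALSE)
  expect_equal(anc$estimate, una$estimate)
})

test_that("scale round-trips hold on comparison outputs", {
  res <- anchored_comparison(
    pred_A = asum("A", 0.3, 0.02), pred_B = asum("B", 0.4, 0.02),
    obs_A = asum("A", 0.3, 0.02), obs_C = asum("C", 0.5, 0.02),
    scale = "logit")
  sc <- res$scale
  expect_lt(abs(sc$g(sc$g_inv(res$estimate)) - res$estimate), 1e-12)
  expect_lt(max(abs(sc$g(sc$g_inv(res$ci95)) - res$ci95)), 1e-12)
})
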