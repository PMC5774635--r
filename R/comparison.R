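#' Within-trial relative treatment effect on a link scale
#'
#' Forms `Delta = g(ybar1) - g(ybar0)` with a delta-method standard error
#' `sqrt(dg(ybar1)^2 se1^2 + dg(ybar0)^2 se0^2)`. Binary arms with zero or
#' all events get a 0.5 continuity correction (Haldane-Anscombe) before a
#' log or logit transform; the correction is logged.
#'
#' @param a1,a0 [arm_summary()] objects (contrast is `a1` vs `a0`).
#' @param scale A [pa_scale()] or scale name.
#' @param population Label of the population the estimate applies to.
#' @return A `pa_effect` object: `contrast`, `population`, `scale`,
#'   `estimate`, `se`.
#' @export
trial_relative_effect <- function(a1, a0, scale, population = "trial") {
  scale <- as_pa_scale(scale)
  a1 <- continuity_correct(a1, scale)
  a0 <- continuity_correct(a0, scale)
  if (is.null(a1$se_ybar) || is.null(a0$se_ybar)) {
    stop("arm summaries need standard errors to form a relative effect",
         call. = FALSE)
  }
  est <- scale$g(a1$ybar) - scale$g(a0$ybar)
  se <- sqrt(scale$dg(a1$ybar)^2 * a1$se_ybar^2 +
             scale$dg(a0$ybar)^2 * a0$se_ybar^2)
  new_effect(contrast = c(a1$arm, a0$arm), population = population,
             scale = scale, estimate = est, se = se)
}

continuity_correct <- function(a, scale) {
  if (scale$name == "identity") return(a)
  if (is.null(a$ybar) || a$ybar < 0 || a$ybar > 1) return(a)
  if (a$ybar == 0 || a$ybar == 1) {
    r <- a$ybar * a$n
    ybar <- (r + 0.5) / (a$n + 1)
    pa_log(sprintf(
      "arm '%s': %g/%g events; applying 0.5 continuity correction",
      a$arm, r, a$n))
    return(arm_summary(a$arm, n = a$n + 1, ybar = ybar,
                       se_ybar = sqrt(ybar * (1 - ybar) / (a$n + 1))))
  }
  a
}

new_effect <- function(contrast, population, scale, estimate, se) {
  if (!is.finite(estimate)) stop("non-finite effect estimate", call. = FALSE)
  if (!is.finite(se) || se < 0) stop("invalid standard error", call. = FALSE)
  structure(
    list(contrast = contrast, population = population, scale = scale,
         estimate = estimate, se = se),
    class = "pa_effect"
  )
}

new_comparison <- function(contrast, population, scale, estimate, se,
                           anchored, method, shared_em_used = FALSE,
                           warnings = character(0), ess = NULL) {
  ci <- estimate + c(-1, 1) * stats::qnorm(0.975) * se
  structure(
    list(contrast = contrast, population = population, scale = scale,
         estimate = estimate, se = se, ci95 = ci,
         anchored = anchored, method = method,
         shared_em_used = shared_em_used, warnings = warnings, ess = ess),
    class = "pa_comparison"
  )
}

check_same_scale <- function(s1, s2) {
  if (s1$name != s2$name) {
    stop(sprintf(
      "scale mismatch: '%s' vs '%s'; effects must be combined on a single linear predictor scale",
      s1$name, s2$name), call. = FALSE)
  }
}

#' Standard (Bucher) indirect comparison
#'
#' `Delta_BC = Delta_AC - Delta_AB` through the common comparator A, with
#' variances summed. Valid only under constancy of relative effects: every
#' effect modifier balanced between the two trial populations. The result
#' is labelled population `"assumed-constant"` to keep that assumption
#' visible.
#'
#' @param d_ac,d_ab `pa_effect` objects sharing the anchor treatment A.
#' @return A `pa_comparison` object, `method = "bucher"`.
#' @export
bucher <- function(d_ac, d_ab) {
  stopifnot(inherits(d_ac, "pa_effect"), inherits(d_ab, "pa_effect"))
  check_same_scale(d_ac$scale, d_ab$scale)
  if (d_ac$contrast[2L] != d_ab$contrast[2L]) {
    stop(sprintf("contrasts do not share an anchor: %s vs %s",
                 d_ac$contrast[2L], d_ab$contrast[2L]), call. = FALSE)
  }
  new_comparison(
    contrast = c(d_ab$contrast[1L], d_ac$contrast[1L]),
    population = "assumed-constant",
    scale = d_ac$scale,
    estimate = d_ac$estimate - d_ab$estimate,
    se = sqrt(d_ac$se^2 + d_ab$se^2),
    anchored = TRUE, method = "bucher",
    warnings = paste(
      "standard indirect comparison assumes relative effects are constant",
      "across trial populations (all effect modifiers balanced)")
  )
}

#' Anchored population-adjusted indirect comparison
#'
#' Combines the observed AC-trial contrast with the predicted B-versus-A
#' contrast in the AC population:
#' `Delta_BC(AC) = (g(Ybar_C) - g(Ybar_A)) - (g(Yhat_B) - g(Yhat_A))`.
#' Randomization within each trial is respected; the AC-trial arm
#' summaries are treated as independent of the IPD-derived predictions.
#'
#' @param pred_A,pred_B Predicted arm summaries for the AC population
#'   (from [weighted_arm_estimates()] or an STC predictor).
#' @param obs_A,obs_C Observed AC-trial arm summaries.
#' @param scale A [pa_scale()] or scale name.
#' @param method Method label (`"maic"`, `"maic_entropy"`, `"stc"`, ...).
#' @param population Population label (defaults to `"AC"`).
#' @param se_pred Optional standard error for the predicted contrast
#'   `g(Yhat_B) - g(Yhat_A)` on the linear predictor scale (e.g. from
#'   [sandwich_se()], which accounts for weight estimation and
#'   within-patient weight sharing); when `NULL` the two predictions'
#'   SEs are combined by the delta method as if independent.
#' @param ess Effective sample size to report alongside.
#' @param warnings Additional warnings to carry.
#' @return A `pa_comparison` with `anchored = TRUE`.
#' @export
anchored_comparison <- function(pred_A, pred_B, obs_A, obs_C, scale,
                                method = "maic", population = "AC",
                                se_pred = NULL, ess = NULL,
                                warnings = character(0)) {
  scale <- as_pa_scale(scale)
  d_obs <- trial_relative_effect(obs_C, obs_A, scale, population)
  pred_A <- continuity_correct(pred_A, scale)
  pred_B <- continuity_correct(pred_B, scale)
  d_pred_est <- scale$g(pred_B$ybar) - scale$g(pred_A$ybar)
  if (is.null(se_pred)) {
    se_pred <- sqrt(scale$dg(pred_B$ybar)^2 * pred_B$se_ybar^2 +
                    scale$dg(pred_A$ybar)^2 * pred_A$se_ybar^2)
  }
  new_comparison(
    contrast = c(pred_B$arm, obs_C$arm),
    population = population, scale = scale,
    estimate = d_obs$estimate - d_pred_est,
    se = sqrt(d_obs$se^2 + se_pred^2),
    anchored = TRUE, method = method, ess = ess,
    warnings = c(warnings, paste(
      "anchored comparison assumes conditional constancy of relative",
      "effects: all effect modifiers (on the", scale$name,
      "scale) are accounted for"))
  )
}

#' Unanchored indirect comparison
#'
#' `Delta_BC(AC) = g(Ybar_C) - g(Yhat_B)`: a direct contrast of absolute
#' outcomes across trials with no common comparator. This requires
#' conditional constancy of absolute effects -- every prognostic variable
#' and effect modifier accounted for -- a much stronger assumption than
#' the anchored form, with residual bias of unknown magnitude. It is
#' refused whenever an anchored route is available.
#'
#' @param pred_B Predicted B-arm summary for the AC population.
#' @param obs_C Observed AC-trial C-arm summary.
#' @param scale A [pa_scale()] or scale name.
#' @param anchored_available Must be `FALSE`; set by the caller after
#'   checking the evidence network. If the network is connected the
#'   unanchored comparison is an error.
#' @param method,population,se_pred,ess,warnings As
#'   [anchored_comparison()].
#' @return A `pa_comparison` with `anchored = FALSE` and a mandatory
#'   assumption warning.
#' @export
unanchored_comparison <- function(pred_B, obs_C, scale,
                                  anchored_available = TRUE,
                                  method = "maic", population = "AC",
                                  se_pred = NULL, ess = NULL,
                                  warnings = character(0)) {
  if (isTRUE(anchored_available)) {
    stop(paste(
      "an anchored route is available: unanchored comparisons may only be",
      "considered in the absence of a connected network of randomized",
      "evidence or with single-arm studies"), call. = FALSE)
  }
  scale <- as_pa_scale(scale)
  obs_C <- continuity_correct(obs_C, scale)
  pred_B <- continuity_correct(pred_B, scale)
  est <- scale$g(obs_C$ybar) - scale$g(pred_B$ybar)
  if (is.null(se_pred)) {
    se_pred <- scale$dg(pred_B$ybar) * pred_B$se_ybar
  }
  se <- sqrt(scale$dg(obs_C$ybar)^2 * obs_C$se_ybar^2 + se_pred^2)
  new_comparison(
    contrast = c(pred_B$arm, obs_C$arm),
    population = population, scale = scale,
    estimate = est, se = se,
    anchored = FALSE, method = method, ess = ess,
    warnings = c(warnings, paste(
      "unanchored comparison assumes conditional constancy of absolute",
      "effects (all effect modifiers AND prognostic variables accounted",
      "for); residual bias from unobserved variables is unquantified and",
      "may exceed the treatment effect"))
  )
}

#' Transport a contrast to another target population
#'
#' Under the shared effect modifier assumption for a treatment set T --
#' the treatments share the same effect modifiers with identical
#' interaction coefficients -- the between-treatment contrast is
#' population-invariant: `d_tu(P) = d_tu(Q)` for any populations P, Q and
#' t, u in T. The estimate and SE are relabelled to the target
#' population; without the assumption, transporting to a different
#' population is an error.
#'
#' @param result A `pa_comparison`.
#' @param target A [target_population()] (or population label).
#' @param shared_em `TRUE` if the shared effect modifier assumption is
#'   asserted for `treatment_set`.
#' @param treatment_set Treatments T for which the assumption is asserted
#'   (default: the contrast's two treatments).
#' @return A `pa_comparison` labelled for the target population, with
#'   `shared_em_used = TRUE` and a justification-required warning.
#' @export
transport_effect <- function(result, target, shared_em = FALSE,
                             treatment_set = result$contrast) {
  stopifnot(inherits(result, "pa_comparison"))
  label <- if (inherits(target, "pa_target")) target$label else target
  if (identical(label, result$population)) return(result)
  if (!isTRUE(shared_em)) {
    stop(paste(
      "cannot transport the estimate to population", shQuote(label),
      "without the shared effect modifier assumption; population-adjusted",
      "estimates apply only to the population they were formed in"),
      call. = FALSE)
  }
  outside <- setdiff(result$contrast, treatment_set)
  if (length(outside)) {
    stop(sprintf(
      "treatment(s) %s not in the set declared to satisfy the shared effect modifier assumption (%s)",
      paste(outside, collapse = ", "),
      paste(treatment_set, collapse = ", ")), call. = FALSE)
  }
  out <- result
  out$population <- label
  out$shared_em_used <- TRUE
  out$warnings <- unique(c(result$warnings, paste(
    "shared effect modifier assumption invoked for treatments",
    paste(treatment_set, collapse = ", "),
    "- requires clinical/biological justification (treatments in the",
    "same class are more plausible candidates)")))
  out
}

#' Back-calculate absolute effects in a target population
#'
#' Given the baseline absolute outcome on the common comparator A in the
#' target population and relative effects applicable to that population,
#' `Yhat_t(P) = g_inv(g(Ybar_A(P)) + Delta_At(P))`. Standard errors by
#' the delta method, treating the baseline and the contrasts as
#' independent (the baseline typically comes from an external registry or
#' cohort).
#'
#' @param target A [target_population()] with `baseline_A` set.
#' @param d_ab,d_ac `pa_effect` or `pa_comparison` objects giving the
#'   A-anchored contrasts in the target population (either may be `NULL`).
#' @param scale A [pa_scale()] or scale name.
#' @return Named list of [arm_summary()] objects (`A` plus one per
#'   supplied contrast).
#' @export
absolute_effects <- function(target, d_ab = NULL, d_ac = NULL, scale) {
  stopifnot(inherits(target, "pa_target"))
  scale <- as_pa_scale(scale)
  if (is.null(target$baseline_A)) {
    stop("target population has no baseline outcome on treatment A; ",
         "absolute effects cannot be produced", call. = FALSE)
  }
  base <- target$baseline_A
  eta_A <- scale$g(base$ybar)
  se_eta_A <- if (is.null(base$se_ybar)) 0 else scale$dg(base$ybar) * base$se_ybar
  out <- list(A = base)
  for (d in list(d_ab, d_ac)) {
    if (is.null(d)) next
    if (!identical(d$population, target$label)) {
      stop(sprintf(
        "relative effect is labelled for population '%s', not the target '%s'; transport it first",
        d$population, target$label), call. = FALSE)
    }
    check_same_scale(d$scale, scale)
    eta_t <- eta_A + d$estimate
    y_t <- scale$g_inv(eta_t)
    se_eta <- sqrt(se_eta_A^2 + d$se^2)
    out[[d$contrast[1L]]] <-
      arm_summary(d$contrast[1L], n = base$n, ybar = y_t,
                  se_ybar = se_eta / scale$dg(y_t))
  }
  out
}

#' Check an analysis against the adjustment recommendations
#'
#' Produces the warning set a reviewer would raise: anchored weighting
#' should adjust for all effect modifiers but no purely prognostic
#' variables (over-matching loses precision without reducing bias);
#' anchored outcome regression should include every imbalanced effect
#' modifier; unanchored analyses of any kind must include all declared
#' prognostic variables and effect modifiers. The scale and target
#' population statements are always emitted.
#'
#' @param method `"maic"`, `"maic_entropy"`, or `"stc"`.
#' @param spec Covariate specification (declared roles).
#' @param anchored Logical.
#' @param adjusted Character vector of covariates adjusted for (matched in
#'   MAIC, included in the STC model).
#' @param scale A [pa_scale()] or scale name.
#' @param population Target population label.
#' @param imbalanced Optional character vector of covariates judged
#'   imbalanced between the trials (defaults to all declared).
#' @return Character vector of warnings/statements, with class
#'   `pa_assumptions`.
#' @export
check_assumptions <- function(method, spec, anchored, adjusted,
                              scale = "identity", population = "AC",
                              imbalanced = NULL) {
  spec <- as_covariate_list(spec)
  scale <- as_pa_scale(scale)
  ems <- em_names(spec)
  progs <- setdiff(spec_names(spec, "prognostic"), ems)
  if (is.null(imbalanced)) imbalanced <- spec_names(spec)
  warns <- character(0)
  is_weighting <- method %in% c("maic", "maic_entropy")
  if (anchored) {
    if (is_weighting) {
      over <- intersect(adjusted, progs)
      if (length(over)) {
        warns <- c(warns, paste0(
          "over-matching: purely prognostic covariate(s) matched (",
          paste(over, collapse = ", "),
          "); this loses precision without reducing bias"))
      }
      omitted <- setdiff(ems, adjusted)
      if (length(omitted)) {
        warns <- c(warns, paste0(
          "effect modifier(s) omitted from matching (",
          paste(omitted, collapse = ", "),
          "); anchored weighting should adjust for all effect modifiers,",
          " in imbalance or not"))
      }
    } else {
      omitted <- setdiff(intersect(ems, imbalanced), adjusted)
      if (length(omitted)) {
        warns <- c(warns, paste0(
          "imbalanced effect modifier(s) excluded from the outcome model (",
          paste(omitted, collapse = ", "), ")"))
      }
    }
  } else {
    omitted <- setdiff(c(ems, progs), adjusted)
    if (length(omitted)) {
      warns <- c(warns, paste0(
        "unanchored analysis omits declared variable(s) (",
        paste(omitted, collapse = ", "),
        "); reliable prediction of absolute outcomes requires all effect",
        " modifiers and prognostic variables"))
    }
  }
  statements <- c(
    sprintf("comparison carried out on the %s linear predictor scale",
            scale$name),
    sprintf("target population: %s", population)
  )
  structure(c(warns, statements), class = "pa_assumptions",
            n_warnings = length(warns))
}

#' @export
print.pa_effect <- function(x, ...) {
  cat(sprintf("<pa_effect %s vs %s in %s, %s scale> %.4g (se %.4g)\n",
              x$contrast[1L], x$contrast[2L], x$population, x$scale$name,
              x$estimate, x$se))
  invisible(x)
}

#' @export
print.pa_comparison <- function(x, ...) {
  cat(sprintf("%s comparison: %s vs %s (%s scale), population: %s\n",
              if (x$anchored) "Anchored" else "UNANCHORED",
              x$contrast[1L], x$contrast[2L], x$scale$name, x$population))
  cat(sprintf("  method: %s\n", x$method))
  cat(sprintf("  estimate: %.4f (se %.4f), 95%% CI [%.4f, %.4f]\n",
              x$estimate, x$se, x$ci95[1L], x$ci95[2L]))
  if (!is.null(x$ess)) cat(sprintf("  ESS: %.1f\n", x$ess))
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}
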