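#' Full MAIC analysis of an IPD trial against an aggregate trial
#'
#' Convenience pipeline: build the moment matrix, estimate weights
#' (method of moments or entropy balancing), form weighted arm estimates,
#' and return the anchored (or, if explicitly requested and justified,
#' unanchored) indirect comparison with a sandwich standard error and the
#' recommendation warnings attached.
#'
#' @param trial A `pa_ipd` object (the AB trial).
#' @param aggregate A `pa_aggregate` object (the AC trial).
#' @param spec Covariate specification (defaults to the trial's).
#' @param scale A [pa_scale()] or scale name.
#' @param anchored Logical; unanchored analyses additionally require
#'   `anchored_available = FALSE`.
#' @param anchored_available Is an anchored route available in the
#'   evidence network? Unanchored analyses are refused while `TRUE`.
#' @param method `"moments"` or `"entropy"`.
#' @param selection Covariates to match; default `"effect_modifiers"` for
#'   anchored analyses, `"all"` for unanchored ones.
#' @param variance `"sandwich"` (default) or `"fixed"` (weights treated
#'   as fixed; diagnostic use only).
#' @return A `pa_comparison` with the weight solution attached as
#'   attribute `"weights"` and diagnostics as `"weight_summary"`.
#' @export
maic_analysis <- function(trial, aggregate, spec = trial$spec,
                          scale = "identity", anchored = TRUE,
                          anchored_available = TRUE,
                          method = c("moments", "entropy"),
                          selection = NULL,
                          variance = c("sandwich", "fixed")) {
  method <- match.arg(method)
  variance <- match.arg(variance)
  scale <- as_pa_scale(scale)
  spec <- as_covariate_list(spec)
  if (is.null(selection)) {
    selection <- if (anchored) "effect_modifiers" else "all"
  }
  no_em <- identical(selection, "effect_modifiers") &&
    length(em_names(spec)) == 0L
  if (no_em || length(selection) == 0L) {
    # no effect modifiers declared: no adjustment occurs, estimates reduce
    # to the unweighted (standard indirect comparison) ones
    Z <- NULL
    w <- uniform_weights(trial, method = method)
    matched <- character(0)
  } else {
    Z <- build_moment_matrix(trial, aggregate, spec, selection = selection)
    w <- if (method == "moments") fit_maic_weights(Z) else
      fit_entropy_weights(Z)
    matched <- unique(sub("\\.(mean|var)$", "", Z$column_labels))
  }
  pred <- weighted_arm_estimates(trial, w)
  vr <- if (variance == "sandwich") sandwich_se(w, trial, Z, scale) else NULL

  method_label <- if (method == "entropy") "maic_entropy" else "maic"
  warns <- check_assumptions(method_label, spec, anchored = anchored,
                             adjusted = matched, scale = scale,
                             population = aggregate$trial_id)

  obs <- aggregate$arm_summaries
  if (anchored) {
    if (!all(c(trial$arms[1L]) %in% names(obs))) {
      stop("anchored comparison requires the common comparator arm '",
           trial$arms[1L], "' in the aggregate trial", call. = FALSE)
    }
    other <- setdiff(names(obs), trial$arms[1L])[1L]
    res <- anchored_comparison(
      pred_A = pred[[trial$arms[1L]]], pred_B = pred[[trial$arms[2L]]],
      obs_A = obs[[trial$arms[1L]]], obs_C = obs[[other]],
      scale = scale, method = method_label,
      population = aggregate$trial_id,
      se_pred = if (is.null(vr)) NULL else vr$se_total,
      ess = w$ess, warnings = unclass(warns))
  } else {
    other <- setdiff(names(obs), trial$arms)[1L]
    if (is.na(other)) other <- names(obs)[length(obs)]
    pb <- pred[[trial$arms[2L]]]
    se_pred <- if (is.null(vr)) NULL else {
      vr$se_components$eta[[trial$arms[2L]]]
    }
    res <- unanchored_comparison(
      pred_B = pb, obs_C = obs[[other]], scale = scale,
      anchored_available = anchored_available,
      method = method_label, population = aggregate$trial_id,
      se_pred = se_pred, ess = w$ess, warnings = unclass(warns))
  }
  attr(res, "weights") <- w
  attr(res, "weight_summary") <- weight_summary(w)
  attr(res, "variance") <- vr
  res
}

#' Full STC analysis of an IPD trial against an aggregate trial
#'
#' Fits the outcome regression on the IPD trial and predicts absolute arm
#' outcomes in the aggregate population, by plug-in of mean covariate
#' values (identity scale) or by averaging predictions over draws from
#' the joint covariate distribution (recommended on non-identity scales,
#' where the plug-in is systematically biased). The comparison is formed
#' on the same scale as the outcome model; this is enforced.
#'
#' @inheritParams maic_analysis
#' @param prediction `"plugin"` or `"simulate"`.
#' @param n_draws,seed For `prediction = "simulate"`.
#' @param correlation Optional correlation matrix for the covariate draw;
#'   defaults to the Pearson correlations observed in the IPD.
#' @return A `pa_comparison` with the fitted `pa_outcome_model` attached
#'   as attribute `"model"`.
#' @export
stc_analysis <- function(trial, aggregate, spec = trial$spec,
                         scale = "identity", anchored = TRUE,
                         anchored_available = TRUE,
                         prediction = c("plugin", "simulate"),
                         n_draws = 1e5, seed = NULL,
                         correlation = NULL) {
  prediction <- match.arg(prediction)
  scale <- as_pa_scale(scale)
  spec <- as_covariate_list(spec)
  model <- fit_outcome_model(trial, spec, scale)

  if (prediction == "plugin") {
    pred <- predict_plugin(model, aggregate)
  } else {
    if (is.null(seed)) stop("prediction = 'simulate' requires a seed",
                            call. = FALSE)
    dist <- covariate_distribution(aggregate, spec,
                                   correlation = correlation, ipd = trial)
    pred <- predict_by_simulation(model, dist, n_draws = n_draws,
                                  seed = seed)
  }
  warns <- check_assumptions("stc", spec, anchored = anchored,
                             adjusted = model$covariates, scale = scale,
                             population = aggregate$trial_id)
  warns <- c(attr(pred, "warnings"), unclass(warns))

  obs <- aggregate$arm_summaries
  if (anchored) {
    other <- setdiff(names(obs), trial$arms[1L])[1L]
    res <- anchored_comparison(
      pred_A = pred$A, pred_B = pred$B,
      obs_A = obs[[trial$arms[1L]]], obs_C = obs[[other]],
      scale = scale, method = "stc", population = aggregate$trial_id,
      se_pred = attr(pred, "se_eta_contrast"),
      warnings = warns)
  } else {
    other <- setdiff(names(obs), trial$arms)[1L]
    if (is.na(other)) other <- names(obs)[length(obs)]
    res <- unanchored_comparison(
      pred_B = pred$B, obs_C = obs[[other]], scale = scale,
      anchored_available = anchored_available,
      method = "stc", population = aggregate$trial_id,
      warnings = warns)
  }
  attr(res, "model") <- model
  attr(res, "prediction") <- pred
  res
}

#' Standard indirect comparison from trial summaries
#'
#' Forms the Bucher estimate from the IPD trial's own arm summaries and
#' the aggregate trial's summaries on the chosen scale.
#'
#' @inheritParams maic_analysis
#' @return A `pa_comparison`, `method = "bucher"`.
#' @export
bucher_analysis <- function(trial, aggregate, scale = "identity") {
  scale <- as_pa_scale(scale)
  s <- summarize_ipd(trial)
  d_ab <- trial_relative_effect(s$arm_summaries[[trial$arms[2L]]],
                                s$arm_summaries[[trial$arms[1L]]],
                                scale, population = trial$trial_id)
  obs <- aggregate$arm_summaries
  other <- setdiff(names(obs), trial$arms[1L])[1L]
  d_ac <- trial_relative_effect(obs[[other]], obs[[trial$arms[1L]]],
                                scale, population = aggregate$trial_id)
  bucher(d_ac, d_ab)
}
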