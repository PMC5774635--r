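#' Fit the STC outcome regression on IPD
#'
#' Simulated treatment comparison fits a generalized linear model to the
#' IPD trial on a declared link scale:
#'
#'   g(mu) = beta0 + beta1' X + (betaB + beta2' X_EM) * I(arm == B)
#'
#' where `beta1` multiplies the full covariate vector (all declared
#' covariates are prognostic candidates), `betaB` is the B-versus-A effect
#' at X = 0, and `beta2` are treatment-by-effect-modifier interactions on
#' the subvector of covariates declared as effect modifiers. The fitted
#' link scale and the scale of any downstream comparison must be the same;
#' mixing scales makes the comparison uninterpretable and is refused at
#' the comparison stage.
#'
#' Continuous outcomes use Gaussian errors with the identity link; binary
#' outcomes use Bernoulli errors with a logit or log link.
#'
#' @param trial A `pa_ipd` object.
#' @param spec Covariate specification (defaults to the trial's).
#' @param scale A [pa_scale()] or scale name.
#' @param backward_aic If `TRUE`, prognostic-only covariates that do not
#'   improve AIC are dropped by a backward step (effect modifiers and the
#'   treatment term are never dropped). Off by default for
#'   reproducibility.
#' @return An object of class `pa_outcome_model` with elements `beta0`,
#'   `beta1` (named), `betaB`, `beta2` (named), `vcov`, `scale`,
#'   `covariates`, `effect_modifiers`, `fit_stats`, `treat_arm`, `fit`.
#' @export
fit_outcome_model <- function(trial, spec = trial$spec, scale = "identity",
                              backward_aic = FALSE) {
  stopifnot(inherits(trial, "pa_ipd"))
  scale <- as_pa_scale(scale)
  spec <- as_covariate_list(spec)
  covs <- spec_names(spec)
  ems <- em_names(spec)

  if (trial$outcome_type == "continuous" && scale$name != "identity") {
    stop("continuous outcomes are modelled on the identity scale",
         call. = FALSE)
  }
  if (trial$outcome_type == "binary" && scale$name == "identity") {
    stop(paste("binary outcomes require a logit or log link for the",
               "outcome model"), call. = FALSE)
  }

  treat_arm <- trial$arms[2L]     # arms are sorted; second arm is "B"
  df <- trial$data
  df$.treat <- as.integer(df$arm == treat_arm)

  n_coef <- 2L + length(covs) + length(ems)
  if (any(table(df$arm) < n_coef + 2L)) {
    stop(sprintf("need at least %d patients per arm to fit %d coefficients",
                 n_coef + 2L, n_coef), call. = FALSE)
  }

  if (trial$outcome_type == "binary") {
    for (a in trial$arms) {
      ya <- df$outcome[df$arm == a]
      if (all(ya == 0) || all(ya == 1)) {
        stop(sprintf(
          "separation: arm '%s' has all outcomes equal to %d; the %s-link model is not identified",
          a, ya[1L], scale$name), call. = FALSE)
      }
    }
  }

  rhs <- c(covs, ".treat",
           if (length(ems)) paste0(".treat:", ems))
  form <- stats::reformulate(rhs, response = "outcome")
  fam <- switch(paste(trial$outcome_type, scale$name),
    "continuous identity" = stats::gaussian(),
    "binary logit" = stats::binomial(link = "logit"),
    "binary log" = stats::binomial(link = "log")
  )
  fit <- stats::glm(form, data = df, family = fam)
  if (!fit$converged) {
    stop("outcome model did not converge (possible separation or a ",
         "log-link probability above 1)", call. = FALSE)
  }
  if (backward_aic && length(covs)) {
    protected <- c("outcome", ems, ".treat",
                   if (length(ems)) paste0(".treat:", ems))
    lower_rhs <- c(intersect(covs, ems), ".treat",
                   if (length(ems)) paste0(".treat:", ems))
    lower <- stats::reformulate(lower_rhs, response = "outcome")
    fit <- stats::step(fit, scope = list(lower = lower, upper = form),
                       direction = "backward", trace = 0)
  }
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    bad <- names(cf)[is.na(cf)]
    stop("rank-deficient outcome model; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  int_names <- grep("(^\\.treat:)|(:\\.treat$)", names(cf), value = TRUE)
  beta1_names <- setdiff(names(cf), c("(Intercept)", ".treat", int_names))
  beta1 <- cf[beta1_names]
  beta2 <- stats::setNames(cf[int_names],
                           sub("^\\.treat:|:\\.treat$", "", int_names))

  V <- stats::vcov(fit)
  canon <- names(cf)
  canon[match(int_names, canon)] <-
    paste0(".treat:", sub("^\\.treat:|:\\.treat$", "", int_names))
  dimnames(V) <- list(canon, canon)

  structure(
    list(
      beta0 = unname(cf[["(Intercept)"]]),
      beta1 = beta1,
      betaB = unname(cf[[".treat"]]),
      beta2 = beta2,
      vcov = V,
      scale = scale,
      covariates = names(beta1),
      effect_modifiers = names(beta2),
      fit_stats = list(aic = stats::AIC(fit), deviance = stats::deviance(fit),
                       df_residual = stats::df.residual(fit),
                       dispersion = summary(fit)$dispersion),
      treat_arm = treat_arm,
      base_arm = trial$arms[1L],
      fit = fit
    ),
    class = "pa_outcome_model"
  )
}

#' Construct an outcome model from known coefficients
#'
#' Useful for scenario calculations and for studying the behaviour of the
#' predictors at known parameter values (no sampling noise).
#'
#' @param beta0 Intercept.
#' @param beta1 Named vector of prognostic coefficients (full covariate
#'   vector).
#' @param betaB Treatment-B main effect at X = 0.
#' @param beta2 Named vector of effect-modifier interaction coefficients
#'   (names a subset of `names(beta1)`).
#' @param scale A [pa_scale()] or scale name.
#' @param vcov Optional coefficient covariance matrix (defaults to zero:
#'   coefficients treated as known).
#' @return A `pa_outcome_model` object.
#' @export
outcome_model <- function(beta0, beta1, betaB, beta2 = numeric(0),
                          scale = "identity", vcov = NULL) {
  scale <- as_pa_scale(scale)
  if (length(beta2) && !all(names(beta2) %in% names(beta1))) {
    stop("effect modifiers must be a subvector of the covariate vector",
         call. = FALSE)
  }
  p <- 2L + length(beta1) + length(beta2)
  if (is.null(vcov)) vcov <- matrix(0, p, p)
  structure(
    list(beta0 = beta0, beta1 = beta1, betaB = betaB, beta2 = beta2,
         vcov = vcov, scale = scale,
         covariates = names(beta1), effect_modifiers = names(beta2),
         fit_stats = NULL, treat_arm = "B", base_arm = "A", fit = NULL),
    class = "pa_outcome_model"
  )
}

model_coef_order <- function(model) {
  c("(Intercept)", model$covariates, ".treat",
    if (length(model$effect_modifiers))
      paste0(".treat:", model$effect_modifiers))
}

model_coef_vector <- function(model) {
  stats::setNames(
    c(model$beta0, model$beta1, model$betaB, model$beta2),
    model_coef_order(model)
  )
}

model_vcov_ordered <- function(model) {
  V <- model$vcov
  ord <- model_coef_order(model)
  if (!is.null(dimnames(V)) && all(ord %in% rownames(V))) {
    V <- V[ord, ord, drop = FALSE]
  }
  V
}

target_means <- function(model, target) {
  container <- inherits(target, "pa_aggregate") || inherits(target, "pa_target")
  if (container) {
    # published trials report covariates beyond the model's; use what the
    # model knows and leave the rest
    target <- target$covariate_summaries
    target <- target[intersect(names(target), model$covariates)]
  }
  target <- as_cov_summary_list(target)
  unknown <- setdiff(names(target), model$covariates)
  if (length(unknown)) {
    stop("prediction refused: covariate(s) unknown to the model: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing_m <- setdiff(model$covariates, names(target))
  if (length(missing_m)) {
    stop("missing covariate mean(s) for prediction: ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  }
  vapply(target[model$covariates], `[[`, 0, "mean")
}

#' Plug-in prediction of absolute outcomes in a target population
#'
#' Substitutes the target population's mean covariate values into the
#' fitted regression and back-transforms:
#' `Yhat_A = g_inv(beta0 + beta1' xbar)` and
#' `Yhat_B = g_inv(beta0 + beta1' xbar + betaB + beta2' xbar_EM)`.
#'
#' When the link is not the identity this estimator is systematically
#' biased: the population mean outcome depends on the whole covariate
#' distribution, not only its mean, and `E[g_inv(eta(X))] !=
#' g_inv(eta(E[X]))` for nonlinear `g_inv` (aggregation bias). A warning
#' to that effect is attached to the result; use
#' [predict_by_simulation()] on non-identity scales.
#'
#' @param model A `pa_outcome_model`.
#' @param target Covariate summaries (list of [covariate_summary()], a
#'   `pa_aggregate`, or a `pa_target`).
#' @return Named list of two [arm_summary()] objects (`A`, `B`), with
#'   delta-method standard errors from the coefficient covariance; a
#'   `warnings` attribute carries the aggregation-bias warning on
#'   non-identity scales.
#' @export
predict_plugin <- function(model, target) {
  stopifnot(inherits(model, "pa_outcome_model"))
  xbar <- target_means(model, target)
  xbar_em <- xbar[model$effect_modifiers]

  eta_A <- model$beta0 + sum(model$beta1 * xbar)
  eta_B <- eta_A + model$betaB + sum(model$beta2 * xbar_em)

  # delta method: d eta / d beta rows for each arm
  dA <- c(1, xbar, 0, rep(0, length(model$effect_modifiers)))
  dB <- c(1, xbar, 1, xbar_em)
  V <- model_vcov_ordered(model)
  se_eta_A <- sqrt(drop(t(dA) %*% V %*% dA))
  se_eta_B <- sqrt(drop(t(dB) %*% V %*% dB))

  yA <- model$scale$g_inv(eta_A)
  yB <- model$scale$g_inv(eta_B)
  out <- list(
    A = arm_summary(model$base_arm, n = 1,
                    ybar = yA, se_ybar = se_eta_A / model$scale$dg(yA)),
    B = arm_summary(model$treat_arm, n = 1,
                    ybar = yB, se_ybar = se_eta_B / model$scale$dg(yB))
  )
  warns <- character(0)
  if (model$scale$name != "identity") {
    warns <- paste(
      "plug-in prediction on a non-identity link scale is systematically",
      "biased: the population mean outcome depends on the full covariate",
      "distribution, not only its mean; use predict_by_simulation()")
  }
  attr(out, "warnings") <- warns
  attr(out, "se_eta") <- c(A = se_eta_A, B = se_eta_B)
  dC <- dB - dA   # gradient of the predicted contrast on the LP scale
  attr(out, "se_eta_contrast") <- sqrt(drop(t(dC) %*% V %*% dC))
  out
}

#' Joint covariate distribution for simulation-based prediction
#'
#' The aggregate trial publishes only marginal covariate summaries; a
#' joint distribution is reconstructed as a Gaussian copula with those
#' marginals (normal for continuous covariates, Bernoulli by thresholding
#' for binary ones) and a correlation matrix either supplied directly or
#' imputed from the Pearson correlations observed in the IPD trial.
#'
#' @param marginals List of [covariate_summary()] objects (continuous
#'   covariates need `sd`), or a `pa_aggregate`/`pa_target`.
#' @param spec Covariate specification (gives each covariate's kind).
#' @param correlation Correlation matrix (unit diagonal, symmetric, PSD),
#'   or `NULL` for independence.
#' @param ipd Optional `pa_ipd`; when given and `correlation` is `NULL`,
#'   Pearson correlations are copied from the IPD.
#' @return A `pa_cov_dist` object.
#' @export
covariate_distribution <- function(marginals, spec, correlation = NULL,
                                   ipd = NULL) {
  if (inherits(marginals, "pa_aggregate") || inherits(marginals, "pa_target")) {
    marginals <- marginals$covariate_summaries
  }
  marginals <- as_cov_summary_list(marginals)
  spec <- as_covariate_list(spec)
  nms <- names(marginals)
  source <- "supplied-marginals"
  if (is.null(correlation)) {
    if (!is.null(ipd) && length(nms) > 1L) {
      correlation <- stats::cor(as.matrix(ipd$data[, nms, drop = FALSE]))
      source <- "target-marginals + IPD-correlations"
    } else {
      correlation <- diag(length(nms))
      dimnames(correlation) <- list(nms, nms)
      source <- "target-marginals, independence"
    }
  }
  correlation <- as.matrix(correlation)
  if (is.null(dimnames(correlation))) {
    dimnames(correlation) <- list(nms, nms)
  }
  validate_correlation(correlation[nms, nms, drop = FALSE])
  for (nm in nms) {
    s <- spec[[nm]]
    if (is.null(s)) stop("covariate '", nm, "' not declared", call. = FALSE)
    if (s$kind == "continuous" && is.null(marginals[[nm]]$sd)) {
      stop(sprintf("continuous covariate '%s' needs an sd to simulate", nm),
           call. = FALSE)
    }
  }
  structure(
    list(marginals = marginals, spec = spec,
         correlation = correlation[nms, nms, drop = FALSE], source = source),
    class = "pa_cov_dist"
  )
}

validate_correlation <- function(R) {
  if (!isSymmetric(unname(R), tol = 1e-8)) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(R) - 1) > 1e-8)) {
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("correlation matrix is not positive semi-definite", call. = FALSE)
  }
  invisible(TRUE)
}

draw_covariates <- function(dist, n) {
  nms <- names(dist$marginals)
  p <- length(nms)
  R <- dist$correlation
  # tiny ridge if semi-definite so mvrnorm accepts it
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) R <- R + diag(1e-8, p)
  Zn <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = R)
  if (p == 1L) Zn <- matrix(Zn, ncol = 1L)
  X <- matrix(0, n, p, dimnames = list(NULL, nms))
  for (j in seq_len(p)) {
    m <- dist$marginals[[nms[j]]]
    s <- dist$spec[[nms[j]]]
    if (s$kind == "binary") {
      X[, j] <- as.numeric(Zn[, j] < stats::qnorm(m$mean))
    } else {
      X[, j] <- m$mean + m$sd * Zn[, j]
    }
  }
  X
}

#' Simulation-based prediction of absolute outcomes
#'
#' Draws covariate vectors from the joint distribution and averages the
#' back-transformed predictions, avoiding the aggregation bias of the
#' plug-in estimator on non-identity scales:
#' `Yhat_t = mean over draws of g_inv(eta_t(X*))`.
#'
#' The reported standard error propagates coefficient uncertainty by the
#' delta method using the Monte-Carlo average of the prediction gradient;
#' the Monte-Carlo error of the average itself is reported separately (as
#' the `mc_se` attribute) so it can be checked to be negligible, and is
#' not folded into the standard error.
#'
#' @param model A `pa_outcome_model`.
#' @param dist A [covariate_distribution()].
#' @param n_draws Number of covariate draws (minimum 1e4).
#' @param seed Integer seed (required, for reproducibility).
#' @return Named list of two [arm_summary()] objects (`A`, `B`), with
#'   attributes `mc_se` (Monte-Carlo SEs) and `se_eta`.
#' @export
predict_by_simulation <- function(model, dist, n_draws = 1e5, seed) {
  stopifnot(inherits(model, "pa_outcome_model"),
            inherits(dist, "pa_cov_dist"))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (n_draws < 1e4) {
    stop("n_draws must be at least 10^4 for a stable average",
         call. = FALSE)
  }
  missing_m <- setdiff(model$covariates, names(dist$marginals))
  if (length(missing_m)) {
    stop("covariate distribution missing model covariate(s): ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  }
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  X <- draw_covariates(dist, n_draws)[, model$covariates, drop = FALSE]
  eta_A <- model$beta0 + drop(X %*% model$beta1)
  Xem <- X[, model$effect_modifiers, drop = FALSE]
  eta_B <- eta_A + model$betaB + drop(Xem %*% model$beta2)

  muA <- model$scale$g_inv(eta_A)
  muB <- model$scale$g_inv(eta_B)
  yA <- mean(muA); yB <- mean(muB)
  mc_se <- c(A = stats::sd(muA), B = stats::sd(muB)) / sqrt(n_draws)

  # delta method with MC-averaged gradients d mean(mu)/d beta
  dinv <- function(eta) {
    switch(model$scale$name,
      identity = rep_len(1, length(eta)),
      log = exp(eta),
      logit = { p <- 1 / (1 + exp(-eta)); p * (1 - p) })
  }
  gA <- dinv(eta_A); gB <- dinv(eta_B)
  k_em <- length(model$effect_modifiers)
  dA <- c(mean(gA), colMeans(X * gA), 0, rep(0, k_em))
  dB <- c(mean(gB), colMeans(X * gB), mean(gB),
          if (k_em) colMeans(Xem * gB))
  V <- model_vcov_ordered(model)
  seA <- sqrt(drop(t(dA) %*% V %*% dA))
  seB <- sqrt(drop(t(dB) %*% V %*% dB))

  out <- list(
    A = arm_summary(model$base_arm, n = 1, ybar = yA, se_ybar = seA),
    B = arm_summary(model$treat_arm, n = 1, ybar = yB, se_ybar = seB)
  )
  attr(out, "mc_se") <- mc_se
  attr(out, "n_draws") <- n_draws
  # SE of the contrast g(Yhat_B) - g(Yhat_A) on the LP scale: gradient of
  # g(mean mu) is dg(ybar) * d ybar / d beta
  dC <- model$scale$dg(yB) * dB - model$scale$dg(yA) * dA
  attr(out, "se_eta_contrast") <- sqrt(drop(t(dC) %*% V %*% dC))
  attr(out, "se_eta") <- c(A = model$scale$dg(yA) * seA,
                           B = model$scale$dg(yB) * seB)
  out
}

# save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream
withr_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.pa_outcome_model <- function(x, ...) {
  cat(sprintf("<pa_outcome_model scale=%s>\n", x$scale$name))
  cat(sprintf("  beta0 = %.4g, betaB (%s vs %s at X=0) = %.4g\n",
              x$beta0, x$treat_arm, x$base_arm, x$betaB))
  if (length(x$beta1)) {
    cat("  beta1:", paste(sprintf("%s=%.4g", names(x$beta1), x$beta1),
                          collapse = ", "), "\n")
  }
  if (length(x$beta2)) {
    cat("  beta2:", paste(sprintf("%s=%.4g", names(x$beta2), x$beta2),
                          collapse = ", "), "\n")
  }
  invisible(x)
}
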