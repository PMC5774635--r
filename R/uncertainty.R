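#' Robust sandwich variance for MAIC estimates
#'
#' The MAIC weights are estimated, not fixed, and the same weights enter
#' both arm averages; a naive weighted-mean variance ignores both facts.
#' This estimator stacks the estimating equations of the whole procedure
#' -- the K moment-balance equations defining the weight coefficients
#' alpha (pooled over both IPD arms) and the two weighted-mean equations
#' for (mu_A, mu_B) -- and applies the M-estimation sandwich
#' `V = A^-1 B A^-T / N`, with `A` the empirical Jacobian of the stacked
#' scores and `B` their outer-product matrix. The SE of the predicted
#' contrast `g(mu_B) - g(mu_A)` follows by the delta method.
#'
#' With no matched moments (K = 0) the sandwich reduces to the classical
#' robust SE of each arm mean.
#'
#' Aggregate-trial (AC) uncertainty is independent of the IPD and enters
#' later, at the comparison stage.
#'
#' @param w A converged `pa_weights` solution.
#' @param trial The `pa_ipd` the weights were fitted on.
#' @param Z The `pa_moment_matrix` used for fitting, or `NULL` for the
#'   fixed-weight (K = 0) limit.
#' @param scale A [pa_scale()] or scale name.
#' @return A `pa_variance` object: `se_total` (SE of the B-vs-A contrast
#'   on the linear predictor scale), `se_components` (per-arm SEs on the
#'   natural and linear predictor scales), `vcov_mu`, `method =
#'   "sandwich"`.
#' @export
sandwich_se <- function(w, trial, Z = NULL, scale = "identity") {
  stopifnot(inherits(trial, "pa_ipd"))
  scale <- as_pa_scale(scale)
  N <- nrow(trial$data)
  if (!is.null(Z)) {
    stopifnot(inherits(Z, "pa_moment_matrix"))
    Zm <- Z$Z
  } else {
    Zm <- matrix(0, N, 0)
  }
  K <- ncol(Zm)
  if (inherits(w, "pa_weights")) {
    if (!isTRUE(w$converged)) {
      stop("sandwich variance requires a converged weight solution",
           call. = FALSE)
    }
    wt <- w$weights
  } else {
    wt <- w
  }
  arm <- trial$data$arm
  y <- trial$data$outcome
  iA <- as.numeric(arm == trial$arms[1L])
  iB <- as.numeric(arm == trial$arms[2L])
  muA <- sum(iA * wt * y) / sum(iA * wt)
  muB <- sum(iB * wt * y) / sum(iB * wt)

  # stacked scores: psi_i = (Z_i w_i, iA w_i (y - muA), iB w_i (y - muB))
  p <- K + 2L
  psi <- cbind(
    if (K) Zm * wt,
    iA * wt * (y - muA),
    iB * wt * (y - muB)
  )
  B <- crossprod(psi) / N

  A <- matrix(0, p, p)
  if (K) {
    A[1:K, 1:K] <- crossprod(Zm * wt, Zm) / N
    A[K + 1L, 1:K] <- colSums(Zm * (iA * wt * (y - muA))) / N
    A[K + 2L, 1:K] <- colSums(Zm * (iB * wt * (y - muB))) / N
  }
  A[K + 1L, K + 1L] <- -sum(iA * wt) / N
  A[K + 2L, K + 2L] <- -sum(iB * wt) / N

  Ainv <- tryCatch(solve(A), error = function(e) {
    stop("singular Jacobian in the sandwich variance (degenerate weights ",
         "or collinear moments)", call. = FALSE)
  })
  V <- Ainv %*% B %*% t(Ainv) / N
  Vmu <- V[(K + 1L):(K + 2L), (K + 1L):(K + 2L), drop = FALSE]
  dimnames(Vmu) <- list(trial$arms, trial$arms)

  grad <- c(-scale$dg(muA), scale$dg(muB))
  se_contrast <- sqrt(drop(t(grad) %*% Vmu %*% grad))
  se_mu <- sqrt(diag(Vmu))

  structure(
    list(
      se_total = se_contrast,
      se_components = list(
        mu = stats::setNames(se_mu, trial$arms),
        eta = stats::setNames(
          c(scale$dg(muA), scale$dg(muB)) * se_mu, trial$arms)
      ),
      mu = stats::setNames(c(muA, muB), trial$arms),
      vcov_mu = Vmu,
      method = "sandwich",
      scale = scale$name
    ),
    class = "pa_variance"
  )
}

#' Bootstrap variance for a population-adjusted analysis
#'
#' Nonparametric bootstrap over the whole pipeline: patients are resampled
#' with replacement within each IPD arm and the full analysis (weight
#' estimation or outcome regression, then the comparison) is re-run per
#' replicate. Aggregate-trial summaries are resampled parametrically:
#' binary arm counts as `r* ~ Binomial(n, ybar)`, continuous arm means as
#' `Normal(ybar, se)`. Replicates where the analysis fails (e.g. weights
#' do not converge on a resample) are dropped and counted; more than 10%
#' failures is an error.
#'
#' Replicate seeds are derived from `seed` by a counter so results are
#' reproducible under any execution order.
#'
#' @param analysis A function `(trial, aggregate) -> pa_comparison` (or a
#'   single numeric estimate) implementing the full analysis.
#' @param trial A `pa_ipd` object.
#' @param aggregate A `pa_aggregate` object.
#' @param n_boot Number of bootstrap replicates (minimum 200).
#' @param seed Integer master seed.
#' @return A `pa_variance` object with `se_total`, percentile and normal
#'   95% CIs, `n_boot`, `n_fail`, and the replicate estimates.
#' @export
bootstrap <- function(analysis, trial, aggregate, n_boot = 1000L, seed) {
  stopifnot(inherits(trial, "pa_ipd"), inherits(aggregate, "pa_aggregate"))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (n_boot < 200L) stop("n_boot must be at least 200", call. = FALSE)

  idx_by_arm <- split(seq_len(nrow(trial$data)), trial$data$arm)
  est <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    old <- withr_seed((seed + b) %% .Machine$integer.max)
    res <- tryCatch({
      idx <- unlist(lapply(idx_by_arm, function(ix) {
        sample(ix, length(ix), replace = TRUE)
      }), use.names = FALSE)
      tr_b <- trial
      tr_b$data <- trial$data[idx, , drop = FALSE]
      agg_b <- resample_aggregate(aggregate)
      out <- analysis(tr_b, agg_b)
      if (inherits(out, "pa_comparison")) out$estimate else as.numeric(out)
    }, error = function(e) NA_real_)
    restore_seed(old)
    est[b] <- res
  }
  ok <- est[is.finite(est)]
  n_fail <- n_boot - length(ok)
  if (n_fail > 0.1 * n_boot) {
    stop(sprintf(
      "bootstrap failed in %d/%d replicates (weight estimation likely near the support boundary)",
      n_fail, n_boot), call. = FALSE)
  }
  se <- stats::sd(ok)
  m <- mean(ok)
  structure(
    list(
      se_total = se,
      se_components = NULL,
      mean = m,
      ci95_percentile = unname(stats::quantile(ok, c(0.025, 0.975))),
      ci95_normal = m + c(-1, 1) * stats::qnorm(0.975) * se,
      n_boot = n_boot, n_fail = n_fail, seed = seed,
      estimates = ok,
      method = "bootstrap"
    ),
    class = "pa_variance"
  )
}

resample_aggregate <- function(aggregate) {
  agg <- aggregate
  agg$arm_summaries <- lapply(aggregate$arm_summaries, function(a) {
    if (aggregate$outcome_type == "binary") {
      r_star <- stats::rbinom(1L, size = round(a$n), prob = a$ybar)
      arm_summary(a$arm, n = a$n, r = r_star)
    } else {
      arm_summary(a$arm, n = a$n,
                  ybar = stats::rnorm(1L, a$ybar, a$se_ybar),
                  se_ybar = a$se_ybar)
    }
  })
  names(agg$arm_summaries) <- names(aggregate$arm_summaries)
  agg
}

#' @export
print.pa_variance <- function(x, ...) {
  cat(sprintf("<pa_variance method=%s> se_total = %.4g\n",
              x$method, x$se_total))
  if (!is.null(x$n_fail) && x$n_fail > 0) {
    cat(sprintf("  %d failed replicates dropped\n", x$n_fail))
  }
  invisible(x)
}
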