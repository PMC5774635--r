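#' Build the centered moment matrix for MAIC weighting
#'
#' MAIC weights are chosen so that covariate moments in the reweighted IPD
#' population exactly equal the published summaries of the aggregate
#' trial. Centering each matched moment at its target reduces the balance
#' conditions to "weighted column means equal zero": the mean column for a
#' covariate is `x - mean_target`; when a continuous covariate is matched
#' on mean and variance a second column `x^2 - (mean_target^2 +
#' sd_target^2)` is added, using the second-raw-moment identity
#' `E[X^2] = mu^2 + sigma^2`.
#'
#' Columns are scaled to unit standard deviation internally for numerical
#' conditioning; the scaling is recorded so weight-model coefficients are
#' reported on the raw covariate scale. Collinear columns are dropped by a
#' rank-revealing QR with a warning naming them.
#'
#' @param trial A `pa_ipd` object.
#' @param target List of [covariate_summary()] objects (or a
#'   `pa_aggregate` / `pa_target`, whose covariate summaries are used).
#' @param spec Covariate specification; defaults to the trial's.
#' @param selection Which declared covariates to match: a character vector
#'   of covariate names, or one of the role filters
#'   `"effect_modifiers"` (default, the anchored-comparison convention),
#'   `"all"` (effect modifiers and prognostics, for unanchored
#'   comparisons).
#' @return An object of class `pa_moment_matrix` with elements `Z` (N x K
#'   centered moment matrix), `column_labels`, `arm` (row arm labels),
#'   `scaling`, and `targets`.
#' @export
build_moment_matrix <- function(trial, target, spec = trial$spec,
                                selection = "effect_modifiers") {
  stopifnot(inherits(trial, "pa_ipd"))
  spec <- as_covariate_list(spec)
  if (inherits(target, "pa_aggregate") || inherits(target, "pa_target")) {
    target <- target$covariate_summaries
  }
  target <- as_cov_summary_list(target)
  sel_names <- if (identical(selection, "effect_modifiers")) {
    em_names(spec)
  } else if (identical(selection, "all")) {
    spec_names(spec)
  } else {
    unknown <- setdiff(selection, spec_names(spec))
    if (length(unknown)) {
      stop("selection names unknown covariate(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    selection
  }
  if (!length(sel_names)) {
    stop("no covariates selected for matching", call. = FALSE)
  }
  missing_t <- setdiff(sel_names, names(target))
  if (length(missing_t)) {
    stop("no target summary for matched covariate(s): ",
         paste(missing_t, collapse = ", "), call. = FALSE)
  }

  cols <- list()
  labels <- character(0)
  tvals <- numeric(0)
  for (nm in sel_names) {
    s <- spec[[nm]]
    x <- trial$data[[nm]]
    tg <- target[[nm]]
    if (tg$mean < min(x) || tg$mean > max(x)) {
      stop(sprintf(
        "target mean %g for '%s' not within support [%g, %g]: no weight set can balance it",
        tg$mean, nm, min(x), max(x)), call. = FALSE)
    }
    if (min(x) == max(x) && tg$mean != x[1L]) {
      stop(sprintf("covariate '%s' is constant in the IPD; target %g not within support",
                   nm, tg$mean), call. = FALSE)
    }
    cols[[length(cols) + 1L]] <- x - tg$mean
    labels <- c(labels, paste0(nm, ".mean"))
    tvals <- c(tvals, tg$mean)
    if (s$kind == "continuous" && s$match_moments == "mean_and_variance") {
      if (is.null(tg$sd)) {
        stop(sprintf("variance matching for '%s' requires a target sd", nm),
             call. = FALSE)
      }
      m2 <- tg$mean^2 + tg$sd^2
      cols[[length(cols) + 1L]] <- x^2 - m2
      labels <- c(labels, paste0(nm, ".var"))
      tvals <- c(tvals, m2)
    }
  }
  Z <- do.call(cbind, cols)
  colnames(Z) <- labels

  # drop collinear columns (rank-revealing QR on the scaled matrix)
  scl <- apply(Z, 2L, stats::sd)
  scl[scl == 0] <- 1
  qrd <- qr(sweep(Z, 2L, scl, "/"))
  if (qrd$rank < ncol(Z)) {
    keep <- sort(qrd$pivot[seq_len(qrd$rank)])
    dropped <- labels[-keep]
    warning("dropping collinear moment column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    Z <- Z[, keep, drop = FALSE]
    labels <- labels[keep]
    tvals <- tvals[keep]
    scl <- scl[keep]
  }

  structure(
    list(Z = Z, column_labels = labels, arm = trial$data$arm,
         scaling = scl, targets = tvals),
    class = "pa_moment_matrix"
  )
}

#' Estimate MAIC weights by the method of moments
#'
#' The weight model is log-linear in the matched moments,
#' `log(w_i) = alpha0 + alpha1' X_i`, where the weight is interpreted as
#' the odds of enrollment in the aggregate trial versus the IPD trial.
#' With moments centered at the aggregate targets, the method-of-moments
#' estimate of `alpha1` minimizes the convex objective
#' `sum_i exp(alpha1' Z_i)` (pooled over both IPD arms); its gradient is
#' exactly the weighted moment-balance condition, so the solution balances
#' every matched moment. The intercept `alpha0` is never estimated: it
#' cancels from all weighted averages, and weights are normalized to sum
#' to N for reporting.
#'
#' Optimization is Newton's method with analytic gradient and Hessian and
#' step-halving line search, with a BFGS fallback; convergence is declared
#' when the gradient infinity-norm (on the internally scaled moments)
#' drops below `tol`.
#'
#' @param Z A `pa_moment_matrix` from [build_moment_matrix()].
#' @param tol Convergence tolerance on the gradient infinity-norm.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `pa_weights`: `alpha` (coefficients on the
#'   raw moment scale), `weights` (normalized, sum N), `ess`, `ess_by_arm`,
#'   `converged`, `gradient_norm`, `method`.
#' @export
fit_maic_weights <- function(Z, tol = 1e-10, max_iter = 200L) {
  stopifnot(inherits(Z, "pa_moment_matrix"))
  Zs <- sweep(Z$Z, 2L, Z$scaling, "/")
  N <- nrow(Zs)
  K <- ncol(Zs)

  obj <- function(a) sum(exp(drop(Zs %*% a)))
  grad <- function(a) drop(crossprod(Zs, exp(drop(Zs %*% a))))

  a <- rep(0, K)
  f <- obj(a)
  converged <- FALSE
  trajectory <- numeric(0)
  for (it in seq_len(max_iter)) {
    ew <- exp(drop(Zs %*% a))
    g <- drop(crossprod(Zs, ew))
    if (max(abs(g)) < tol * f) { converged <- TRUE; break }
    H <- crossprod(Zs * sqrt(ew))
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) { # singular Hessian: fall back to gradient direction
      step <- g / max(abs(g))
    }
    # step-halving line search on the convex objective
    lambda <- 1
    repeat {
      a_new <- a - lambda * step
      f_new <- obj(a_new)
      if (is.finite(f_new) && f_new <= f + 1e-12 * abs(f)) break
      lambda <- lambda / 2
      if (lambda < 1e-12) break
    }
    a <- a - lambda * step
    f <- obj(a)
    trajectory <- c(trajectory, sqrt(sum(a^2)))
  }
  if (!converged) {
    # quasi-Newton fallback before giving up
    opt <- stats::optim(a, fn = obj, gr = grad, method = "BFGS",
                        control = list(maxit = 500L, reltol = 1e-14))
    a <- opt$par
    g <- grad(a)
    converged <- max(abs(g)) < 1e-6 * obj(a)
    if (!converged) {
      stop(sprintf(
        paste("MAIC weight estimation did not converge (gradient norm %.3g;",
              "|alpha| trajectory: %s). This usually signals a target near",
              "the boundary of the observed covariate support."),
        max(abs(g)),
        paste(sprintf("%.3g", utils::tail(trajectory, 5L)), collapse = " -> ")
      ), call. = FALSE)
    }
  }

  ew <- exp(drop(Zs %*% a))
  w <- ew * (N / sum(ew))
  alpha <- a / Z$scaling
  names(alpha) <- Z$column_labels
  new_weight_solution(alpha, w, Z, method = "moments",
                      converged = converged,
                      gradient_norm = max(abs(grad(a))))
}

#' Estimate entropy-balancing weights
#'
#' Entropy balancing selects, among all weight sets satisfying the same
#' moment constraints as MAIC, the set closest to uniform in the
#' Kullback-Leibler sense: it minimizes `sum_i w_i log(w_i)` subject to
#' `Z'w = 0` and `sum w_i = N`. The dual of this program is the
#' log-partition function `log sum_i exp(lambda' Z_i)`, an exponential
#' family identical to the MAIC weight model, so the two weight sets
#' coincide; this function solves the dual directly (BFGS on the
#' log-sum-exp, a deliberately different route from the Newton solver in
#' [fit_maic_weights()]) and tags the solution `method = "entropy"`.
#'
#' @inheritParams fit_maic_weights
#' @return A `pa_weights` object with `method = "entropy"`.
#' @export
fit_entropy_weights <- function(Z, tol = 1e-10, max_iter = 200L) {
  stopifnot(inherits(Z, "pa_moment_matrix"))
  Zs <- sweep(Z$Z, 2L, Z$scaling, "/")
  N <- nrow(Zs)
  K <- ncol(Zs)

  logsumexp <- function(eta) {
    m <- max(eta)
    m + log(sum(exp(eta - m)))
  }
  dual <- function(l) logsumexp(drop(Zs %*% l))
  dual_grad <- function(l) {
    eta <- drop(Zs %*% l)
    p <- exp(eta - logsumexp(eta))
    drop(crossprod(Zs, p))
  }
  opt <- stats::optim(rep(0, K), fn = dual, gr = dual_grad, method = "BFGS",
                      control = list(maxit = 1000L, reltol = 1e-15))
  l <- opt$par
  # polish with Newton steps on the dual for tight balance
  for (it in seq_len(max_iter)) {
    eta <- drop(Zs %*% l)
    p <- exp(eta - logsumexp(eta))
    g <- drop(crossprod(Zs, p))
    if (max(abs(g)) < tol) break
    H <- crossprod(Zs * sqrt(p)) - tcrossprod(g)
    step <- tryCatch(solve(H, g), error = function(e) g)
    l <- l - step
  }
  eta <- drop(Zs %*% l)
  g <- dual_grad(l)
  if (max(abs(g)) > 1e-6) {
    stop("entropy balancing failed to satisfy the moment constraints; ",
         "the target may be near the boundary of the covariate support",
         call. = FALSE)
  }
  p <- exp(eta - logsumexp(eta))
  w <- p * N / sum(p)
  alpha <- l / Z$scaling
  names(alpha) <- Z$column_labels
  new_weight_solution(alpha, w, Z, method = "entropy",
                      converged = TRUE, gradient_norm = max(abs(g)))
}

uniform_weights <- function(trial, method = "moments") {
  N <- nrow(trial$data)
  structure(
    list(alpha = numeric(0), weights = rep(1, N), ess = N,
         ess_by_arm = vapply(split(rep(1, N), trial$data$arm), length, 0L),
         arm = trial$data$arm, balance = numeric(0),
         converged = TRUE, gradient_norm = 0, method = method),
    class = "pa_weights"
  )
}

new_weight_solution <- function(alpha, w, Z, method, converged,
                                gradient_norm) {
  bal <- drop(crossprod(Z$Z, w)) / sum(w)
  ess_arm <- vapply(split(w, Z$arm), effective_sample_size, 0)
  structure(
    list(alpha = alpha, weights = w,
         ess = effective_sample_size(w),
         ess_by_arm = ess_arm,
         arm = Z$arm,
         balance = stats::setNames(bal, Z$column_labels),
         converged = converged, gradient_norm = gradient_norm,
         method = method),
    class = "pa_weights"
  )
}

#' Effective sample size of a weighted sample
#'
#' `ESS = (sum w)^2 / sum(w^2)`: the size of an equally weighted sample
#' carrying the same precision. Invariant to rescaling of the weights;
#' equals N exactly when all weights are equal. Because it treats the
#' weights as fixed and known, this approximation tends to understate the
#' true effective sample size when the weights are estimated.
#'
#' @param weights Non-negative weight vector, not all zero.
#' @return The effective sample size (scalar).
#' @export
effective_sample_size <- function(weights) {
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  s <- sum(weights)
  if (s <= 0) stop("all weights are zero", call. = FALSE)
  s^2 / sum(weights^2)
}

#' Weighted arm estimates in the aggregate population
#'
#' Estimates the absolute outcome that each IPD arm would show in the
#' aggregate trial population, as the weighted average of patient outcomes
#' with the MAIC (or entropy) weights. The reported `n` is the per-arm
#' effective sample size.
#'
#' @param trial A `pa_ipd` object (the one the weights were fitted on).
#' @param w A `pa_weights` object aligned with the trial rows.
#' @return Named list of [arm_summary()] objects, one per arm.
#' @export
weighted_arm_estimates <- function(trial, w) {
  stopifnot(inherits(trial, "pa_ipd"), inherits(w, "pa_weights"))
  if (length(w$weights) != nrow(trial$data)) {
    stop("weights are not aligned with the trial rows", call. = FALSE)
  }
  out <- lapply(trial$arms, function(a) {
    idx <- trial$data$arm == a
    wi <- w$weights[idx]
    sw <- sum(wi)
    if (sw < 1e-12) {
      stop(sprintf("arm '%s' effectively empty after weighting", a),
           call. = FALSE)
    }
    yi <- trial$data$outcome[idx]
    ybar <- sum(yi * wi) / sw
    ess <- effective_sample_size(wi)
    # weighted-sample SE treating weights as fixed (the sandwich estimator
    # accounts for their estimation)
    se <- sqrt(sum(wi^2 * (yi - ybar)^2)) / sw
    arm_summary(a, n = ess, ybar = ybar, se_ybar = se)
  })
  stats::setNames(out, trial$arms)
}

#' Weight diagnostics
#'
#' Reports the distribution of the weights so a lack of population overlap
#' or overly influential patients can be diagnosed: quantiles, the largest
#' individual weight shares, histogram bin counts, and the effective
#' sample size both pooled and per arm.
#'
#' @param w A `pa_weights` object.
#' @param n_bins Number of histogram bins.
#' @return An object of class `pa_weight_summary` (printable list).
#' @export
weight_summary <- function(w, n_bins = 10L) {
  stopifnot(inherits(w, "pa_weights"))
  wt <- w$weights
  N <- length(wt)
  shares <- sort(wt / sum(wt), decreasing = TRUE)
  h <- graphics::hist(wt, breaks = n_bins, plot = FALSE)
  flags <- character(0)
  if (w$ess < 0.1 * N) flags <- c(flags, "ESS < 10% of N")
  structure(
    list(
      n = N,
      quantiles = stats::quantile(wt, c(0, 0.25, 0.5, 0.75, 1)),
      top_shares = utils::head(shares, 5L),
      hist_breaks = h$breaks, hist_counts = h$counts,
      ess = w$ess, ess_fraction = w$ess / N,
      ess_by_arm = w$ess_by_arm,
      flags = flags,
      caveat = paste(
        "The ESS approximation (sum w)^2 / sum(w^2) treats the weights as",
        "fixed; with estimated weights it tends to understate the true",
        "effective sample size.")
    ),
    class = "pa_weight_summary"
  )
}

#' @export
print.pa_weight_summary <- function(x, ...) {
  cat(sprintf("Weight diagnostics (N = %d)\n", x$n))
  cat(sprintf("  ESS = %.2f (%.1f%% of N)\n", x$ess, 100 * x$ess_fraction))
  cat("  per-arm ESS:",
      paste(sprintf("%s=%.2f", names(x$ess_by_arm), x$ess_by_arm),
            collapse = ", "), "\n")
  q <- x$quantiles
  cat(sprintf("  weights: min %.3g / q25 %.3g / median %.3g / q75 %.3g / max %.3g\n",
              q[1], q[2], q[3], q[4], q[5]))
  cat("  top-5 weight shares:",
      paste(sprintf("%.3f", x$top_shares), collapse = ", "), "\n")
  for (f in x$flags) cat("  FLAG:", f, "\n")
  cat(" ", x$caveat, "\n")
  invisible(x)
}

#' @export
print.pa_weights <- function(x, ...) {
  cat(sprintf("<pa_weights method=%s> N=%d, ESS=%.2f, max|balance|=%.2g\n",
              x$method, length(x$weights), x$ess, max(abs(x$balance))))
  invisible(x)
}
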