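#' Define a simulation scenario
#'
#' A scenario describes two randomized trials drawn from a common
#' outcome-generating model: an AB trial (IPD retained) and an AC trial
#' (reduced to aggregate summaries), with covariate distributions that
#' may differ between the two trial populations. Outcomes are generated
#' from
#'
#'   g(mu) = beta0 + beta1' X + (d_t0 + gamma_t' X_EM) * I(arm = t)
#'
#' so each covariate's prognostic coefficient (`beta1`) and per-treatment
#' interaction (`gamma_b`, `gamma_c`) are set explicitly, and analytic
#' (identity scale) or Monte-Carlo (other scales) truths are available
#' from [true_effects()].
#'
#' Defaults describe a typical effect-modifier imbalance: one standard
#' normal covariate that is both prognostic (`beta1 = 1`) and an effect
#' modifier for B (`gamma_b = 1`) but not C (`gamma_c = 0`), centered at
#' 0.2 in the AB population and 0.6 in the AC population, continuous
#' outcomes with unit residual SD on the identity scale, 500 patients per
#' arm in both trials.
#'
#' @param n_ab,n_ac Patients per arm in the AB and AC trials.
#' @param covariates List of covariate definitions, each a list with
#'   `name`, `kind` (`"continuous"`/`"binary"`), `role`, `mean_ab`,
#'   `mean_ac`, optionally `mean_p` (a distinct target population),
#'   `sd` (continuous), and `match_moments`.
#' @param correlation Correlation matrix across covariates (default
#'   independence).
#' @param outcome List: `type` (`"continuous"`/`"binary"`), `scale`
#'   (link name), `sd_resid` (continuous only).
#' @param truth List: `beta0`, `beta1` (named), `d_ab0`, `d_ac0` (B- and
#'   C-versus-A effects at X_EM = 0), `gamma_b`, `gamma_c` (named
#'   interaction vectors over the effect modifiers).
#' @param infinite_ac If `TRUE` the AC aggregate reports population
#'   (not sample) covariate and outcome summaries, for sharp oracle
#'   checks.
#' @return A `pa_scenario` object.
#' @export
scenario_config <- function(n_ab = 500L, n_ac = 500L,
                            covariates = list(list(
                              name = "x1", kind = "continuous",
                              role = "both",
                              mean_ab = 0.2, mean_ac = 0.6, sd = 1)),
                            correlation = NULL,
                            outcome = list(type = "continuous",
                                           scale = "identity",
                                           sd_resid = 1),
                            truth = list(beta0 = 0, beta1 = c(x1 = 1),
                                         d_ab0 = 1, d_ac0 = 0.5,
                                         gamma_b = c(x1 = 1),
                                         gamma_c = c(x1 = 0)),
                            infinite_ac = FALSE) {
  nms <- vapply(covariates, `[[`, "", "name")
  stopifnot(!anyDuplicated(nms))
  if (is.null(correlation)) {
    correlation <- diag(length(nms))
    dimnames(correlation) <- list(nms, nms)
  }
  validate_correlation(correlation)
  outcome$scale <- as_pa_scale(outcome$scale %||% "identity")$name
  ems <- nms[vapply(covariates, function(cv)
    (cv$role %||% "prognostic") %in% c("effect_modifier", "both"), TRUE)]
  truth$gamma_b <- expand_named(truth$gamma_b, ems)
  truth$gamma_c <- expand_named(truth$gamma_c, ems)
  truth$beta1 <- expand_named(truth$beta1, nms)
  dead <- ems[truth$gamma_b[ems] == 0 & truth$gamma_c[ems] == 0]
  if (length(dead)) {
    warning("declared effect modifier(s) with zero interaction for every ",
            "treatment: ", paste(dead, collapse = ", "), call. = FALSE)
  }
  structure(
    list(n_ab = n_ab, n_ac = n_ac, covariates = covariates,
         covariate_names = nms, em_names = ems,
         correlation = correlation, outcome = outcome, truth = truth,
         infinite_ac = infinite_ac),
    class = "pa_scenario"
  )
}

expand_named <- function(x, nms) {
  out <- stats::setNames(rep(0, length(nms)), nms)
  if (length(x)) {
    if (is.null(names(x))) {
      stopifnot(length(x) == length(nms))
      out[] <- x
    } else {
      out[intersect(names(x), nms)] <- x[intersect(names(x), nms)]
    }
  }
  out
}

scenario_spec <- function(cfg) {
  lapply(cfg$covariates, function(cv) {
    covariate_spec(cv$name, kind = cv$kind %||% "continuous",
                   role = cv$role %||% "prognostic",
                   match_moments = cv$match_moments %||% "mean_only")
  })
}

scenario_dist <- function(cfg, population) {
  marg <- lapply(cfg$covariates, function(cv) {
    m <- switch(population,
                AB = cv$mean_ab, AC = cv$mean_ac,
                P = cv$mean_p %||% cv$mean_ac)
    covariate_summary(cv$name, mean = m,
                      sd = if ((cv$kind %||% "continuous") == "continuous")
                        cv$sd else NULL)
  })
  covariate_distribution(marg, scenario_spec(cfg),
                         correlation = cfg$correlation)
}

scenario_eta <- function(cfg, X, arm) {
  tr <- cfg$truth
  eta <- tr$beta0 + drop(X[, names(tr$beta1), drop = FALSE] %*% tr$beta1)
  Xem <- X[, cfg$em_names, drop = FALSE]
  if (arm == "B") {
    eta <- eta + tr$d_ab0 + drop(Xem %*% tr$gamma_b[cfg$em_names])
  } else if (arm == "C") {
    eta <- eta + tr$d_ac0 + drop(Xem %*% tr$gamma_c[cfg$em_names])
  }
  eta
}

scenario_outcome <- function(cfg, eta) {
  scale <- pa_scale(cfg$outcome$scale)
  if (cfg$outcome$type == "binary") {
    p <- scale$g_inv(eta)
    stats::rbinom(length(eta), 1L, p)
  } else {
    eta + stats::rnorm(length(eta), 0, cfg$outcome$sd_resid %||% 1)
  }
}

#' Generate one replicate of a scenario
#'
#' Draws the AB IPD trial, the AC trial at patient level (retained only
#' for oracle checks), and the AC aggregate summaries a publication would
#' report. With `infinite_ac = TRUE` in the scenario, the aggregate
#' reports population values instead of sample summaries.
#'
#' @param cfg A [scenario_config()].
#' @param seed Integer seed.
#' @return List with `ab` (`pa_ipd`), `ac_full` (`pa_ipd`), `aggregate`
#'   (`pa_aggregate`), `truth` ([true_effects()] for the AC population),
#'   and `spec`.
#' @export
generate_scenario <- function(cfg, seed) {
  stopifnot(inherits(cfg, "pa_scenario"))
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  spec <- scenario_spec(cfg)

  draw_trial <- function(n_per_arm, population, arms, trial_id) {
    dist <- scenario_dist(cfg, population)
    X <- draw_covariates(dist, 2L * n_per_arm)
    arm <- rep(arms, each = n_per_arm)
    eta <- numeric(2L * n_per_arm)
    for (a in arms) {
      idx <- arm == a
      eta[idx] <- scenario_eta(cfg, X[idx, , drop = FALSE], a)
    }
    y <- scenario_outcome(cfg, eta)
    df <- data.frame(arm = arm, outcome = y)
    df <- cbind(df, as.data.frame(X))
    ipd_trial(df, spec, trial_id = trial_id,
              outcome_type = cfg$outcome$type)
  }

  ab <- draw_trial(cfg$n_ab, "AB", c("A", "B"), "AB")
  ac_full <- draw_trial(cfg$n_ac, "AC", c("A", "C"), "AC")

  if (cfg$infinite_ac) {
    tr_ac <- true_effects(cfg, "AC")
    covs <- lapply(cfg$covariates, function(cv) {
      covariate_summary(cv$name, mean = cv$mean_ac,
                        sd = if ((cv$kind %||% "continuous") == "continuous")
                          cv$sd else NULL)
    })
    arms <- list(
      arm_summary("A", n = cfg$n_ac, ybar = tr_ac$mu["A"],
                  se_ybar = 1e-8),
      arm_summary("C", n = cfg$n_ac, ybar = tr_ac$mu["C"],
                  se_ybar = 1e-8)
    )
    aggregate <- aggregate_trial(arms, covs, trial_id = "AC",
                                 outcome_type = cfg$outcome$type,
                                 spec = spec)
  } else {
    s <- summarize_ipd(ac_full)
    aggregate <- aggregate_trial(s$arm_summaries, s$covariate_summaries,
                                 trial_id = "AC",
                                 outcome_type = cfg$outcome$type,
                                 spec = spec)
  }

  list(ab = ab, ac_full = ac_full, aggregate = aggregate,
       truth = true_effects(cfg, "AC"), spec = spec)
}

#' Analytic or Monte-Carlo truths for a scenario population
#'
#' On the identity scale the population-average relative effects are
#' linear in the effect-modifier means:
#' `d_AB(pop) = d_ab0 + gamma_b' E[X_EM | pop]`, and similarly for C.
#' On non-identity scales the marginal contrast of arm-average outcomes
#' is not linear in the covariates, so truths are computed by Monte-Carlo
#' integration: average `g_inv(eta_t(X))` over `n_mc` covariate draws
#' from the population, then difference on the link scale. The MC error
#' of each truth is reported.
#'
#' @param cfg A [scenario_config()].
#' @param population `"AB"`, `"AC"`, or `"P"`.
#' @param n_mc Draws for the MC integration (non-identity scales).
#' @param seed Seed for the MC integration.
#' @return List with `d_ab`, `d_ac`, `d_bc` (satisfying
#'   `d_bc = d_ac - d_ab`), `mu` (per-arm population mean outcomes),
#'   `population`, and `mc_error`.
#' @export
true_effects <- function(cfg, population = "AC", n_mc = 1e6, seed = 90210) {
  stopifnot(inherits(cfg, "pa_scenario"))
  if (!population %in% c("AB", "AC", "P")) {
    stop("unknown population label: ", population, call. = FALSE)
  }
  tr <- cfg$truth
  scale <- pa_scale(cfg$outcome$scale)
  em_mean <- vapply(cfg$covariates, function(cv) {
    switch(population, AB = cv$mean_ab, AC = cv$mean_ac,
           P = cv$mean_p %||% cv$mean_ac)
  }, 0)
  names(em_mean) <- cfg$covariate_names

  if (scale$name == "identity" && cfg$outcome$type == "continuous") {
    d_ab <- tr$d_ab0 + sum(tr$gamma_b[cfg$em_names] * em_mean[cfg$em_names])
    d_ac <- tr$d_ac0 + sum(tr$gamma_c[cfg$em_names] * em_mean[cfg$em_names])
    mu_A <- tr$beta0 + sum(tr$beta1 * em_mean[names(tr$beta1)])
    mu <- c(A = mu_A, B = mu_A + d_ab, C = mu_A + d_ac)
    mc_error <- 0
  } else {
    old <- withr_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    X <- draw_covariates(scenario_dist(cfg, population), n_mc)
    mu_draws <- lapply(c(A = "A", B = "B", C = "C"), function(a) {
      scale$g_inv(scenario_eta(cfg, X, a))
    })
    mu <- vapply(mu_draws, mean, 0)
    mc_error <- max(vapply(mu_draws, stats::sd, 0)) / sqrt(n_mc)
    d_ab <- scale$g(mu[["B"]]) - scale$g(mu[["A"]])
    d_ac <- scale$g(mu[["C"]]) - scale$g(mu[["A"]])
  }
  list(d_ab = unname(d_ab), d_ac = unname(d_ac),
       d_bc = unname(d_ac - d_ab), mu = mu,
       population = population, mc_error = mc_error)
}

#' Replicate a scenario and summarize estimator performance
#'
#' Runs `n_reps` independent replicates of a scenario, applies each
#' requested method to every replicate, and reports mean bias (with its
#' Monte-Carlo error), empirical SE, mean reported SE, 95% CI coverage,
#' mean ESS (weighting methods), and failure counts, all against the
#' analytic/MC truth for the stated target population.
#'
#' Available methods: `"bucher"`, `"maic"`, `"maic_entropy"`,
#' `"stc_plugin"`, `"stc_simulate"`, and unanchored variants
#' `"maic_unanchored"`, `"stc_unanchored"` (these assume a disconnected
#' network within the replicate). Unanchored variants accept a
#' `selection` through `unanchored_selection` to study omitted-variable
#' bias.
#'
#' @param cfg A [scenario_config()].
#' @param methods Character vector of method names.
#' @param n_reps Number of replicates (minimum 100).
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param target_population Population whose truth the estimates are
#'   compared against (`"AC"` default, `"P"` for transport studies).
#' @param n_draws Covariate draws for `"stc_simulate"`.
#' @param unanchored_selection Covariates matched/included by the
#'   unanchored variants (default `"all"`).
#' @return A `pa_simreport`: `summary` data frame (one row per method),
#'   `estimates` matrix, `truth`, `n_reps`, `seed`.
#' @export
run_study <- function(cfg, methods = c("bucher", "maic", "stc_plugin"),
                      n_reps = 1000L, seed = 1L,
                      target_population = "AC",
                      n_draws = 1e4,
                      unanchored_selection = "all") {
  stopifnot(inherits(cfg, "pa_scenario"))
  if (n_reps < 100L) stop("n_reps must be at least 100", call. = FALSE)
  truth <- true_effects(cfg, target_population)
  d_true <- truth$d_bc

  old <- withr_seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  restore_seed(old)

  est <- matrix(NA_real_, n_reps, length(methods),
                dimnames = list(NULL, methods))
  ses <- est
  cover <- est
  ess <- est

  for (r in seq_len(n_reps)) {
    gen <- generate_scenario(cfg, rep_seeds[r])
    for (m in methods) {
      res <- tryCatch(
        run_one_method(m, gen, cfg, seed = rep_seeds[r],
                       n_draws = n_draws,
                       unanchored_selection = unanchored_selection),
        error = function(e) NULL)
      if (is.null(res)) next
      est[r, m] <- res$estimate
      ses[r, m] <- res$se
      cover[r, m] <- as.numeric(res$ci95[1L] <= d_true &
                                d_true <= res$ci95[2L])
      ess[r, m] <- res$ess %||% NA_real_
    }
  }

  summ <- do.call(rbind, lapply(methods, function(m) {
    e <- est[, m]
    ok <- is.finite(e)
    emp_se <- stats::sd(e[ok])
    data.frame(
      method = m,
      bias = mean(e[ok]) - d_true,
      bias_mc_error = emp_se / sqrt(sum(ok)),
      empirical_se = emp_se,
      mean_reported_se = mean(ses[ok, m]),
      coverage = mean(cover[ok, m]),
      mean_ess = mean(ess[ok, m]),
      n_fail = sum(!ok),
      stringsAsFactors = FALSE
    )
  }))
  n_fail_max <- max(summ$n_fail)
  if (n_fail_max > 0.1 * n_reps) {
    warning("a method failed in more than 10% of replicates",
            call. = FALSE)
  }
  structure(
    list(summary = summ, estimates = est, reported_se = ses,
         coverage = cover, truth = truth, n_reps = n_reps, seed = seed,
         target_population = target_population),
    class = "pa_simreport"
  )
}

run_one_method <- function(method, gen, cfg, seed, n_draws = 1e4,
                           unanchored_selection = "all") {
  scale <- cfg$outcome$scale
  switch(method,
    bucher = bucher_analysis(gen$ab, gen$aggregate, scale),
    maic = maic_analysis(gen$ab, gen$aggregate, gen$spec, scale,
                         anchored = TRUE),
    maic_entropy = maic_analysis(gen$ab, gen$aggregate, gen$spec, scale,
                                 anchored = TRUE, method = "entropy"),
    stc_plugin = stc_analysis(gen$ab, gen$aggregate, gen$spec, scale,
                              anchored = TRUE, prediction = "plugin"),
    stc_simulate = stc_analysis(gen$ab, gen$aggregate, gen$spec, scale,
                                anchored = TRUE, prediction = "simulate",
                                n_draws = n_draws,
                                seed = (seed + 1L) %% .Machine$integer.max),
    maic_unanchored = maic_analysis(gen$ab, gen$aggregate, gen$spec, scale,
                                    anchored = FALSE,
                                    anchored_available = FALSE,
                                    selection = unanchored_selection),
    stc_unanchored = stc_analysis(gen$ab, gen$aggregate,
                                  subset_spec(gen$spec,
                                              unanchored_selection),
                                  scale,
                                  anchored = FALSE,
                                  anchored_available = FALSE,
                                  prediction = "plugin"),
    stop("unknown method: ", method, call. = FALSE)
  )
}

subset_spec <- function(spec, selection) {
  spec <- as_covariate_list(spec)
  if (identical(selection, "all")) return(spec)
  keep <- if (identical(selection, "effect_modifiers")) {
    em_names(spec)
  } else {
    selection
  }
  as_covariate_list(spec[keep])
}

#' @export
print.pa_simreport <- function(x, ...) {
  cat(sprintf(
    "Simulation study: %d replicates, truth d_BC(%s) = %.4f\n",
    x$n_reps, x$target_population, x$truth$d_bc))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
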