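#' Declare covariates and their roles
#'
#' Covariate roles must be declared a priori (from clinical knowledge or a
#' review of the subject area), never inferred from the data at hand. An
#' effect modifier changes the relative treatment effect on the chosen
#' linear predictor scale; a prognostic variable shifts the outcome level
#' regardless of treatment; `"both"` marks a variable playing both roles.
#'
#' @param name Covariate name (must match the IPD column after mapping).
#' @param kind `"continuous"` or `"binary"`. Binary covariates must be
#'   coded 0/1.
#' @param role `"effect_modifier"`, `"prognostic"`, or `"both"`.
#' @param match_moments For continuous covariates, `"mean_only"` or
#'   `"mean_and_variance"` (the latter also balances the second moment in
#'   MAIC). Binary covariates are always `"mean_only"`.
#' @return A `pa_covariate` object; combine several into a list to form a
#'   covariate specification.
#' @export
covariate_spec <- function(name,
                           kind = c("continuous", "binary"),
                           role = c("effect_modifier", "prognostic", "both"),
                           match_moments = c("mean_only", "mean_and_variance")) {
  kind <- match.arg(kind)
  role <- match.arg(role)
  match_moments <- match.arg(match_moments)
  if (kind == "binary" && match_moments != "mean_only") {
    stop("binary covariates always use match_moments = 'mean_only'",
         call. = FALSE)
  }
  structure(
    list(name = name, kind = kind, role = role,
         match_moments = match_moments),
    class = "pa_covariate"
  )
}

as_covariate_list <- function(spec) {
  if (inherits(spec, "pa_covariate")) spec <- list(spec)
  stopifnot(is.list(spec), all(vapply(spec, inherits, TRUE, "pa_covariate")))
  names(spec) <- vapply(spec, `[[`, "", "name")
  spec
}

spec_names <- function(spec, roles = NULL) {
  spec <- as_covariate_list(spec)
  if (!is.null(roles)) {
    spec <- Filter(function(s) s$role %in% roles, spec)
  }
  vapply(spec, `[[`, "", "name")
}

em_names <- function(spec) spec_names(spec, c("effect_modifier", "both"))
prognostic_names <- function(spec) spec_names(spec, c("prognostic", "both"))

#' Construct an IPD trial object
#'
#' Holds patient-level data for the AB trial: one row per patient with an
#' arm label, an outcome, and the declared covariates. Exactly two arms are
#' required; binary covariates and binary outcomes must be coded 0/1; rows
#' with missing values are not allowed (drop them at load time with
#' [load_ipd()]).
#'
#' @param data Data frame with columns `arm`, `outcome`, and one column per
#'   declared covariate.
#' @param spec List of [covariate_spec()] objects.
#' @param trial_id Label for the trial (default `"AB"`).
#' @param outcome_type `"continuous"` or `"binary"`.
#' @return An object of class `pa_ipd`.
#' @export
ipd_trial <- function(data, spec, trial_id = "AB",
                      outcome_type = c("continuous", "binary")) {
  outcome_type <- match.arg(outcome_type)
  spec <- as_covariate_list(spec)
  needed <- c("arm", "outcome", spec_names(spec))
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("IPD is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(data)[, needed, drop = FALSE]
  if (anyNA(data)) {
    stop("IPD contains missing values; use load_ipd() for complete-case ",
         "filtering", call. = FALSE)
  }
  data$arm <- as.character(data$arm)
  arms <- sort(unique(data$arm))
  if (length(arms) != 2L) {
    stop("the IPD trial must have exactly two arms, found: ",
         paste(arms, collapse = ", "), call. = FALSE)
  }
  if (any(table(data$arm) == 0L)) stop("empty arm in IPD", call. = FALSE)
  if (outcome_type == "binary" && !all(data$outcome %in% c(0, 1))) {
    stop("binary outcomes must be coded exactly 0/1", call. = FALSE)
  }
  for (s in spec) {
    if (s$kind == "binary" && !all(data[[s$name]] %in% c(0, 1))) {
      stop(sprintf("binary covariate '%s' has values outside {0,1}", s$name),
           call. = FALSE)
    }
  }
  structure(
    list(trial_id = trial_id, arms = arms, data = data, spec = spec,
         outcome_type = outcome_type),
    class = "pa_ipd"
  )
}

#' Load IPD from a delimited file
#'
#' Reads a CSV of patient-level data, renames columns according to
#' `mapping`, drops incomplete rows (complete-case analysis; the count of
#' dropped rows is reported as a warning and logged to stderr), and
#' validates the result.
#'
#' @param path Path to a CSV file with a header row.
#' @param spec List of [covariate_spec()] objects.
#' @param mapping Named list/character vector mapping the canonical names
#'   (`arm`, `outcome`, covariate names) to column names in the file.
#'   Names absent from the mapping are assumed to match directly.
#' @param trial_id,outcome_type Passed to [ipd_trial()].
#' @param arms Optional character vector of allowed arm labels; any other
#'   label is an error naming the offending label.
#' @return A `pa_ipd` object.
#' @export
load_ipd <- function(path, spec, mapping = list(), trial_id = "AB",
                     outcome_type = c("continuous", "binary"),
                     arms = NULL) {
  outcome_type <- match.arg(outcome_type)
  if (!file.exists(path)) stop("IPD file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  spec <- as_covariate_list(spec)
  canonical <- c("arm", "outcome", spec_names(spec))
  mapping <- unlist(mapping)
  cols <- ifelse(canonical %in% names(mapping), mapping[canonical], canonical)
  absent <- setdiff(cols, names(raw))
  if (length(absent)) {
    stop("mapped column(s) not present in ", path, ": ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  df <- raw[, cols, drop = FALSE]
  names(df) <- canonical
  keep <- stats::complete.cases(df)
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    msg <- sprintf("%d row%s dropped (missing values)", n_drop,
                   if (n_drop == 1L) "" else "s")
    pa_log(msg)
    warning(msg, call. = FALSE)
  }
  df <- df[keep, , drop = FALSE]
  if (!is.null(arms)) {
    bad <- setdiff(unique(as.character(df$arm)), arms)
    if (length(bad)) {
      stop("unknown arm label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  ipd_trial(df, spec, trial_id = trial_id, outcome_type = outcome_type)
}

#' Per-arm summary outcome
#'
#' @param arm Treatment label.
#' @param n Sample size (or effective sample size for weighted estimates).
#' @param ybar Summary absolute outcome (mean, or proportion for binary).
#' @param se_ybar Standard error of `ybar`. For binary outcomes it may be
#'   omitted when an event count `r` is given; it is then derived as
#'   `sqrt(ybar (1 - ybar) / n)`.
#' @param r Event count for binary outcomes (optional).
#' @return An `pa_arm_summary` object.
#' @export
arm_summary <- function(arm, n, ybar = NULL, se_ybar = NULL, r = NULL) {
  if (n < 1) stop("arm sample size must be >= 1", call. = FALSE)
  if (is.null(ybar)) {
    if (is.null(r)) stop("supply ybar or an event count r", call. = FALSE)
    ybar <- r / n
  } else if (!is.null(r)) {
    if (abs(r - round(ybar * n)) > 0.5 + 1e-8) {
      stop(sprintf("event count r=%g inconsistent with ybar=%g, n=%g",
                   r, ybar, n), call. = FALSE)
    }
  }
  if (!is.null(r) || (!is.null(ybar) && is.null(se_ybar))) {
    if (ybar < 0 || ybar > 1) {
      stop("binary summary outcome must satisfy 0 <= ybar <= 1",
           call. = FALSE)
    }
    if (is.null(se_ybar)) se_ybar <- sqrt(ybar * (1 - ybar) / n)
  }
  structure(list(arm = arm, n = n, ybar = ybar, se_ybar = se_ybar, r = r),
            class = "pa_arm_summary")
}

#' Per-covariate summary (published marginals)
#'
#' @param name Covariate name.
#' @param mean Published mean (proportion for a binary covariate).
#' @param sd Published standard deviation (continuous covariates only;
#'   required when the covariate is matched on mean and variance).
#' @return A `pa_cov_summary` object.
#' @export
covariate_summary <- function(name, mean, sd = NULL) {
  if (!is.null(sd)) {
    if (!is.finite(sd) || sd <= 0) {
      stop(sprintf("sd must be positive for covariate '%s'", name),
           call. = FALSE)
    }
  }
  structure(list(name = name, mean = mean, sd = sd),
            class = "pa_cov_summary")
}

as_cov_summary_list <- function(x) {
  if (inherits(x, "pa_cov_summary")) x <- list(x)
  stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "pa_cov_summary")))
  names(x) <- vapply(x, `[[`, "", "name")
  x
}

#' Aggregate (published) trial data
#'
#' Holds what a publication typically reports for the AC trial: per-arm
#' sample sizes and summary outcomes, plus trial-level covariate summaries
#' shared across arms.
#'
#' @param arm_summaries List of [arm_summary()] objects (arms A and C).
#' @param covariate_summaries List of [covariate_summary()] objects.
#' @param trial_id Label (default `"AC"`).
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param spec Optional covariate specification; when given, covariate
#'   summary names must be a subset of the declared covariates.
#' @return An object of class `pa_aggregate`.
#' @export
aggregate_trial <- function(arm_summaries, covariate_summaries,
                            trial_id = "AC",
                            outcome_type = c("continuous", "binary"),
                            spec = NULL) {
  outcome_type <- match.arg(outcome_type)
  stopifnot(all(vapply(arm_summaries, inherits, TRUE, "pa_arm_summary")))
  names(arm_summaries) <- vapply(arm_summaries, `[[`, "", "arm")
  covariate_summaries <- as_cov_summary_list(covariate_summaries)
  if (!is.null(spec)) {
    unknown <- setdiff(names(covariate_summaries), spec_names(spec))
    if (length(unknown)) {
      stop("aggregate covariate(s) not in the declared specification: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(trial_id = trial_id, arm_summaries = arm_summaries,
         covariate_summaries = covariate_summaries,
         outcome_type = outcome_type),
    class = "pa_aggregate"
  )
}

#' Load aggregate trial data from a YAML config
#'
#' The config supplies, per arm, `n` and either `ybar` (+ `se`) or a
#' binary event count `r`; and per covariate, `mean` (+ `sd` for
#' continuous). For binary outcomes given as counts, the standard error is
#' derived as `sqrt(ybar (1 - ybar) / n)`.
#'
#' @param config Path to a YAML file, or an equivalent nested list with
#'   elements `trial_id`, `outcome_type`, `arms` (named list of
#'   `{n, ybar|r, se}`), and `covariates` (named list of `{mean, sd}`).
#' @param spec Optional covariate specification used to validate names and
#'   to require `sd` for covariates matched on mean and variance.
#' @return A `pa_aggregate` object.
#' @export
load_aggregate <- function(config, spec = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("aggregate config not found: ", config, call. = FALSE)
    }
    config <- read_yaml_config(config)
  }
  stopifnot(is.list(config), !is.null(config$arms))
  outcome_type <- config$outcome_type %||% "continuous"
  arms <- lapply(names(config$arms), function(a) {
    x <- config$arms[[a]]
    if (!is.null(x$r)) {
      arm_summary(a, n = x$n, r = x$r)
    } else {
      if (!is.null(x$ybar) && outcome_type == "binary" &&
          (x$ybar < 0 || x$ybar > 1)) {
        stop(sprintf("proportion outside [0,1] for arm '%s'", a),
             call. = FALSE)
      }
      arm_summary(a, n = x$n, ybar = x$ybar, se_ybar = x$se)
    }
  })
  covs <- lapply(names(config$covariates %||% list()), function(nm) {
    x <- config$covariates[[nm]]
    pa_log(sprintf("aggregate covariate '%s': mean=%g%s", nm, x$mean,
                   if (is.null(x$sd)) "" else sprintf(", sd=%g", x$sd)))
    covariate_summary(nm, mean = x$mean, sd = x$sd)
  })
  if (!is.null(spec)) {
    spec <- as_covariate_list(spec)
    for (s in spec) {
      if (s$kind == "continuous" && s$match_moments == "mean_and_variance") {
        cs <- Filter(function(cv) cv$name == s$name, covs)
        if (length(cs) && is.null(cs[[1L]]$sd)) {
          stop(sprintf(paste(
            "covariate '%s' is matched on mean and variance",
            "but the config supplies no sd"), s$name), call. = FALSE)
        }
      }
    }
  }
  aggregate_trial(arms, covs, trial_id = config$trial_id %||% "AC",
                  outcome_type = outcome_type, spec = spec)
}

#' Read a YAML config without YAML-1.1 boolean surprises
#'
#' Plain YAML treats the bare scalars `y`/`n` (and `yes`/`no`) as
#' booleans, which silently corrupts configs using `n:` for sample sizes
#' or `y` as a column name. This reader keeps single-letter `y`/`n`
#' tokens as strings while still parsing `true`/`false`/`yes`/`no` as
#' logicals.
#'
#' @param path Path to a YAML file.
#' @return The parsed list.
#' @export
read_yaml_config <- function(path) {
  handlers <- list(
    "bool#yes" = function(x) if (x %in% c("y", "Y")) x else TRUE,
    "bool#no" = function(x) if (x %in% c("n", "N")) x else FALSE
  )
  yaml::yaml.load_file(path, handlers = handlers)
}

#' Target population for decision making
#'
#' The population for which the comparison is produced must always be
#' explicit. A target population carries covariate summaries and,
#' optionally, the baseline absolute outcome on the common comparator A
#' (required before absolute effects can be back-calculated).
#'
#' @param label Population label (e.g. `"AC"`, `"registry-P"`).
#' @param covariate_summaries List of [covariate_summary()] objects.
#' @param baseline_A Optional [arm_summary()] giving the absolute outcome
#'   on treatment A in this population.
#' @return A `pa_target` object.
#' @export
target_population <- function(label, covariate_summaries = list(),
                              baseline_A = NULL) {
  if (!is.null(baseline_A)) {
    stopifnot(inherits(baseline_A, "pa_arm_summary"))
  }
  structure(
    list(label = label,
         covariate_summaries = as_cov_summary_list(covariate_summaries),
         baseline_A = baseline_A),
    class = "pa_target"
  )
}

#' Summarize an IPD trial in publication form
#'
#' Computes pooled-across-arms covariate summaries (sample SD with
#' denominator n-1, the publication convention) and per-arm outcome
#' summaries, mirroring what an aggregate-data trial would report.
#'
#' @param trial A `pa_ipd` object.
#' @return List with `covariate_summaries` and `arm_summaries`.
#' @export
summarize_ipd <- function(trial) {
  stopifnot(inherits(trial, "pa_ipd"))
  covs <- lapply(trial$spec, function(s) {
    x <- trial$data[[s$name]]
    covariate_summary(s$name, mean = mean(x),
                      sd = if (s$kind == "continuous") stats::sd(x) else NULL)
  })
  arms <- lapply(trial$arms, function(a) {
    y <- trial$data$outcome[trial$data$arm == a]
    n <- length(y)
    if (trial$outcome_type == "binary") {
      arm_summary(a, n = n, r = sum(y))
    } else {
      arm_summary(a, n = n, ybar = mean(y),
                  se_ybar = stats::sd(y) / sqrt(n))
    }
  })
  names(arms) <- trial$arms
  list(covariate_summaries = as_cov_summary_list(covs),
       arm_summaries = arms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pa_log <- function(msg, level = "INFO") {
  message(sprintf("[popadjust %s] %s", level, msg))
}

#' @export
print.pa_ipd <- function(x, ...) {
  cat(sprintf("<pa_ipd '%s'> %d patients, arms: %s, outcome: %s\n",
              x$trial_id, nrow(x$data), paste(x$arms, collapse = "/"),
              x$outcome_type))
  invisible(x)
}

#' @export
print.pa_aggregate <- function(x, ...) {
  cat(sprintf("<pa_aggregate '%s'> arms: %s\n", x$trial_id,
              paste(names(x$arm_summaries), collapse = "/")))
  for (a in x$arm_summaries) {
    cat(sprintf("  %s: n=%g ybar=%.4g se=%.4g\n", a$arm, a$n, a$ybar,
                a$se_ybar %||% NA_real_))
  }
  invisible(x)
}
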