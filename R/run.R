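#' Run a complete analysis from a YAML config
#'
#' One auditable config per analysis: it names the IPD file and its
#' column mapping, the aggregate-data config, the covariate roles, the
#' scale, the method, anchoring, the variance method, and seeds. The
#' config (not command-line flags) is the specification of record, so a
#' submission can be re-run exactly.
#'
#' Config schema (YAML):
#' \preformatted{
#' method: maic            # maic | maic_entropy | stc | bucher
#' anchored: true
#' connected_network: true # refuses anchored=false while true
#' scale: identity
#' ipd:
#'   path: ab.csv
#'   outcome_type: continuous
#'   mapping: {arm: treat, outcome: y}
#' aggregate: ac.yaml      # or an inline mapping with arms/covariates
#' covariates:
#'   - {name: x1, kind: continuous, role: both,
#'      match_moments: mean_only}
#' prediction: plugin      # stc only: plugin | simulate
#' n_draws: 100000
#' variance: sandwich      # sandwich | bootstrap | fixed
#' n_boot: 1000
#' seed: 42
#' }
#'
#' @param config Path to a YAML file or an equivalent nested list.
#' @param out_dir Output directory; when non-`NULL`, writes
#'   `results.json`, `balance.csv` (pre/post-weighting covariate means
#'   vs targets, weighting methods), `weights.csv`, and
#'   `assumptions.txt`.
#' @return The `pa_comparison` result, invisibly when writing files.
#' @export
run_analysis <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    base_dir <- dirname(config)
    config <- read_yaml_config(config)
  } else {
    base_dir <- "."
  }
  cfg_require(config, "method")
  method <- config$method
  anchored <- config$anchored %||% TRUE
  connected <- config$connected_network %||% TRUE
  if (!anchored && connected) {
    stop(paste(
      "config error at 'anchored'/'connected_network': an unanchored",
      "analysis may only be requested when the network is disconnected",
      "or single-arm"), call. = FALSE)
  }
  scale <- as_pa_scale(config$scale %||% "identity")
  seed <- config$seed %||% 1L

  spec <- lapply(config$covariates %||% list(), function(cv) {
    covariate_spec(cv$name, kind = cv$kind %||% "continuous",
                   role = cv$role %||% "prognostic",
                   match_moments = cv$match_moments %||% "mean_only")
  })
  if (!length(spec)) {
    stop("config error at 'covariates': at least one covariate must be ",
         "declared with its role", call. = FALSE)
  }

  cfg_require(config, "ipd")
  ipd_path <- config$ipd$path
  if (!is.null(ipd_path) && !file.exists(ipd_path)) {
    ipd_path2 <- file.path(base_dir, config$ipd$path)
    if (file.exists(ipd_path2)) ipd_path <- ipd_path2
  }
  trial <- load_ipd(ipd_path, spec,
                    mapping = config$ipd$mapping %||% list(),
                    outcome_type = config$ipd$outcome_type %||% "continuous",
                    arms = config$ipd$arms)

  cfg_require(config, "aggregate")
  agg_cfg <- config$aggregate
  if (is.character(agg_cfg) && !file.exists(agg_cfg)) {
    agg2 <- file.path(base_dir, agg_cfg)
    if (file.exists(agg2)) agg_cfg <- agg2
  }
  aggregate <- load_aggregate(agg_cfg, spec)

  variance <- config$variance %||% "sandwich"
  res <- switch(method,
    bucher = bucher_analysis(trial, aggregate, scale),
    maic = ,
    maic_entropy = maic_analysis(
      trial, aggregate, spec, scale, anchored = anchored,
      anchored_available = connected,
      method = if (method == "maic_entropy") "entropy" else "moments",
      variance = if (variance == "sandwich") "sandwich" else "fixed"),
    stc = stc_analysis(
      trial, aggregate, spec, scale, anchored = anchored,
      anchored_available = connected,
      prediction = config$prediction %||% "plugin",
      n_draws = config$n_draws %||% 1e5, seed = seed),
    stop("config error at 'method': unknown method '", method, "'",
         call. = FALSE)
  )

  if (identical(variance, "bootstrap") && method != "bucher") {
    analysis_fn <- function(tr, agg) {
      switch(method,
        maic = ,
        maic_entropy = maic_analysis(
          tr, agg, spec, scale, anchored = anchored,
          anchored_available = connected,
          method = if (method == "maic_entropy") "entropy" else "moments",
          variance = "fixed"),
        stc = stc_analysis(tr, agg, spec, scale, anchored = anchored,
                           anchored_available = connected,
                           prediction = config$prediction %||% "plugin",
                           n_draws = config$n_draws %||% 1e5,
                           seed = seed))
    }
    boot <- bootstrap(analysis_fn, trial, aggregate,
                      n_boot = config$n_boot %||% 1000L, seed = seed)
    res$se <- boot$se_total
    res$ci95 <- boot$ci95_percentile
    attr(res, "variance") <- boot
  }

  if (!is.null(out_dir)) {
    write_results(res, trial, aggregate, out_dir)
    return(invisible(res))
  }
  res
}

cfg_require <- function(config, field) {
  if (is.null(config[[field]])) {
    stop("config error at '", field, "': required field missing",
         call. = FALSE)
  }
}

write_results <- function(res, trial, aggregate, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  nat <- res$scale$g_inv(res$estimate)
  out <- list(
    contrast = paste(res$contrast, collapse = " vs "),
    population = res$population,
    scale = res$scale$name,
    estimate = res$estimate,
    se = res$se,
    ci95 = res$ci95,
    natural_scale_estimates = list(
      estimate = nat,
      ci95 = res$scale$g_inv(res$ci95)
    ),
    anchored = res$anchored,
    method = res$method,
    ess = res$ess,
    warnings = res$warnings
  )
  jsonlite::write_json(out, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  w <- attr(res, "weights")
  if (!is.null(w)) {
    utils::write.csv(
      data.frame(row = seq_along(w$weights), arm = w$arm,
                 weight = w$weights),
      file.path(out_dir, "weights.csv"), row.names = FALSE)
    utils::write.csv(balance_table(trial, aggregate, w),
                     file.path(out_dir, "balance.csv"), row.names = FALSE)
    ws <- weight_summary(w)
    jsonlite::write_json(
      lapply(unclass(ws), function(v) unname(v)),
      file.path(out_dir, "weight_diagnostics.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  writeLines(format_assumptions(res), file.path(out_dir, "assumptions.txt"))
  invisible(out)
}

#' Pre- and post-weighting balance table
#'
#' Compares unweighted and weighted IPD covariate means with the
#' aggregate-trial targets.
#'
#' @param trial A `pa_ipd`.
#' @param aggregate A `pa_aggregate` (or covariate summary list).
#' @param w A `pa_weights`.
#' @return Data frame with columns `covariate`, `ipd_mean`,
#'   `weighted_mean`, `target_mean`.
#' @export
balance_table <- function(trial, aggregate, w) {
  target <- if (inherits(aggregate, "pa_aggregate")) {
    aggregate$covariate_summaries
  } else {
    as_cov_summary_list(aggregate)
  }
  nms <- intersect(spec_names(trial$spec), names(target))
  do.call(rbind, lapply(nms, function(nm) {
    x <- trial$data[[nm]]
    data.frame(
      covariate = nm,
      ipd_mean = mean(x),
      weighted_mean = sum(x * w$weights) / sum(w$weights),
      target_mean = target[[nm]]$mean
    )
  }))
}

format_assumptions <- function(res) {
  c(
    sprintf("Method: %s (%s)", res$method,
            if (res$anchored) "anchored" else "UNANCHORED"),
    sprintf("Contrast: %s vs %s", res$contrast[1L], res$contrast[2L]),
    sprintf("Scale: %s linear predictor", res$scale$name),
    sprintf("Target population: %s", res$population),
    "",
    "Assumption statements and warnings:",
    paste(" -", res$warnings)
  )
}
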