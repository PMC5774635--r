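#' Link scales for relative treatment effects
#'
#' Population-adjusted indirect comparisons are formed on a linear predictor
#' scale: treatment effects are assumed additive after transforming summary
#' outcomes with a link function g. A `pa_scale` object bundles the link
#' `g`, its inverse `g_inv`, and its derivative `dg` (used for delta-method
#' standard errors).
#'
#' Three scales are supported: `"identity"` (mean difference, or risk
#' difference when the outcome is binary), `"log"` (log relative risk),
#' and `"logit"` (log odds ratio).
#'
#' @param name One of `"identity"`, `"log"`, `"logit"`.
#' @return An object of class `pa_scale` with elements `name`, `g`,
#'   `g_inv`, and `dg`.
#' @examples
#' sc <- pa_scale("logit")
#' sc$g(0.5)        # 0
#' sc$g_inv(0)      # 0.5
#' @export
pa_scale <- function(name = c("identity", "log", "logit")) {
  name <- match.arg(name)
  obj <- switch(name,
    identity = list(
      name = "identity",
      g = function(y) y,
      g_inv = function(eta) eta,
      dg = function(y) rep_len(1, length(y))
    ),
    log = list(
      name = "log",
      g = function(y) {
        check_scale_domain("log", y, y > 0, "y > 0")
        log(y)
      },
      g_inv = function(eta) exp(eta),
      dg = function(y) 1 / y
    ),
    logit = list(
      name = "logit",
      g = function(y) {
        check_scale_domain("logit", y, y > 0 & y < 1, "0 < y < 1")
        log(y / (1 - y))
      },
      g_inv = function(eta) 1 / (1 + exp(-eta)),
      dg = function(y) 1 / (y * (1 - y))
    )
  )
  structure(obj, class = "pa_scale")
}

check_scale_domain <- function(scale_name, y, ok, domain) {
  bad <- !ok & !is.na(y)
  if (any(bad)) {
    stop(sprintf(
      "value %g outside the domain of the %s scale (requires %s)",
      y[which(bad)[1L]], scale_name, domain
    ), call. = FALSE)
  }
  invisible(TRUE)
}

as_pa_scale <- function(scale) {
  if (inherits(scale, "pa_scale")) return(scale)
  if (is.character(scale) && length(scale) == 1L) return(pa_scale(scale))
  stop("`scale` must be a pa_scale object or a scale name", call. = FALSE)
}

#' Apply a link function or its inverse
#'
#' @param scale A [pa_scale()] object or scale name.
#' @param y Outcome value(s) on the natural scale (for `link`).
#' @param eta Value(s) on the linear predictor scale (for `link_inv`).
#' @return Transformed numeric vector.
#' @export
link <- function(scale, y) as_pa_scale(scale)$g(y)

#' @rdname link
#' @export
link_inv <- function(scale, eta) as_pa_scale(scale)$g_inv(eta)

#' @export
print.pa_scale <- function(x, ...) {
  cat("<pa_scale:", x$name, ">\n")
  invisible(x)
}
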