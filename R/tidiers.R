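# broom-style tidiers -----------------------------------------------------

fit_tidy <- function(coef, se, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  stat <- coef / se
  tibble(
    term = names(coef), estimate = unname(coef), std.error = unname(se),
    statistic = unname(stat),
    p.value = unname(2 * stats::pnorm(-abs(stat))),
    conf.low = unname(coef - z * se), conf.high = unname(coef + z * se)
  )
}

#' Tidy a fitted productivity model
#'
#' @param x A `vg_prod_fit`.
#' @param conf.level Confidence level for Wald intervals.
#' @param ... Unused.
#' @return One row per coefficient on the logit scale.
#' @method tidy vg_prod_fit
#' @export
tidy.vg_prod_fit <- function(x, conf.level = 0.95, ...) {
  fit_tidy(x$coef, x$se, conf.level)
}

#' @rdname tidy.vg_prod_fit
#' @method tidy vg_barker_fit
#' @export
tidy.vg_barker_fit <- function(x, conf.level = 0.95, ...) {
  fit_tidy(x$coef, x$se, conf.level)
}

#' @rdname tidy.vg_prod_fit
#' @method tidy rain_evi_fit
#' @export
tidy.rain_evi_fit <- function(x, conf.level = 0.95, ...) {
  out <- fit_tidy(coef(x$fit), x$se, conf.level)
  out$term <- c("(Intercept)", "log(rain_mm)")
  out
}

#' One-line summaries of fitted models
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A one-row tibble with fit statistics (log-likelihood, K,
#'   effective sample size, AICc, convergence).
#' @method glance vg_prod_fit
#' @export
glance.vg_prod_fit <- function(x, ...) {
  tibble(
    model = x$label, logLik = x$logLik, K = x$K, n_eff = x$n_eff,
    AICc = aicc(x$logLik, x$K, x$n_eff), converged = x$converged
  )
}

#' @rdname glance.vg_prod_fit
#' @method glance vg_barker_fit
#' @export
glance.vg_barker_fit <- function(x, ...) {
  tibble(
    model = x$label, logLik = x$logLik, K = x$K, n_eff = x$n_eff,
    AICc = aicc(x$logLik, x$K, x$n_eff), converged = x$converged
  )
}

#' @rdname glance.vg_prod_fit
#' @method glance rain_evi_fit
#' @export
glance.rain_evi_fit <- function(x, ...) {
  tibble(
    slope = x$slope, se = x$se[2], t = x$t, p.value = x$p_value,
    n = x$n, sigma = x$sigma
  )
}
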