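# AICc multimodel inference ----------------------------------------------

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 logLik + 2K + 2K(K + 1) / (n_eff - K - 1)`.
#'
#' @param logLik Maximized log-likelihood.
#' @param K Number of estimated parameters.
#' @param n_eff Effective sample size; must exceed `K + 1`.
#' @return Numeric vector (arguments recycle).
#' @export
aicc <- function(logLik, K, n_eff) {
  if (any(n_eff <= K + 1)) abort("AICc undefined: n_eff must exceed K + 1")
  -2 * logLik + 2 * K + 2 * K * (K + 1) / (n_eff - K - 1)
}

#' Akaike model weights
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = AICc_i - min(AICc)`. Non-finite entries (e.g. non-converged
#' fits) get weight `NA` and are excluded from the normalization, so weights
#' stay a proper distribution over trustworthy models.
#'
#' @param aicc_values Numeric vector of AICc values.
#' @return Numeric vector of weights summing to 1 over finite entries.
#' @export
akaike_weights <- function(aicc_values) {
  ok <- is.finite(aicc_values)
  if (!any(ok)) abort("no finite AICc values")
  delta <- aicc_values - min(aicc_values[ok])
  w <- rep(NA_real_, length(aicc_values))
  ew <- exp(-delta[ok] / 2)
  w[ok] <- ew / sum(ew)
  w
}

#' Rank a set of fitted models by AICc
#'
#' Builds the standard model-selection table shared by the productivity and
#' survival analyses: one row per fit with `K`, `logLik`, `n_eff`, `AICc`,
#' `delta_AICc` and Akaike weight, sorted by AICc. Fits flagged as
#' non-converged (or separated) are listed last with `NA` weight and are
#' excluded from the weight normalization, with a warning naming them.
#'
#' @param fits A list of fitted model objects, each with `label`, `logLik`,
#'   `K`, `n_eff` and `converged` entries (as returned by [fit_binomial()]
#'   and [fit_barker()]).
#' @return A tibble of class `vg_model_table`.
#' @export
model_table <- function(fits) {
  stopifnot(length(fits) >= 1)
  tab <- purrr::map_dfr(fits, function(f) {
    tibble(
      model = f$label, K = f$K, logLik = f$logLik, n_eff = f$n_eff,
      converged = isTRUE(f$converged)
    )
  })
  tab$AICc <- ifelse(tab$converged, aicc(tab$logLik, tab$K, tab$n_eff), NA_real_)
  if (any(!tab$converged)) {
    warn(sprintf(
      "excluded from AICc ranking (not converged): %s",
      paste(tab$model[!tab$converged], collapse = ", ")
    ))
  }
  tab$delta_AICc <- tab$AICc - min(tab$AICc, na.rm = TRUE)
  tab$weight <- akaike_weights(ifelse(is.na(tab$AICc), Inf, tab$AICc))
  tab$weight[!tab$converged] <- NA_real_
  # renormalize over converged fits only (Inf sentinel already gave them ~0)
  tab$weight <- tab$weight / sum(tab$weight, na.rm = TRUE)
  tab <- arrange(tab, !.data$converged, .data$AICc)
  attr(tab, "fits") <- fits
  class(tab) <- c("vg_model_table", class(tab))
  tab
}
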