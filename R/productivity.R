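# Productivity index from age-ratio capture data -------------------------
#
# The productivity index is the proportion of young (hatching-year) birds
# among aged individuals captured in a fixed annual window (11 Apr - 19 Jul),
# modeled as a binomial with a logit-linear predictor in seasonal greenness
# covariates and a prior-effort correction.

window_dates <- function(year, window_start = "04-11", window_end = "07-19") {
  c(
    as.Date(sprintf("%d-%s", year, window_start)),
    as.Date(sprintf("%d-%s", year, window_end))
  )
}

#' Year-unique aged individuals inside the productivity window
#'
#' Keeps captures dated inside the closed annual window, collapses to one
#' record per band per year, and drops individuals of unknown age. An
#' individual aged young at any window capture of a year counts as young for
#' that year (conflicting young/adult ages in one window are a data error and
#' resolve to young with a warning).
#'
#' @param captures Capture records: columns `band_id`, `station`, `date`
#'   (Date or ISO-8601 string), `age` in `{"Y", "A", "U"}`.
#' @param years Calendar years to tally.
#' @param window_start,window_end Month-day strings (`"04-11"`, `"07-19"`).
#' @return Tibble with one row per band-year: `band_id`, `station`, `year`,
#'   `age` in `{"Y", "A"}`.
#' @export
window_filter <- function(captures, years, window_start = "04-11",
                          window_end = "07-19") {
  stopifnot(all(c("band_id", "station", "date", "age") %in% names(captures)))
  dt <- parse_dates(captures$date)
  if (anyNA(dt)) abort("unparseable capture date(s)")
  out <- purrr::map_dfr(as.integer(years), function(yr) {
    w <- window_dates(yr, window_start, window_end)
    rows <- captures[dt >= w[1] & dt <= w[2], , drop = FALSE]
    if (nrow(rows) == 0) return(tibble())
    rows <- rows[rows$age %in% c("Y", "A"), , drop = FALSE]
    rows %>%
      group_by(.data$band_id) %>%
      summarise(
        station = .data$station[1],
        conflict = any(.data$age == "Y") && any(.data$age == "A"),
        age = if (any(.data$age == "Y")) "Y" else "A",
        .groups = "drop"
      ) %>%
      mutate(year = yr)
  })
  if (nrow(out) == 0) {
    return(tibble(
      band_id = character(), station = character(),
      year = integer(), age = character()
    ))
  }
  if (any(out$conflict)) {
    warn(sprintf(
      "%d individual-year(s) aged both young and adult within one window; resolved to young",
      sum(out$conflict)
    ))
  }
  out %>% select("band_id", "station", "year", "age")
}

#' Prior-effort covariate for one station-year
#'
#' `log(1 + summed net-hours)` between the end of the previous year's
#' productivity window and the start of the current year's window (both
#' exclusive), a correction for net avoidance induced by netting before the
#' window. The first study year has no prior window and returns `log(1) = 0`.
#'
#' @param effort Effort records: columns `station`, `date`, `net_hours`.
#' @param station Station code.
#' @param year Calendar year.
#' @param first_year First study year (prior effort defined as 0 there).
#' @inheritParams window_filter
#' @return Length-1 numeric.
#' @export
prior_effort <- function(effort, station, year, first_year,
                         window_start = "04-11", window_end = "07-19") {
  stopifnot(all(c("station", "date", "net_hours") %in% names(effort)))
  if (any(effort$net_hours < 0)) abort("negative net-hours")
  if (year <= first_year) return(0)
  prev_end <- window_dates(year - 1L, window_start, window_end)[2]
  cur_start <- window_dates(year, window_start, window_end)[1]
  dt <- parse_dates(effort$date)
  keep <- effort$station == station & dt > prev_end & dt < cur_start
  log(1 + sum(effort$net_hours[keep]))
}

#' Total within-window netting effort for a year
#'
#' Sums net-hours across stations inside the annual productivity window. When
#' `truncate = TRUE` (the default) the sum is truncated toward zero, the
#' convention used when effort totals are reported as whole net-hours.
#'
#' @param effort Effort records with `net_hours` and either a `date` column
#'   (rows are filtered to the window of `year`) or no `date` column (rows
#'   are taken as already window-scoped and summed as-is).
#' @param year Calendar year; ignored when `effort` has no `date` column.
#' @param truncate Truncate the sum toward zero?
#' @inheritParams window_filter
#' @return Length-1 numeric.
#' @export
total_window_effort <- function(effort, year = NULL, truncate = TRUE,
                                window_start = "04-11", window_end = "07-19") {
  stopifnot("net_hours" %in% names(effort))
  if ("date" %in% names(effort) && !is.null(year)) {
    w <- window_dates(year, window_start, window_end)
    dt <- parse_dates(effort$date)
    effort <- effort[dt >= w[1] & dt <= w[2], , drop = FALSE]
  }
  total <- sum(effort$net_hours)
  if (truncate) trunc(total) else total
}

#' Station-year age-count table
#'
#' Combines [window_filter()] and [prior_effort()] into the analysis table
#' for the productivity model: year-unique young (`n_young`) and adult
#' (`n_adult`) counts per station-year plus the prior-effort covariate
#' `pr_ef`. Station-years with no aged captures get zero counts.
#'
#' @inheritParams window_filter
#' @inheritParams prior_effort
#' @param stations Stations to tabulate; defaults to those present in
#'   `effort` (falling back to `captures`).
#' @return Tibble: `station`, `year`, `n_young`, `n_adult`, `pr_ef`.
#' @export
build_age_counts <- function(captures, effort, years,
                             stations = NULL,
                             window_start = "04-11", window_end = "07-19") {
  years <- sort(as.integer(years))
  if (is.null(stations)) {
    stations <- sort(unique(c(effort$station, captures$station)))
  }
  uniq <- window_filter(captures, years, window_start, window_end)
  counts <- tidyr::expand_grid(station = stations, year = years) %>%
    left_join(
      uniq %>%
        count(.data$station, .data$year, .data$age) %>%
        tidyr::pivot_wider(
          names_from = "age", values_from = "n", values_fill = 0L
        ),
      by = c("station", "year")
    )
  for (cl in c("Y", "A")) if (!cl %in% names(counts)) counts[[cl]] <- 0L
  counts$Y[is.na(counts$Y)] <- 0L
  counts$A[is.na(counts$A)] <- 0L
  counts %>%
    mutate(
      n_young = as.integer(.data$Y), n_adult = as.integer(.data$A),
      pr_ef = purrr::map2_dbl(
        .data$station, .data$year,
        ~ prior_effort(effort, .x, .y, years[1], window_start, window_end)
      )
    ) %>%
    select("station", "year", "n_young", "n_adult", "pr_ef")
}

# Covariate families for the productivity model. Wet-season terms enter
# lagged (previous calendar year's Sep-Nov); evi_w_prev and evi_d never
# co-occur because the two are strongly correlated in these data.
prod_evi_structures <- function() {
  list(
    character(0),
    "evi_mn",
    "evi_w_prev",
    "evi_d",
    "evi_w_dev_prev",
    "evi_d_dev",
    c("evi_w_dev_prev", "evi_d_dev"),
    c("evi_w_dev_prev", "evi_d_dev", "evi_w_dev_prev:evi_d_dev")
  )
}

#' Enumerate the 16 candidate productivity models
#'
#' Eight greenness structures (none; station mean; lagged wet or dry seasonal
#' mean; lagged wet or dry deviation; additive deviations; deviations plus
#' their interaction) crossed with presence/absence of the prior-effort term.
#' The interaction appears only with both deviation main effects, and the
#' correlated seasonal means never co-occur.
#'
#' @return A list of 16 model specifications (term character vectors with a
#'   `label`), each including an implicit intercept.
#' @export
enumerate_productivity_models <- function() {
  specs <- list()
  for (ef in c(FALSE, TRUE)) {
    for (ev in prod_evi_structures()) {
      terms <- c(if (ef) "pr_ef", ev)
      label <- if (length(terms)) paste(terms, collapse = " + ") else "1"
      specs[[length(specs) + 1L]] <- list(label = label, terms = terms)
    }
  }
  specs
}

# Design matrix for a productivity spec: counts joined to covariates, dry /
# mean terms on the row year, wet terms on year - 1, all standardized
# (EVI columns arrive standardized in the covariate table; pr_ef is
# standardized here over the analysis rows).
prod_design <- function(counts, covariates, terms) {
  cur <- covariates %>%
    select("station", "year", evi_mn = "evi_mn_z", evi_d = "evi_d_z",
           evi_d_dev = "evi_d_dev_z")
  prev <- covariates %>%
    mutate(year = .data$year + 1L) %>%
    select("station", "year", evi_w_prev = "evi_w_z",
           evi_w_dev_prev = "evi_w_dev_z")
  d <- counts %>%
    left_join(cur, by = c("station", "year")) %>%
    left_join(prev, by = c("station", "year"))
  pr_mean <- mean(d$pr_ef)
  pr_sd <- stats::sd(d$pr_ef)
  d$pr_ef_raw <- d$pr_ef
  d$pr_ef <- if (is.finite(pr_sd) && pr_sd > 0) (d$pr_ef - pr_mean) / pr_sd else 0 * d$pr_ef
  main <- setdiff(terms, grep(":", terms, value = TRUE))
  missing <- setdiff(main, names(d))
  if (length(missing)) abort(paste("unknown term(s):", paste(missing, collapse = ", ")))
  if (anyNA(d[main])) {
    abort("covariate table does not cover a year needed by the design (wet terms join on year - 1)")
  }
  X <- cbind(`(Intercept)` = rep(1, nrow(d)))
  for (tm in terms) {
    if (grepl(":", tm)) {
      parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
      X <- cbind(X, d[[parts[1]]] * d[[parts[2]]])
    } else {
      X <- cbind(X, d[[tm]])
    }
  }
  colnames(X) <- c("(Intercept)", terms)
  list(X = X, data = d, pr_scaler = list(mean = pr_mean, sd = pr_sd))
}

#' Fit a binomial logit-linear productivity model
#'
#' Maximum-likelihood fit of `n_young | total ~ Binomial(total, p)` with
#' `logit(p) = x'beta`, by Newton-Raphson (iteratively reweighted least
#' squares). The log-likelihood keeps the binomial coefficient terms so AICc
#' values are comparable across any model set fit to the same rows.
#'
#' @param counts Age-count table from [build_age_counts()] (columns
#'   `station`, `year`, `n_young`, `n_adult`, `pr_ef`). Rows with zero total
#'   are dropped before fitting.
#' @param covariates Seasonal covariate table from [build_covariates()]; it
#'   must cover `year - 1` for any wet-season term in the model.
#' @param spec One element of [enumerate_productivity_models()], or a
#'   character vector of terms.
#' @param n_eff_convention Effective sample size for AICc: `"trials"`
#'   (default, total binomial trials) or `"rows"` (station-year rows).
#' @return An object of class `vg_prod_fit` with coefficients, `vcov`,
#'   `logLik`, `K`, `n_eff` and a `converged` flag (separation or failure to
#'   converge clears the flag).
#' @export
fit_binomial <- function(counts, covariates, spec = list(label = "1", terms = character(0)),
                         n_eff_convention = c("trials", "rows")) {
  n_eff_convention <- match.arg(n_eff_convention)
  if (is.character(spec)) {
    spec <- list(label = paste(spec, collapse = " + "), terms = spec)
  }
  keep <- counts$n_young + counts$n_adult > 0
  if (!any(keep)) abort("no station-year rows with aged captures")
  counts <- counts[keep, , drop = FALSE]
  des <- prod_design(counts, covariates, spec$terms)
  X <- des$X
  y <- counts$n_young
  size <- counts$n_young + counts$n_adult
  if (qr(X)$rank < ncol(X)) abort("rank-deficient design matrix")

  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(100)) {
    eta <- drop(X %*% beta)
    p <- invlogit(eta)
    score <- drop(crossprod(X, y - size * p))
    W <- size * p * (1 - p)
    H <- crossprod(X, X * W)
    step <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(step)) break
    # step-halve if the likelihood would not improve
    ll_old <- sum(y * eta - size * log1pexp(eta))
    for (half in 0:20) {
      beta_new <- beta + step / 2^half
      eta_new <- drop(X %*% beta_new)
      ll_new <- sum(y * eta_new - size * log1pexp(eta_new))
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
    }
    beta <- beta_new
    if (max(abs(step)) < 1e-10) {
      converged <- TRUE
      break
    }
  }
  separated <- max(abs(beta)) > 15
  eta <- drop(X %*% beta)
  p <- invlogit(eta)
  ll <- sum(lchoose(size, y) + y * eta - size * log1pexp(eta))
  H <- crossprod(X, X * (size * p * (1 - p)))
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  dimnames(V) <- list(colnames(X), colnames(X))
  n_eff <- if (n_eff_convention == "trials") sum(size) else nrow(counts)
  out <- list(
    label = spec$label, spec = spec,
    coef = setNames(drop(beta), colnames(X)),
    se = setNames(sqrt(pmax(diag(V), 0)), colnames(X)),
    vcov = V,
    logLik = ll, K = ncol(X), n_eff = n_eff,
    converged = converged && !separated, separated = separated,
    data = des$data, X = X, y = y, size = size,
    pr_scaler = des$pr_scaler,
    cov_scalers = attr(covariates, "scalers")
  )
  class(out) <- "vg_prod_fit"
  out
}

#' Fit and rank the productivity model set
#'
#' Fits every spec (default: the 16-model set) to the same station-year rows
#' and returns the AICc model table.
#'
#' @inheritParams fit_binomial
#' @param specs List of model specifications.
#' @return A `vg_model_table` tibble; individual fits are in
#'   `attr(, "fits")`.
#' @export
fit_productivity_models <- function(counts, covariates,
                                    specs = enumerate_productivity_models(),
                                    n_eff_convention = c("trials", "rows")) {
  n_eff_convention <- match.arg(n_eff_convention)
  fits <- purrr::map(specs, function(sp) {
    fit_binomial(counts, covariates, sp, n_eff_convention)
  })
  model_table(fits)
}

#' Predicted productivity with delta-method confidence interval
#'
#' Back-transforms `x'beta +/- z * sqrt(x' V x)` from the logit scale, so the
#' interval always lies inside (0, 1).
#'
#' @param fit A `vg_prod_fit`.
#' @param newdata Tibble of covariate values on the scale the model terms use
#'   (standardized EVI columns / standardized `pr_ef`); missing terms default
#'   to 0, i.e. the covariate mean.
#' @param level Confidence level.
#' @return `newdata` with columns `estimate`, `conf_low`, `conf_high`.
#' @export
predict_productivity <- function(fit, newdata = tibble(.rows = 1), level = 0.95) {
  if (!isTRUE(fit$converged)) warn("predicting from a non-converged fit")
  predict_link_ci(fit, newdata, level)
}

# Shared link-scale prediction for productivity and survival fits.
predict_link_ci <- function(fit, newdata, level) {
  terms <- setdiff(names(fit$coef), "(Intercept)")
  X <- cbind(rep(1, max(nrow(newdata), 1)))
  for (tm in terms) {
    val <- if (grepl(":", tm)) {
      parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
      v1 <- if (parts[1] %in% names(newdata)) newdata[[parts[1]]] else 0
      v2 <- if (parts[2] %in% names(newdata)) newdata[[parts[2]]] else 0
      v1 * v2
    } else if (tm %in% names(newdata)) {
      newdata[[tm]]
    } else {
      0
    }
    X <- cbind(X, val)
  }
  colnames(X) <- names(fit$coef)
  out_of_range <- vapply(terms[!grepl(":", terms)], function(tm) {
    tm %in% names(newdata) && any(abs(newdata[[tm]]) > 4)
  }, logical(1))
  if (any(out_of_range)) {
    warn(sprintf(
      "extrapolating beyond +/-4 SD in: %s",
      paste(terms[!grepl(":", terms)][out_of_range], collapse = ", ")
    ))
  }
  eta <- drop(X %*% fit$coef)
  se <- sqrt(pmax(rowSums((X %*% fit$vcov) * X), 0))
  z <- qnorm(1 - (1 - level) / 2)
  out <- as_tibble(newdata)
  if (nrow(out) == 0) out <- tibble(.rows = length(eta))
  out$estimate <- invlogit(eta)
  out$conf_low <- invlogit(eta - z * se)
  out$conf_high <- invlogit(eta + z * se)
  out
}

#' @export
print.vg_prod_fit <- function(x, ...) {
  cat(sprintf(
    "Binomial productivity model [%s]%s\n", x$label,
    if (x$converged) "" else "  (NOT converged)"
  ))
  print(round(cbind(estimate = x$coef, se = x$se), 4))
  cat(sprintf("logLik %.3f  K %d  n_eff %d\n", x$logLik, x$K, x$n_eff))
  invisible(x)
}
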