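# Constrained Barker joint capture-recapture likelihood ------------------
#
# Live recaptures inside a fixed annual window (the primary periods) are
# joined with captures falling between windows (the "between-period"
# detections). The model is the Barker joint likelihood constrained to the
# study design: site fidelity F = 1, return rate F' = 0 (all captures on the
# study areas), dead-recovery rate r = 0 (no dead recoveries), and shared
# between-period detection rates R (given the bird survives the interval)
# and R' (given it dies during the interval, detection preceding death),
# fixed to 0 on intervals with no between-period effort. Survival S is
# logit-linear in station-interval greenness covariates; recapture p is
# time-constant or year-specific. With R = R' = 0 everywhere the likelihood
# reduces to Cormack-Jolly-Seber.

#' Build encounter histories from capture records
#'
#' Converts dated adult capture records into per-individual encounter
#' histories: `y[t] = 1` if the bird was caught inside the primary window
#' (11 Apr - 19 Jul) of year `t`, and `z[t] = 1` if it was caught between the
#' windows of years `t` and `t + 1` (strictly after 19 Jul, strictly before
#' the next 11 Apr; pre-window captures of a year therefore attach to the
#' preceding interval). Histories condition on the first window capture:
#' records before it are dropped, as are individuals never caught inside a
#' window. Identical `(station, f, y, z)` histories are collapsed with a
#' multiplicity for fast likelihood evaluation.
#'
#' @param captures Capture records: `band_id`, `station`, `date`, `age`
#'   (`"Y"`, `"A"`, `"U"`), `fate` (`"released"` or `"died_in_net"`).
#'   Only adult (`"A"`) records enter; any individual that died in a net is
#'   excluded entirely.
#' @param years The study years (one primary period each), e.g. `2008:2012`.
#' @inheritParams window_filter
#' @return A tibble with columns `station`, `f` (first period, 1-based), `y`
#'   and `z` (0/1 strings over periods / intervals), `n` (multiplicity), and
#'   attributes `years` and `n_periods`. Cross-station recaptures are an
#'   error: the constrained model assumes full site fidelity.
#' @export
build_histories <- function(captures, years, window_start = "04-11",
                            window_end = "07-19") {
  stopifnot(all(c("band_id", "station", "date", "age") %in% names(captures)))
  years <- sort(as.integer(years))
  T <- length(years)
  if (T < 2) abort("need at least 2 study years")
  if ("fate" %in% names(captures)) {
    died <- unique(captures$band_id[captures$fate == "died_in_net"])
    captures <- captures[!captures$band_id %in% died, , drop = FALSE]
  }
  captures <- captures[captures$age == "A", , drop = FALSE]
  if (nrow(captures) == 0) {
    out <- tibble(station = character(), f = integer(),
                  y = character(), z = character(), n = integer())
    attr(out, "years") <- years
    attr(out, "n_periods") <- T
    return(out)
  }
  dt <- parse_dates(captures$date)
  if (anyNA(dt)) abort("unparseable capture date(s)")
  starts <- as.Date(sprintf("%d-%s", years, window_start))
  ends <- as.Date(sprintf("%d-%s", years, window_end))

  # period index if inside a window, else interval index (between windows)
  period <- rep(NA_integer_, length(dt))
  interval <- rep(NA_integer_, length(dt))
  for (t in seq_len(T)) {
    period[dt >= starts[t] & dt <= ends[t]] <- t
  }
  for (t in seq_len(T - 1)) {
    interval[dt > ends[t] & dt < starts[t + 1]] <- t
  }
  bad <- is.na(period) & is.na(interval)
  if (any(bad)) {
    abort(sprintf(
      "capture date %s falls outside the study span (no window or interval)",
      as.character(dt[which(bad)[1]])
    ))
  }

  df <- tibble(
    band_id = captures$band_id, station = captures$station,
    period = period, interval = interval
  )
  cross <- df %>%
    group_by(.data$band_id) %>%
    summarise(k = dplyr::n_distinct(.data$station), .groups = "drop") %>%
    filter(.data$k > 1)
  if (nrow(cross)) {
    abort(sprintf(
      "individual(s) recaptured at a different station (e.g. %s): the model assumes site fidelity F = 1",
      cross$band_id[1]
    ))
  }

  hist_one <- function(period, interval) {
    if (all(is.na(period))) return(NULL)  # never caught inside a window
    f <- min(period, na.rm = TRUE)
    y <- integer(T)
    y[period[!is.na(period)]] <- 1L
    z <- integer(max(T - 1, 0))
    zi <- interval[!is.na(interval)]
    z[zi[zi >= f]] <- 1L  # detections before first release are dropped
    list(f = f, y = paste(y, collapse = ""), z = paste(z, collapse = ""))
  }
  per_bird <- df %>%
    group_by(.data$band_id, .data$station) %>%
    summarise(h = list(hist_one(.data$period, .data$interval)), .groups = "drop") %>%
    filter(!purrr::map_lgl(.data$h, is.null))
  out <- per_bird %>%
    mutate(
      f = purrr::map_int(.data$h, "f"),
      y = purrr::map_chr(.data$h, "y"),
      z = purrr::map_chr(.data$h, "z")
    ) %>%
    count(.data$station, .data$f, .data$y, .data$z, name = "n") %>%
    arrange(.data$station, .data$f, .data$y, .data$z)
  attr(out, "years") <- years
  attr(out, "n_periods") <- T
  out
}

# Decode collapsed histories into matrices for vectorized likelihoods.
encode_histories <- function(histories) {
  T <- attr(histories, "n_periods")
  if (is.null(T)) T <- nchar(histories$y[1])
  n_h <- nrow(histories)
  Y <- matrix(0L, n_h, T)
  Z <- matrix(0L, n_h, max(T - 1, 1))
  for (i in seq_len(n_h)) {
    Y[i, ] <- as.integer(strsplit(histories$y[i], "")[[1]])
    if (T > 1) Z[i, ] <- as.integer(strsplit(histories$z[i], "")[[1]])
  }
  # tail0[i, t]: no detections of any kind after interval t (needed by the
  # death branch: a bird dying in interval t can never be seen again)
  tail0 <- matrix(TRUE, n_h, max(T - 1, 1))
  if (T >= 2) {
    later_y <- rep(0L, n_h)
    later_z <- rep(0L, n_h)
    for (t in (T - 1):1) {
      later_y <- later_y + Y[, t + 1]
      tail0[, t] <- later_y == 0L & later_z == 0L
      later_z <- later_z + Z[, t]
    }
  }
  list(
    Y = Y, Z = Z, tail0 = tail0, f = histories$f, mult = histories$n,
    station = histories$station, T = T
  )
}

#' Probability of one encounter history under the constrained Barker model
#'
#' Sums over the latent alive/dead trajectory by backward recursion: given
#' alive at period `t`, the bird survives interval `t` with probability
#' `S[t]` (and is detected between periods with probability `R[t]`) or dies
#' (detected before death with probability `Rp[t]`), after which no further
#' detection is possible; a survivor is recaptured in period `t + 1` with
#' probability `p[t + 1]`. The probability conditions on release at the
#' first capture, so a bird first caught in the final period contributes 1.
#'
#' @param h List with `f` (first period), `y` (0/1 vector over the `T`
#'   periods, `y[f] = 1`), `z` (0/1 vector over the `T - 1` intervals).
#' @param params List with `S`, `R`, `Rp` (length `T - 1`) and `p` (length
#'   `T`; `p[1]` is unused). Intervals with `R = Rp = 0` cannot carry
#'   `z = 1`; that combination is a data/model conflict and errors.
#' @return The history probability.
#' @export
history_probability <- function(h, params) {
  y <- h$y
  z <- h$z
  f <- h$f
  T <- length(y)
  S <- rep_len(params$S, T - 1)
  p <- rep_len(params$p, T)
  R <- rep_len(params$R, T - 1)
  Rp <- rep_len(params$Rp, T - 1)
  p_used <- if (f < T) p[(f + 1):T] else numeric(0)  # p before release is unused
  probs <- c(S, p_used, R, Rp)
  stopifnot(y[f] == 1, all(probs >= 0), all(probs <= 1))
  if (any(z == 1 & R == 0 & Rp == 0)) {
    abort("between-period detection on an interval with R and R' fixed to 0")
  }
  if (f >= T) return(1)
  L <- 1
  for (t in (T - 1):f) {
    tail_clear <- if (t == T - 1) TRUE else all(y[(t + 2):T] == 0) && all(z[(t + 1):(T - 1)] == 0)
    pay <- if (y[t + 1] == 1) p[t + 1] else 1 - p[t + 1]
    Rz <- if (z[t] == 1) R[t] else 1 - R[t]
    Rpz <- if (z[t] == 1) Rp[t] else 1 - Rp[t]
    L <- S[t] * Rz * pay * L +
      (1 - S[t]) * Rpz * (if (y[t + 1] == 0 && tail_clear) 1 else 0)
  }
  L
}

# Survival covariate structures: term names resolve against the standardized
# covariate table. For the interval from spring of year t to spring of year
# t + 1, wet-season terms use the wet season of year t (inside the interval)
# and dry-season terms the dry season of year t + 1 (ending at recapture).
surv_structures <- function() {
  list(
    constant = character(0),
    evi_mn = "evi_mn",
    evi_w = "evi_w",
    evi_d = "evi_d",
    evi_w_dev = "evi_w_dev",
    evi_d_dev = "evi_d_dev",
    `evi_w_dev + evi_d_dev` = c("evi_w_dev", "evi_d_dev"),
    `evi_w_dev * evi_d_dev` = c("evi_w_dev", "evi_d_dev", "evi_w_dev:evi_d_dev")
  )
}

#' Enumerate the 16 candidate survival models
#'
#' Eight structures for survival (constant; each single greenness covariate;
#' additive seasonal deviations; deviations plus interaction) crossed with
#' time-constant or year-specific recapture probability.
#'
#' @return List of 16 specs, each `list(label, s_terms, p_structure)`.
#' @export
enumerate_survival_models <- function() {
  specs <- list()
  ss <- surv_structures()
  for (p_structure in c("constant", "year")) {
    for (i in seq_along(ss)) {
      specs[[length(specs) + 1L]] <- list(
        label = sprintf("S(%s) p(%s)", names(ss)[i],
                        if (p_structure == "year") "year" else "."),
        s_terms = ss[[i]],
        p_structure = p_structure
      )
    }
  }
  specs
}

# Design array for S: rows = stations (sorted), one slice per interval.
# Returns list(stations, X = array[station, interval, coef], terms).
surv_design <- function(covariates, years, s_terms) {
  T <- length(years)
  stations <- sort(unique(covariates$station))
  cov_of <- function(col, yr) {
    m <- covariates[covariates$year == yr, , drop = FALSE]
    m <- m[match(stations, m$station), , drop = FALSE]
    v <- m[[col]]
    if (anyNA(v)) abort(sprintf("covariate table missing %s for year %d", col, yr))
    v
  }
  coefs <- c("(Intercept)", s_terms)
  X <- array(0, dim = c(length(stations), T - 1, length(coefs)),
             dimnames = list(stations, NULL, coefs))
  X[, , 1] <- 1
  base <- function(tm, t) {
    switch(tm,
      evi_mn = cov_of("evi_mn_z", years[t]),        # station constant
      evi_w = cov_of("evi_w_z", years[t]),          # wet season inside interval
      evi_w_dev = cov_of("evi_w_dev_z", years[t]),
      evi_d = cov_of("evi_d_z", years[t + 1]),      # dry season ending interval
      evi_d_dev = cov_of("evi_d_dev_z", years[t + 1]),
      abort(paste("unknown survival term:", tm))
    )
  }
  for (t in seq_len(T - 1)) {
    for (tm in s_terms) {
      X[, t, tm] <- if (grepl(":", tm)) {
        parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
        base(parts[1], t) * base(parts[2], t)
      } else {
        base(tm, t)
      }
    }
  }
  list(stations = stations, X = X, coefs = coefs)
}

# Unpack the unconstrained parameter vector for a survival spec.
# Layout: beta (S coefficients) | p (1 or T-1 logits) | logit R | logit R'.
surv_par_layout <- function(spec, T, n_coef, any_unmasked) {
  n_p <- if (spec$p_structure == "year") T - 1 else 1
  list(
    beta = seq_len(n_coef),
    p = n_coef + seq_len(n_p),
    RRp = if (any_unmasked) n_coef + n_p + 1:2 else integer(0),
    K = n_coef + n_p + if (any_unmasked) 2L else 0L
  )
}

#' Negative log-likelihood of the constrained Barker model
#'
#' Link-scale wrapper around [history_probability()], vectorized over
#' collapsed histories: survival is `invlogit` of the station-interval
#' design times `beta`, recapture is constant or year-specific, and single
#' `R`, `R'` logits are shared across all unmasked intervals.
#'
#' @param theta Unconstrained parameter vector: S coefficients, then the
#'   recapture logit(s), then `logit(R)` and `logit(R')` (omitted when every
#'   interval is masked).
#' @param histories Collapsed histories from [build_histories()].
#' @param spec One element of [enumerate_survival_models()].
#' @param covariates Standardized covariate table from [build_covariates()]
#'   covering the study years.
#' @param masked_intervals Intervals (1-based) on which `R` and `R'` are
#'   fixed to 0 (no between-period effort); default the first interval, as
#'   when no netting occurred between the first two study years.
#' @return The negative log-likelihood (a length-1 numeric).
#' @export
barker_neg_loglik <- function(theta, histories, spec, covariates,
                              masked_intervals = 1L) {
  ctx <- barker_context(histories, spec, covariates, masked_intervals)
  barker_nll_ctx(theta, ctx)
}

# Precompute everything theta-independent for repeated likelihood calls.
barker_context <- function(histories, spec, covariates, masked_intervals) {
  enc <- encode_histories(histories)
  years <- attr(histories, "years")
  if (is.null(years)) years <- seq_len(enc$T)
  des <- surv_design(covariates, years, spec$s_terms)
  st_idx <- match(enc$station, des$stations)
  if (anyNA(st_idx)) abort("history station absent from covariate table")
  mask <- seq_len(enc$T - 1) %in% masked_intervals
  if (any(enc$Z[, mask, drop = FALSE] == 1)) {
    abort("between-period detection recorded on a masked interval (R, R' fixed to 0)")
  }
  layout <- surv_par_layout(spec, enc$T, length(des$coefs), any(!mask))
  c(enc, list(des = des, st_idx = st_idx, mask = mask, layout = layout,
              spec = spec, years = years))
}

barker_nll_ctx <- function(theta, ctx) {
  T <- ctx$T
  lay <- ctx$layout
  beta <- theta[lay$beta]
  p_par <- theta[lay$p]
  p <- c(NA_real_, invlogit(if (length(p_par) == 1) rep(p_par, T - 1) else p_par))
  if (length(lay$RRp)) {
    R <- ifelse(ctx$mask, 0, invlogit(theta[lay$RRp[1]]))
    Rp <- ifelse(ctx$mask, 0, invlogit(theta[lay$RRp[2]]))
  } else {
    R <- Rp <- rep(0, T - 1)
  }
  # S[station, interval] on the probability scale
  Xm <- matrix(ctx$des$X, nrow = length(ctx$des$stations) * (T - 1))
  S_mat <- matrix(invlogit(drop(Xm %*% beta)), nrow = length(ctx$des$stations))

  L <- rep(1, nrow(ctx$Y))
  for (t in (T - 1):1) {
    S_t <- S_mat[ctx$st_idx, t]
    pay <- ifelse(ctx$Y[, t + 1] == 1, p[t + 1], 1 - p[t + 1])
    Rz <- ifelse(ctx$Z[, t] == 1, R[t], 1 - R[t])
    Rpz <- ifelse(ctx$Z[, t] == 1, Rp[t], 1 - Rp[t])
    dead_ok <- ctx$tail0[, t] & ctx$Y[, t + 1] == 0
    newL <- S_t * Rz * pay * L + (1 - S_t) * Rpz * dead_ok
    L <- ifelse(ctx$f <= t, newL, L)
  }
  if (any(L <= 0)) return(1e10)
  -sum(ctx$mult * log(L))
}

#' Fit a constrained Barker survival model
#'
#' Quasi-Newton (BFGS) maximization of the joint likelihood on the
#' unconstrained link scale, starting from all parameters 0 (probabilities
#' 0.5) with restarts from +/-1 perturbations if convergence fails.
#' Standard errors come from the inverse numerical Hessian at the optimum.
#'
#' @inheritParams barker_neg_loglik
#' @param start Optional start vector.
#' @return An object of class `vg_barker_fit`: `coef`, `se`, `vcov`,
#'   `logLik`, `K` (estimated parameters), `n_eff` (released individuals),
#'   fitted `S`/`p`/`R` on the probability scale, and a `converged` flag. A
#'   singular Hessian leaves SEs `NA` but keeps the fit.
#' @export
fit_barker <- function(histories, spec, covariates, masked_intervals = 1L,
                       start = NULL) {
  if (nrow(histories) == 0) abort("no encounter histories")
  ctx <- barker_context(histories, spec, covariates, masked_intervals)
  lay <- ctx$layout
  if (is.null(start)) start <- rep(0, lay$K)
  stopifnot(length(start) == lay$K)

  run <- function(s0) {
    tryCatch(
      optim(s0, barker_nll_ctx, ctx = ctx, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL
    )
  }
  opt <- run(start)
  converged <- !is.null(opt) && opt$convergence == 0
  if (!converged) {
    for (delta in list(1, -1)) {
      opt2 <- run(start + delta)
      if (!is.null(opt2) && opt2$convergence == 0 &&
          (is.null(opt) || opt2$value <= opt$value)) {
        opt <- opt2
        converged <- TRUE
        break
      }
    }
  }
  if (is.null(opt)) abort("optimization failed from all starts")

  theta <- opt$par
  H <- tryCatch(optimHess(theta, barker_nll_ctx, ctx = ctx),
                error = function(e) NULL)
  V <- if (!is.null(H)) {
    tryCatch(solve(H), error = function(e) matrix(NA_real_, lay$K, lay$K))
  } else {
    matrix(NA_real_, lay$K, lay$K)
  }

  T <- ctx$T
  p_names <- if (ctx$spec$p_structure == "year") {
    paste0("p[", ctx$years[-1], "]")
  } else {
    "p"
  }
  par_names <- c(paste0("S:", ctx$des$coefs), p_names,
                 if (length(lay$RRp)) c("logit(R)", "logit(R')"))
  names(theta) <- par_names
  dimnames(V) <- list(par_names, par_names)

  s_idx <- lay$beta
  out <- list(
    label = spec$label, spec = spec,
    coef = theta,
    se = setNames(sqrt(pmax(diag(V), 0)), par_names),
    vcov = V,
    s_coef = setNames(theta[s_idx], ctx$des$coefs),
    s_vcov = V[s_idx, s_idx, drop = FALSE],
    p = invlogit(if (ctx$spec$p_structure == "year") theta[lay$p] else rep(theta[lay$p], T - 1)),
    R = if (length(lay$RRp)) invlogit(theta[lay$RRp[1]]) else 0,
    Rp = if (length(lay$RRp)) invlogit(theta[lay$RRp[2]]) else 0,
    logLik = -opt$value, K = lay$K, n_eff = sum(histories$n),
    converged = converged, masked_intervals = masked_intervals,
    years = ctx$years,
    cov_scalers = attr(covariates, "scalers")
  )
  class(out) <- "vg_barker_fit"
  out
}

#' Fit and rank the survival model set
#'
#' @inheritParams fit_barker
#' @param specs List of model specifications, default the 16-model set.
#' @return A `vg_model_table` tibble; fits are in `attr(, "fits")`.
#' @export
fit_survival_models <- function(histories, covariates,
                                specs = enumerate_survival_models(),
                                masked_intervals = 1L) {
  fits <- purrr::map(specs, function(sp) {
    fit_barker(histories, sp, covariates, masked_intervals)
  })
  model_table(fits)
}

#' Predicted apparent survival with delta-method confidence interval
#'
#' @param fit A `vg_barker_fit`.
#' @param newdata Tibble of standardized covariate values for the survival
#'   terms (e.g. `evi_w_dev`, `evi_d_dev`); missing terms default to 0.
#' @param level Confidence level.
#' @return `newdata` with `estimate`, `conf_low`, `conf_high` in (0, 1).
#' @export
predict_survival <- function(fit, newdata = tibble(.rows = 1), level = 0.95) {
  if (!isTRUE(fit$converged)) warn("predicting from a non-converged fit")
  sfit <- list(coef = fit$s_coef, vcov = fit$s_vcov, converged = fit$converged)
  predict_link_ci(sfit, newdata, level)
}

#' @export
print.vg_barker_fit <- function(x, ...) {
  cat(sprintf(
    "Barker survival model [%s]%s\n", x$label,
    if (x$converged) "" else "  (NOT converged)"
  ))
  print(round(cbind(estimate = x$coef, se = x$se), 4))
  cat(sprintf("logLik %.3f  K %d  n_eff %d\n", x$logLik, x$K, x$n_eff))
  invisible(x)
}

#' Export encounter histories in a MARK-style LDLD encoding
#'
#' One character pair per primary period: live capture in the window, then
#' any between-period detection in the following interval (the final period
#' has no following interval and contributes a single character). Periods
#' before the first capture print as `"00"`.
#'
#' @param histories Tibble from [build_histories()].
#' @return Tibble with `station`, `ldld`, `n`.
#' @export
format_ldld <- function(histories) {
  T <- attr(histories, "n_periods")
  ldld <- purrr::map2_chr(histories$y, histories$z, function(y, z) {
    yy <- strsplit(y, "")[[1]]
    zz <- c(strsplit(z, "")[[1]], "")
    paste0(yy, zz[seq_len(T)], collapse = "")
  })
  tibble(station = histories$station, ldld = ldld, n = histories$n)
}
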