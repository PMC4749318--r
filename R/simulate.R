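# Synthetic data generator -----------------------------------------------
#
# Emulates the four input streams of a multi-station constant-effort
# banding study on a seasonally wet tropical island: lognormal monthly
# rainfall with a Jul-Nov wet season, station-scale EVI responding
# log-linearly to one-month-lagged rainfall with saturation, capture/effort
# records generated under the constrained Barker process, and station-year
# age counts generated under the binomial logit-linear productivity model.
# Every true parameter is recorded so downstream estimates can be checked
# for recovery.

#' Simulation configuration
#'
#' Defaults encode the study conditions the package is designed around:
#' six stations sampled over five consecutive years (with greenness data
#' starting the year before), most rain falling Jul-Nov, an EVI response of
#' 0.08 per log-mm rainfall saturating near 350 mm, station baselines giving
#' monthly mean EVI between roughly 0.41 and 0.60, adult apparent survival
#' near 0.6 with opposing dry/wet relative-greenness effects (+0.5 / -0.5
#' per SD), recapture probability declining from 0.40 to 0.16 across years,
#' between-period detection R = 0.35 (R' = 0.10) except in the first
#' interval (no between-period effort), and productivity effects matching a
#' strongly responding insectivore (prior-effort 0.73, wet / dry deviations
#' 0.28 / 0.46, interaction 0.41 on the logit scale, around a young
#' fraction of about 0.24).
#'
#' @param n_stations Number of banding stations.
#' @param years Study years (one primary period each), n >= 2.
#' @param station_baselines Per-station EVI offset (unitless), recycled to
#'   `n_stations`.
#' @param rain_log_mean_by_month 12 monthly means of log rainfall (log mm),
#'   January first.
#' @param rain_log_sd SD of log monthly rainfall (> 0).
#' @param evi_slope EVI change per unit log rainfall.
#' @param evi_saturation_mm Rainfall (mm) above which the EVI response is
#'   flat.
#' @param evi_noise_sd SD of monthly EVI noise (>= 0).
#' @param n_recruits_per_station_year Newly marked individuals per
#'   station-year: a scalar or an `n_stations x n_years` matrix.
#' @param true_survival_coefs Named logit-scale coefficients for annual
#'   survival: `"(Intercept)"` plus any of the survival covariate terms
#'   (see [enumerate_survival_models()]).
#' @param true_p_by_year Recapture probabilities for periods 2..T (recycled
#'   if length 1).
#' @param true_R,true_R_prime Between-period detection probabilities given
#'   survival / given death within the interval.
#' @param mask_first_interval Force R = R' = 0 in the first interval (no
#'   between-period effort there), as in the study design.
#' @param true_productivity_coefs Named logit-scale coefficients for the
#'   probability that an aged individual is young: `"(Intercept)"` plus any
#'   of `pr_ef`, `evi_mn`, `evi_w_prev`, `evi_d`, `evi_w_dev_prev`,
#'   `evi_d_dev`, `evi_w_dev_prev:evi_d_dev`.
#' @param n_aged_per_station_year Binomial totals for the age-count stream
#'   (scalar or `n_stations x n_years` matrix), all > 0.
#' @param seed Integer master seed; all stage seeds derive from it.
#' @return A list of class `vg_sim_config`.
#' @export
sim_config <- function(
    n_stations = 6,
    years = 2008:2012,
    station_baselines = c(0.06, 0.20, 0.12, 0.10, 0.19, 0.01),
    rain_log_mean_by_month = log(c(95, 75, 65, 70, 90, 130, 240, 300, 310, 280, 200, 130)),
    rain_log_sd = 0.4,
    evi_slope = 0.08,
    evi_saturation_mm = 350,
    evi_noise_sd = 0.02,
    n_recruits_per_station_year = 36,
    true_survival_coefs = c("(Intercept)" = logit(0.6), evi_w_dev = -0.5, evi_d_dev = 0.5),
    true_p_by_year = c(0.40, 0.33, 0.25, 0.16),
    true_R = 0.35,
    true_R_prime = 0.10,
    mask_first_interval = TRUE,
    true_productivity_coefs = c(
      "(Intercept)" = -1.15, pr_ef = 0.73,
      evi_w_dev_prev = 0.28, evi_d_dev = 0.46,
      "evi_w_dev_prev:evi_d_dev" = 0.41
    ),
    n_aged_per_station_year = 60,
    seed = 1L) {
  years <- sort(as.integer(years))
  n_years <- length(years)
  cfg <- list(
    n_stations = as.integer(n_stations), years = years, n_years = n_years,
    stations = sprintf("ST%d", seq_len(n_stations)),
    station_baselines = rep_len(station_baselines, n_stations),
    rain_log_mean_by_month = rain_log_mean_by_month,
    rain_log_sd = rain_log_sd,
    evi_slope = evi_slope, evi_saturation_mm = evi_saturation_mm,
    evi_noise_sd = evi_noise_sd,
    n_recruits_per_station_year = n_recruits_per_station_year,
    true_survival_coefs = true_survival_coefs,
    true_p_by_year = rep_len(true_p_by_year, n_years - 1),
    true_R = true_R, true_R_prime = true_R_prime,
    mask_first_interval = isTRUE(mask_first_interval),
    true_productivity_coefs = true_productivity_coefs,
    n_aged_per_station_year = n_aged_per_station_year,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "vg_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_stations < 1) abort("n_stations must be >= 1")
    if (n_years < 2) abort("need at least 2 study years")
    if (length(rain_log_mean_by_month) != 12) abort("need 12 monthly log-rain means")
    check_finite(rain_log_mean_by_month, "rain_log_mean_by_month")
    check_finite(station_baselines, "station_baselines")
    check_finite(c(true_survival_coefs, true_productivity_coefs), "true coefficients")
    if (!is.finite(rain_log_sd) || rain_log_sd <= 0) abort("rain_log_sd must be > 0")
    if (!is.finite(evi_noise_sd) || evi_noise_sd < 0) abort("evi_noise_sd must be >= 0")
    probs <- c(true_p_by_year, true_R, true_R_prime)
    if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
      abort("probabilities must lie in [0, 1]")
    }
  })
  invisible(cfg)
}

# Recruits / aged totals as a station x year matrix.
per_station_year <- function(x, cfg) {
  if (is.matrix(x)) {
    stopifnot(nrow(x) == cfg$n_stations, ncol(x) == cfg$n_years)
    return(x)
  }
  matrix(rep_len(x, cfg$n_stations * cfg$n_years), cfg$n_stations, cfg$n_years)
}

# Months the generator covers: Jan of the pre-study year through Dec of the
# last study year, so lagged wet-season covariates exist for every study
# year. Rainfall gets one extra leading month for the EVI lag.
sim_month_grid <- function(cfg, leading = 0L) {
  y0 <- cfg$years[1] - 1L
  yT <- cfg$years[cfg$n_years]
  grid <- tidyr::expand_grid(year = y0:yT, month = 1:12)
  if (leading > 0) {
    lead <- tibble(year = y0 - 1L, month = 12L - rev(seq_len(leading)) + 1L)
    grid <- bind_rows(lead, grid)
  }
  grid
}

#' Simulate monthly rainfall
#'
#' One lognormal draw per month: `rain = exp(N(mu[month], sd))`, with the
#' monthly means encoding the Jul-Nov wet season. The series starts one
#' month before the EVI span so the one-month lag is always available.
#'
#' @param config A [sim_config()].
#' @return Tibble: `year`, `month`, `rain_mm`.
#' @export
sim_rainfall <- function(config) {
  validate_sim_config(config)
  grid <- sim_month_grid(config, leading = 1L)
  mu <- config$rain_log_mean_by_month[grid$month]
  with_seed(derive_seed(config$seed, 101L), {
    grid$rain_mm <- exp(rnorm(nrow(grid), mu, config$rain_log_sd))
  })
  grid
}

#' Simulate monthly station EVI from rainfall
#'
#' `EVI[s, m] = clip(baseline_s + slope * log(min(rain[m - 1], saturation)) +
#' noise, 0, 1)`: greenness follows last month's rainfall log-linearly,
#' flattening above the saturation level.
#'
#' @param rainfall Tibble from [sim_rainfall()] (must include the month
#'   before the first EVI month).
#' @param config A [sim_config()].
#' @return Monthly EVI tibble: `station`, `year`, `month`, `evi`.
#' @export
sim_evi <- function(rainfall, config) {
  validate_sim_config(config)
  grid <- sim_month_grid(config)
  # previous-month rainfall by position in the full series
  series <- arrange(rainfall, .data$year, .data$month)
  key <- paste(grid$year, grid$month)
  prev <- dplyr::lag(series$rain_mm)[match(key, paste(series$year, series$month))]
  if (anyNA(prev)) abort("rainfall series must include the month before each EVI month")
  signal <- config$evi_slope * log(pmin(prev, config$evi_saturation_mm))
  out <- tidyr::expand_grid(station = config$stations, grid)
  base <- config$station_baselines[match(out$station, config$stations)]
  with_seed(derive_seed(config$seed, 202L), {
    eps <- if (config$evi_noise_sd > 0) {
      rnorm(nrow(out), 0, config$evi_noise_sd)
    } else {
      0
    }
    out$evi <- pmin(pmax(
      base + signal[match(paste(out$year, out$month), key)] + eps, 0
    ), 1)
  })
  out
}

# True per-station-interval survival probabilities implied by the config.
true_survival_probs <- function(covariates, config) {
  terms <- setdiff(names(config$true_survival_coefs), "(Intercept)")
  des <- surv_design(covariates, config$years, terms)
  beta <- config$true_survival_coefs[c("(Intercept)", terms)]
  Xm <- matrix(des$X, nrow = length(des$stations) * (config$n_years - 1))
  S <- matrix(invlogit(drop(Xm %*% beta)), nrow = length(des$stations),
              dimnames = list(des$stations, NULL))
  S
}

#' True young-fraction probabilities implied by the config
#'
#' Evaluates the productivity linear predictor on the station-year grid
#' using the standardized covariate columns and a prior-effort covariate
#' standardized over the same grid, exactly as the fitting code does.
#'
#' @param covariates Covariate table from [build_covariates()] covering the
#'   pre-study year through the last study year.
#' @param effort Effort records (for the prior-effort covariate).
#' @param config A [sim_config()].
#' @return Tibble: `station`, `year`, `pr_ef`, `p_young`.
#' @export
true_young_prob <- function(covariates, effort, config) {
  grid <- tidyr::expand_grid(station = config$stations, year = config$years)
  grid$pr_ef <- purrr::map2_dbl(
    grid$station, grid$year,
    ~ prior_effort(effort, .x, .y, config$years[1])
  )
  counts0 <- grid
  counts0$n_young <- 1L
  counts0$n_adult <- 1L
  terms <- setdiff(names(config$true_productivity_coefs), "(Intercept)")
  des <- prod_design(counts0, covariates, terms)
  beta <- config$true_productivity_coefs[c("(Intercept)", terms)]
  grid$p_young <- invlogit(drop(des$X %*% beta))
  grid
}

# Deterministic effort schedule: ten window sampling days per station-year
# (54 net-hours each: nine 12-m nets for six morning hours), plus one
# 54 net-hour day per month between windows in intervals that had
# between-period effort (all but the first when mask_first_interval).
sim_effort <- function(config) {
  rows <- list()
  for (j in seq_len(config$n_years)) {
    yr <- config$years[j]
    w <- window_dates(yr)
    days <- w[1] + round(seq(0, as.numeric(w[2] - w[1]), length.out = 10))
    rows[[length(rows) + 1L]] <- tidyr::expand_grid(
      station = config$stations, date = days
    ) %>% mutate(net_hours = 54)
    if (j < config$n_years && !(j == 1 && config$mask_first_interval)) {
      mdays <- as.Date(sprintf("%d-%02d-15", c(rep(yr, 5), rep(yr + 1, 3)),
                               c(8:12, 1:3)))
      rows[[length(rows) + 1L]] <- tidyr::expand_grid(
        station = config$stations, date = mdays
      ) %>% mutate(net_hours = 54)
    }
  }
  bind_rows(rows) %>% arrange(.data$station, .data$date)
}

#' Simulate capture and effort records under the constrained Barker process
#'
#' Recruits a fixed number of newly marked individuals per station-year,
#' each released at a first capture inside that year's window, then draws
#' its alive/dead trajectory (survival logit-linear in the station-interval
#' covariates), within-window recaptures (probability `p_t`), and at most
#' one between-period detection per interval (`R` if the bird survived the
#' interval, `R'` if it died during it, detection preceding death; never on
#' a masked interval). Individuals are aged young in their recruitment year
#' with the true productivity probability and adult thereafter.
#'
#' @param covariates Covariate table from [build_covariates()] covering the
#'   pre-study year through the last study year.
#' @param config A [sim_config()].
#' @return A list: `captures` (band_id, species, station, date, age, fate),
#'   `effort` (station, date, net_hours), and `truth` — the configuration
#'   echo plus every realized probability (`S` station x interval matrix,
#'   `p_by_period`, `R_t`, `Rp_t`, the young-fraction table) and the
#'   covariate table used.
#' @export
sim_capture_data <- function(covariates, config) {
  validate_sim_config(config)
  if (nrow(covariates) == 0) abort("empty covariate table")
  T <- config$n_years
  effort <- sim_effort(config)
  S <- true_survival_probs(covariates, config)
  p <- c(NA_real_, config$true_p_by_year)
  masked <- if (config$mask_first_interval) 1L else integer(0)
  R_t <- ifelse(seq_len(T - 1) %in% masked, 0, config$true_R)
  Rp_t <- ifelse(seq_len(T - 1) %in% masked, 0, config$true_R_prime)
  pY <- true_young_prob(covariates, effort, config)
  recruits <- per_station_year(config$n_recruits_per_station_year, config)

  windows <- purrr::map(config$years, window_dates)
  runif_date <- function(n, d1, d2) {
    d1 + floor(runif(n) * (as.numeric(d2 - d1) + 1))
  }

  caps <- list()
  with_seed(derive_seed(config$seed, 303L), {
    id0 <- 0L
    for (s in seq_len(config$n_stations)) {
      st <- config$stations[s]
      for (j in seq_len(T)) {
        n <- recruits[s, j]
        if (n == 0) next
        ids <- sprintf("B%06d", id0 + seq_len(n))
        id0 <- id0 + n
        py <- pY$p_young[pY$station == st & pY$year == config$years[j]]
        young <- runif(n) < py
        # release capture
        caps[[length(caps) + 1L]] <- tibble(
          band_id = ids, station = st,
          date = runif_date(n, windows[[j]][1], windows[[j]][2]),
          age = ifelse(young, "Y", "A")
        )
        if (j == T) next
        alive <- rep(TRUE, n)
        for (t in j:(T - 1)) {
          surv <- alive & (runif(n) < S[s, t])
          died <- alive & !surv
          z <- (surv & runif(n) < R_t[t]) | (died & runif(n) < Rp_t[t])
          if (any(z)) {
            caps[[length(caps) + 1L]] <- tibble(
              band_id = ids[z], station = st,
              date = runif_date(sum(z), windows[[t]][2] + 1, windows[[t + 1]][1] - 1),
              age = "A"
            )
          }
          recap <- surv & runif(n) < p[t + 1]
          if (any(recap)) {
            caps[[length(caps) + 1L]] <- tibble(
              band_id = ids[recap], station = st,
              date = runif_date(sum(recap), windows[[t + 1]][1], windows[[t + 1]][2]),
              age = "A"
            )
          }
          alive <- surv
        }
      }
    }
  })
  captures <- bind_rows(caps) %>%
    mutate(species = "SYNT", fate = "released") %>%
    select("band_id", "species", "station", "date", "age", "fate") %>%
    arrange(.data$band_id, .data$date)

  truth <- list(
    config = config, covariates = covariates,
    S = S, p_by_period = p, R_t = R_t, Rp_t = Rp_t,
    masked_intervals = masked, p_young = pY
  )
  class(truth) <- "vg_truth"
  list(captures = captures, effort = effort, truth = truth)
}

#' Simulate station-year age counts
#'
#' Draws the number of young among the aged catch of each station-year from
#' `Binomial(total, p_young)` with the true logit-linear productivity model.
#'
#' @inheritParams sim_capture_data
#' @param effort Effort records (for the prior-effort covariate).
#' @return Age-count tibble (`station`, `year`, `n_young`, `n_adult`,
#'   `pr_ef`) with the true `p_young` attached as attribute `"truth"`.
#' @export
sim_age_counts <- function(covariates, effort, config) {
  validate_sim_config(config)
  totals <- per_station_year(config$n_aged_per_station_year, config)
  if (any(totals <= 0)) abort("aged totals must be > 0 for every station-year")
  pY <- true_young_prob(covariates, effort, config)
  pY <- arrange(pY, .data$station, .data$year)
  idx <- cbind(
    match(pY$station, config$stations),
    match(pY$year, config$years)
  )
  tot <- totals[idx]
  with_seed(derive_seed(config$seed, 404L), {
    ny <- rbinom(nrow(pY), tot, pY$p_young)
  })
  out <- tibble(
    station = pY$station, year = pY$year,
    n_young = ny, n_adult = as.integer(tot - ny), pr_ef = pY$pr_ef
  )
  attr(out, "truth") <- pY
  out
}
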