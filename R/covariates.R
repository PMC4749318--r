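# Seasonal greenness covariates ------------------------------------------
#
# Month sets follow the study design: the late dry season is Mar-May and the
# late wet season Sep-Nov; the rainfall windows paired with them are shifted
# back one month (Feb-Apr, Aug-Oct) because monthly EVI composites are dated
# at the start of the month while rain gauges report end-of-month sums.

season_months <- function(season) {
  switch(season,
    dry = 3:5,
    wet = 9:11,
    abort("season must be 'dry' or 'wet'")
  )
}

rain_months <- function(season) season_months(season) - 1L

#' Bilinear interpolation of a greenness raster at a point
#'
#' Interpolates a gridded value (e.g. 1-km EVI) at arbitrary coordinates from
#' the four nearest cell centers, the standard way station-scale greenness is
#' read off a satellite raster.
#'
#' @param grid A list with components `x` (ascending cell-center coordinates),
#'   `y` (ascending cell-center coordinates) and `values`, a matrix with
#'   `values[i, j]` the cell value at `(x[i], y[j])`.
#' @param x,y Point coordinates. Must lie within the rectangle spanned by the
#'   outermost cell centers.
#' @return The interpolated value (length-1 numeric). Weights of the four
#'   surrounding cell centers always sum to 1.
#' @examples
#' g <- list(x = 0:1, y = 0:1, values = matrix(c(0, 1, 0, 1), 2))
#' bilinear_extract(g, 0.5, 0.5)
#' @export
bilinear_extract <- function(grid, x, y) {
  stopifnot(is.list(grid), length(x) == 1, length(y) == 1)
  gx <- grid$x
  gy <- grid$y
  v <- grid$values
  if (!is.matrix(v) || nrow(v) != length(gx) || ncol(v) != length(gy)) {
    abort("grid$values must be a length(x) by length(y) matrix")
  }
  if (is.unsorted(gx) || is.unsorted(gy)) abort("grid coordinates must be ascending")
  if (x < gx[1] || x > gx[length(gx)] || y < gy[1] || y > gy[length(gy)]) {
    abort("point lies outside the grid of cell centers")
  }
  i <- max(1L, min(findInterval(x, gx), length(gx) - 1L))
  j <- max(1L, min(findInterval(y, gy), length(gy) - 1L))
  tx <- (x - gx[i]) / (gx[i + 1L] - gx[i])
  ty <- (y - gy[j]) / (gy[j + 1L] - gy[j])
  (1 - tx) * (1 - ty) * v[i, j] +
    tx * (1 - ty) * v[i + 1L, j] +
    (1 - tx) * ty * v[i, j + 1L] +
    tx * ty * v[i + 1L, j + 1L]
}

#' Seasonal mean EVI for one station-year
#'
#' Arithmetic mean of the three monthly EVI values making up the late dry
#' (Mar-May) or late wet (Sep-Nov) season of a calendar year.
#'
#' @param evi Monthly EVI table: columns `station`, `year`, `month`, `evi`.
#' @param station Station code.
#' @param year Calendar year.
#' @param season `"dry"` or `"wet"`.
#' @return Length-1 numeric.
#' @export
seasonal_mean <- function(evi, station, year, season = c("dry", "wet")) {
  season <- match.arg(season)
  mos <- season_months(season)
  rows <- evi[evi$station == station & evi$year == year & evi$month %in% mos, ]
  if (nrow(rows) != 3L) {
    missing <- setdiff(mos, rows$month)
    abort(sprintf(
      "station %s year %d: missing %s-season month(s) %s",
      station, year, season, paste(missing, collapse = ", ")
    ))
  }
  mean(rows$evi)
}

#' Build the station-year seasonal covariate table
#'
#' Turns monthly station-scale EVI into the covariates the demographic models
#' consume: the station's across-span monthly mean (`evi_mn`), year-specific
#' wet (Sep-Nov) and dry (Mar-May) season means (`evi_w`, `evi_d`), their
#' deviations from the station's across-year seasonal means (`evi_w_dev`,
#' `evi_d_dev`, the "relative greenness" covariates), and standardized copies
#' of each (`*_z`, pooled mean 0 / sd 1 over the station-year rows, sd with
#' the n-1 divisor).
#'
#' Wet-season values are stored under the calendar year of their Sep-Nov
#' months; the productivity design joins on the previous year at
#' design-matrix time, so the table stays year-unambiguous.
#'
#' @param evi Monthly EVI table: columns `station`, `year`, `month`, `evi`.
#'   `evi_mn` averages every monthly value supplied for a station, so pass
#'   exactly the span the mean should cover.
#' @param years Calendar years to produce rows for. Every station must have
#'   all dry- and wet-season months in each of these years.
#' @return A tibble with one row per station-year and an attached
#'   `"scalers"` attribute recording the mean/sd used for each standardized
#'   column, so new covariate values can be transformed identically at
#'   prediction time.
#' @export
build_covariates <- function(evi, years = sort(unique(evi$year))) {
  stopifnot(all(c("station", "year", "month", "evi") %in% names(evi)))
  check_finite(evi$evi, "evi")
  if (anyDuplicated(evi[c("station", "year", "month")])) {
    abort("duplicate station-month rows in monthly EVI table")
  }
  stations <- sort(unique(evi$station))
  need <- tidyr::expand_grid(
    station = stations, year = as.integer(years),
    month = c(season_months("dry"), season_months("wet"))
  )
  have <- dplyr::semi_join(need, evi, by = c("station", "year", "month"))
  if (nrow(have) < nrow(need)) {
    gap <- dplyr::anti_join(need, evi, by = c("station", "year", "month"))
    abort(sprintf(
      "incomplete monthly coverage: first gap station %s year %d month %d",
      gap$station[1], gap$year[1], gap$month[1]
    ))
  }

  mn <- evi %>%
    group_by(.data$station) %>%
    summarise(evi_mn = mean(.data$evi), .groups = "drop")

  seas <- evi %>%
    filter(.data$year %in% .env$years) %>%
    mutate(season = dplyr::case_when(
      .data$month %in% season_months("dry") ~ "dry",
      .data$month %in% season_months("wet") ~ "wet",
      TRUE ~ NA_character_
    )) %>%
    filter(!is.na(.data$season)) %>%
    group_by(.data$station, .data$year, .data$season) %>%
    summarise(value = mean(.data$evi), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "season", values_from = "value") %>%
    rename(evi_d = "dry", evi_w = "wet")

  tab <- seas %>%
    left_join(mn, by = "station") %>%
    group_by(.data$station) %>%
    mutate(
      evi_w_dev = .data$evi_w - mean(.data$evi_w),
      evi_d_dev = .data$evi_d - mean(.data$evi_d)
    ) %>%
    ungroup() %>%
    arrange(.data$station, .data$year) %>%
    select("station", "year", "evi_mn", "evi_w", "evi_d", "evi_w_dev", "evi_d_dev")

  raw_cols <- c("evi_mn", "evi_w", "evi_d", "evi_w_dev", "evi_d_dev")
  scalers <- purrr::map(setNames(raw_cols, raw_cols), function(cl) {
    list(mean = mean(tab[[cl]]), sd = stats::sd(tab[[cl]]))
  })
  for (cl in raw_cols) {
    s <- scalers[[cl]]
    tab[[paste0(cl, "_z")]] <- if (s$sd > 0) (tab[[cl]] - s$mean) / s$sd else tab[[cl]] * 0
  }
  attr(tab, "scalers") <- scalers
  tab
}

#' Seasonal mean rainfall with the one-month satellite lag
#'
#' Mean monthly rainfall over the window paired with a greenness season:
#' Feb-Apr for the dry season and Aug-Oct for the wet season of the same
#' calendar year (one month earlier than the EVI months, matching composite
#' acquisition at the start of the month versus end-of-month rain totals).
#'
#' @param rain Monthly rainfall table: columns `year`, `month`, `rain_mm`.
#' @param season `"dry"` or `"wet"`.
#' @param year Calendar year.
#' @return Length-1 numeric, mm.
#' @export
lag_align <- function(rain, season = c("dry", "wet"), year) {
  season <- match.arg(season)
  mos <- rain_months(season)
  rows <- rain[rain$year == year & rain$month %in% mos, ]
  if (nrow(rows) != length(mos)) {
    abort(sprintf(
      "year %d: missing rainfall month(s) %s",
      year, paste(setdiff(mos, rows$month), collapse = ", ")
    ))
  }
  mean(rows$rain_mm)
}

#' Regress seasonal EVI on log rainfall
#'
#' Ordinary least squares of mean EVI on log-transformed lagged mean monthly
#' rainfall, the standard check that greenness tracks rainfall. Accepts any
#' paired sample, so the same code path serves seasonal means and monthly
#' series.
#'
#' @param data Data frame with columns `evi` and `rain_mm` (mm, all > 0).
#' @return An object of class `rain_evi_fit`; see [tidy()] and [glance()]
#'   methods, `$fit` holds the underlying [stats::lm] object.
#' @export
fit_rain_evi <- function(data) {
  stopifnot(all(c("evi", "rain_mm") %in% names(data)))
  data <- data[complete.cases(data[c("evi", "rain_mm")]), , drop = FALSE]
  if (nrow(data) < 3L) abort("need at least 3 complete (evi, rain) pairs")
  if (any(data$rain_mm <= 0)) abort("rainfall must be positive (log transform)")
  fit <- lm(evi ~ log(rain_mm), data = data)
  sm <- summary(fit)
  out <- list(
    fit = fit,
    intercept = unname(coef(fit)[1]),
    slope = unname(coef(fit)[2]),
    se = unname(sm$coefficients[, "Std. Error"]),
    t = unname(sm$coefficients[2, "t value"]),
    p_value = unname(sm$coefficients[2, "Pr(>|t|)"]),
    n = nrow(data),
    sigma = sm$sigma
  )
  class(out) <- "rain_evi_fit"
  out
}

#' @export
print.rain_evi_fit <- function(x, ...) {
  cat("EVI ~ log(rainfall) regression\n")
  cat(sprintf(
    "  slope = %.4f (SE %.4f), t = %.2f, p = %.3g, n = %d\n",
    x$slope, x$se[2], x$t, x$p_value, x$n
  ))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Returns the correlation together with its degrees of freedom (n - 2) and
#' the two-sided p-value from `t = r * sqrt(df / (1 - r^2))`.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), finite, each with
#'   positive variance.
#' @return A one-row tibble with columns `r`, `df`, `p`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) abort("x and y lengths differ")
  if (length(x) < 3L) abort("need n >= 3")
  check_finite(x, "x")
  check_finite(y, "y")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("zero variance input")
  r <- stats::cor(x, y)
  df <- length(x) - 2L
  tstat <- r * sqrt(df / (1 - r^2))
  tibble(r = r, df = df, p = 2 * pt(-abs(tstat), df))
}
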