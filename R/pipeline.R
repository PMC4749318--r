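# End-to-end orchestration ------------------------------------------------

capture_cols <- c("band_id", "species", "station", "date", "age", "fate")
effort_cols <- c("station", "date", "net_hours")
evi_cols <- c("station", "year", "month", "evi")
rain_cols <- c("year", "month", "rain_mm")

check_schema <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s: missing column(s) %s", what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Read the pipeline's CSV inputs
#'
#' Strict readers for the four input streams. Column names are fixed; dates
#' are ISO-8601.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @name read_inputs
NULL

#' @rdname read_inputs
#' @export
read_captures <- function(path) {
  check_schema(readr::read_csv(path, show_col_types = FALSE), capture_cols, path)
}

#' @rdname read_inputs
#' @export
read_effort <- function(path) {
  check_schema(readr::read_csv(path, show_col_types = FALSE), effort_cols, path)
}

#' @rdname read_inputs
#' @export
read_monthly_evi <- function(path) {
  check_schema(readr::read_csv(path, show_col_types = FALSE), evi_cols, path)
}

#' @rdname read_inputs
#' @export
read_rainfall <- function(path) {
  check_schema(readr::read_csv(path, show_col_types = FALSE), rain_cols, path)
}

#' Generate a complete synthetic dataset on disk
#'
#' Runs the full generator ([sim_rainfall()], [sim_evi()],
#' [sim_capture_data()], [sim_age_counts()]) and writes the four CSV streams
#' plus the ground truth as JSON. Identical seed and configuration give
#' byte-identical files.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the generated tibbles, the truth bundle,
#'   and the file paths.
#' @export
run_simulate <- function(config = sim_config(), dir = tempfile("vgsim")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rain <- sim_rainfall(config)
  evi <- sim_evi(rain, config)
  covs <- build_covariates(evi, years = (config$years[1] - 1L):config$years[config$n_years])
  cap <- sim_capture_data(covs, config)
  counts <- sim_age_counts(covs, cap$effort, config)

  paths <- list(
    captures = file.path(dir, "captures.csv"),
    effort = file.path(dir, "effort.csv"),
    evi = file.path(dir, "evi_monthly.csv"),
    rainfall = file.path(dir, "rainfall.csv"),
    age_counts = file.path(dir, "age_counts.csv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_csv(cap$captures, paths$captures)
  readr::write_csv(cap$effort, paths$effort)
  readr::write_csv(evi, paths$evi)
  readr::write_csv(rain, paths$rainfall)
  readr::write_csv(counts, paths$age_counts)

  truth_json <- list(
    config = unclass(cap$truth$config),
    S = cap$truth$S,
    p_by_period = cap$truth$p_by_period,
    R_t = cap$truth$R_t,
    Rp_t = cap$truth$Rp_t,
    masked_intervals = cap$truth$masked_intervals,
    p_young = cap$truth$p_young
  )
  jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE, digits = NA)

  invisible(list(
    captures = cap$captures, effort = cap$effort, evi = evi, rainfall = rain,
    age_counts = counts, covariates = covs, truth = cap$truth, paths = paths,
    dir = dir
  ))
}

#' Run the full analysis chain
#'
#' Covariate construction, the rainfall-greenness regression (skipped with a
#' warning when no rainfall data are supplied), the 16-model binomial
#' productivity analysis, and the 16-model Barker survival analysis, with
#' AICc model tables and top-model predictions.
#'
#' @param captures,effort,evi Input tibbles (see [read_inputs]).
#' @param rainfall Optional monthly rainfall tibble.
#' @param years Study years; default the years spanned by the capture
#'   records.
#' @param species Optional species code filter applied to `captures`.
#' @param masked_intervals Intervals with no between-period effort (R, R'
#'   fixed to 0); default the first.
#' @param n_eff_convention AICc effective sample size for the productivity
#'   models ("trials" or "rows").
#' @param out_dir Optional directory: model tables, predictions and the
#'   covariate table are written there as CSV.
#' @return A list of class `vg_report`: `covariates`, `rain_evi`,
#'   `age_counts`, `productivity` and `survival` model tables (with fits
#'   attached), and top-model prediction grids.
#' @export
run_all <- function(captures, effort, evi, rainfall = NULL, years = NULL,
                    species = NULL, masked_intervals = 1L,
                    n_eff_convention = "trials", out_dir = NULL) {
  check_schema(captures, setdiff(capture_cols, "species"), "captures")
  check_schema(effort, effort_cols, "effort")
  check_schema(evi, evi_cols, "evi")
  if (!is.null(species) && "species" %in% names(captures)) {
    captures <- filter(captures, .data$species %in% .env$species)
  }
  if (is.null(years)) {
    yrs <- as.integer(format(as.Date(captures$date), "%Y"))
    years <- seq(min(yrs), max(yrs))
  }
  years <- sort(as.integer(years))

  cov_years <- intersect((years[1] - 1L):years[length(years)], unique(evi$year))
  covariates <- build_covariates(evi, years = cov_years)

  rain_evi <- NULL
  if (!is.null(rainfall)) {
    check_schema(rainfall, rain_cols, "rainfall")
    pairs <- purrr::map_dfr(c("dry", "wet"), function(se) {
      purrr::map_dfr(unique(covariates$year), function(yr) {
        rmm <- tryCatch(lag_align(rainfall, se, yr), error = function(e) NA_real_)
        vals <- covariates[covariates$year == yr, paste0("evi_", substr(se, 1, 1))]
        tibble(evi = vals[[1]], rain_mm = rmm)
      })
    })
    rain_evi <- fit_rain_evi(pairs[complete.cases(pairs), ])
  } else {
    warn("no rainfall data: skipping the rainfall-greenness regression")
  }

  age_counts <- build_age_counts(captures, effort, years)
  productivity <- fit_productivity_models(
    age_counts, covariates, n_eff_convention = n_eff_convention
  )
  histories <- build_histories(captures, years)
  survival <- fit_survival_models(histories, covariates,
                                  masked_intervals = masked_intervals)

  grid <- tidyr::expand_grid(
    evi_d_dev = seq(-2, 2, by = 0.25),
    evi_w_dev = c(-1, 0, 1)
  )
  top_prod <- attr(productivity, "fits")[[
    match(productivity$model[1], purrr::map_chr(attr(productivity, "fits"), "label"))
  ]]
  top_surv <- attr(survival, "fits")[[
    match(survival$model[1], purrr::map_chr(attr(survival, "fits"), "label"))
  ]]
  prod_pred <- predict_productivity(
    top_prod, rename(grid, evi_w_dev_prev = "evi_w_dev")
  )
  surv_pred <- predict_survival(top_surv, grid)

  report <- list(
    years = years, covariates = covariates, rain_evi = rain_evi,
    age_counts = age_counts, histories = histories,
    productivity = productivity, survival = survival,
    productivity_top = top_prod, survival_top = top_surv,
    productivity_predictions = prod_pred, survival_predictions = surv_pred
  )
  class(report) <- "vg_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(covariates, file.path(out_dir, "covariates.csv"))
    readr::write_csv(as_tibble(productivity), file.path(out_dir, "productivity_models.csv"))
    readr::write_csv(as_tibble(survival), file.path(out_dir, "survival_models.csv"))
    readr::write_csv(prod_pred, file.path(out_dir, "productivity_predictions.csv"))
    readr::write_csv(surv_pred, file.path(out_dir, "survival_predictions.csv"))
  }
  report
}

#' @export
print.vg_report <- function(x, ...) {
  cat("Rainfall-greenness-demography analysis report\n")
  cat(sprintf("  years: %s\n", paste(range(x$years), collapse = "-")))
  if (!is.null(x$rain_evi)) {
    cat(sprintf("  EVI ~ log(rain): slope %.4f (SE %.4f)\n",
                x$rain_evi$slope, x$rain_evi$se[2]))
  }
  cat(sprintf("  top productivity model: %s (w = %.2f)\n",
              x$productivity$model[1], x$productivity$weight[1]))
  cat(sprintf("  top survival model:     %s (w = %.2f)\n",
              x$survival$model[1], x$survival$weight[1]))
  invisible(x)
}

#' Within-window effort summary from the six-station worked example
#'
#' Annual mist-netting effort (net-hours) per station for a six-station,
#' five-year banding program: total effort and the effort falling inside the
#' ten sampling periods (11 Apr - 19 Jul) shared by all years. Shipped as a
#' plain-text worked example for the effort-accounting functions.
#'
#' @return Tibble: `station`, `year`, `net_hours`, `net_hours_window`.
#' @export
saipan_effort <- function() {
  readr::read_csv(
    system.file("extdata", "saipan_effort_table.csv", package = "vitalgreen"),
    show_col_types = FALSE
  )
}
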