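toy_captures <- function() {
  tibble::tribble(
    ~band_id, ~station, ~date, ~age,
    "b1", "A", "2010-04-11", "Y",   # boundary: first window day counts
    "b1", "A", "2010-05-02", "Y",   # same bird, counted once
    "b1", "A", "2010-07-19", "Y",   # boundary: last window day counts
    "b2", "A", "2010-04-10", "A",   # day before the window: excluded
    "b3", "A", "2010-06-15", "A",
    "b4", "A", "2010-07-20", "A",   # day after the window: excluded
    "b5", "A", "2010-05-05", "U",   # unknown age: dropped
    "b6", "B", "2010-05-05", "Y",
    "b7", "B", "2010-05-06", "A",
    "b8", "B", "2010-05-07", "A",
    "b6", "B", "2011-05-01", "A",   # same bird next year: new record, adult
    "b9", "B", "2011-06-01", "Y"
  )
}

test_that("window filtering keeps year-unique aged individuals", {
  u <- window_filter(toy_captures(), 2010:2011)
  # hand tally: 2010 A -> b1(Y), b3(A); 2010 B -> b6(Y), b7(A), b8(A)
  u10 <- u[u$year == 2010, ]
  expect_setequal(u10$band_id, c("b1", "b3", "b6", "b7", "b8"))
  expect_equal(u10$age[u10$band_id == "b1"], "Y")
  expect_equal(sum(u10$age == "Y"), 2)
  u11 <- u[u$year == 2011, ]
  expect_setequal(u11$band_id, c("b6", "b9"))
  expect_equal(u11$age[u11$band_id == "b6"], "A")

  # young-at-one-capture, adult-at-another resolves young with a warning
  conf <- tibble::tibble(
    band_id = "x", station = "A", date = c("2010-05-01", "2010-06-01"),
    age = c("A", "Y")
  )
  expect_warning(uc <- window_filter(conf, 2010), "resolved to young")
  expect_equal(uc$age, "Y")

  bad <- toy_captures()
  bad$date[1] <- "not-a-date"
  expect_error(window_filter(bad, 2010), "unparseable")
})

test_that("prior effort sums net-hours strictly between windows", {
  eff <- tibble::tibble(
    station = "A",
    date = as.Date(c(
      "2009-07-19",  # last day of previous window: excluded
      "2009-07-20", "2009-12-01", "2010-04-10",  # between windows: included
      "2010-04-11"   # first day of current window: excluded
    )),
    net_hours = c(10, 50, 40, 9, 10)
  )
  expect_equal(prior_effort(eff, "A", 2010, first_year = 2009), log(100))
  # first study year: log(1 + 0) = 0
  expect_equal(prior_effort(eff, "A", 2009, first_year = 2009), 0)
  # no out-of-window effort at this station
  expect_equal(prior_effort(eff, "B", 2010, first_year = 2009), 0)
  eff$net_hours[2] <- -1
  expect_error(prior_effort(eff, "A", 2010, 2009), "negative")

  # brute-force date-filtered oracle on simulated effort
  inp <- default_sim_inputs(seed = 6)
  sim <- sim_capture_data(inp$covs, inp$cfg)
  d <- as.Date(sim$effort$date)
  oracle <- log(1 + sum(sim$effort$net_hours[
    sim$effort$station == "ST2" &
      d > as.Date("2010-07-19") & d < as.Date("2011-04-11")
  ]))
  expect_equal(prior_effort(sim$effort, "ST2", 2011, 2008), oracle)
})

test_that("window effort totals follow the truncation convention", {
  expect_equal(total_window_effort(tibble::tibble(net_hours = numeric(0))), 0)
  eff <- tibble::tibble(net_hours = c(572.3, 520.5))
  expect_equal(total_window_effort(eff), 1092)
  expect_equal(total_window_effort(eff, truncate = FALSE), 1092.8)
  dated <- tibble::tibble(
    station = "A", date = as.Date(c("2010-04-10", "2010-05-01", "2010-08-01")),
    net_hours = c(100, 50.7, 100)
  )
  expect_equal(total_window_effort(dated, year = 2010), 50)
})

test_that("the productivity model set is the stated 16-model grid", {
  specs <- enumerate_productivity_models()
  expect_length(specs, 16)
  labels <- purrr::map_chr(specs, "label")
  expect_equal(anyDuplicated(labels), 0L)
  for (sp in specs) {
    has_int <- any(grepl(":", sp$terms))
    if (has_int) {
      expect_true(all(c("evi_w_dev_prev", "evi_d_dev") %in% sp$terms))
    }
    expect_false(all(c("evi_w_prev", "evi_d") %in% sp$terms))
  }
  expect_equal(sum(purrr::map_lgl(specs, ~ "pr_ef" %in% .x$terms)), 8)
})

test_that("binomial fitting agrees with closed forms and the reference GLM", {
  inp <- default_sim_inputs(seed = 23)
  sim <- sim_capture_data(inp$covs, inp$cfg)
  counts <- sim_age_counts(inp$covs, sim$effort, inp$cfg)

  # intercept-only MLE in closed form: logit(sum Y / sum total)
  f0 <- fit_binomial(counts, inp$covs, character(0))
  expect_equal(
    unname(f0$coef[1]),
    log(sum(counts$n_young) / sum(counts$n_adult)),
    tolerance = 1e-8
  )

  # full-model coefficients match stats::glm (independent IRLS route)
  terms <- c("pr_ef", "evi_w_dev_prev", "evi_d_dev", "evi_w_dev_prev:evi_d_dev")
  fit <- fit_binomial(counts, inp$covs, terms)
  des <- vitalgreen:::prod_design(counts, inp$covs, terms)
  g <- glm(
    cbind(counts$n_young, counts$n_adult) ~ des$X - 1,
    family = binomial()
  )
  expect_equal(unname(fit$coef), unname(coef(g)), tolerance = 1e-6)
  expect_equal(fit$logLik, as.numeric(logLik(g)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(g)))), tolerance = 1e-5)
  expect_equal(fit$n_eff, sum(counts$n_young + counts$n_adult))
  expect_true(fit$converged)

  # all-young-zero data: separation flagged, not an error
  c0 <- counts
  c0$n_young <- 0L
  f_sep <- fit_binomial(c0, inp$covs, "evi_d_dev")
  expect_false(f_sep$converged)

  # duplicated covariate column: rank deficient
  expect_error(
    fit_binomial(counts, inp$covs, c("evi_d_dev", "evi_d_dev")),
    "rank"
  )
})

test_that("model log-likelihoods are monotone in nesting and weights rank them", {
  inp <- default_sim_inputs(seed = 29)
  sim <- sim_capture_data(inp$covs, inp$cfg)
  counts <- sim_age_counts(inp$covs, sim$effort, inp$cfg)
  tab <- fit_productivity_models(counts, inp$covs)
  expect_s3_class(tab, "vg_model_table")
  expect_equal(nrow(tab), 16)
  expect_equal(sum(tab$weight, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_equal(sum(tab$delta_AICc == 0), 1)
  expect_true(all(diff(tab$AICc[tab$converged]) >= 0))

  fits <- attr(tab, "fits")
  ll <- setNames(purrr::map_dbl(fits, "logLik"), purrr::map_chr(fits, "label"))
  # every model dominates its nested sub-models at the MLE
  expect_gte(ll[["pr_ef + evi_d_dev"]], ll[["evi_d_dev"]])
  expect_gte(ll[["evi_w_dev_prev + evi_d_dev"]], ll[["evi_d_dev"]])
  expect_gte(
    ll[["pr_ef + evi_w_dev_prev + evi_d_dev + evi_w_dev_prev:evi_d_dev"]],
    ll[["pr_ef + evi_w_dev_prev + evi_d_dev"]]
  )
  expect_gte(ll[["evi_d_dev"]], ll[["1"]])
})

test_that("productivity predictions back-transform the link-scale interval", {
  inp <- default_sim_inputs(seed = 41)
  sim <- sim_capture_data(inp$covs, inp$cfg)
  counts <- sim_age_counts(inp$covs, sim$effort, inp$cfg)
  fit <- fit_binomial(counts, inp$covs,
                      c("pr_ef", "evi_w_dev_prev", "evi_d_dev"))

  # zero covariates: invlogit of the intercept
  p0 <- predict_productivity(fit, tibble::tibble(
    pr_ef = 0, evi_w_dev_prev = 0, evi_d_dev = 0
  ))
  expect_equal(p0$estimate, plogis(unname(fit$coef[1])))

  # endpoints equal the brute-force link-scale computation
  nd <- tibble::tibble(pr_ef = 0.5, evi_w_dev_prev = -1, evi_d_dev = 1)
  pr <- predict_productivity(fit, nd)
  x <- c(1, 0.5, -1, 1)
  eta <- sum(x * fit$coef)
  se <- sqrt(drop(t(x) %*% fit$vcov %*% x))
  expect_equal(pr$estimate, plogis(eta))
  expect_equal(pr$conf_low, plogis(eta - qnorm(0.975) * se))
  expect_equal(pr$conf_high, plogis(eta + qnorm(0.975) * se))
  expect_true(pr$conf_low > 0 && pr$conf_high < 1)

  # degenerate vcov: zero-width interval
  fit0 <- fit
  fit0$vcov[] <- 0
  pz <- predict_productivity(fit0, nd)
  expect_equal(pz$conf_low, pz$conf_high)

  # monotonicity in prior effort when its coefficient is positive
  expect_gt(fit$coef[["pr_ef"]], 0)
  ps <- predict_productivity(fit, tibble::tibble(pr_ef = c(-1, 0, 1)))
  expect_true(all(diff(ps$estimate) > 0))

  expect_warning(
    predict_productivity(fit, tibble::tibble(evi_d_dev = 8)),
    "extrapolating"
  )
})

test_that("refitting the generating model recovers the true coefficients", {
  inp <- default_sim_inputs(seed = 47)
  cfg <- sim_config(n_aged_per_station_year = 100, seed = 47)
  sim <- sim_capture_data(inp$covs, sim_config(seed = 47))
  counts <- sim_age_counts(inp$covs, sim$effort, cfg)
  terms <- c("pr_ef", "evi_w_dev_prev", "evi_d_dev", "evi_w_dev_prev:evi_d_dev")
  fit <- fit_binomial(counts, inp$covs, terms)
  truth <- cfg$true_productivity_coefs
  for (i in seq_along(fit$coef)) {
    expect_lt(abs(fit$coef[i] - truth[i]) / fit$se[i], 3)
  }
})
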