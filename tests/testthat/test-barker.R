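# Fast five-year fixture shared by several blocks.
barker_fixture <- function(seed = 51, n = 36, ...) {
  cfg <- do.call(sim_config, utils::modifyList(
    list(n_recruits_per_station_year = n, seed = seed), list(...)
  ))
  rain <- sim_rainfall(cfg)
  covs <- build_covariates(sim_evi(rain, cfg),
                           years = (cfg$years[1] - 1L):max(cfg$years))
  sim <- sim_capture_data(covs, cfg)
  list(cfg = cfg, covs = covs, sim = sim,
       hist = build_histories(sim$captures, cfg$years))
}

test_that("encounter histories encode windows, intervals and conditioning", {
  caps <- tibble::tribble(
    ~band_id, ~station, ~date, ~age, ~fate,
    "a", "A", "2012-05-01", "A", "released",            # only in final window
    "b", "A", "2010-06-10", "A", "released",
    "b", "A", "2011-02-15", "A", "released",            # pre-window -> interval 2010-2011
    "c", "A", "2008-05-01", "A", "released",
    "c", "A", "2009-06-01", "A", "released",
    "c", "A", "2011-06-01", "A", "released",
    "d", "A", "2008-05-02", "A", "released",
    "d", "A", "2009-06-02", "A", "released",
    "d", "A", "2011-06-02", "A", "released",            # same history as c
    "e", "A", "2009-09-01", "A", "released",            # interval capture before any window: dropped
    "f", "A", "2010-05-01", "Y", "released",            # young record: not an adult history
    "g", "A", "2010-05-01", "A", "died_in_net",         # net casualty: excluded
    "g", "A", "2011-05-01", "A", "released",
    "h", "B", "2009-05-01", "A", "released",
    "h", "B", "2009-12-01", "A", "released",
    "h", "B", "2010-05-01", "A", "released"
  )
  h <- build_histories(caps, 2008:2012)
  expect_equal(attr(h, "n_periods"), 5)
  # bird a: released in the last period, empty remaining history
  ha <- h[h$y == "00001", ]
  expect_equal(ha$f, 5L)
  expect_equal(ha$z, "0000")
  # bird b: window 2010 then a pre-window 2011 capture -> z on interval 3
  hb <- h[h$y == "00100", ]
  expect_equal(hb$z, "0010")
  # birds c and d collapse with multiplicity 2
  hc <- h[h$y == "11010", ]
  expect_equal(hc$n, 2L)
  # bird e (interval capture only) and f (young) contribute nothing
  expect_equal(sum(h$n), 5)
  # bird h: consecutive windows with a between-period detection
  hh <- h[h$station == "B", ]
  expect_equal(hh$y, "01100")
  expect_equal(hh$z, "0100")

  # a bird moving between stations violates F = 1
  moved <- dplyr::bind_rows(
    caps[caps$band_id == "h", ],
    tibble::tibble(band_id = "h", station = "A", date = "2011-05-01",
                   age = "A", fate = "released")
  )
  expect_error(build_histories(moved, 2008:2012), "fidelity")
  # a capture before the study span has no window or interval
  expect_error(
    build_histories(
      tibble::tibble(band_id = "q", station = "A", date = "2007-05-01",
                     age = "A", fate = "released"),
      2008:2012
    ),
    "outside the study span"
  )
})

test_that("history probabilities match hand-enumerated closed forms", {
  S <- 0.7; p <- 0.4; R <- 0.3; Rp <- 0.1
  par2 <- list(S = S, p = c(NA, p), R = R, Rp = Rp)
  # survive + not detected between + recaptured
  expect_equal(
    history_probability(list(f = 1, y = c(1, 1), z = 0), par2),
    S * (1 - R) * p
  )
  # y = (1,0), z = 1: survived-and-missed or died-after-detection
  expect_equal(
    history_probability(list(f = 1, y = c(1, 0), z = 1), par2),
    S * R * (1 - p) + (1 - S) * Rp
  )
  # y = (1,0), z = 0: all remaining paths
  expect_equal(
    history_probability(list(f = 1, y = c(1, 0), z = 0), par2),
    S * (1 - R) * (1 - p) + (1 - S) * (1 - Rp)
  )
  # release in final period: probability 1
  expect_equal(history_probability(list(f = 2, y = c(0, 1), z = 0), par2), 1)
  # masked interval cannot carry a detection
  expect_error(
    history_probability(list(f = 1, y = c(1, 1), z = 1),
                        list(S = S, p = c(NA, p), R = 0, Rp = 0)),
    "fixed to 0"
  )
})

test_that("history probabilities over all completions sum to one", {
  for (T in 2:4) {
    params <- list(
      S = seq(0.3, 0.8, length.out = T - 1),
      p = c(NA, seq(0.2, 0.6, length.out = T - 1)),
      R = 0.25, Rp = 0.15
    )
    for (f in 1:(T - 1)) {
      expect_equal(completion_total(T, f, params), 1, tolerance = 1e-12)
    }
  }
})

test_that("the vectorized likelihood equals per-history recursion", {
  fx <- barker_fixture(seed = 53)
  spec <- list(label = "S(evi_w_dev + evi_d_dev) p(year)",
               s_terms = c("evi_w_dev", "evi_d_dev"), p_structure = "year")
  theta <- c(0.3, -0.4, 0.5, -0.2, -0.5, -0.8, -1.2, -0.6, -2)
  nll <- barker_neg_loglik(theta, fx$hist, spec, fx$covs)

  # independent route: history_probability per history with probabilities
  # assembled by hand from theta
  des <- vitalgreen:::surv_design(fx$covs, fx$cfg$years, spec$s_terms)
  T <- 5
  p <- c(NA, plogis(theta[4:7]))
  R <- c(0, rep(plogis(theta[8]), 3))
  Rp <- c(0, rep(plogis(theta[9]), 3))
  ll <- 0
  for (i in seq_len(nrow(fx$hist))) {
    st <- match(fx$hist$station[i], des$stations)
    S <- plogis(des$X[st, , ] %*% theta[1:3])
    pr <- history_probability(
      list(
        f = fx$hist$f[i],
        y = as.integer(strsplit(fx$hist$y[i], "")[[1]]),
        z = as.integer(strsplit(fx$hist$z[i], "")[[1]])
      ),
      list(S = drop(S), p = p, R = R, Rp = Rp)
    )
    ll <- ll + fx$hist$n[i] * log(pr)
  }
  expect_equal(nll, -ll, tolerance = 1e-10)

  # certain event has likelihood one: S = 1, p = 1, R = 0 on a single history
  one <- tibble::tibble(station = "ST1", f = 1L, y = "11111", z = "0000", n = 1L)
  attr(one, "years") <- fx$cfg$years
  attr(one, "n_periods") <- 5L
  spec0 <- list(label = "S(constant) p(.)", s_terms = character(0),
                p_structure = "constant")
  expect_equal(
    barker_neg_loglik(c(40, 40, -40, -40), one, spec0, fx$covs,
                      masked_intervals = integer(0)),
    0, tolerance = 1e-10
  )

  # multiplicity linearity: doubling every multiplicity doubles the value
  doubled <- fx$hist
  doubled$n <- doubled$n * 2L
  attr(doubled, "years") <- fx$cfg$years
  attr(doubled, "n_periods") <- 5L
  expect_equal(
    barker_neg_loglik(theta, doubled, spec, fx$covs),
    2 * nll, tolerance = 1e-10
  )
})

test_that("collapsed and uncollapsed histories give identical fits", {
  fx <- barker_fixture(seed = 57, n = 20)
  un <- fx$hist[rep(seq_len(nrow(fx$hist)), fx$hist$n), ]
  un$n <- 1L
  attr(un, "years") <- fx$cfg$years
  attr(un, "n_periods") <- 5L
  spec <- list(label = "S(evi_d_dev) p(.)", s_terms = "evi_d_dev",
               p_structure = "constant")
  f1 <- fit_barker(fx$hist, spec, fx$covs)
  f2 <- fit_barker(un, spec, fx$covs)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-10)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-8)
})

test_that("with no between-period detection the model reduces to CJS", {
  fx <- barker_fixture(seed = 59, true_R = 0, true_R_prime = 0,
                       n = 60, true_p_by_year = 0.45)
  spec <- list(label = "S(constant) p(.)", s_terms = character(0),
               p_structure = "constant")
  # masking every interval fixes R = R' = 0 and drops them from estimation
  fit <- fit_barker(fx$hist, spec, fx$covs, masked_intervals = 1:4)
  expect_equal(fit$K, 2)

  # profile equality: the Barker likelihood at (S, p) equals the chi-form
  # CJS likelihood on the y-vectors, over a parameter grid
  for (S0 in c(0.3, 0.6, 0.9)) {
    for (p0 in c(0.2, 0.5, 0.8)) {
      nll <- barker_neg_loglik(
        c(qlogis(S0), qlogis(p0)), fx$hist, spec, fx$covs,
        masked_intervals = 1:4
      )
      expect_equal(-nll, cjs_loglik(fx$hist, S0, c(NA, rep(p0, 4))),
                   tolerance = 1e-8)
    }
  }

  # and the MLEs agree with the independent CJS fit
  oracle <- cjs_fit(fx$hist, "constant")
  expect_equal(plogis(unname(fit$coef[1])), oracle$S, tolerance = 1e-5)
  expect_equal(plogis(unname(fit$coef[2])), oracle$p, tolerance = 1e-5)

  expect_error(fit_barker(fx$hist[0, ], spec, fx$covs), "no encounter histories")
})

test_that("the survival model set crosses 8 S structures with 2 p structures", {
  specs <- enumerate_survival_models()
  expect_length(specs, 16)
  labels <- purrr::map_chr(specs, "label")
  expect_equal(anyDuplicated(labels), 0L)
  s_kinds <- unique(purrr::map_chr(specs, ~ paste(.x$s_terms, collapse = "+")))
  expect_length(s_kinds, 8)
  expect_equal(sum(purrr::map_chr(specs, "p_structure") == "year"), 8)
  has_int <- purrr::map_lgl(specs, ~ any(grepl(":", .x$s_terms)))
  for (sp in specs[has_int]) {
    expect_true(all(c("evi_w_dev", "evi_d_dev") %in% sp$s_terms))
  }
  expect_equal(sum(has_int & purrr::map_chr(specs, "p_structure") == "year"), 1)
})

test_that("fitting recovers constant survival and detection parameters", {
  cfg <- sim_config(
    n_stations = 3, station_baselines = c(0.1, 0.15, 0.2),
    true_survival_coefs = c("(Intercept)" = qlogis(0.6)),
    true_p_by_year = 0.4, n_recruits_per_station_year = 200,
    seed = 61
  )
  rain <- sim_rainfall(cfg)
  covs <- build_covariates(sim_evi(rain, cfg), years = 2007:2012)
  sim <- sim_capture_data(covs, cfg)
  h <- build_histories(sim$captures, cfg$years)
  spec <- list(label = "S(constant) p(.)", s_terms = character(0),
               p_structure = "constant")
  fit <- fit_barker(h, spec, covs)
  expect_true(fit$converged)
  expect_lt(abs(fit$coef[["S:(Intercept)"]] - qlogis(0.6)) /
              fit$se[["S:(Intercept)"]], 3)
  expect_lt(abs(fit$coef[["p"]] - qlogis(0.4)) / fit$se[["p"]], 3)
  expect_lt(abs(fit$coef[["logit(R)"]] - qlogis(cfg$true_R)) /
              fit$se[["logit(R)"]], 3)
  expect_equal(fit$n_eff, sum(h$n))
})

test_that("survival predictions and LDLD export are consistent", {
  fx <- barker_fixture(seed = 63, n = 60)
  spec <- list(label = "S(evi_w_dev + evi_d_dev) p(year)",
               s_terms = c("evi_w_dev", "evi_d_dev"), p_structure = "year")
  fit <- fit_barker(fx$hist, spec, fx$covs)
  p0 <- predict_survival(fit, tibble::tibble(evi_w_dev = 0, evi_d_dev = 0))
  expect_equal(p0$estimate, plogis(unname(fit$s_coef[1])))
  nd <- tibble::tibble(evi_w_dev = 1, evi_d_dev = -1)
  pr <- predict_survival(fit, nd)
  x <- c(1, 1, -1)
  eta <- sum(x * fit$s_coef)
  se <- sqrt(drop(t(x) %*% fit$s_vcov %*% x))
  expect_equal(pr$estimate, plogis(eta))
  expect_equal(pr$conf_low, plogis(eta - qnorm(0.975) * se))
  expect_true(pr$conf_low > 0 && pr$conf_high < 1)

  ld <- format_ldld(fx$hist)
  expect_equal(nrow(ld), nrow(fx$hist))
  expect_true(all(nchar(ld$ldld) == 2 * 5 - 1))
  i <- which(fx$hist$f == 1)[1]
  manual <- paste0(
    substr(fx$hist$y[i], 1, 1), substr(fx$hist$z[i], 1, 1),
    substr(fx$hist$y[i], 2, 2), substr(fx$hist$z[i], 2, 2),
    substr(fx$hist$y[i], 3, 3), substr(fx$hist$z[i], 3, 3),
    substr(fx$hist$y[i], 4, 4), substr(fx$hist$z[i], 4, 4),
    substr(fx$hist$y[i], 5, 5)
  )
  expect_equal(ld$ldld[i], manual)
})
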