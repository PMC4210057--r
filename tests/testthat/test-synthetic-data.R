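test_that("spatial field draws respect the CAR geometry", {
  g <- lattice_graph(12, nrow = 3)
  expect_equal(unname(sample_spatial_field(g, 0)), rep(0, 12))
  f <- sample_spatial_field(g, 0.5, seed = 61)
  expect_lt(abs(sum(f)), 1e-10)
  expect_identical(f, sample_spatial_field(g, 0.5, seed = 61))

  # Monte-Carlo check: f' K f / sigma2 ~ chi-squared with rank(K) dof
  K <- car_structure(g)$K
  set.seed(62)
  q <- replicate(1000, {
    fi <- sample_spatial_field(g, 0.3)
    drop(crossprod(fi, K %*% fi)) / 0.3
  })
  expect_equal(mean(q), 11, tolerance = 0.15)  # rank = 12 - 1, sd ~ sqrt(2*11/1000)

  # disconnected graph: per-component sum-to-zero
  g2 <- district_graph(rbind(c("a", "b"), c("c", "d")))
  f2 <- sample_spatial_field(g2, 1, seed = 63)
  expect_lt(abs(f2[["a"]] + f2[["b"]]), 1e-10)
  expect_lt(abs(f2[["c"]] + f2[["d"]]), 1e-10)
})

test_that("covariate sampling follows the episode regime", {
  ev <- ads_events_fixture()
  cal <- label_periods("2002-01-01", "2007-12-31", ev)
  # zero SDs: pollutants exactly equal the period means
  reg0 <- default_pollutant_regime()
  reg0$sd <- 0
  cov0 <- sample_covariates(cal, reg0, seed = 64)
  ads_mean <- reg0$mean[reg0$pollutant == "PM10" & reg0$period == "ADS"]
  expect_true(all(cov0$PM10[cal$period == "ADS"] == ads_mean))

  # same seed reproduces the table
  expect_identical(sample_covariates(cal, seed = 65),
                   sample_covariates(cal, seed = 65))
  expect_error(sample_covariates(cal, within(default_pollutant_regime(),
                                             sd <- -1)), "SD")

  # default regime: O3 ADS-stratum mean within 3 SE of its configured mean
  cov1 <- sample_covariates(cal, seed = 66)
  o3_ads <- cov1$O3[cal$period == "ADS"]
  se <- 7.40 / sqrt(length(o3_ads))
  expect_lt(abs(mean(o3_ads) - 25.13), 3 * se)
  expect_true(all(cov1$CO >= 0) && all(cov1$SO2 >= 0))
})

test_that("the generated panel has the configured dimensions and Poisson
           structure", {
  cfg <- sim_config(seed = 67, n_districts = 6, start = "2002-01-01",
                    end = "2002-06-30")
  sim <- generate_panel(cfg)
  expect_equal(nrow(sim$panel), 6 * 181)
  expect_identical(generate_panel(cfg)$panel, sim$panel)  # determinism

  # truth record reconstructs the generating predictor exactly
  i <- 534
  d <- match(sim$panel$district[i], sim$graph$ids)
  t_ <- match(sim$panel$date[i], sim$calendar$date)
  tr <- sim$truth
  eta_manual <- log(tr$baseline) +
    (if (as.character(sim$calendar$dow[t_]) == "Sun") 0
     else tr$dow_log[[as.character(sim$calendar$dow[t_])]]) +
    tr$beta_ads * (sim$calendar$period[t_] == "ADS") +
    tr$beta_post * (sim$calendar$period[t_] == "POST_ADS") +
    sum(vapply(names(tr$gamma), function(p)
      tr$gamma[[p]] * sim$covariates[[p]][t_], 0)) +
    tr$f_time[t_] + tr$f_temp[t_] + tr$f_spat[[sim$panel$district[i]]]
  expect_equal(tr$eta[d, t_], eta_manual, ignore_attr = TRUE)

  # all effects zero: counts are Poisson(pop * baseline)
  cfg0 <- sim_config(seed = 68, n_districts = 6, start = "2002-01-01",
                     end = "2002-12-31", baseline = 2e-3,
                     dow_multipliers = c(Mon = 1, Tue = 1, Wed = 1, Thu = 1,
                                         Fri = 1, Sat = 1),
                     beta_ads = 0, beta_post = 0, gamma = numeric(0),
                     temp_effect = function(tp) 0 * tp,
                     time_effect = function(t) 0 * t, sigma2_spat = 0)
  sim0 <- generate_panel(cfg0)
  rate_hat <- sum(sim0$panel$count) / sum(sim0$panel$population)
  se <- sqrt(sum(sim0$panel$population * 2e-3)) / sum(sim0$panel$population)
  expect_lt(abs(rate_hat - 2e-3), 3 * se)

  # ADS-only effect shows up as the configured rate ratio
  cfg1 <- cfg0
  cfg1$beta_ads <- log(1.0948)
  cfg1$seed <- 69L
  sim1 <- generate_panel(cfg1)
  per <- sim1$calendar$period[match(sim1$panel$date, sim1$calendar$date)]
  r_ads <- sum(sim1$panel$count[per == "ADS"]) /
    sum(sim1$panel$population[per == "ADS"])
  r_oth <- sum(sim1$panel$count[per == "OTHER"]) /
    sum(sim1$panel$population[per == "OTHER"])
  expect_equal(r_ads / r_oth, 1.0948, tolerance = 0.05)

  # rate overflow guard names the problem
  cfg_bad <- sim_config(seed = 70, n_districts = 4, start = "2002-01-01",
                        end = "2002-01-31", baseline = 1e6)
  expect_error(generate_panel(cfg_bad), "overflow")
})

test_that("the default configuration reproduces the study dimensions", {
  cfg <- sim_config(seed = 71)
  expect_equal(cfg$n_districts, 41)
  expect_equal(as.integer(cfg$end - cfg$start) + 1L, 2191L)
  expect_equal(nrow(cfg$events), 30)
  expect_equal(cfg$gamma[["NOx"]], log(1.0349) / 22.16)
  expect_equal(cfg$beta_ads, log(1.0948))
})

test_that("pipeline closure: fitting the true spec recovers the generating
           fixed effects", {
  # single-replicate closure check; the acceptance suite measures coverage
  sim <- tiny_sim(seed = 72, n_districts = 12, end = "2003-12-31")
  spec <- tiny_spec(pollutants = c("NOx", "O3"))
  fit <- fit_star(build_design(sim$panel, sim$covariates, sim$calendar,
                               sim$graph, spec))
  tr <- sim$truth
  expect_lt(abs(fit$coefficients[["I_ADS"]] - tr$beta_ads),
            4 * fit$se[["I_ADS"]])
  expect_lt(abs(fit$coefficients[["I_SAT"]] - tr$dow_log[["Sat"]]),
            4 * fit$se[["I_SAT"]])
  expect_lt(abs(fit$coefficients[["NOx"]] - tr$gamma[["NOx"]]),
            4 * fit$se[["NOx"]])
  # spatial field recovery (correlation, not equality: the field is latent)
  map <- spatial_effect_map(fit)
  expect_gt(cor(log(map$rr), tr$f_spat[map$district]), 0.9)
})
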