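test_that("Kaplan-Meier matches closed-form and hand-computed product limits", {
  # all events, one group: steps 2/3, 1/3, 0
  d <- data.frame(time = c(2, 4, 6), event = 1)
  km <- kaplan_meier(d)
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))

  # all censored: flat at 1, median undefined
  d2 <- data.frame(time = c(5, 10, 15), event = 0)
  km2 <- kaplan_meier(d2)
  expect_true(all(km2$survival == 1))
  expect_true(is.na(attr(km2, "medians")[["all"]]))

  # mixed censoring fixture against the product-limit table computed by hand
  d3 <- data.frame(time = c(1, 2, 2, 3, 4, 5, 6, 7, 8, 9),
                   event = c(1, 1, 1, 1, 0, 1, 0, 1, 0, 1))
  km3 <- kaplan_meier(d3)
  got <- km3$survival[km3$n_event > 0]
  expect_equal(got, c(0.9, 0.7, 0.6, 0.48, 0.32, 0))
  expect_equal(attr(km3, "medians")[["all"]], 5)

  expect_error(kaplan_meier(d[0, , drop = FALSE]), "empty")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(21)
  d <- data.frame(time = round(rexp(200, 0.1), 2) + 0.01, event = 1)
  km <- kaplan_meier(d)
  emp <- vapply(km$time, function(t) mean(d$time > t), numeric(1))
  expect_equal(km$survival, emp, tolerance = 1e-12)
})

test_that("total-effect Cox recovers a known exponential rate ratio", {
  set.seed(31)
  n <- 10000
  a <- rep(0:1, each = n / 2)
  d <- data.frame(exposure = a, time = rexp(n, 0.05 * 2^a), event = 1,
                  cluster_id = seq_len(n))
  rf <- fit_total_effect(d, confounders = character(0))
  hr <- rf$exp_estimate[rf$term == "exposure"]
  expect_gt(hr, 1.9)
  expect_lt(hr, 2.1)
  expect_true(all(rf$conf_low <= rf$exp_estimate & rf$exp_estimate <= rf$conf_high))
})

test_that("robust variance changes SEs but not Cox point estimates", {
  co <- simulate_cohort(small_config(seed = 12))
  rf <- fit_total_effect(co)
  co2 <- co
  co2$age5 <- (co2$age - mean(co2$age)) / 5
  naive <- survival::coxph(
    survival::Surv(time, event) ~ exposure + age5 + ecog + ascites +
      comorbidity + histology + grade, data = co2, ties = "efron")
  expect_equal(rf$estimate, unname(coef(naive)), tolerance = 1e-10)
})

test_that("total-effect Cox rejects degenerate inputs", {
  co <- simulate_cohort(small_config(seed = 13))
  co$event <- 0
  expect_error(fit_total_effect(co), "events")
  co2 <- simulate_cohort(small_config(seed = 13))
  co2$cluster_id <- 1
  expect_error(fit_total_effect(co2), "clusters")
})

test_that("adherence model recovers a known exposure odds ratio", {
  cfg <- flat_config(seed = 14, n = 20000)
  cfg$mediator_coefs$m1$exposure <- log(1.6)
  co <- simulate_cohort(cfg)
  rf <- fit_adherence(co, "m1")
  est <- rf[rf$term == "exposure", ]
  expect_lt(abs(est$estimate - log(1.6)) / est$robust_se, 3)

  # mediator independent of exposure: OR near 1 at n = 5000
  co0 <- simulate_cohort(null_path_config(seed = 18, n = 5000))
  rf0 <- fit_adherence(co0, "m1")
  or0 <- rf0$exp_estimate[rf0$term == "exposure"]
  expect_gt(or0, 0.9)
  expect_lt(or0, 1.1)
})

test_that("adherence model handles degenerate clustering and constant mediators", {
  co <- simulate_cohort(small_config(seed = 16))
  co$m1 <- 1
  expect_error(fit_adherence(co, "m1"), "constant")

  co2 <- simulate_cohort(small_config(seed = 16))
  co2$cluster_id <- 1  # single cluster: sandwich degenerates but runs
  rf <- fit_adherence(co2, "m2")
  expect_s3_class(rf, "regression_fit")
  expect_true(all(is.finite(rf$robust_se)))
})

test_that("adherence proportions by arm track the generator margins at large n", {
  cfg <- flat_config(seed = 17, n = 1e5)
  co <- simulate_cohort(cfg)
  by_arm <- tapply(co$m1, co$exposure, mean)
  # calibrated preset margins: about 54% unexposed, 64-66% exposed
  expect_equal(unname(by_arm[1]), 0.54, tolerance = 0.02)
  expect_equal(unname(by_arm[2]), 0.645, tolerance = 0.02)
})
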