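test_that("the decomposition identity holds exactly on fitted objects", {
  for (s in c(31, 32, 33)) {
    fit <- mediate_survival(simulate_cohort(small_config(seed = s)),
                            mediators = c("m1", "m2"))
    d <- fit$decomposition
    expect_identical(d$hr_total, d$hr_direct * prod(d$hr_indirect))
    expect_identical(d$hr_indirect_joint, prod(d$hr_indirect))
    expect_equal(d$prop_mediated_joint,
                 log(d$hr_indirect_joint) / log(d$hr_total), tolerance = 1e-15)
  }
})

test_that("proportion mediated is undefined at a null total effect", {
  expect_true(is.na(proportion_mediated(0.9, 1)))
  expect_equal(round(100 * proportion_mediated(0.93, 0.58)), 13)
})

test_that("repeated runs on the same cohort give identical decompositions", {
  co <- simulate_cohort(small_config(seed = 35))
  f1 <- mediate_survival(co, mediators = c("m1", "m2"))
  f2 <- mediate_survival(co, mediators = c("m1", "m2"))
  expect_identical(f1$decomposition$hr_total, f2$decomposition$hr_total)
  expect_identical(coef(f1), coef(f2))
})

test_that("a single-mediator run on a two-mediator cohort is a valid decomposition", {
  co <- simulate_cohort(small_config(seed = 36))
  fit <- mediate_survival(co, mediators = "m1")
  d <- fit$decomposition
  expect_length(d$hr_indirect, 1)
  expect_identical(d$hr_total, d$hr_direct * d$hr_indirect[["m1"]])
})

test_that("the lean refitting engine reproduces the full pipeline exactly", {
  co <- simulate_cohort(small_config(seed = 37))
  fit <- mediate_survival(co, mediators = c("m1", "m2"))
  prep <- survmediate:::prepare_mediation(co)
  lean <- survmediate:::mediation_point(prep)
  keys <- c("direct", "indirect_m1", "indirect_m2", "total")
  expect_equal(lean[keys], coef(fit)[keys], tolerance = 1e-10)

  fit1 <- mediate_survival(co, mediators = "m1")
  prep1 <- survmediate:::prepare_mediation(co, mediators = "m1")
  lean1 <- survmediate:::mediation_point(prep1)
  expect_equal(lean1[c("direct", "indirect_m1")],
               coef(fit1)[c("direct", "indirect_m1")], tolerance = 1e-10)
})

test_that("a fully null generator yields near-null hazard ratios", {
  cfg <- null_path_config(seed = 38, n = 5000)
  cfg$outcome_coefs$exposure <- 0
  cfg$outcome_coefs$mediators[] <- 0
  co <- simulate_cohort(validate_cohort_config(cfg))
  fit <- mediate_survival(co, mediators = c("m1", "m2"))
  d <- fit$decomposition
  for (hr in c(d$hr_total, d$hr_direct, d$hr_indirect)) {
    expect_gt(hr, 0.9)
    expect_lt(hr, 1.1)
  }
})

test_that("fitting without weights or events is refused", {
  co <- simulate_cohort(small_config(seed = 39))
  ex <- expand_cohort(co, c("m1", "m2"))
  expect_error(fit_natural_effects(ex), "weights")
  co$event <- 0
  expect_error(mediate_survival(co, mediators = c("m1", "m2")), "events")
})

test_that("patient-level robust SEs are attached to the weighted fit", {
  co <- simulate_cohort(small_config(seed = 40))
  fit <- mediate_survival(co, mediators = c("m1", "m2"))
  se <- attr(fit$decomposition, "robust_se")
  expect_named(se, c("direct", "indirect_m1", "indirect_m2"))
  expect_true(all(is.finite(se) & se > 0))
})
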