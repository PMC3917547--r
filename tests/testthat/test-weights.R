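test_that("mediator model predictions are coherent probabilities", {
  mod <- mediator_model(c("(Intercept)" = 0.2, exposure = 0.5, ecog = -0.4),
                        mediator = "m1")
  nd <- data.frame(ecog = c(0, 1))
  p1 <- predict(mod, nd, a = 1, m = 1)
  p0 <- predict(mod, nd, a = 1, m = 0)
  expect_equal(p1 + p0, c(1, 1))
  expect_true(all(p1 > 0 & p1 < 1))
  expect_error(mediator_model(c(exposure = 1), "m1"), "Intercept")
})

test_that("the counterfactual weight equals the mediator-probability ratio", {
  # P(M=1|A=1) = 0.70, P(M=1|A=0) = 0.59; observed M=1, A=0, flipped A*=1
  mod <- mediator_model(c("(Intercept)" = qlogis(0.59),
                          exposure = qlogis(0.70) - qlogis(0.59)),
                        mediator = "m1")
  d <- data.frame(patient_id = 1, cluster_id = 1, exposure = 0, m1 = 1,
                  time = 10, event = 1)
  ex <- compute_weights(expand_cohort(d, "m1"), list(mod))
  expect_equal(ex$weight[ex$a_star == 0], 1)
  expect_equal(ex$weight[ex$a_star == 1], 0.70 / 0.59, tolerance = 1e-10)
})

test_that("expansion enumerates counterfactual patterns and projects back", {
  co <- simulate_cohort(small_config(seed = 21))
  ex <- expand_cohort(co, c("m1", "m2"))
  expect_equal(nrow(ex), 4 * nrow(co))
  combos <- tapply(paste(ex$a1_star, ex$a2_star),
                   ex$patient_id, function(x) length(unique(x)))
  expect_true(all(combos == 4))
  # factual replicate: counterfactual columns equal observed exposure
  factual <- ex[ex$a1_star == ex$exposure & ex$a2_star == ex$exposure, ]
  expect_equal(factual$replicate, rep(1L, nrow(co)))
  projected <- as.data.frame(factual[order(factual$patient_id), names(co)])
  rownames(projected) <- NULL
  expect_equal(projected, co, ignore_attr = TRUE)

  # single mediator on one exposed patient: stars are {1, 0}
  one <- data.frame(patient_id = 1, cluster_id = 1, exposure = 1, m1 = 1,
                    time = 5, event = 1)
  ex1 <- expand_cohort(one, "m1")
  expect_equal(nrow(ex1), 2)
  expect_setequal(ex1$a_star, c(1, 0))
})

test_that("null exposure coefficients force every weight to one", {
  co <- simulate_cohort(small_config(seed = 22))
  mods <- lapply(c("m1", "m2"), function(m) {
    mod <- fit_weight_model(co, m)
    mod$coef["exposure"] <- 0
    mod
  })
  ex <- compute_weights(expand_cohort(co, c("m1", "m2")), mods)
  expect_true(all(ex$weight == 1))
})

test_that("the factual replicate has weight exactly one under any fitted model", {
  co <- simulate_cohort(small_config(seed = 23))
  mods <- lapply(c("m1", "m2"), fit_weight_model, data = co)
  ex <- compute_weights(expand_cohort(co, c("m1", "m2")), mods)
  expect_true(all(ex$weight[ex$replicate == 1] == 1))
  expect_true(all(is.finite(ex$weight) & ex$weight > 0))
})

test_that("weight models recover their generating coefficients", {
  cfg <- flat_config(seed = 24, n = 10000)
  co <- simulate_cohort(cfg)
  mod <- fit_weight_model(co, "m2")
  truth <- c(cfg$mediator_coefs$m2$intercept, cfg$mediator_coefs$m2$exposure,
             cfg$mediator_coefs$m2$conf)
  co$age5 <- (co$age - cfg$confounder_spec$age_mean) / 5
  ref <- glm(m2 ~ exposure + age5 + ecog + ascites + comorbidity + histology + grade,
             family = binomial(), data = co)
  # joint Wald check of all 8 coefficients against the generating values
  delta <- mod$coef - truth
  wald <- drop(delta %*% solve(vcov(ref), delta))
  expect_lt(wald, qchisq(0.999, df = length(delta)))
  # exposure log-OR individually within 3 SE
  expect_lt(abs(delta[["exposure"]]) / sqrt(vcov(ref)["exposure", "exposure"]), 3)
})

test_that("degenerate weight-model inputs raise errors", {
  co <- simulate_cohort(small_config(seed = 25))
  co$m1 <- 0
  expect_error(fit_weight_model(co, "m1"), "constant")

  # positivity violation: probabilities pinned to 1 under the flip
  mod <- mediator_model(c("(Intercept)" = 50, exposure = -100), mediator = "m2")
  co2 <- simulate_cohort(small_config(seed = 25))
  ex <- expand_cohort(co2, "m2")
  expect_error(compute_weights(ex, list(mod)), "positivity")
})
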