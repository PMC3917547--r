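test_that("cohort CSV round-trips with the documented column order", {
  co <- simulate_cohort(small_config(seed = 51))
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_identical(names(back), survmediate:::cohort_column_order)
  expect_equal(back$time, co$time, tolerance = 1e-12)
  expect_identical(back$cluster_id, co$cluster_id)

  expect_error(write_cohort_csv(co[, -3], path), "missing columns")
  writeLines("a,b", path)
  expect_error(read_cohort_csv(path), "empty|missing")
  writeLines(character(0), tmp2 <- tempfile(fileext = ".csv"))
  expect_error(read_cohort_csv(tmp2))
})

test_that("simulation to disk is byte-identical across reruns", {
  cfg <- small_config(seed = 52, n_clusters = 20)
  d1 <- tempfile(); d2 <- tempfile()
  run_simulate(cfg, d1, oracle_draws = 2000)
  run_simulate(cfg, d2, oracle_draws = 2000)
  expect_identical(readLines(file.path(d1, "cohort.csv")),
                   readLines(file.path(d2, "cohort.csv")))
  expect_identical(readLines(file.path(d1, "truth.json")),
                   readLines(file.path(d2, "truth.json")))
  expect_equal(length(unique(read_cohort_csv(file.path(d1, "cohort.csv"))$cluster_id)),
               20)
})

test_that("cohort description reports arm counts and percentages", {
  co <- simulate_cohort(small_config(seed = 53))
  desc <- describe_cohort(co)
  expect_equal(desc$exposed$n + desc$unexposed$n, desc$n)
  expect_equal(desc$exposed$pct, round(100 * desc$exposed$n / desc$n, 1))
  expect_true(all(c("m1_pct", "m2_pct", "ecog_pct") %in% names(desc$exposed)))
})

test_that("the analysis pipeline writes a consistent JSON + text report", {
  cfg <- analysis_config(preset = "paper_like", n_resamples = 40, seed = 54,
                         output_dir = tempfile())
  rep <- run_analysis(cfg)
  json_path <- file.path(cfg$output_dir, "report.json")
  txt_path <- file.path(cfg$output_dir, "report.txt")
  expect_true(file.exists(json_path) && file.exists(txt_path))
  parsed <- jsonlite::read_json(json_path)
  expect_identical(parsed$schema_version, "1")
  expect_length(parsed$failures, 0)

  # rounded numbers in the text report equal those in the JSON report
  txt <- readLines(txt_path)
  dec <- parsed$decomposition
  expect_true(any(grepl(sprintf("total.*HR %.2f", dec$total$hr), txt)))
  expect_true(any(grepl(sprintf("direct.*HR %.2f", dec$direct$hr), txt)))
  expect_true(any(grepl(sprintf("prop_mediated_joint.*%d%%",
                                dec$prop_mediated_joint$percent), txt)))
  # decomposition identity survives 2-decimal report rounding
  expect_lt(abs(dec$total$hr - dec$direct$hr * dec$indirect_joint$hr), 0.02)

  # deterministic: same config, same bytes
  cfg2 <- analysis_config(preset = "paper_like", n_resamples = 40, seed = 54,
                          output_dir = tempfile())
  run_analysis(cfg2)
  expect_identical(readLines(json_path),
                   readLines(file.path(cfg2$output_dir, "report.json")))
})

test_that("analysis of a CSV input with one mediator works end to end", {
  co <- simulate_cohort(small_config(seed = 55))
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  cfg <- analysis_config(input = path, mediators = "m1", n_resamples = 20,
                         seed = 55, output_dir = tempfile())
  rep <- run_analysis(cfg)
  expect_length(rep$failures, 0)
  expect_named(rep$adherence, "m1")
  expect_true(!is.null(rep$decomposition$indirect_m1))
})

test_that("configuration errors are informative", {
  expect_error(analysis_config(), "input.*preset|preset.*input")
  expect_error(analysis_config(preset = "bogus"), "paper_like")
  cfg <- analysis_config(input = tempfile(fileext = ".csv"), n_resamples = 5,
                         output_dir = tempfile())
  expect_error(suppressWarnings(run_analysis(cfg)))
})
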