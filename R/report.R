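cohort_column_order <- c("patient_id", "cluster_id", "exposure", "m1", "m2",
                         "age", "ecog", "ascites", "comorbidity", "histology",
                         "grade", "time", "event")

#' Write / read a cohort table as CSV
#'
#' The CSV uses a fixed, documented column order: `patient_id, cluster_id,
#' exposure, m1, m2, age, ecog, ascites, comorbidity, histology, grade,
#' time, event`. Reading validates completeness (no missing values) and the
#' presence of all columns.
#'
#' @param data cohort `data.frame`.
#' @param path file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the cohort `data.frame`.
#' @export
write_cohort_csv <- function(data, path) {
  missing_cols <- setdiff(cohort_column_order, names(data))
  if (length(missing_cols))
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  utils::write.csv(data[, cohort_column_order], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  data <- utils::read.csv(path)
  if (nrow(data) == 0) stop("empty cohort file: ", path, call. = FALSE)
  missing_cols <- setdiff(cohort_column_order, names(data))
  if (length(missing_cols))
    stop("cohort file is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyNA(data)) stop("cohort file contains missing values", call. = FALSE)
  data[, cohort_column_order]
}

#' Cohort characteristics by exposure arm
#'
#' Counts and percentages by arm: patients, median age with IQR, binary
#' confounder prevalences, mediator adherence and observed deaths.
#' Percentages are rounded to one decimal.
#'
#' @param data cohort `data.frame`.
#' @param exposure,mediators,event column names.
#' @return a list with `n`, and per arm (`exposed`, `unexposed`): `n`,
#'   `pct`, `age_median`, `age_iqr`, per-confounder and per-mediator
#'   percentages, and `events`.
#' @export
describe_cohort <- function(data, exposure = "exposure",
                            mediators = c("m1", "m2"), event = "event") {
  n <- nrow(data)
  arm <- function(d) {
    out <- list(n = nrow(d), pct = pct(nrow(d), n),
                age_median = round(stats::median(d$age)),
                age_iqr = round(unname(stats::quantile(d$age, c(0.25, 0.75)))),
                events = sum(d[[event]]),
                event_pct = pct(sum(d[[event]]), nrow(d)))
    for (v in c("ecog", "ascites", "comorbidity", "histology", "grade"))
      out[[paste0(v, "_pct")]] <- pct(sum(d[[v]]), nrow(d))
    for (m in mediators)
      out[[paste0(m, "_pct")]] <- pct(sum(d[[m]]), nrow(d))
    out
  }
  list(n = n,
       exposed = arm(data[data[[exposure]] == 1, , drop = FALSE]),
       unexposed = arm(data[data[[exposure]] == 0, , drop = FALSE]))
}

#' Analysis configuration
#'
#' Bundles the inputs of [run_analysis()]: either a cohort CSV path or a
#' generator preset, the column mapping, the mediator list, bootstrap size,
#' seed and output directory. Column mapping defaults match the generator's
#' schema; map them to analyze an external cohort.
#'
#' @param input path to a cohort CSV, or `NULL` to use `preset`.
#' @param preset generator preset name (only `"paper_like"` is defined).
#' @param columns named list overriding any of `time`, `event`, `exposure`,
#'   `cluster`, `confounders` (character vector).
#' @param mediators 1 or 2 mediator column names.
#' @param n_resamples bootstrap resamples for the confidence intervals.
#' @param seed integer seed (generator and bootstrap).
#' @param output_dir directory for report files.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(input = NULL, preset = NULL,
                            columns = list(), mediators = c("m1", "m2"),
                            n_resamples = 10000, seed = 1L,
                            output_dir = tempdir()) {
  if (is.null(input) && is.null(preset))
    stop("either 'input' or 'preset' must be given", call. = FALSE)
  if (!is.null(preset) && !identical(preset, "paper_like"))
    stop(sprintf("unknown preset '%s'; available: paper_like", preset),
         call. = FALSE)
  defaults <- list(time = "time", event = "event", exposure = "exposure",
                   cluster = "cluster_id", patient_id = "patient_id",
                   confounders = c("age5", "ecog", "ascites", "comorbidity",
                                   "histology", "grade"))
  for (k in names(columns)) defaults[[k]] <- columns[[k]]
  structure(list(input = input, preset = preset, columns = defaults,
                 mediators = mediators, n_resamples = as.integer(n_resamples),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "analysis_config")
}

#' Simulate a cohort and its simulation truth to disk
#'
#' Writes `cohort.csv` ([write_cohort_csv()] schema) and `truth.json` (the
#' [counterfactual_truth()] hazard ratios) into `output_dir`. Deterministic
#' given the config: rerunning reproduces byte-identical files.
#'
#' @param config a [cohort_config()].
#' @param output_dir output directory, created if needed.
#' @param oracle_draws Monte-Carlo draws per regime for the truth.
#' @return invisibly, a list with the written paths and the cohort.
#' @export
run_simulate <- function(config, output_dir, oracle_draws = 1e5) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config)
  truth <- counterfactual_truth(config, mc_draws = oracle_draws,
                                seed = config$seed + 1L)
  cohort_path <- file.path(output_dir, "cohort.csv")
  truth_path <- file.path(output_dir, "truth.json")
  write_cohort_csv(cohort, cohort_path)
  jsonlite::write_json(unclass(truth), truth_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort_path, truth = truth_path, data = cohort))
}

#' Run the full mediation analysis and write a report
#'
#' End-to-end pipeline on a cohort CSV or a generator preset: cohort
#' characteristics, Kaplan-Meier medians per arm, the adjusted total-effect
#' Cox model, mediator adherence odds ratios, the natural-effect
#' decomposition and its cluster-bootstrap confidence intervals. Writes
#' `report.json` and `report.txt` (plus `km_curves.csv`) into the output
#' directory; every number in the text report appears in the JSON with the
#' same rounding (hazard/odds ratios to 2 decimals, arm percentages to one
#' decimal, proportions mediated to integer percent). Stage failures are
#' recorded in the report under `failures` and the partial report is still
#' written.
#'
#' @param config an [analysis_config()].
#' @param verbose log pipeline stages.
#' @return the report list, invisibly.
#' @export
run_analysis <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  cols <- config$columns
  data <- if (!is.null(config$input)) read_cohort_csv(config$input) else
    simulate_cohort(paper_like_config(seed = config$seed))
  stage_log(verbose, "input", "%d patients in %d clusters", nrow(data),
            length(unique(data[[cols$cluster]])))

  report <- list(schema_version = "1",
                 seed = config$seed, n_resamples = config$n_resamples,
                 failures = list())
  fail <- function(stage, e) {
    report$failures[[stage]] <<- conditionMessage(e)
    stage_log(TRUE, stage, "FAILED: %s", conditionMessage(e))
    NULL
  }

  report$cohort <- tryCatch(
    describe_cohort(data, exposure = cols$exposure,
                    mediators = config$mediators, event = cols$event),
    error = function(e) fail("cohort description", e))

  km <- tryCatch(kaplan_meier(data, time = cols$time, event = cols$event,
                              group = cols$exposure),
                 error = function(e) fail("kaplan-meier", e))
  if (!is.null(km)) {
    report$km_median_months <- as.list(attr(km, "medians"))
    utils::write.csv(as.data.frame(km), file.path(config$output_dir, "km_curves.csv"),
                     row.names = FALSE)
  }

  tot <- tryCatch(fit_total_effect(data, exposure = cols$exposure,
                                   confounders = cols$confounders,
                                   time = cols$time, event = cols$event,
                                   cluster = cols$cluster),
                  error = function(e) fail("total-effect Cox", e))
  if (!is.null(tot)) report$total_effect <- round_fit(tot)

  report$adherence <- list()
  for (m in config$mediators) {
    ad <- tryCatch(fit_adherence(data, m, exposure = cols$exposure,
                                 confounders = cols$confounders,
                                 cluster = cols$cluster),
                   error = function(e) fail(paste("adherence", m), e))
    if (!is.null(ad)) report$adherence[[m]] <- round_fit(ad)
  }

  fit <- tryCatch(mediate_survival(data, exposure = cols$exposure,
                                   mediators = config$mediators,
                                   confounders = cols$confounders,
                                   time = cols$time, event = cols$event,
                                   cluster = cols$cluster,
                                   patient_id = cols$patient_id,
                                   verbose = verbose),
                  error = function(e) fail("mediation", e))
  if (!is.null(fit)) {
    report$weight_summary <- as.list(round(fit$weight_summary, 3))
    bs <- tryCatch(cluster_bootstrap(fit, n_resamples = config$n_resamples,
                                     seed = config$seed),
                   error = function(e) fail("bootstrap", e))
    report$decomposition <- round_decomposition(fit$decomposition, bs)
  }

  json_path <- file.path(config$output_dir, "report.json")
  txt_path <- file.path(config$output_dir, "report.txt")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(render_report_text(report), txt_path)
  stage_log(verbose, "report", "written to %s", config$output_dir)
  invisible(report)
}

round_fit <- function(rf) {
  lapply(seq_len(nrow(rf)), function(i)
    list(term = rf$term[i], estimate = round(rf$exp_estimate[i], 2),
         conf_low = round(rf$conf_low[i], 2), conf_high = round(rf$conf_high[i], 2)))
}

round_decomposition <- function(d, bs) {
  ci <- function(effect) {
    if (is.null(bs)) return(list(conf_low = NA, conf_high = NA))
    row <- bs$summary[bs$summary$effect == effect, ]
    dg <- if (startsWith(effect, "prop_mediated")) NULL else 2
    if (is.null(dg))
      list(conf_low = round(100 * row$conf_low), conf_high = round(100 * row$conf_high))
    else
      list(conf_low = round(row$conf_low, dg), conf_high = round(row$conf_high, dg))
  }
  med <- names(d$hr_indirect)
  eff <- list(total = c(list(hr = round(d$hr_total, 2)), ci("total")),
              direct = c(list(hr = round(d$hr_direct, 2)), ci("direct")))
  for (m in med)
    eff[[paste0("indirect_", m)]] <-
      c(list(hr = round(d$hr_indirect[[m]], 2)), ci(paste0("indirect_", m)))
  eff$indirect_joint <- c(list(hr = round(d$hr_indirect_joint, 2)),
                          ci("indirect_joint"))
  for (m in med)
    eff[[paste0("prop_mediated_", m)]] <-
      c(list(percent = round(100 * d$prop_mediated[[m]])),
        ci(paste0("prop_mediated_", m)))
  eff$prop_mediated_joint <- c(list(percent = round(100 * d$prop_mediated_joint)),
                               ci("prop_mediated_joint"))
  eff
}

render_report_text <- function(report) {
  lines <- c("Mediation analysis report",
             sprintf("seed %d, %d bootstrap resamples", report$seed,
                     report$n_resamples), "")
  if (!is.null(report$cohort)) {
    co <- report$cohort
    lines <- c(lines, "Cohort:",
               sprintf("  %d patients; exposed %d (%s%%), unexposed %d (%s%%)",
                       co$n, co$exposed$n, co$exposed$pct,
                       co$unexposed$n, co$unexposed$pct),
               sprintf("  deaths: exposed %d (%s%%), unexposed %d (%s%%)",
                       co$exposed$events, co$exposed$event_pct,
                       co$unexposed$events, co$unexposed$event_pct), "")
  }
  if (!is.null(report$km_median_months)) {
    med <- report$km_median_months
    lines <- c(lines, "Median overall survival (months):",
               vapply(names(med), function(g)
                 sprintf("  group %s: %s", g,
                         if (is.na(med[[g]])) "not reached" else format(med[[g]])),
                 character(1)), "")
  }
  fit_lines <- function(title, terms, lab) {
    c(title, vapply(terms, function(tm)
      sprintf("  %-12s %s %.2f [%.2f; %.2f]", tm$term, lab, tm$estimate,
              tm$conf_low, tm$conf_high), character(1)), "")
  }
  if (!is.null(report$total_effect))
    lines <- c(lines, fit_lines("Total-effect Cox model (cluster-robust):",
                                report$total_effect, "HR"))
  for (m in names(report$adherence))
    lines <- c(lines, fit_lines(sprintf("Adherence model (%s):", m),
                                report$adherence[[m]], "OR"))
  if (!is.null(report$decomposition)) {
    dec <- report$decomposition
    lines <- c(lines, "Natural-effect decomposition (bootstrap 95% CI):")
    for (e in names(dec)) {
      x <- dec[[e]]
      if (!is.null(x$hr))
        lines <- c(lines, sprintf("  %-20s HR %.2f [%s; %s]", e, x$hr,
                                  format(x$conf_low), format(x$conf_high)))
      else
        lines <- c(lines, sprintf("  %-20s %d%% [%s%%; %s%%]", e, x$percent,
                                  format(x$conf_low), format(x$conf_high)))
    }
    lines <- c(lines, "")
  }
  if (length(report$failures)) {
    lines <- c(lines, "FAILED stages:",
               vapply(names(report$failures), function(s)
                 sprintf("  %s: %s", s, report$failures[[s]]), character(1)))
  }
  lines
}
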