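#' Proportion of a total effect mediated, on the log hazard-ratio scale
#'
#' `log(hr_indirect) / log(hr_total)`, the standard proportion-mediated
#' measure for hazard ratios. Undefined (`NA`) when the total hazard ratio
#' is 1, where the ratio of logs is 0/0.
#'
#' @param hr_indirect indirect-effect hazard ratio(s).
#' @param hr_total total-effect hazard ratio.
#' @return numeric fraction(s); multiply by 100 for percent.
#' @export
#' @examples
#' round(100 * proportion_mediated(0.93, 0.58))  # 13
proportion_mediated <- function(hr_indirect, hr_total) {
  if (abs(log(hr_total)) < .Machine$double.eps^0.5)
    return(rep(NA_real_, length(hr_indirect)))
  log(hr_indirect) / log(hr_total)
}

#' Assemble a natural-effect decomposition from hazard ratios
#'
#' Builds the decomposition container from a direct-effect hazard ratio and
#' one or two mediator-specific indirect hazard ratios. By construction the
#' total effect is the product of all components, the joint indirect effect
#' is the product of the indirect components, and proportions mediated are
#' ratios of log hazard ratios.
#'
#' @param hr_direct natural direct effect hazard ratio.
#' @param hr_indirect named vector of natural indirect hazard ratios, one
#'   per mediator.
#' @param confounders optional `regression_fit`-style table of the other
#'   covariates from the weighted fit.
#' @return an object of class `effect_decomposition` with elements
#'   `hr_total`, `hr_direct`, `hr_indirect`, `hr_indirect_joint`,
#'   `prop_mediated`, `prop_mediated_joint`, `confounders`.
#' @export
#' @examples
#' d <- effect_decomposition(0.67, c(surgery = 0.93, chemo = 0.93))
#' round(d$hr_total, 2)  # 0.58
effect_decomposition <- function(hr_direct, hr_indirect, confounders = NULL) {
  stopifnot(hr_direct > 0, all(hr_indirect > 0))
  if (is.null(names(hr_indirect)))
    names(hr_indirect) <- paste0("m", seq_along(hr_indirect))
  hr_joint <- prod(hr_indirect)
  hr_total <- hr_direct * hr_joint
  structure(
    list(hr_total = hr_total,
         hr_direct = hr_direct,
         hr_indirect = hr_indirect,
         hr_indirect_joint = hr_joint,
         prop_mediated = proportion_mediated(hr_indirect, hr_total),
         prop_mediated_joint = proportion_mediated(hr_joint, hr_total),
         confounders = confounders),
    class = "effect_decomposition")
}

#' @export
print.effect_decomposition <- function(x, digits = 2, ...) {
  cat("Natural-effect decomposition (hazard-ratio scale)\n")
  cat(sprintf("  Total effect            %.*f\n", digits, x$hr_total))
  cat(sprintf("  Direct effect           %.*f\n", digits, x$hr_direct))
  for (m in names(x$hr_indirect))
    cat(sprintf("  Indirect effect (%s)  %.*f\n", format(m, width = 4),
                digits, x$hr_indirect[[m]]))
  if (length(x$hr_indirect) > 1)
    cat(sprintf("  Indirect effect (joint) %.*f\n", digits, x$hr_indirect_joint))
  pm <- x$prop_mediated_joint
  if (!is.na(pm))
    cat(sprintf("  Proportion mediated     %d%% (log-HR scale)\n", round(100 * pm)))
  invisible(x)
}

#' Weighted Cox fit of natural direct and indirect effects
#'
#' Fits the natural-effects marginal structural Cox model on a weighted
#' expanded cohort: survival is regressed on the observed exposure, the
#' counterfactual exposure column(s) and the baseline confounders, with the
#' counterfactual mediator weights as row weights (Efron ties). The
#' exponentiated exposure coefficient is the natural direct effect; each
#' exponentiated counterfactual coefficient is the natural indirect effect
#' through the corresponding mediator; the total effect is their product.
#' A sandwich variance grouped by patient accounts for the `2^K` correlated
#' rows each patient contributes; hospital-level uncertainty is the job of
#' [cluster_bootstrap()].
#'
#' @param expanded a weighted `expanded_cohort` (see [compute_weights()]).
#' @param confounders confounder column names in the outcome model.
#' @param time,event,patient_id column names.
#' @return an `effect_decomposition` with the underlying [survival::coxph()]
#'   fit in attribute `fit` and patient-level robust log-scale SEs in
#'   attribute `robust_se`.
#' @export
fit_natural_effects <- function(expanded,
                                confounders = c("age5", "ecog", "ascites",
                                                "comorbidity", "histology", "grade"),
                                time = "time", event = "event",
                                patient_id = "patient_id") {
  if (!isTRUE(attr(expanded, "weights_set")))
    stop("weights are not set; call compute_weights() first", call. = FALSE)
  if (sum(expanded[[event]]) == 0) stop("no events in expanded data", call. = FALSE)
  exposure <- attr(expanded, "exposure")
  stars <- attr(expanded, "star_cols")
  mediators <- attr(expanded, "mediators")
  df <- model_data(as.data.frame(expanded), confounders)
  fml <- stats::as.formula(sprintf("survival::Surv(%s, %s) ~ %s", time, event,
                                   paste(c(exposure, stars, confounders), collapse = " + ")))
  .w <- df$weight
  .cl <- df[[patient_id]]
  fit <- survival::coxph(fml, data = df, weights = .w, ties = "efron",
                         robust = TRUE, cluster = .cl, model = FALSE)
  co <- fit$coefficients
  if (any(!is.finite(co)))
    stop("weighted Cox fit did not converge", call. = FALSE)
  hr_ind <- stats::setNames(exp(co[stars]), mediators)
  conf_tab <- new_regression_fit(co[confounders], sqrt(diag(stats::vcov(fit)))[confounders],
                                 family = "proportional-hazards",
                                 n = fit$n, events = fit$nevent)
  out <- effect_decomposition(exp(co[[exposure]]), hr_ind, confounders = conf_tab)
  attr(out, "fit") <- fit
  attr(out, "robust_se") <- stats::setNames(sqrt(diag(stats::vcov(fit)))[c(exposure, stars)],
                                            c("direct", paste0("indirect_", mediators)))
  out
}

#' Mediation analysis of a survival outcome with one or two binary mediators
#'
#' The main fitting function. Decomposes the total effect of a binary
#' exposure on a right-censored survival outcome into a natural direct
#' effect and mediator-specific natural indirect effects, assuming separate
#' causal pathways through the mediators:
#'
#' 1. fit a logistic weight model P(M_k | A, C) per mediator
#'    ([fit_weight_model()]);
#' 2. expand the data `2^K`-fold with counterfactual exposure columns
#'    ([expand_cohort()]);
#' 3. attach counterfactual weights
#'    `W = prod_k P(M_k | A_k*, C) / P(M_k | A, C)` ([compute_weights()]);
#' 4. run the weighted Cox regression of the outcome on exposure,
#'    counterfactual exposure(s) and confounders ([fit_natural_effects()]).
#'
#' @param data cohort `data.frame`, one row per patient, complete cases.
#' @param exposure name of the binary (0/1) exposure column.
#' @param mediators names of 1 or 2 binary mediator columns.
#' @param confounders names of the baseline confounder columns; `"age5"` is
#'   derived from an `age` column (per 5-year unit, centred) when absent.
#' @param time,event,cluster,patient_id column names; `patient_id` is
#'   created as the row index when missing.
#' @param max_weight_warn log a warning when any weight exceeds this value
#'   (weights are never truncated by default; truncation would change the
#'   estimand).
#' @param verbose log one line per pipeline stage.
#' @return an object of class `medsurv`: the `effect_decomposition` plus the
#'   fitted weight models, the expanded-table weight diagnostics, the data
#'   and the call. Methods: [print.medsurv()], [summary.medsurv()],
#'   [coef.medsurv()], [confint.medsurv()].
#' @export
#' @examples
#' cohort <- simulate_cohort(paper_like_config(seed = 3))
#' fit <- mediate_survival(cohort, mediators = c("m1", "m2"))
#' fit
mediate_survival <- function(data, exposure = "exposure",
                             mediators = c("m1", "m2"),
                             confounders = c("age5", "ecog", "ascites",
                                             "comorbidity", "histology", "grade"),
                             time = "time", event = "event",
                             cluster = "cluster_id", patient_id = "patient_id",
                             max_weight_warn = 10, verbose = FALSE) {
  cl <- match.call()
  if (!patient_id %in% names(data)) data[[patient_id]] <- seq_len(nrow(data))
  if (anyDuplicated(data[[patient_id]]))
    stop("patient_id must be unique per row", call. = FALSE)
  data <- model_data(data, confounders)

  models <- with_stage("weight models", lapply(mediators, function(m)
    fit_weight_model(data, m, exposure = exposure, confounders = confounders)))
  names(models) <- mediators
  stage_log(verbose, "weight models", "fitted %d logistic model(s) on %d patients",
            length(models), nrow(data))

  expanded <- with_stage("expansion", expand_cohort(data, mediators, exposure))
  stage_log(verbose, "expansion", "%d rows (%d replicates x %d patients)",
            nrow(expanded), 2^length(mediators), nrow(data))

  expanded <- with_stage("weights", compute_weights(expanded, models))
  wmin <- min(expanded$weight); wmean <- mean(expanded$weight)
  wmax <- max(expanded$weight)
  stage_log(verbose, "weights", "min/mean/max = %.3f/%.3f/%.3f", wmin, wmean, wmax)
  if (wmax > max_weight_warn)
    warning(sprintf("maximum counterfactual weight %.1f exceeds %g; consider the estimand implications before truncating",
                    wmax, max_weight_warn), call. = FALSE)

  dec <- with_stage("weighted Cox", fit_natural_effects(
    expanded, confounders = confounders, time = time, event = event,
    patient_id = patient_id))
  stage_log(verbose, "weighted Cox",
            "total HR %.3f = direct %.3f x joint indirect %.3f",
            dec$hr_total, dec$hr_direct, dec$hr_indirect_joint)

  structure(
    list(decomposition = dec,
         weight_models = models,
         weight_summary = c(min = wmin, mean = wmean, max = wmax),
         columns = list(exposure = exposure, mediators = mediators,
                        confounders = confounders, time = time, event = event,
                        cluster = cluster, patient_id = patient_id),
         data = data,
         n = nrow(data), events = sum(data[[event]]),
         call = cl),
    class = "medsurv")
}

#' @export
print.medsurv <- function(x, digits = 2, ...) {
  cat("Counterfactual mediation analysis for survival\n")
  cat(sprintf("  n = %d patients, %d events, mediators: %s\n\n", x$n, x$events,
              paste(x$columns$mediators, collapse = ", ")))
  print(x$decomposition, digits = digits)
  invisible(x)
}

#' @export
coef.medsurv <- function(object, ...) {
  d <- object$decomposition
  c(total = log(d$hr_total), direct = log(d$hr_direct),
    stats::setNames(log(d$hr_indirect), paste0("indirect_", names(d$hr_indirect))),
    indirect_joint = log(d$hr_indirect_joint))
}

#' Summarise a mediation fit
#'
#' @param object a `medsurv` fit.
#' @param ... unused.
#' @return the object, invisibly; prints the decomposition, proportions
#'   mediated, weight diagnostics and the confounder hazard ratios from the
#'   weighted model.
#' @export
summary.medsurv <- function(object, ...) {
  print(object)
  d <- object$decomposition
  cat("\nProportions mediated (log-HR scale):\n")
  pm <- c(stats::setNames(d$prop_mediated, names(d$hr_indirect)),
          joint = d$prop_mediated_joint)
  print(round(100 * pm), ...)
  cat(sprintf("\nWeights: min %.3f, mean %.3f, max %.3f\n",
              object$weight_summary["min"], object$weight_summary["mean"],
              object$weight_summary["max"]))
  cat("\nConfounders (weighted Cox):\n")
  print(d$confounders)
  invisible(object)
}

#' Bootstrap confidence intervals for a mediation fit
#'
#' Percentile intervals from the hospital-level cluster bootstrap; see
#' [cluster_bootstrap()].
#'
#' @param object a `medsurv` fit.
#' @param parm unused (all effects are returned).
#' @param level confidence level.
#' @param R number of cluster-bootstrap resamples.
#' @param seed integer seed for the resampling.
#' @param ... passed to [cluster_bootstrap()].
#' @return matrix of lower/upper bounds on the hazard-ratio scale, one row
#'   per effect.
#' @export
confint.medsurv <- function(object, parm, level = 0.95, R = 1000, seed = 1L, ...) {
  bs <- cluster_bootstrap(object, n_resamples = R, seed = seed, level = level, ...)
  as.matrix(bs$summary[, c("conf_low", "conf_high")])
}
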