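#' Kaplan-Meier survival curves, optionally by exposure group
#'
#' Product-limit estimate via [survival::survfit()], returned as a tidy
#' table. The median is the smallest observed time with survival <= 0.5 and
#' is `NA` when the curve never reaches 0.5.
#'
#' @param data a cohort `data.frame`.
#' @param time,event,group column names; `group = NULL` gives a single curve.
#' @return an object of class `km_curves`: a `data.frame` with columns
#'   `group`, `time`, `n_risk`, `n_event`, `survival`, and an attribute
#'   `medians` (named numeric, months).
#' @export
kaplan_meier <- function(data, time = "time", event = "event", group = NULL) {
  if (nrow(data) == 0) stop("empty cohort", call. = FALSE)
  g <- if (is.null(group)) factor(rep("all", nrow(data))) else factor(data[[group]])
  if (any(table(g) == 0) || nlevels(g) == 0)
    stop("each group must contain at least one record", call. = FALSE)
  sf <- survival::survfit(survival::Surv(data[[time]], data[[event]]) ~ g)
  sm <- summary(sf, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(g), length(sm$time)) else
    sub("^g=", "", as.character(sm$strata))
  out <- data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
                    n_event = sm$n.event, survival = sm$surv)
  medians <- vapply(split(out, out$group), function(d) {
    hit <- d$time[d$survival <= 0.5]
    if (length(hit)) min(hit) else NA_real_
  }, numeric(1))
  structure(out, medians = medians, class = c("km_curves", "data.frame"))
}

#' @export
print.km_curves <- function(x, ...) {
  med <- attr(x, "medians")
  cat("Kaplan-Meier curves:", length(med), "group(s)\n")
  for (g in names(med)) {
    cat(sprintf("  %s: %d steps, median %s months\n", g, sum(x$group == g),
                if (is.na(med[g])) "not reached" else format(med[g])))
  }
  invisible(x)
}

#' Plot Kaplan-Meier curves
#'
#' @param x a `km_curves` object.
#' @param col line colours, recycled over groups.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.km_curves <- function(x, col = seq_along(unique(x$group)), ...) {
  groups <- unique(x$group)
  graphics::plot(NA, xlim = c(0, max(x$time)), ylim = c(0, 1),
                 xlab = "Months", ylab = "Survival probability", ...)
  for (i in seq_along(groups)) {
    d <- x[x$group == groups[i], ]
    graphics::lines(c(0, d$time), c(1, d$survival), type = "s", col = col[i])
  }
  if (length(groups) > 1)
    graphics::legend("topright", legend = groups, col = col, lty = 1, bty = "n")
  invisible(x)
}

# Assemble the common regression-fit container from log-scale estimates and
# cluster-robust SEs.
new_regression_fit <- function(coef, se, family, n, events = NA_integer_,
                               level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(
    data.frame(term = names(coef),
               estimate = unname(coef),
               robust_se = unname(se),
               exp_estimate = exp(unname(coef)),
               conf_low = exp(unname(coef) - z * se),
               conf_high = exp(unname(coef) + z * se),
               row.names = NULL),
    family = family, n = n, events = events, class = c("regression_fit", "data.frame"))
}

#' @export
print.regression_fit <- function(x, digits = 2, ...) {
  fam <- attr(x, "family")
  lab <- if (fam == "proportional-hazards") "HR" else "OR"
  cat(sprintf("%s fit (cluster-robust SEs): n = %d%s\n",
              if (fam == "proportional-hazards") "Cox proportional hazards" else "Logistic",
              attr(x, "n"),
              if (!is.na(attr(x, "events"))) sprintf(", events = %d", attr(x, "events")) else ""))
  tab <- data.frame(term = x$term,
                    round(x[, c("exp_estimate", "conf_low", "conf_high")], digits))
  names(tab) <- c("term", lab, "lower95", "upper95")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Adjusted total-effect Cox model with cluster-robust variance
#'
#' Cox proportional hazards fit (Efron ties) of survival on exposure plus
#' confounders, with a sandwich variance grouped by cluster. This is the
#' "total effect" model against which the mediation decomposition is
#' compared.
#'
#' @param data cohort `data.frame`.
#' @param exposure,confounders,time,event,cluster column names.
#' @return a `regression_fit` (data.frame of terms with hazard ratios and
#'   95% Wald CIs on the log scale) with the underlying
#'   [survival::coxph()] fit in attribute `fit`.
#' @export
fit_total_effect <- function(data, exposure = "exposure",
                             confounders = c("age5", "ecog", "ascites",
                                             "comorbidity", "histology", "grade"),
                             time = "time", event = "event",
                             cluster = "cluster_id") {
  if (sum(data[[event]]) == 0) stop("no events in cohort", call. = FALSE)
  if (length(unique(data[[cluster]])) < 2)
    stop("at least 2 clusters are required", call. = FALSE)
  df <- model_data(data, confounders)
  fml <- stats::as.formula(sprintf("survival::Surv(%s, %s) ~ %s", time, event,
                                   paste(c(exposure, confounders), collapse = " + ")))
  .cl <- df[[cluster]]
  fit <- survival::coxph(fml, data = df, ties = "efron", robust = TRUE,
                         cluster = .cl, model = FALSE)
  if (any(!is.finite(fit$coefficients)))
    stop(sprintf("non-converged or separated covariate(s): %s",
                 paste(names(fit$coefficients)[!is.finite(fit$coefficients)],
                       collapse = ", ")), call. = FALSE)
  out <- new_regression_fit(fit$coefficients, sqrt(diag(stats::vcov(fit))),
                            family = "proportional-hazards",
                            n = fit$n, events = fit$nevent)
  attr(out, "fit") <- fit
  out
}

#' Mediator adherence model: cluster-robust logistic regression
#'
#' Logistic regression of a binary mediator on exposure and confounders.
#' Point estimates are ordinary maximum likelihood (equivalently, GEE with
#' an independence working correlation); standard errors are cluster-robust
#' sandwich estimates from [sandwich::vcovCL()]. With a single cluster the
#' sandwich degenerates to a one-group estimator; the fit still runs.
#'
#' @param data cohort `data.frame`.
#' @param mediator mediator column name (`"m1"` or `"m2"` for generated
#'   cohorts).
#' @param exposure,confounders,cluster column names.
#' @return a `regression_fit` with odds ratios and 95% CIs.
#' @export
fit_adherence <- function(data, mediator, exposure = "exposure",
                          confounders = c("age5", "ecog", "ascites",
                                          "comorbidity", "histology", "grade"),
                          cluster = "cluster_id") {
  if (length(unique(data[[mediator]])) < 2)
    stop(sprintf("mediator '%s' is constant", mediator), call. = FALSE)
  df <- model_data(data, confounders)
  fml <- stats::reformulate(c(exposure, confounders), response = mediator)
  fit <- stats::glm(fml, family = stats::binomial(), data = df)
  if (!fit$converged) stop("logistic model did not converge", call. = FALSE)
  cl_vec <- df[[cluster]]
  # with a single cluster the clustered meat is degenerate; fall back to the
  # observation-level sandwich
  vc <- if (length(unique(cl_vec)) < 2) sandwich::sandwich(fit) else
    sandwich::vcovCL(fit, cluster = cl_vec)
  out <- new_regression_fit(stats::coef(fit), sqrt(diag(vc)),
                            family = "logistic", n = nrow(df))
  attr(out, "fit") <- fit
  out
}

# Derive age5 (age per 5-year unit, centred at the cohort mean) when the
# model asks for it and the table carries raw age instead.
model_data <- function(data, confounders) {
  if ("age5" %in% confounders && !"age5" %in% names(data)) {
    if (!"age" %in% names(data))
      stop("neither 'age5' nor 'age' found in data", call. = FALSE)
    data$age5 <- (data$age - mean(data$age)) / 5
  }
  data
}
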