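#' Construct a mediator model from logistic coefficients
#'
#' A mediator model is the logistic regression P(M = 1 | A, C) used to build
#' counterfactual weights. Usually obtained by [fit_weight_model()]; this
#' constructor builds one directly from known coefficients, which is useful
#' for simulation truth checks and for degenerate cases (e.g. a zero
#' exposure coefficient forces all weights to 1).
#'
#' @param coef named numeric vector: `(Intercept)`, the exposure column, and
#'   any confounder columns.
#' @param mediator name of the mediator column this model describes.
#' @param exposure name of the exposure column.
#' @return an object of class `mediator_model`.
#' @export
mediator_model <- function(coef, mediator, exposure = "exposure") {
  stopifnot(is.numeric(coef), !is.null(names(coef)))
  if (!"(Intercept)" %in% names(coef))
    stop("coef must contain an '(Intercept)' term", call. = FALSE)
  if (!exposure %in% names(coef))
    stop(sprintf("coef must contain the exposure term '%s'", exposure), call. = FALSE)
  structure(list(coef = coef, mediator = mediator, exposure = exposure,
                 confounders = setdiff(names(coef), c("(Intercept)", exposure))),
            class = "mediator_model")
}

#' Fit the weight model for one mediator
#'
#' Plain (unweighted, unclustered) maximum-likelihood logistic regression of
#' the mediator on exposure and baseline confounders. Clustering is
#' deliberately ignored here: the working correlation does not change the
#' point estimates, and clustered uncertainty is handled downstream by the
#' cluster bootstrap.
#'
#' @param data cohort `data.frame`.
#' @param mediator mediator column name.
#' @param exposure,confounders column names entering the model.
#' @return a `mediator_model`.
#' @export
fit_weight_model <- function(data, mediator, exposure = "exposure",
                             confounders = c("age5", "ecog", "ascites",
                                             "comorbidity", "histology", "grade")) {
  if (length(unique(data[[mediator]])) < 2)
    stop(sprintf("mediator '%s' is constant; cannot fit a weight model", mediator),
         call. = FALSE)
  df <- model_data(data, confounders)
  fml <- stats::reformulate(c(exposure, confounders), response = mediator)
  fit <- stats::glm(fml, family = stats::binomial(), data = df)
  co <- stats::coef(fit)
  if (!fit$converged || any(!is.finite(co)) || any(abs(co) > 15))
    stop(sprintf("weight model for '%s' did not converge (possible separation)",
                 mediator), call. = FALSE)
  mediator_model(co, mediator = mediator, exposure = exposure)
}

#' @export
print.mediator_model <- function(x, ...) {
  cat(sprintf("Mediator model for '%s': logit P(%s = 1 | %s, C)\n",
              x$mediator, x$mediator, x$exposure))
  print(round(x$coef, 4))
  invisible(x)
}

#' Predicted mediator probabilities under a set exposure level
#'
#' Evaluates P(M = m | A = a, C) from a `mediator_model`, with the exposure
#' column overridden to `a` and confounders taken from `newdata`.
#'
#' @param object a `mediator_model`.
#' @param newdata `data.frame` holding the confounder columns.
#' @param a exposure level (scalar or vector) at which to evaluate.
#' @param m mediator value(s) whose probability is requested (default 1).
#' @param ... unused.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict.mediator_model <- function(object, newdata, a, m = 1, ...) {
  newdata <- model_data(newdata, object$confounders)
  eta <- object$coef[["(Intercept)"]] + object$coef[[object$exposure]] * a
  for (v in object$confounders) eta <- eta + object$coef[[v]] * newdata[[v]]
  p1 <- stats::plogis(eta)
  m <- rep_len(m, length(p1))
  ifelse(m == 1, p1, 1 - p1)
}

star_columns <- function(k) if (k == 1) "a_star" else paste0("a", seq_len(k), "_star")

#' Counterfactual expansion of a cohort
#'
#' Replicates every patient `2^K` times for `K` mediators and attaches
#' counterfactual exposure columns (`a_star` for one mediator, `a1_star`,
#' `a2_star` for two) that enumerate all combinations of "same as observed"
#' and "opposite of observed" exposure. Replicate 1 is the factual copy in
#' which every counterfactual column equals the observed exposure. Weights
#' are initialised to `NA` and set by [compute_weights()].
#'
#' @param data cohort `data.frame`.
#' @param mediators character vector of 1 or 2 mediator column names.
#' @param exposure exposure column name.
#' @return an `expanded_cohort` `data.frame`: all original columns plus
#'   `replicate`, the counterfactual columns and `weight`.
#' @export
expand_cohort <- function(data, mediators, exposure = "exposure") {
  k <- length(mediators)
  if (!k %in% c(1L, 2L)) stop("1 or 2 mediators are supported", call. = FALSE)
  if (!all(mediators %in% names(data)))
    stop("mediator column(s) not found in data", call. = FALSE)
  # flip pattern per replicate: 0 keeps the observed exposure, 1 flips it;
  # replicate 1 is always the factual copy
  flips <- if (k == 1) matrix(0:1, ncol = 1) else
    rbind(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  out <- do.call(rbind, lapply(seq_len(nrow(flips)), function(r) {
    d <- data
    d$replicate <- r
    a <- d[[exposure]]
    for (j in seq_len(k)) {
      d[[star_columns(k)[j]]] <- if (flips[r, j] == 1) 1L - a else a
    }
    d
  }))
  out$weight <- NA_real_
  rownames(out) <- NULL
  structure(out, mediators = mediators, exposure = exposure,
            star_cols = star_columns(k), weights_set = FALSE,
            class = c("expanded_cohort", "data.frame"))
}

#' Counterfactual mediator weights for an expanded cohort
#'
#' Sets the row weight
#' `W = prod_k P(M_k = m_k | A = a_k*, C) / P(M_k = m_k | A = a, C)`,
#' where `m_k` is the observed mediator value, `a` the observed exposure and
#' `a_k*` the row's counterfactual exposure for mediator `k`. Rows whose
#' counterfactual exposure equals the observed exposure contribute an exact
#' factor 1 for that mediator, so the factual replicate always has weight 1.
#'
#' @param expanded an `expanded_cohort` from [expand_cohort()].
#' @param models list of `mediator_model`s, one per mediator, in the order
#'   of `attr(expanded, "mediators")`.
#' @return the `expanded_cohort` with `weight` filled in; all weights are
#'   finite and positive.
#' @export
compute_weights <- function(expanded, models) {
  mediators <- attr(expanded, "mediators")
  stars <- attr(expanded, "star_cols")
  exposure <- attr(expanded, "exposure")
  if (length(models) != length(mediators))
    stop("need one mediator model per mediator", call. = FALSE)
  w <- rep(1, nrow(expanded))
  a_obs <- expanded[[exposure]]
  for (j in seq_along(mediators)) {
    mod <- models[[j]]
    if (!inherits(mod, "mediator_model"))
      stop("models must be 'mediator_model' objects", call. = FALSE)
    m_obs <- expanded[[mediators[j]]]
    a_star <- expanded[[stars[j]]]
    flip <- which(a_star != a_obs)
    if (length(flip)) {
      num <- predict(mod, expanded[flip, , drop = FALSE], a = a_star[flip],
                     m = m_obs[flip])
      den <- predict(mod, expanded[flip, , drop = FALSE], a = a_obs[flip],
                     m = m_obs[flip])
      eps <- 1e-12
      if (any(num <= eps | num >= 1 - eps | den <= eps | den >= 1 - eps))
        stop(sprintf("positivity violation in weight model for '%s'",
                     mediators[j]), call. = FALSE)
      w[flip] <- w[flip] * num / den
    }
  }
  if (any(!is.finite(w)) || any(w <= 0))
    stop("non-finite or non-positive weights", call. = FALSE)
  expanded$weight <- w
  attr(expanded, "weights_set") <- TRUE
  expanded
}
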