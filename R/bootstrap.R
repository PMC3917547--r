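# Lean refitting engine used by the cluster bootstrap and by simulation
# studies: the same estimator as mediate_survival() (logistic weight models
# by maximum likelihood, counterfactual expansion, weighted Efron Cox fit),
# computed on prebuilt design matrices via glm.fit / survival::coxph.fit,
# with no variance estimation. A unit test pins this path to the full one.

prepare_mediation <- function(data, exposure = "exposure",
                              mediators = c("m1", "m2"),
                              confounders = c("age5", "ecog", "ascites",
                                              "comorbidity", "histology", "grade"),
                              time = "time", event = "event",
                              cluster = "cluster_id") {
  data <- model_data(data, confounders)
  cmat <- as.matrix(data[, confounders, drop = FALSE])
  cl <- data[[cluster]]
  list(n = nrow(data),
       time = data[[time]], event = data[[event]],
       a = data[[exposure]],
       m = as.matrix(data[, mediators, drop = FALSE]),
       cmat = cmat,
       mediators = mediators,
       cluster_rows = split(seq_len(nrow(data)), cl))
}

# Point estimates of the natural-effect log hazard ratios on the patient
# rows `rows` (duplicates allowed, as produced by cluster resampling).
mediation_point <- function(prep, rows = seq_len(prep$n)) {
  a <- prep$a[rows]
  cmat <- prep$cmat[rows, , drop = FALSE]
  n <- length(rows)
  k <- length(prep$mediators)
  xmed <- cbind(1, a, cmat)

  # per-mediator flip factor P(M = m_obs | A = 1 - a, C) / P(M = m_obs | A = a, C)
  flip_factor <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    m <- prep$m[rows, j]
    gf <- suppressWarnings(stats::glm.fit(xmed, m, family = stats::binomial()))
    beta <- gf$coefficients
    if (!gf$converged || any(!is.finite(beta)) || any(abs(beta) > 15))
      stop("weight model did not converge", call. = FALSE)
    eta0 <- beta[1] + drop(cmat %*% beta[-(1:2)])
    p1 <- stats::plogis(eta0 + beta[2])
    p0 <- stats::plogis(eta0)
    p_at <- function(aa) ifelse(m == 1, ifelse(aa == 1, p1, p0),
                                1 - ifelse(aa == 1, p1, p0))
    num <- p_at(1 - a); den <- p_at(a)
    if (any(den < 1e-12) || any(num < 1e-12))
      stop("positivity violation in weight model", call. = FALSE)
    flip_factor[, j] <- num / den
  }

  # expanded design: replicates enumerate flip patterns, factual first
  flips <- if (k == 1) matrix(0:1, ncol = 1) else
    rbind(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  nrep <- nrow(flips)
  xo <- matrix(NA_real_, n * nrep, 1 + k + ncol(cmat))
  w <- numeric(n * nrep)
  for (r in seq_len(nrep)) {
    idx <- (r - 1L) * n + seq_len(n)
    stars <- vapply(seq_len(k), function(j)
      if (flips[r, j] == 1) 1 - a else a, numeric(n))
    xo[idx, ] <- cbind(a, stars, cmat)
    wr <- rep(1, n)
    for (j in seq_len(k)) if (flips[r, j] == 1) wr <- wr * flip_factor[, j]
    w[idx] <- wr
  }
  colnames(xo) <- c("a", if (k == 1) "a_star" else paste0("a", 1:k, "_star"),
                    colnames(prep$cmat))
  y <- survival::Surv(rep(prep$time[rows], nrep), rep(prep$event[rows], nrep))
  fit <- suppressWarnings(
    survival::coxph.fit(xo, y, strata = NULL, offset = NULL, init = NULL,
                        control = survival::coxph.control(),
                        weights = w, method = "efron", rownames = NULL))
  beta <- fit$coefficients
  # abs(beta) > 15 flags monotone-likelihood pseudo-infinite coefficients
  if (any(!is.finite(beta)) || any(abs(beta) > 15))
    stop("weighted Cox fit did not converge", call. = FALSE)
  log_direct <- beta[["a"]]
  log_ind <- beta[2:(k + 1)]
  names(log_ind) <- prep$mediators
  c(direct = log_direct, stats::setNames(log_ind, paste0("indirect_", prep$mediators)),
    indirect_joint = sum(log_ind), total = log_direct + sum(log_ind))
}

boot_effect_names <- function(mediators) {
  c("total", "direct", paste0("indirect_", mediators), "indirect_joint",
    paste0("prop_mediated_", mediators), "prop_mediated_joint")
}

#' Cluster bootstrap confidence intervals for natural effects
#'
#' Simple random cluster sampling: each resample draws the original number
#' of clusters (hospitals) with replacement, carries every patient of each
#' drawn cluster (duplicate clusters act as distinct clusters), refits the
#' complete estimator — weight models and weighted Cox — on the resample,
#' and records all effects. Confidence intervals are percentile intervals
#' over the successful resamples; proportions mediated are computed within
#' each resample before taking percentiles. Non-converged resamples are
#' skipped and counted, with a warning when they exceed 5% of the requested
#' resamples. Deterministic given the seed.
#'
#' @param object a `medsurv` fit from [mediate_survival()].
#' @param n_resamples number of bootstrap resamples (default 10000; use a
#'   few hundred for quick interactive runs).
#' @param seed integer seed.
#' @param level confidence level for the percentile intervals.
#' @param keep_resamples keep the per-resample log-scale draws (matrix) for
#'   diagnostics.
#' @return an object of class `medsurv_boot`: `summary` (data.frame with
#'   effect, point estimate, lower and upper bounds — hazard-ratio scale for
#'   effects, fraction scale for proportions mediated), `n_resamples`,
#'   `n_failed`, `seed`, `level`, and optionally `draws`.
#' @export
#' @examples
#' cohort <- simulate_cohort(paper_like_config(seed = 3))
#' fit <- mediate_survival(cohort, mediators = c("m1", "m2"))
#' cluster_bootstrap(fit, n_resamples = 50, seed = 1)
cluster_bootstrap <- function(object, n_resamples = 10000, seed = 1L,
                              level = 0.95, keep_resamples = FALSE) {
  stopifnot(inherits(object, "medsurv"), n_resamples >= 1)
  cols <- object$columns
  prep <- prepare_mediation(object$data, exposure = cols$exposure,
                            mediators = cols$mediators,
                            confounders = cols$confounders,
                            time = cols$time, event = cols$event,
                            cluster = cols$cluster)
  n_cl <- length(prep$cluster_rows)
  k <- length(cols$mediators)

  draws <- with_seed(seed, {
    idx_mat <- matrix(sample.int(n_cl, n_cl * n_resamples, replace = TRUE),
                      nrow = n_cl)
    out <- matrix(NA_real_, n_resamples, 3 + k)
    for (b in seq_len(n_resamples)) {
      rows <- unlist(prep$cluster_rows[idx_mat[, b]], use.names = FALSE)
      est <- tryCatch(mediation_point(prep, rows), error = function(e) NULL)
      if (!is.null(est)) out[b, ] <- est
    }
    colnames(out) <- names(mediation_point(prep, seq_len(prep$n)))
    out
  })

  ok <- stats::complete.cases(draws)
  n_failed <- sum(!ok)
  if (n_failed == n_resamples)
    stop("all bootstrap resamples failed", call. = FALSE)
  if (n_failed >= 0.05 * n_resamples)
    warning(sprintf("%d of %d bootstrap resamples failed to converge",
                    n_failed, n_resamples), call. = FALSE)
  good <- draws[ok, , drop = FALSE]

  # per-resample proportions mediated (log-ratio transform within resample)
  pm_cols <- sweep(good[, grep("^indirect", colnames(good)), drop = FALSE],
                   1, good[, "total"], "/")
  pm_cols[abs(good[, "total"]) < .Machine$double.eps^0.5, ] <- NA
  colnames(pm_cols) <- sub("^indirect", "prop_mediated", colnames(pm_cols))

  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qr <- function(v) stats::quantile(v, probs, na.rm = TRUE, names = FALSE)

  d <- object$decomposition
  med <- cols$mediators
  point <- c(total = d$hr_total, direct = d$hr_direct,
             stats::setNames(unname(d$hr_indirect), paste0("indirect_", med)),
             indirect_joint = d$hr_indirect_joint,
             stats::setNames(unname(d$prop_mediated), paste0("prop_mediated_", med)),
             prop_mediated_joint = d$prop_mediated_joint)
  eff <- boot_effect_names(med)
  lo <- hi <- numeric(length(eff)); names(lo) <- names(hi) <- eff
  for (e in eff) {
    v <- if (startsWith(e, "prop_mediated")) {
      pm_cols[, sub("^prop_mediated", "prop_mediated", e)]
    } else exp(good[, e])
    b <- qr(v); lo[e] <- b[1]; hi[e] <- b[2]
  }
  summary_df <- data.frame(effect = eff, point = unname(point[eff]),
                           conf_low = unname(lo), conf_high = unname(hi),
                           row.names = NULL)
  structure(list(summary = summary_df, n_resamples = n_resamples,
                 n_failed = n_failed, seed = as.integer(seed), level = level,
                 draws = if (keep_resamples) draws else NULL),
            class = "medsurv_boot")
}

#' @export
print.medsurv_boot <- function(x, digits = 2, ...) {
  cat(sprintf("Cluster bootstrap: %d resamples (%d failed), %.0f%% percentile intervals, seed %d\n",
              x$n_resamples, x$n_failed, 100 * x$level, x$seed))
  tab <- x$summary
  is_pm <- startsWith(tab$effect, "prop_mediated")
  shown <- tab
  shown[is_pm, c("point", "conf_low", "conf_high")] <-
    round(100 * shown[is_pm, c("point", "conf_low", "conf_high")])
  shown[!is_pm, c("point", "conf_low", "conf_high")] <-
    round(shown[!is_pm, c("point", "conf_low", "conf_high")], digits)
  shown$effect[is_pm] <- paste0(shown$effect[is_pm], " (%)")
  print(shown, row.names = FALSE)
  invisible(x)
}
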