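---
title: "Counterfactual mediation analysis for survival outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual mediation analysis for survival outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survmediate)
```

## The problem

Observational oncology cohorts often show that *where* a patient is treated
changes survival: for instance, patients with advanced ovarian cancer treated
in research-active hospitals live longer than patients in hospitals that do
not take part in clinical trials. The pragmatic question "does it work?" is
answered by a total-effect hazard ratio; the mechanistic question "how does
it work?" requires splitting that total effect into

* a **natural direct effect** — the effect that would remain if the exposure
  could be changed without changing the candidate mediators, and
* **natural indirect effects** — the parts transmitted by letting each
  mediator respond to the exposure (e.g. more complete surgical debulking, or
  guideline-adherent platinum–taxane chemotherapy) without touching the
  exposure itself.

Classical product- and difference-of-coefficients mediation does not carry
over to censored time-to-event outcomes. `survmediate` implements a
counterfactual-weighting estimator tailored to survival data with one or two
binary mediators, a binary (here: hospital-level) exposure and baseline
confounders.

## The estimator

Write $A$ for the exposure, $M_1, M_2$ for binary mediators, $C$ for
baseline confounders and $T$ for survival time. Under a cluster-level
exposure, conditional exchangeability given $C$ for the exposure–outcome,
exposure–mediator and mediator–outcome relations, positivity, and separate
causal pathways through the two mediators (no $M_1 \to M_2$ path), the
natural effects are estimable by:

1. **Weight models.** For each mediator, an ordinary logistic regression
   $\operatorname{logit} P(M_k = 1 \mid A, C)$. Point estimates are what
   matter here, so these are plain maximum-likelihood fits; clustered
   uncertainty is handled later by the bootstrap.
2. **Counterfactual expansion.** Each patient is replicated $2^K$ times
   ($K$ = number of mediators) with counterfactual exposure columns
   $A_1^*, A_2^*$ enumerating "same as observed" / "opposite of observed"
   per mediator. The first replicate is the factual copy.
3. **Weights.** Each row receives
   $W = \prod_k P(M_k = m_k \mid A = a_k^*, C)\,/\,P(M_k = m_k \mid A = a, C)$
   with $m_k$, $a$ the observed values. A mediator whose counterfactual
   column equals the observed exposure contributes an exact factor 1, so the
   factual replicate always has weight 1. Weights are never truncated by
   default (truncation changes the estimand); a warning is logged when the
   maximum weight exceeds 10.
4. **Weighted Cox fit.** A weighted proportional-hazards regression (Efron
   ties) of the outcome on $A$, $A_1^*$, $A_2^*$ and $C$. Then
   $\exp(\beta_A)$ is the natural direct effect, $\exp(\beta_{A_k^*})$ the
   indirect effect through mediator $k$, and the total effect is the product
   of all three, exactly, by construction. The proportion mediated is the
   ratio of log hazard ratios,
   $\log \mathrm{HR}_{\text{indirect}} / \log \mathrm{HR}_{\text{total}}$,
   and is reported as undefined when the total hazard ratio is 1.

The point-estimate fit carries a sandwich variance grouped by *patient*
(each patient contributes $2^K$ correlated rows). Between-hospital
correlation is deliberately delegated to the cluster bootstrap: hospitals
are resampled with replacement (as many as in the original data, duplicates
treated as distinct hospitals), the entire estimator — weight models
included — is refitted on every resample, and percentile intervals are taken
over the successful resamples. Proportion-mediated intervals apply the
log-ratio transform within each resample. Percentile intervals were chosen
over normal-approximation or BCa intervals as the simplest scheme consistent
with plain resampling; failed resamples are skipped and counted, with a
warning beyond 5%.

```{r fit}
cohort <- simulate_cohort(paper_like_config(seed = 11))
fit <- mediate_survival(cohort, mediators = c("m1", "m2"))
fit
cluster_bootstrap(fit, n_resamples = 200, seed = 1)
```

(Use `n_resamples = 10000` for production intervals; 200 keeps this vignette
quick.)

## The synthetic cohort generator

No patient-level data ships with the package; the generator produces
clustered cohorts with a known causal structure so that every stage is
testable end to end. Mechanism, per `cohort_config()`:

* clusters (hospitals) with sizes drawn from `cluster_size_range`, uniformly
  or with explicit weights;
* a cluster-level Bernoulli exposure;
* six baseline confounders: age $\sim N(\mu, \sigma)$ in years, entered into
  every model per 5-year unit centred at the generating mean, plus five
  Bernoulli indicators (performance status, ascites, comorbidity, histology,
  grade);
* mediators $M_1, M_2$ drawn independently from logistic models in $(A, C)$;
* exponential event times with hazard
  $\lambda_0 \exp(\beta_A A + \beta_1 M_1 + \beta_2 M_2 + \beta_C' C + u)$,
  where $u$ is an optional log-normal cluster frailty (default sd 0, so that
  robust-variance behaviour can be probed separately);
* administrative censoring at 36 months and nothing else — the generator
  deliberately has no dropout, so non-informative-censoring violations are
  out of its scope.

The exponential law is the simplest one consistent with proportional
hazards and gives closed-form sanity checks. The `paper_like_config()`
preset emulates a German ovarian-cancer quality-assurance cohort: 149
hospitals with 1–12 patients each and median 2 (a truncated-geometric size
distribution with ratio 0.6 — a uniform distribution cannot produce that
skew), 62% of patients in exposed clusters, adherence margins near 54%/66%
and 59%/70% by arm, about half of the patients dying within the window, a
direct-effect hazard ratio of 0.67 and mediator hazard ratios of 0.46 and
0.42. The two mediator-model intercepts and the baseline hazard
(0.0317/month) were calibrated once, by large-sample simulation, to the
unexposed-arm adherence margins and the ~52% three-year event fraction;
they are fixed constants of the preset, not tuning knobs.

What the generator does *not* emulate: socioeconomic or other unmeasured
confounding, informative censoring, mediator misclassification,
exposure–mediator interactions, and any $M_1 \to M_2$ pathway. Passing
tests therefore demonstrate internal validity of the estimator under its
stated assumptions, not robustness to their violation in real registries.

## The counterfactual oracle

`counterfactual_truth()` is the brute-force referent for the simulation
studies: for each of the eight regimes $(a, a_1, a_2) \in \{0,1\}^3$ it
draws nested counterfactual times $T(a, M_1(a_1), M_2(a_2))$ directly from
the mechanism and fits one Cox model of the pooled times on
$(a, a_1, a_2, C)$.

Two choices deserve a note. First, the oracle fit conditions on $C$,
because hazard ratios are non-collapsible: the estimator's weighted Cox
model conditions on $C$, and truth and estimator must target the same
conditional parameter. Second, mediator mixing makes the counterfactual
hazards non-proportional in $(a, a_1, a_2)$, so the fitted coefficients
are working-model quantities that depend on the follow-up window; the
oracle therefore truncates the counterfactual times at the configured
administrative horizon (36 months for the preset) so that both routes
refer to the same study window. `horizon = Inf` gives untruncated times.
Neither choice involves censoring noise: every oracle observation is an
event inside the window or censored exactly at the horizon.

## Numerical choices and degenerate inputs

* Ties: Efron approximation throughout (month-resolution times make ties
  likely in real data).
* Weight positivity: predicted mediator probabilities within `1e-12` of 0
  or 1 abort with a positivity error rather than producing huge weights.
* Separation: weight models abort when the IRLS fit fails to converge or a
  coefficient exceeds 15 on the logit scale.
* Constant mediators, zero events, fewer than two clusters: explicit errors.
* Single-cluster adherence models fall back to the observation-level
  sandwich; a single-cluster bootstrap degenerates to zero-width intervals.
* Determinism: a config carries its seed; the generator, oracle and
  bootstrap restore the session RNG state after use.

## Simulation-study scale

The validation suite runs three studies, sized for a desk machine:

* *Bias:* 200 cohorts of ≈5,000 patients (2,120 clusters of the preset
  mechanism); mean bias of the direct and indirect log hazard ratios is
  compared with the oracle (300,000 draws per regime) at 3 combined
  Monte-Carlo standard errors.
* *Coverage:* 200 cohorts at study scale (149 hospitals) with 500
  bootstrap resamples each; 95% percentile intervals for the direct log
  hazard ratio are expected to cover the oracle value in 90–99% of cohorts.
  (Production analyses should use 10,000 resamples; 500 is a deliberate
  desk-scale compromise whose slight undercoverage the band accommodates.)
* *Null paths:* with zero exposure→mediator coefficients all weights are
  exactly 1 and indirect hazard ratios concentrate near 1.

The bootstrap inside these loops uses an internal lean refitting path
(`glm.fit`/`coxph.fit` on prebuilt design matrices) that is pinned to the
user-facing pipeline by an exactness test.

## Limitations

Everything rests on no-unmeasured-confounding for all three relations and
on separate mediator pathways; both are untestable from data. The weighted
Cox natural-effects model is a working model when mediators mix hazards,
so effects are window-specific summaries. Ordinal or continuous mediators,
exposure–mediator interaction in the outcome model, and time-varying
exposures or mediators are out of scope.
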