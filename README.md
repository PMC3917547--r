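# survmediate

Causal mediation analysis for right-censored survival outcomes with one or
two binary mediators. `survmediate` answers "how does it work?" for
exposure–survival effects: it decomposes a total exposure hazard ratio into
a **natural direct effect** and mediator-specific **natural indirect
effects** using counterfactual data expansion, mediator-model weights and
weighted Cox regression, with cluster-bootstrap percentile confidence
intervals for clustered (e.g. hospital-level) exposures.

The motivating setting is hospital research activity and ovarian-cancer
survival: patients in research-active hospitals survive longer, and part of
that benefit flows through better guideline adherence — more complete
surgical debulking and platinum–taxane chemotherapy.

## Method in brief

For exposure $A$, binary mediators $M_1, M_2$, confounders $C$ and survival
time $T$, assuming separate causal pathways through the mediators:

1. fit logistic weight models $P(M_k = 1 \mid A, C)$;
2. replicate every patient $2^K$ times with counterfactual exposure columns
   $A_1^\*, A_2^\*$ enumerating same/opposite of the observed exposure;
3. weight each row by
   $W = \prod_k P(M_k = m_k \mid A = a_k^\*, C) / P(M_k = m_k \mid A = a, C)$;
4. fit a weighted Cox model of $T$ on $A, A_1^\*, A_2^\*, C$.

Then $\exp(\beta_A)$ is the natural direct hazard ratio,
$\exp(\beta_{A_k^\*})$ the indirect hazard ratio through mediator $k$, and
the total effect is their product — e.g. a direct 0.67 with two indirect
0.93s composes to a total of $0.67 \times 0.93 \times 0.93 = 0.58$. The
proportion mediated is the ratio of log hazard ratios. Confidence intervals
come from resampling whole clusters with replacement and refitting the
entire estimator per resample.

Because no patient-level cohort of this kind is publicly deposited, the
package ships a clustered synthetic-cohort generator
(`paper_like_config()`, `simulate_cohort()`) emulating the study margins
(149 hospitals of 1–12 patients, ~62% exposed patients, ~52% deaths in 36
months) and a brute-force counterfactual oracle
(`counterfactual_truth()`) that computes the true natural effects of any
generator configuration by Monte-Carlo simulation of nested counterfactual
event times — the referent for the package's bias and coverage studies.

## Worked example

```r
library(survmediate)

cohort <- simulate_cohort(paper_like_config(seed = 11))
fit <- mediate_survival(cohort, mediators = c("m1", "m2"))
fit
#> Counterfactual mediation analysis for survival
#>   n = 313 patients, 161 events, mediators: m1, m2
#>
#> Natural-effect decomposition (hazard-ratio scale)
#>   Total effect            0.66
#>   Direct effect           0.75
#>   Indirect effect (m1  )  0.96
#>   Indirect effect (m2  )  0.92
#>   Indirect effect (joint) 0.88
#>   Proportion mediated     31% (log-HR scale)

cluster_bootstrap(fit, n_resamples = 10000, seed = 2)
```

Reading: on this simulated cohort the exposure reduces the death hazard by
34% in total (HR 0.66); holding both mediators at their unexposed values
would still reduce it by 25% (direct HR 0.75), and letting each mediator
respond to the exposure contributes indirect HRs of 0.96 and 0.92. By
construction 0.75 × 0.96 × 0.92 = 0.66, and 31% of the total log-hazard
effect flows through the two mediators combined. The
bootstrap output adds 95% percentile intervals per effect. Lower-level
steps (`fit_weight_model()`, `expand_cohort()`, `compute_weights()`,
`fit_natural_effects()`) are exported for audit, as are Kaplan-Meier
(`kaplan_meier()`) and cluster-robust total-effect/adherence models
(`fit_total_effect()`, `fit_adherence()`). `run_analysis()` produces a
full JSON + text report; `inst/cli/survmediate.R` wraps simulation and
analysis for the shell.

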