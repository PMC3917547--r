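# Shared fixtures: small configs, a hand-built micro cohort, and a cached
# oracle truth for the calibrated preset (expensive, computed once per run).

small_config <- function(seed = 1L, n_clusters = 60, ...) {
  paper_like_config(seed = seed, n_clusters = n_clusters, ...)
}

# many small clusters of fixed size 2 -> n patients
flat_config <- function(seed = 1L, n = 5000, ...) {
  paper_like_config(seed = seed, n_clusters = as.integer(n / 2),
                    cluster_size_range = c(2L, 2L), cluster_size_probs = NULL,
                    ...)
}

# config with no exposure -> mediator paths (null indirect effects)
null_path_config <- function(seed = 1L, n = 5000) {
  cfg <- flat_config(seed = seed, n = n)
  cfg$mediator_coefs$m1$exposure <- 0
  cfg$mediator_coefs$m2$exposure <- 0
  validate_cohort_config(cfg)
}

# deterministic micro cohort built by hand (no generator involved)
micro_cohort <- function(n = 40, seed = 42) {
  set.seed(seed)
  cl <- rep(1:10, each = n / 10)
  a <- c(1, 0, 1, 0, 1, 1, 0, 0, 1, 0)[cl]
  data.frame(patient_id = 1:n, cluster_id = cl, exposure = a,
             m1 = rbinom(n, 1, 0.5 + 0.1 * a), m2 = rbinom(n, 1, 0.6),
             age = round(rnorm(n, 65, 10)), ecog = rbinom(n, 1, 0.25),
             ascites = rbinom(n, 1, 0.5), comorbidity = rbinom(n, 1, 0.3),
             histology = rbinom(n, 1, 0.75), grade = rbinom(n, 1, 0.5),
             time = round(rexp(n, 0.04), 1) + 0.1, event = rbinom(n, 1, 0.6))
}

.truth_cache <- new.env(parent = emptyenv())

# oracle truth for the calibrated preset, shared by the simulation studies
preset_truth <- function() {
  if (is.null(.truth_cache$truth)) {
    .truth_cache$truth <- counterfactual_truth(paper_like_config(seed = 1),
                                               mc_draws = 3e5, seed = 909L)
  }
  .truth_cache$truth
}
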