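# Shared, lazily computed fixtures. The cohort simulation is the expensive
# part of the suite, so the default study cohort (30 neurons per type,
# jitter 0.1, seed 1) is simulated once and reused by every test that needs
# it; template (unjittered) neurons are cached the same way.

.fixture_env <- new.env(parent = emptyenv())

cohort_fixture <- function() {
  if (is.null(.fixture_env$cohort)) {
    cohort <- make_cohort(c(I = 30, II = 30, III = 30, Others = 30),
                          jitter = 0.1, seed = 1)
    fx <- cohort_features(cohort)
    .fixture_env$cohort <- list(cohort = cohort,
                                features = classify_neurons(fx$features),
                                step_features = fx$step_features)
  }
  .fixture_env$cohort
}

template_sims <- function(phenotype) {
  key <- paste0("tmpl_", phenotype)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <-
      simulate_neuron(phenotype_template(phenotype))
  }
  .fixture_env[[key]]
}

template_features <- function(phenotype) {
  key <- paste0("feat_", phenotype)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- extract_features(template_sims(phenotype))
  }
  .fixture_env[[key]]
}
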