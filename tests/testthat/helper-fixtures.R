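# Shared fixtures, generated once per test run and cached across files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small cohort exercising all channels, decoys, and misspellings
fixture_cohort <- function() {
  cached("cohort_small", generate_cohort(sim_config(n_patients = 80L,
                                                    seed = 101L)))
}

# noise-free cohort: no misspellings, exact surfaces
fixture_cohort_clean <- function() {
  cached("cohort_clean", generate_cohort(sim_config(
    n_patients = 60L, misspelling_rate = 0, seed = 102L)))
}

# larger cohort for negation-corpus sampling
fixture_corpus_cohort <- function() {
  cached("cohort_corpus", generate_cohort(sim_config(n_patients = 400L,
                                                     seed = 202L)))
}

fixture_corpus <- function() {
  cached("corpus", emit_negation_corpus(fixture_corpus_cohort(),
                                        n_es = 572L, n_ca = 277L,
                                        heldout_frac = 0.25, seed = 5L))
}

# compact CRF trained on a subset, enough to tag template sentences
fixture_model <- function() {
  cached("model", {
    train <- fixture_corpus()$train
    train_tagger(train[seq_len(min(300L, length(train)))], maxit = 150L)
  })
}

fixture_lexicon <- function() {
  cached("lexicon", combine_lexicons(default_drug_lexicon(),
                                     default_disorder_lexicon()))
}

fixture_pipeline <- function() {
  cached("pipeline", run_pipeline(fixture_cohort(), negation = "rule"))
}
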