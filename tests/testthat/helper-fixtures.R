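# Minimal metadata construction for unit tests.
make_samples <- function(sample_id, subject_id,
                         dataset_id = "D01", body_site = "gut",
                         collection_day = 0L, age_years = 30,
                         household_id = NA_character_,
                         village_id = NA_character_,
                         mother_id = NA_character_,
                         father_id = NA_character_,
                         westernized = TRUE) {
  data.frame(sample_id = sample_id, subject_id = subject_id,
             dataset_id = dataset_id, body_site = body_site,
             collection_day = as.integer(collection_day),
             age_years = age_years, household_id = household_id,
             village_id = village_id, mother_id = mother_id,
             father_id = father_id, westernized = westernized,
             stringsAsFactors = FALSE)
}

# A small default synthetic study shared by several test files
# (computed once per test run).
default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(seed = 7L)
      samples <- generate_cohort(cfg)
      trees <- generate_sgb_trees(samples, cfg)
      cache <<- list(cfg = cfg, samples = samples, trees = trees)
    }
    cache
  }
})
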