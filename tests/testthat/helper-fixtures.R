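# Shared fixtures, built once per test run.

# small catalog: 2 dorsal + 2 ventral + 2 limbic + 1 thalamic + 1 callosal
small_catalog <- function() {
  tc <- tract_catalog()
  tc[tc$pair_id %in% c("AF", "SLF1", "IFOF", "ILF", "C_FP", "C_PH",
                       "TR_A", "CC_Body"), ]
}

# memoised small simulated cohort used across test files
.fixture_env <- new.env()
small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cc <- cohort_config(n_subjects = 200, catalog = small_catalog(),
                        nodes_per_tract = 15, seed = 71L)
    .fixture_env$sim <- simulate_puberty_hormones(simulate_cohort(cc))
  }
  .fixture_env$sim
}

# deviations-plus-noise stand-in for a fitted BAG matrix (tracts as columns);
# used where the test targets the sCCA / group-model stages rather than the
# GP itself
noisy_dev_matrix <- function(sim, noise_sd = 1, seed = 1L) {
  set.seed(seed)
  d <- sim$truth$dev_tract
  d + matrix(rnorm(length(d), 0, noise_sd), nrow(d), ncol(d))
}

baseline_covariates <- function(sim) {
  cb <- sim$cohort[sim$cohort$visit == "baseline", ]
  cbind(age = cb$age, sex = cb$sex)
}
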