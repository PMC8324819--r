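# Shared fixtures.  Heavy objects (study-scale datasets and fits) are
# built once per test run and memoised here.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# small datasets for unit tests
small_dataset <- function(name = "flux", seed = 42) {
  memo(paste("small", name, seed, sep = "_"),
       fp_simulate(fp_example(name), n_sequences = 12, n_times = 20,
                   n_train = 10, seed = seed))
}

small_fit <- function(name = "flux", n = 2) {
  memo(paste("smallfit", name, n, sep = "_"),
       fpe_fit(small_dataset(name), n = n))
}

# study-scale datasets and fits (acceptance suite); seeds fixed per system
study_seed <- c(flux = 101L, bubble = 202L, wealth = 303L)

study_dataset <- function(name) {
  memo(paste("study", name, sep = "_"),
       fp_simulate(fp_example(name), seed = study_seed[[name]]))
}

study_fit <- function(name, n) {
  memo(paste("studyfit", name, n, sep = "_"),
       fpe_fit(study_dataset(name), n = n))
}
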