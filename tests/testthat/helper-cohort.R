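# Shared fixtures, all generated in code. The full-scale cohort and its
# trained classifier are expensive, so they are memoized across test files.

.mall_test_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .mall_test_cache))
    assign(key, expr, envir = .mall_test_cache)
  get(key, envir = .mall_test_cache)
}

# Default-scale synthetic cohort (the study conditions: 546 ALL across the
# eight subtypes + 139 reference, 5000 probes, 30 planted sites/task).
default_sim <- function() memo("default_sim",
                               simulate_cohort(generator_config(seed = 20260925)))

# Classifier trained on the default cohort with the default 5x5/17 scheme.
default_classifier <- function() memo(
  "default_clf",
  suppressWarnings(build_consensus_classifier(default_sim()$data, seed = 7)))

# Small, fast cohort for pipeline-shape tests.
small_config <- function(seed = 3, noise = 10, ...) {
  generator_config(
    n_probes = 600, n_signature_sites = 8,
    subtype_sample_counts = c("T-ALL" = 12, "HeH" = 14, "t(12;21)" = 12,
                              "11q23/MLL" = 10, "t(1;19)" = 10,
                              "dic(9;20)" = 10, "t(9;22)" = 10,
                              "iAMP21" = 8),
    n_reference = 16, sex_site_count = 8,
    beta_noise_concentration = noise, seed = seed, ...)
}

small_sim <- function() memo("small_sim", simulate_cohort(small_config()))

# Tiny two-class beta matrix with one planted signature, for toy fits.
toy_binary <- function(seed = 1, p = 6, n1 = 4, n2 = 4, sig = 1:2) {
  set.seed(seed)
  x <- matrix(runif(p * (n1 + n2), 0.4, 0.6), p,
              dimnames = list(sprintf("cg%03d", 1:p),
                              sprintf("s%02d", 1:(n1 + n2))))
  x[sig, 1:n1] <- runif(length(sig) * n1, 0.05, 0.15)
  x[sig, (n1 + 1):(n1 + n2)] <- runif(length(sig) * n2, 0.85, 0.95)
  list(x = x, y = c(rep("pos", n1), rep("rest", n2)))
}

# A tiny trained classifier over two subtype tasks, for IO round-trips.
toy_classifier <- function() memo("toy_clf", {
  cfg <- generator_config(
    n_probes = 300, n_signature_sites = 6,
    subtype_sample_counts = c("T-ALL" = 10, "HeH" = 10, "t(12;21)" = 8,
                              "11q23/MLL" = 6, "t(1;19)" = 6,
                              "dic(9;20)" = 6, "t(9;22)" = 6, "iAMP21" = 6),
    n_reference = 10, sex_site_count = 6, missing_rate = 0, seed = 5)
  sim <- simulate_cohort(cfg)
  tasks <- default_tasks()[c("T-ALL", "HeH")]
  suppressWarnings(build_consensus_classifier(sim$data, tasks = tasks,
                                              seed = 11))
})
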