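# Shared fixtures, built once per test run and memoized.  All fixtures are
# generated in code from the package's own simulator; nothing is stored on
# disk.

.fx <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

# noise-free instrument in pseudo-logit space (all-interval items used raw):
# exact rank-6 structure with log-age first dimension, blocked missingness.
nf_instrument <- function() memo("nf_instrument", {
  spec <- simulation_spec(n_persons = 200, n_items = 80, true_d = 6,
                          noise_base = 0, frac_dichotomous = 0,
                          frac_timing = 0, seed = 11)
  simulate_instrument(spec)
})

# full calibration of the noise-free instrument (exact fit)
nf_calibration <- function() memo("nf_calibration", {
  sim <- nf_instrument()
  calibrate(sim$X$values, ages = sim$ages, ratings = sim$ratings,
            d_residual = 5, seed = 2, tol = 1e-10, max_iter = 150,
            refine_iter = 60)
})

# moderately noisy instrument with mixed metrics (raw dichotomous/timing
# columns) exercising the metric transform
noisy_instrument <- function() memo("noisy_instrument", {
  spec <- simulation_spec(n_persons = 250, n_items = 80, true_d = 6,
                          noise_base = 0.3, seed = 17)
  simulate_instrument(spec)
})

# heteroscedastic pseudo-logit dataset with known truth plus its fit and
# noise model (shared by the error-model and acceptance suites)
hetero_fit <- function() memo("hetero_fit", {
  spec <- simulation_spec(n_persons = 300, n_items = 80, true_d = 6,
                          noise_base = 1, row_noise_spread = 0.5,
                          col_noise_spread = 0.5,
                          missing_pattern = "random", seed = 21)
  sim <- simulate_dataset(spec)
  fit <- als_decompose(sim$X, 6, tol = 1e-7, max_iter = 100)
  nm <- estimate_noise_model(sim$X, fit, seed = 5)
  list(sim = sim, fit = fit, noise = nm)
})
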