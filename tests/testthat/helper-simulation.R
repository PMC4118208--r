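# Shared fixtures. Unit and property tests run on a coarse-but-stable
# discretization (64 points, dt = 2 ms) so the whole suite stays fast;
# acceptance tests use the full default resolution through the cache below.

coarse_grid <- icg_grid(64)
coarse_dt <- 2e-3

coarse_sim <- function(alpha = 0, p = icg_params(alpha = alpha), ...) {
  simulate_icg(p, coarse_grid, dt = coarse_dt, ...)
}

# Full-resolution simulations are the expensive ingredient shared by many
# acceptance checks; cache them per clearance value.
.acc_cache <- new.env(parent = emptyenv())

acc_sim <- function(alpha) {
  key <- paste0("a", alpha)
  if (is.null(.acc_cache[[key]]))
    .acc_cache[[key]] <- simulate_icg(icg_params(alpha = alpha))
  .acc_cache[[key]]
}

acc_fit <- function(alpha) fit_monoexp(sample_trace(acc_sim(alpha)))

# Exact timed samples from a clean mono-exponential A * exp(-k t).
monoexp_samples <- function(A, k, times = seq(2, 5, by = 0.5)) {
  tibble::tibble(time_min = times, conc = A * exp(-k * times))
}
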