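test_that("the default schedule is 7 samples from 2 to 5 minutes", {
  s <- sampling_schedule()
  expect_equal(s$times, seq(2, 5, by = 0.5))
  expect_length(s$times, 7)
  expect_error(sampling_schedule(start = 2, end = 2),
               class = "icgpv_bad_schedule")
  expect_error(sampling_schedule(interval = 0.7),
               class = "icgpv_bad_schedule")
})

test_that("sampling a well-mixed zero-clearance run returns the system mean", {
  sim <- coarse_sim(alpha = 0)
  s <- sample_trace(sim)
  expect_equal(nrow(s), 7)
  expect_equal(s$conc, rep(1, 7), tolerance = 0.05)
  expect_error(sample_trace(sim, sampling_schedule(end = 6)),
               class = "icgpv_bad_schedule")
})

test_that("an exact mono-exponential is recovered to machine precision", {
  fit <- fit_monoexp(monoexp_samples(3, 0.2))
  expect_equal(fit$intercept_conc, 3, tolerance = 1e-12)
  expect_equal(fit$decay_rate, 0.2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("the log-linear fit matches a brute-force SSE minimizer on noisy data", {
  set.seed(42)
  s <- monoexp_samples(2.4, 0.31)
  s$conc <- s$conc * exp(rnorm(7, 0, 0.05))
  fit <- fit_monoexp(s)

  # oracle: iteratively refined grid search over (log A, k) minimizing the
  # log-space sum of squared errors, independent of lm()
  sse <- function(logA, k) sum((log(s$conc) - (logA - k * s$time_min))^2)
  ctr <- c(log(2.4), 0.31); half <- c(0.5, 0.3)
  for (round in 1:12) {
    la <- seq(ctr[1] - half[1], ctr[1] + half[1], length.out = 21)
    kk <- seq(ctr[2] - half[2], ctr[2] + half[2], length.out = 21)
    val <- outer(la, kk, Vectorize(sse))
    i <- which(val == min(val), arr.ind = TRUE)[1, ]
    ctr <- c(la[i[1]], kk[i[2]]); half <- half / 4
  }
  expect_equal(fit$intercept_conc, exp(ctr[1]), tolerance = 1e-4)
  expect_equal(fit$decay_rate, ctr[2], tolerance = 1e-4)
})

test_that("degenerate sample sets are rejected with informative errors", {
  s <- monoexp_samples(3, 0.2)
  s$conc[4] <- 0
  expect_error(fit_monoexp(s), "t = 3.5", class = "icgpv_bad_samples")
  expect_error(fit_monoexp(monoexp_samples(3, 0.2, times = c(2, 2.5))),
               class = "icgpv_bad_samples")
})

test_that("back-extrapolation evaluates the fitted curve", {
  fit <- fit_monoexp(monoexp_samples(3, 0.2))
  expect_equal(back_extrapolate(fit, 0), fit$intercept_conc)
  expect_error(back_extrapolate(fit, -0.5), class = "icgpv_bad_ta")
  # extrapolating to t_a then decaying forward reproduces the samples
  pred <- back_extrapolate(fit, 1.3) * exp(-fit$decay_rate *
                                             (seq(2, 5, 0.5) - 1.3))
  expect_equal(pred, monoexp_samples(3, 0.2)$conc, tolerance = 1e-12)
})

test_that("the dilution formula and its error propagation are exact", {
  fit <- fit_monoexp(monoexp_samples(2, 0.25))
  # direct division: dose 5, ICG(t_a) = 2 at t_a = 0 gives 2.5 L
  est0 <- estimate_pv(5, fit, t_a = 0)
  expect_equal(est0$pv, 5 / 2)
  expect_error(estimate_pv(0, fit), class = "icgpv_bad_dose")

  # a +20% error in ICG_0 maps to a -16.7% error in PV
  fit12 <- fit_monoexp(monoexp_samples(1.2, 0.25))
  pv <- estimate_pv(1, fit12, t_a = 0)$pv
  expect_equal(1 - pv, 1 - 1 / 1.2, tolerance = 1e-12)

  # per-kg reporting and the 0.25 mg/kg dose rule
  w <- 94
  estw <- estimate_pv(0.25 * w, fit, t_a = 0, weight_kg = w)
  expect_equal(estw$dose, 23.5)
  expect_equal(estw$pv_per_kg, 1000 * estw$pv / w)
})

test_that("fitting is scale-equivariant", {
  s <- monoexp_samples(1.7, 0.22)
  set.seed(7)
  s$conc <- s$conc * exp(rnorm(7, 0, 0.03))
  f1 <- fit_monoexp(s)
  s2 <- s; s2$conc <- 13 * s$conc
  f2 <- fit_monoexp(s2)
  expect_equal(f2$intercept_conc, 13 * f1$intercept_conc, tolerance = 1e-12)
  expect_equal(f2$decay_rate, f1$decay_rate, tolerance = 1e-12)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-12)
})

test_that("PV estimates at two extrapolation times differ by exp(k dt) exactly", {
  set.seed(11)
  s <- monoexp_samples(2.1, 0.28)
  s$conc <- s$conc * exp(rnorm(7, 0, 0.04))
  fit <- fit_monoexp(s)
  est <- estimate_pv(10, fit, t_a = c(0, 0.6, 1.08))
  expect_equal(est$pv[2], est$pv[1] * exp(fit$decay_rate * 0.6),
               tolerance = 1e-12)
  expect_equal(est$pv[3], est$pv[1] * exp(fit$decay_rate * 1.08),
               tolerance = 1e-12)
})

test_that("noiseless input recovers the generating volume exactly", {
  pv_true <- 3.2; dose <- 23; k <- 0.26; t_mix <- 1
  s <- tibble::tibble(time_min = seq(2, 5, 0.5),
                      conc = dose / pv_true * exp(-k * (seq(2, 5, 0.5) - t_mix)))
  fit <- fit_monoexp(s)
  expect_equal(estimate_pv(dose, fit, t_a = t_mix)$pv, pv_true,
               tolerance = 1e-12)
})
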