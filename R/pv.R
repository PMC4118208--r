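#' Sampling schedule for the dilution protocol
#'
#' The clinical protocol draws blood every 30 seconds from 2 to 5 minutes
#' after injection (7 samples); those are the defaults.
#'
#' @param start,end First and last sampling time, minutes.
#' @param interval Spacing between samples, minutes.
#' @return An object of class `sampling_schedule` with the sample `times`.
#' @export
sampling_schedule <- function(start = 2, end = 5, interval = 0.5) {
  if (!(start < end)) abort("Schedule must have start < end.",
                            class = "icgpv_bad_schedule")
  n_int <- (end - start) / interval
  if (interval <= 0 || abs(n_int - round(n_int)) > 1e-8)
    abort("interval must be positive and divide end - start.",
          class = "icgpv_bad_schedule")
  structure(
    list(start = start, end = end, interval = interval,
         times = seq(start, end, by = interval)),
    class = "sampling_schedule"
  )
}

#' Extract timed samples from a simulated measurement trace
#'
#' Reads the simulated peripheral-vein measurements `v(t, pi)` off a
#' simulation at exactly the schedule times. The storage grid of the
#' simulation must contain every schedule time (the default `store_every =
#' 0.01` makes 30-second times exact), so no interpolation is involved.
#'
#' @param result An `icg_sim` from [simulate_icg()].
#' @param schedule A [sampling_schedule()].
#' @return A tibble with columns `time_min` and `conc`.
#' @export
sample_trace <- function(result, schedule = sampling_schedule()) {
  stopifnot(inherits(result, "icg_sim"))
  idx <- match_times(schedule$times, result$times)
  tibble(time_min = schedule$times, conc = result$trace$v_at_pi[idx])
}

match_times <- function(wanted, stored) {
  idx <- vapply(wanted, function(t) {
    j <- which.min(abs(stored - t))
    if (abs(stored[j] - t) > 1e-6)
      abort(sprintf("Sample time %.4g min is not a stored simulation time.",
                    t), class = "icgpv_bad_schedule")
    j
  }, integer(1))
  idx
}

#' Mono-exponential fit of timed concentrations
#'
#' Fits `conc(t) = A * exp(-k * t)` by ordinary least squares of
#' `log(conc)` on `t` -- the standard log-linear regression used with the
#' 2-5 minute ICG protocol. The goodness of fit `r_squared` is the
#' coefficient of determination of the log-space regression.
#'
#' @param samples A data frame with columns `time_min` and `conc`; at least
#'   3 rows, all concentrations strictly positive.
#' @return An object of class `monoexp_fit` with `intercept_conc` (A, the
#'   fitted concentration at `t = 0`), `decay_rate` (k, 1/min) and
#'   `r_squared`. [tidy()] and [glance()] methods are provided.
#' @examples
#' s <- tibble::tibble(time_min = seq(2, 5, 0.5),
#'                     conc = 3 * exp(-0.2 * seq(2, 5, 0.5)))
#' fit_monoexp(s)
#' @export
fit_monoexp <- function(samples) {
  samples <- as_tibble(samples)
  if (!all(c("time_min", "conc") %in% names(samples)))
    abort("samples must have columns time_min and conc.",
          class = "icgpv_bad_samples")
  if (nrow(samples) < 3)
    abort("At least 3 samples are needed for a mono-exponential fit.",
          class = "icgpv_bad_samples")
  bad <- which(!is.finite(samples$conc) | samples$conc <= 0)
  if (length(bad) > 0)
    abort(sprintf(
      "Non-positive concentration at t = %.4g min (sample %d); cannot log-transform.",
      samples$time_min[bad[1]], bad[1]), class = "icgpv_bad_samples")
  if (is.unsorted(samples$time_min, strictly = TRUE))
    abort("Sample times must be strictly increasing.",
          class = "icgpv_bad_samples")

  m <- lm(log(conc) ~ time_min, data = samples)
  # summary.lm warns on exact (noise-free) data; the fit itself is fine
  sm <- suppressWarnings(summary(m))
  structure(
    list(
      intercept_conc = exp(coef(m)[[1]]),
      decay_rate = -coef(m)[[2]],
      r_squared = sm$r.squared,
      n = nrow(samples),
      log_coef = coef(sm),
      sigma = sm$sigma
    ),
    class = "monoexp_fit"
  )
}

#' @export
print.monoexp_fit <- function(x, ...) {
  cat(sprintf(
    "<monoexp_fit> A = %.6g, k = %.6g /min, r^2 = %.4f (n = %d)\n",
    x$intercept_conc, x$decay_rate, x$r_squared, x$n))
  invisible(x)
}

#' @describeIn fit_monoexp Per-term estimates of the log-space regression.
#' @param x A `monoexp_fit`.
#' @param ... Unused.
#' @method tidy monoexp_fit
#' @export
tidy.monoexp_fit <- function(x, ...) {
  tibble(
    term = c("intercept_conc", "decay_rate"),
    estimate = c(x$intercept_conc, x$decay_rate),
    std.error = unname(x$log_coef[, "Std. Error"])
  )
}

#' @describeIn fit_monoexp One-row fit summary.
#' @method glance monoexp_fit
#' @export
glance.monoexp_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, sigma = x$sigma, nobs = x$n)
}

#' Back-extrapolate a fitted decay to time t_a
#'
#' Evaluates the fitted mono-exponential `A * exp(-k * t_a)`. At `t_a = 0`
#' this is the traditional theoretical initial concentration ICG_0; the
#' proposed method uses `t_a = 1` minute to account for the transit delay
#' before hepatic clearance begins.
#'
#' @param fit A [fit_monoexp()] object.
#' @param t_a Back-extrapolation time(s), minutes, nonnegative.
#' @return Concentration(s) at `t_a`.
#' @export
back_extrapolate <- function(fit, t_a) {
  stopifnot(inherits(fit, "monoexp_fit"))
  if (any(!is.finite(t_a)) || any(t_a < 0))
    abort("t_a must be nonnegative.", class = "icgpv_bad_ta")
  fit$intercept_conc * exp(-fit$decay_rate * t_a)
}

#' Plasma volume by indicator dilution
#'
#' The dilution estimate `PV = dose / ICG(t_a)`, where `ICG(t_a)` is the
#' fitted concentration back-extrapolated to `t_a`. With `dose` in mg and
#' concentrations in mg/L the volume is in litres; with the simulator's
#' normalized units (dose 1, true concentration 1) the estimate is directly
#' the estimated-to-true volume ratio.
#'
#' @param dose Injected ICG dose (mg, or normalized units); positive.
#' @param fit A [fit_monoexp()] object.
#' @param t_a Back-extrapolation time(s), minutes. Default 1 minute, the
#'   proposed optimal protocol; use 0 for the traditional method.
#' @param weight_kg Optional body weight for a per-kg volume.
#' @return A tibble with one row per `t_a`: `dose`, `t_a`, `icg_at_ta`,
#'   `pv`, and `pv_per_kg` (mL/kg; `NA` without a weight).
#' @examples
#' fit <- fit_monoexp(tibble::tibble(time_min = seq(2, 5, 0.5),
#'                                   conc = 8 * exp(-0.25 * seq(2, 5, 0.5))))
#' estimate_pv(23.5, fit, t_a = c(0, 1), weight_kg = 94)
#' @export
estimate_pv <- function(dose, fit, t_a = 1, weight_kg = NULL) {
  if (!is.numeric(dose) || length(dose) != 1 || !is.finite(dose) || dose <= 0)
    abort("dose must be a single positive number.", class = "icgpv_bad_dose")
  conc <- back_extrapolate(fit, t_a)
  pv <- dose / conc
  tibble(
    dose = dose, t_a = t_a, icg_at_ta = conc, pv = pv,
    pv_per_kg = if (is.null(weight_kg)) NA_real_ else 1000 * pv / weight_kg
  )
}
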