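#' Model parameters for the 3-loop circulation model
#'
#' Constructs the full parameter set of the three-loop advection-diffusion
#' model of ICG circulation. The circulation is split into a hepatic loop
#' (concentration `u`, flow fraction `r_u`), the non-hepatic loop where
#' samples are drawn (`v`, `r_v`) and the loop containing the injection vein
#' (`w`, `r_w`). Each loop is a periodic domain of circumference `2*pi`
#' traversed at advection speed `c`; all magnitudes of the localized terms
#' live in `alpha` (hepatic clearance) and `beta` (heart mixing), while the
#' site functions [liver_site()] and [heart_site()] are dimensionless shapes
#' with peak value 1.
#'
#' Positions are radians on `[0, 2*pi)` with the heart at `x = 0` and the
#' liver, injection and measurement sites at `x = pi`; time is in minutes.
#' The defaults encode a 1-minute whole-body transit time (`c = 2*pi`),
#' hepatic flow at 30% of cardiac output, and diffusion/mixing values
#' calibrated so that, with no clearance, concentrations are well mixed in
#' the sampled loop by 2 minutes (see [calibrate_mixing()]).
#'
#' @param c Advection speed, radians/min. Default `2*pi` (one loop per min).
#' @param nu_u,nu_v,nu_w Diffusion coefficients per loop, radians^2/min.
#' @param alpha Hepatic clearance magnitude, 1/min, scaling `liver_site()`.
#' @param beta Heart mixing rate, 1/min, scaling `heart_site()`.
#' @param r_u,r_v,r_w Flow (and volume) fractions of the three loops; must
#'   be positive and sum to 1.
#' @param liver_center,liver_width Location and support width of the hepatic
#'   clearance region in loop 1, radians.
#' @param heart_halfwidth Half-extent of the heart mixing region around the
#'   periodic seam `x = 0`, radians.
#' @param injection_center,injection_width Location and support width of the
#'   injected bolus in loop 3, radians.
#' @param normalized_dose Dimensionless injected amount; 1 means the dose
#'   equals total system volume times unit concentration, so the well-mixed
#'   system-average concentration is 1.
#' @param heart_mixing Either `"pointwise"` (the heart term relaxes each
#'   loop toward the local flow-weighted mixture
#'   `m(x) = r_u*u + r_v*v + r_w*w`) or `"scalar"` (relaxation toward the
#'   flow-weighted average concentration over the heart region).
#'
#' @return An object of class `icg_params` (a named list).
#' @seealso [icg_grid()], [initial_state()], [simulate_icg()]
#' @examples
#' p <- icg_params(alpha = 27)
#' p$r_u + p$r_v + p$r_w
#' @export
icg_params <- function(c = 2 * pi,
                       nu_u = 2, nu_v = 2, nu_w = 2,
                       alpha = 0, beta = 128,
                       r_u = 0.3, r_v = 0.65, r_w = 0.05,
                       liver_center = pi, liver_width = pi / 4,
                       heart_halfwidth = pi / 8,
                       injection_center = pi, injection_width = pi / 8,
                       normalized_dose = 1,
                       heart_mixing = c("pointwise", "scalar")) {
  heart_mixing <- match.arg(heart_mixing)
  p <- list(
    c = c, nu_u = nu_u, nu_v = nu_v, nu_w = nu_w,
    alpha = alpha, beta = beta,
    r_u = r_u, r_v = r_v, r_w = r_w,
    liver_center = liver_center, liver_width = liver_width,
    heart_halfwidth = heart_halfwidth,
    injection_center = injection_center, injection_width = injection_width,
    normalized_dose = normalized_dose,
    heart_mixing = heart_mixing
  )
  validate_icg_params(structure(p, class = "icg_params"))
}

validate_icg_params <- function(p) {
  stopifnot(is.list(p))
  num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (f in c("c", "nu_u", "nu_v", "nu_w", "alpha", "beta", "r_u", "r_v",
              "r_w", "liver_center", "liver_width", "heart_halfwidth",
              "injection_center", "injection_width", "normalized_dose")) {
    if (!num(p[[f]])) abort(paste0("`", f, "` must be a finite numeric scalar."),
                            class = "icgpv_bad_params")
  }
  if (abs(p$r_u + p$r_v + p$r_w - 1) > 1e-10)
    abort("Flow fractions r_u + r_v + r_w must sum to 1.",
          class = "icgpv_bad_params")
  if (min(p$r_u, p$r_v, p$r_w) <= 0)
    abort("Flow fractions must all be positive.", class = "icgpv_bad_params")
  if (p$alpha < 0 || p$beta < 0)
    abort("alpha and beta must be nonnegative.", class = "icgpv_bad_params")
  if (min(p$nu_u, p$nu_v, p$nu_w) <= 0)
    abort("Diffusion coefficients must be positive.", class = "icgpv_bad_params")
  if (p$c < 0) abort("Advection speed c must be nonnegative.",
                     class = "icgpv_bad_params")
  widths <- c(p$liver_width, 2 * p$heart_halfwidth, p$injection_width)
  if (any(widths <= 0) || any(widths >= 2 * pi))
    abort("Site widths must lie strictly between 0 and 2*pi.",
          class = "icgpv_bad_params")
  p
}

#' @export
print.icg_params <- function(x, ...) {
  cat("<icg_params>\n")
  cat(sprintf("  transit: c = %.4g rad/min;  clearance alpha = %.4g /min;  mixing beta = %.4g /min\n",
              x$c, x$alpha, x$beta))
  cat(sprintf("  diffusion nu = (%.3g, %.3g, %.3g) rad^2/min;  flows r = (%.3g, %.3g, %.3g)\n",
              x$nu_u, x$nu_v, x$nu_w, x$r_u, x$r_v, x$r_w))
  cat(sprintf("  liver at %.3g (width %.3g), heart halfwidth %.3g, bolus at %.3g (width %.3g)\n",
              x$liver_center, x$liver_width, x$heart_halfwidth,
              x$injection_center, x$injection_width))
  cat(sprintf("  normalized dose %.4g;  heart mixing: %s\n",
              x$normalized_dose, x$heart_mixing))
  invisible(x)
}

#' Spatial collocation grid
#'
#' Equispaced points on the half-open periodic interval `[0, 2*pi)`, shared
#' by all three loops. Point 1 sits at the heart (`x = 0`).
#'
#' @param n_points Number of collocation points; at least 64 and even, so
#'   that the Fourier transform has a clean Nyquist mode and `x = pi` is an
#'   exact grid point.
#' @return An object of class `icg_grid` with fields `n_points`, `dx` and
#'   the point vector `x`.
#' @export
icg_grid <- function(n_points = 256) {
  if (!is.numeric(n_points) || length(n_points) != 1 || n_points < 64 ||
      n_points %% 2 != 0)
    abort("n_points must be a single even integer >= 64.",
          class = "icgpv_bad_grid")
  n_points <- as.integer(n_points)
  structure(
    list(n_points = n_points, dx = 2 * pi / n_points,
         x = 2 * pi * (seq_len(n_points) - 1) / n_points),
    class = "icg_grid"
  )
}

#' @export
print.icg_grid <- function(x, ...) {
  cat(sprintf("<icg_grid> %d points on [0, 2*pi), dx = %.5g rad\n",
              x$n_points, x$dx))
  invisible(x)
}

# Raised-cosine bump with peak 1, compact support of total width `width`
# centred at `center`, wrapped periodically onto [0, 2*pi). C^1 smooth, so
# its Fourier coefficients decay fast enough for spectral differencing.
raised_cosine <- function(x, center, width) {
  d <- (x - center) %% (2 * pi)
  d[d > pi] <- d[d > pi] - 2 * pi
  out <- numeric(length(x))
  inside <- abs(d) < width / 2
  out[inside] <- (1 + cos(2 * pi * d[inside] / width)) / 2
  out
}

#' Hepatic clearance site function f(x)
#'
#' Dimensionless shape of the liver region in the hepatic loop: a smooth
#' raised-cosine bump with peak 1 centred at `liver_center`, zero outside a
#' support of width `liver_width`. The clearance term in the model is
#' `alpha * liver_site(x) * u`.
#'
#' @param x Positions in radians (wrapped modulo `2*pi`).
#' @param p An [icg_params()] object.
#' @return Nonnegative weights, same length as `x`.
#' @export
liver_site <- function(x, p = icg_params()) {
  raised_cosine(x, p$liver_center, p$liver_width)
}

#' Heart mixing site function h(x)
#'
#' Dimensionless shape of the heart region: a raised-cosine bump of peak 1
#' straddling the periodic seam, supported on
#' `[2*pi - heart_halfwidth, 2*pi) U [0, heart_halfwidth)`. The mixing term
#' in the model is `beta * heart_site(x) * (m - concentration)`.
#'
#' @inheritParams liver_site
#' @return Nonnegative weights, same length as `x`.
#' @export
heart_site <- function(x, p = icg_params()) {
  raised_cosine(x, 0, 2 * p$heart_halfwidth)
}

#' Initial concentration field: the injected bolus
#'
#' Builds the state at `t = 0`: no dye in loops 1 and 2, and a raised-cosine
#' bolus in loop 3 centred at `injection_center`. The bolus is normalized on
#' the grid's own quadrature rule so that the volume-weighted system average
#' `r_w * mean(w)` equals `normalized_dose` to machine precision.
#'
#' @param p An [icg_params()] object.
#' @param g An [icg_grid()] object.
#' @return An object of class `icg_state`: a list with time `t`, positions
#'   `x` and the three concentration vectors `u`, `v`, `w`.
#' @examples
#' st <- initial_state(icg_params(), icg_grid())
#' system_average(st, icg_params())  # 1 for the unit normalized dose
#' @export
initial_state <- function(p = icg_params(), g = icg_grid()) {
  if (p$injection_width <= g$dx)
    abort(sprintf(
      "Injection bolus (width %.4g) is unresolvable on this grid (dx = %.4g).",
      p$injection_width, g$dx), class = "icgpv_unresolved_bolus")
  w <- raised_cosine(g$x, p$injection_center, p$injection_width)
  mass <- p$r_w * mean(w)  # trapezoid rule on a periodic grid = plain mean
  if (mass <= 0)
    abort("Injection bolus has zero mass on the grid.",
          class = "icgpv_unresolved_bolus")
  w <- w * (p$normalized_dose / mass)
  structure(
    list(t = 0, x = g$x, u = numeric(g$n_points), v = numeric(g$n_points),
         w = w),
    class = "icg_state"
  )
}

#' Spatial average of a concentration profile
#'
#' The loop average `(1/2pi) * integral of the profile over [0, 2*pi)`,
#' evaluated by the equispaced trapezoid rule, which on a periodic grid is
#' the plain mean of the point values and is spectrally accurate for smooth
#' periodic data.
#'
#' @param values Numeric vector of grid point values (or a matrix whose
#'   columns are profiles).
#' @return The average (or one average per column).
#' @export
loop_average <- function(values) {
  if (is.matrix(values)) colMeans(values) else mean(values)
}

#' Volume-weighted whole-system average concentration
#'
#' `r_u * mean(u) + r_v * mean(v) + r_w * mean(w)`: total dye divided by
#' total system volume, in normalized concentration units.
#'
#' @param state An `icg_state` object.
#' @param p An [icg_params()] object.
#' @return A scalar.
#' @export
system_average <- function(state, p = icg_params()) {
  p$r_u * mean(state$u) + p$r_v * mean(state$v) + p$r_w * mean(state$w)
}
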