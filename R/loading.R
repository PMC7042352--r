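#' Thermal loading programs applied at the heated surface
#'
#' The outer surface `x = 0` carries a prescribed temperature increment
#' `theta(0, t) = g(t)`.  Three programs are supported:
#' \describe{
#'   \item{thermal shock}{`g(t) = theta0 * H(t - nu)`, a Heaviside step
#'     delayed by the shock time parameter `nu >= 0` (with `H(0) = 1`).}
#'   \item{ramp}{`g(t) = theta0 * t/t0` for `t < t0`, then `theta0`: a linear
#'     rise completed at the ramping time `t0 > 0`.}
#'   \item{harmonic}{an oscillatory program with angular parameter
#'     `omega > 0`.  Two dialects exist because the reference transform
#'     `theta0*omega/(s^2 - omega^2)` is the Laplace transform of
#'     `sinh(omega*t)`, not of `sin(omega*t)`: `"as_printed"` (default) uses
#'     the sinh pair, which reproduces the reference boundary values;
#'     `"standard_sine"` uses the physically periodic sin pair with transform
#'     `theta0*omega/(s^2 + omega^2)`.}
#' }
#'
#' @param kind one of `"thermal_shock"` (alias `"shock"`), `"ramp"`,
#'   `"harmonic"`.
#' @param theta0 loading strength (dimensionless temperature), > 0.
#' @param nu thermal shock delay, dimensionless time, >= 0 (shock only).
#' @param t0 ramping time parameter, dimensionless time, > 0 (ramp only).
#' @param omega angular thermal parameter, dimensionless frequency, > 0
#'   (harmonic only).
#' @param harmonic_dialect `"as_printed"` or `"standard_sine"`; see Details.
#' @return An object of class `"dpl_loading"`.
#' @examples
#' thermal_loading("ramp", t0 = 0.07)
#' thermal_loading("harmonic", omega = 20)
#' @export
thermal_loading <- function(kind = c("thermal_shock", "ramp", "harmonic", "shock"),
                            theta0 = 1, nu = 0, t0 = 0.05, omega = 10,
                            harmonic_dialect = c("as_printed", "standard_sine")) {
  kind <- match.arg(kind)
  if (kind == "shock") kind <- "thermal_shock"
  harmonic_dialect <- match.arg(harmonic_dialect)
  if (!is.numeric(theta0) || length(theta0) != 1 || !is.finite(theta0) || theta0 <= 0)
    stop_dpl("dpl_invalid_parameter", "theta0 must be a positive scalar")
  shape <- switch(kind,
    thermal_shock = {
      if (!is.finite(nu) || nu < 0)
        stop_dpl("dpl_invalid_parameter", "shock parameter nu must be >= 0")
      list(nu = nu)
    },
    ramp = {
      if (!is.finite(t0) || t0 <= 0)
        stop_dpl("dpl_invalid_parameter", "ramping time t0 must be > 0")
      list(t0 = t0)
    },
    harmonic = {
      if (!is.finite(omega) || omega <= 0)
        stop_dpl("dpl_invalid_parameter", "angular parameter omega must be > 0")
      list(omega = omega, harmonic_dialect = harmonic_dialect)
    })
  structure(c(list(kind = kind, theta0 = theta0), shape), class = "dpl_loading")
}

#' @export
print.dpl_loading <- function(x, ...) {
  shape <- switch(x$kind,
    thermal_shock = sprintf("nu = %g", x$nu),
    ramp = sprintf("t0 = %g", x$t0),
    harmonic = sprintf("omega = %g, dialect = %s", x$omega, x$harmonic_dialect))
  cat(sprintf("Thermal loading: %s (theta0 = %g, %s)\n", x$kind, x$theta0, shape))
  invisible(x)
}

#' Evaluate a thermal loading in the time domain
#'
#' @param load a [thermal_loading()] object.
#' @param t dimensionless time, numeric vector with all elements >= 0.
#' @return The surface temperature increment `g(t)`, same length as `t`.
#' @examples
#' loading_time_value(thermal_loading("ramp", t0 = 0.07), 0.05)  # 5/7
#' @export
loading_time_value <- function(load, t) {
  if (any(!is.finite(t)) || any(t < 0))
    stop_dpl("dpl_domain_error", "time t must be finite and non-negative")
  switch(load$kind,
    thermal_shock = load$theta0 * as.numeric(t >= load$nu),
    ramp = load$theta0 * pmin(t / load$t0, 1),
    harmonic = if (load$harmonic_dialect == "as_printed")
      load$theta0 * sinh(load$omega * t)
    else
      load$theta0 * sin(load$omega * t))
}

#' Evaluate a thermal loading in the Laplace domain
#'
#' Returns the transform `g_bar(s)` of the surface program:
#' `theta0*exp(-nu*s)/s` (shock), `theta0*(1 - exp(-t0*s))/(t0*s^2)` (ramp),
#' `theta0*omega/(s^2 - omega^2)` (harmonic, `"as_printed"` dialect) or
#' `theta0*omega/(s^2 + omega^2)` (`"standard_sine"`).
#'
#' @param load a [thermal_loading()] object.
#' @param s complex (or real) frequency vector; must avoid the transform's
#'   poles (`s = 0`; `s^2 = omega^2` as printed; `s^2 = -omega^2` for sine).
#' @return Complex vector `g_bar(s)`.
#' @export
loading_transform <- function(load, s) {
  s <- as.complex(s)
  switch(load$kind,
    thermal_shock = {
      if (any(s == 0))
        stop_dpl("dpl_singular_transform", "shock transform has a pole at s = 0")
      load$theta0 * exp(-load$nu * s) / s
    },
    ramp = {
      if (any(s == 0))
        stop_dpl("dpl_singular_transform", "ramp transform has a pole at s = 0")
      load$theta0 * (1 - exp(-load$t0 * s)) / (load$t0 * s^2)
    },
    harmonic = {
      w2 <- load$omega^2
      if (load$harmonic_dialect == "as_printed") {
        if (any(s^2 == w2))
          stop_dpl("dpl_singular_transform",
                   "harmonic transform (as printed) has poles at s = +/- omega")
        load$theta0 * load$omega / (s^2 - w2)
      } else {
        if (any(s^2 == -w2))
          stop_dpl("dpl_singular_transform",
                   "sine transform has poles at s = +/- i*omega")
        load$theta0 * load$omega / (s^2 + w2)
      }
    })
}
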