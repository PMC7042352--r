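#' Dual-phase-lag thermoelastic tissue model
#'
#' Constructs the model object tying together the dimensionless tissue
#' parameters, a surface thermal loading, and the inversion controls.  The
#' object is the package's main interface: `predict()` evaluates the
#' temperature-increment, strain, displacement and stress fields at requested
#' positions and time, `plot()` draws the four profiles, and `coef()` returns
#' the dimensionless parameter vector.
#'
#' @param loading a [thermal_loading()] object (default: unit thermal shock).
#' @param params a [dpl_params()] object.
#' @param inversion an [inversion_options()] object.
#' @return An object of class `"dpl_tissue"`.
#' @examples
#' fit <- dpl_tissue(thermal_loading("ramp", t0 = 0.07))
#' coef(fit)
#' predict(fit, x = c(0, 0.15, 0.3), t = 0.05,
#'         opts = inversion_options(n_terms = 500), adaptive = FALSE)
#' @export
dpl_tissue <- function(loading = thermal_loading("thermal_shock"),
                       params = dpl_params(),
                       inversion = inversion_options()) {
  if (!inherits(loading, "dpl_loading"))
    stop_dpl("dpl_invalid_parameter", "loading must be a thermal_loading() object")
  if (!inherits(params, "dpl_params"))
    stop_dpl("dpl_invalid_parameter", "params must be a dpl_params() object")
  structure(list(loading = loading, params = params, inversion = inversion,
                 call = match.call()),
            class = "dpl_tissue")
}

#' @export
print.dpl_tissue <- function(x, ...) {
  cat("One-dimensional dual-phase-lag thermoelastic tissue model\n\n")
  print(x$loading)
  print(x$params)
  invisible(x)
}

#' @export
summary.dpl_tissue <- function(object, t = 0.05, ...) {
  p <- object$params
  sp <- list(model = object, t = t,
             boundary_theta = loading_time_value(object$loading, t),
             boundary_strain = p$beta3 * loading_time_value(object$loading, t))
  class(sp) <- "summary.dpl_tissue"
  sp
}

#' @export
print.summary.dpl_tissue <- function(x, ...) {
  print(x$model)
  cat(sprintf("\nAt t = %g the boundary identities force:\n", x$t))
  cat(sprintf("  theta(0, t) = g(t)        = %.6g\n", x$boundary_theta))
  cat(sprintf("  e(0, t)     = beta3 g(t)  = %.6g\n", x$boundary_strain))
  cat("  sigma(0, t) = sigma(L, t) = 0 (traction-free faces)\n")
  invisible(x)
}

#' @export
coef.dpl_tissue <- function(object, ...) {
  p <- object$params
  c(beta1 = p$beta1, beta2 = p$beta2, beta3 = p$beta3, Q = p$Q,
    tau_q = p$tau_q, tau_T = p$tau_T, L = p$L)
}

#' Evaluate the model fields
#'
#' @param object a [dpl_tissue()] model.
#' @param x dimensionless positions in `[0, L]`; default 121 uniform points.
#' @param t dimensionless time, > 0.
#' @param opts inversion options; defaults to the model's.
#' @param adaptive passed to [compute_profile()].
#' @param ... unused.
#' @return A [compute_profile()] result (`"dpl_profile"` data frame).
#' @export
predict.dpl_tissue <- function(object, x = NULL, t = 0.05, opts = NULL,
                               adaptive = TRUE, ...) {
  p <- object$params
  if (is.null(x)) x <- seq(0, p$L, length.out = 121)
  if (is.null(opts)) opts <- object$inversion
  compute_profile(p, object$loading, t, x_grid = x, opts = opts,
                  adaptive = adaptive)
}

#' @export
plot.dpl_tissue <- function(x, t = 0.05, ...) {
  plot(predict(x, t = t), ...)
}
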