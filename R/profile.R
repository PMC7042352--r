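# Shared-contour inversion of all four field transforms over an x-grid.
# One Laplace solve per contour node serves every grid point and field.
invert_profile <- function(p, load, t, x, opts, adaptive = TRUE) {
  kappa <- opts$kappa_t_product / t
  pref <- exp(kappa * t) / t
  f0 <- transform_fields(as.complex(kappa), x, p, load)
  nx <- length(x)
  acc <- lapply(f0, function(m) 0.5 * Re(m[1, ]))
  add_terms <- function(acc, n_from, n_to) {
    n <- n_from
    while (n <= n_to) {
      hi <- min(n + opts$chunk - 1L, n_to)
      idx <- n:hi
      s <- complex(real = kappa, imaginary = idx * pi / t)
      fl <- transform_fields(s, x, p, load)
      sg <- (-1)^idx
      for (nm in names(acc))
        acc[[nm]] <- acc[[nm]] + as.numeric(crossprod(sg, Re(fl[[nm]])))
      n <- hi + 1L
    }
    acc
  }
  n <- opts$n_terms
  acc <- add_terms(acc, 1L, n)
  value <- lapply(acc, function(a) pref * a)
  est <- Inf
  converged <- !adaptive
  if (adaptive) {
    while (n < opts$max_terms) {
      n2 <- min(2L * n, opts$max_terms)
      acc <- add_terms(acc, n + 1L, n2)
      new_value <- lapply(acc, function(a) pref * a)
      est <- max(mapply(function(a, b) max(abs(a - b)), new_value, value))
      scale <- max(1, max(vapply(new_value, function(v) max(abs(v)), 0)))
      value <- new_value
      n <- n2
      if (est < opts$rel_tol * scale) {
        converged <- TRUE
        break
      }
    }
  }
  list(fields = value, n_used = n, est_error = est, converged = converged)
}

#' Compute field profiles at a fixed time
#'
#' Drives the full pipeline: for every point of `x_grid`, the temperature
#' increment, strain, displacement and stress are the Riemann-sum inversions
#' of their Laplace-domain transforms under the given loading.  The Laplace
#' solve at each contour node is shared across the grid, so refining the grid
#' does not change the value at any given point.
#'
#' @param p a [dpl_params()] object.
#' @param load a [thermal_loading()] object.
#' @param t dimensionless evaluation time, > 0.
#' @param x_grid ordered dimensionless positions; defaults to 121 uniform
#'   points on `[0, L]`.
#' @param opts an [inversion_options()] object.
#' @param adaptive if `TRUE` (default) the number of contour terms is doubled
#'   until the whole profile is converged to `opts$rel_tol`; if `FALSE` the
#'   fixed `opts$n_terms` is used.
#' @return An object of class `c("dpl_profile", "data.frame")` with columns
#'   `x`, `theta`, `strain`, `displacement`, `stress`, and attributes
#'   `params`, `loading`, `t`, `n_used`, `est_error`, `converged`.
#' @examples
#' pr <- compute_profile(dpl_params(), thermal_loading("ramp", t0 = 0.07),
#'                       t = 0.05, x_grid = seq(0, 0.3, length.out = 13),
#'                       opts = inversion_options(n_terms = 500),
#'                       adaptive = FALSE)
#' head(pr)
#' @export
compute_profile <- function(p, load, t,
                            x_grid = seq(0, p$L, length.out = 121),
                            opts = inversion_options(), adaptive = TRUE) {
  if (!is.numeric(t) || length(t) != 1 || t <= 0)
    stop_dpl("dpl_domain_error", "t must be a positive scalar")
  if (length(x_grid) < 1 || is.unsorted(x_grid, strictly = TRUE))
    stop_dpl("dpl_domain_error", "x_grid must be strictly increasing")
  if (any(x_grid < 0 | x_grid > p$L))
    stop_dpl("dpl_domain_error", "x_grid must lie in [0, L]")
  inv <- invert_profile(p, load, t, x_grid, opts, adaptive = adaptive)
  out <- data.frame(x = x_grid,
                    theta = inv$fields$theta_bar,
                    strain = inv$fields$e_bar,
                    displacement = inv$fields$u_bar,
                    stress = inv$fields$sigma_bar)
  structure(out,
            params = p, loading = load, t = t,
            n_used = inv$n_used, est_error = inv$est_error,
            converged = inv$converged,
            class = c("dpl_profile", "data.frame"))
}

#' @export
print.dpl_profile <- function(x, ...) {
  load <- attr(x, "loading")
  cat(sprintf("DPL thermoelastic profile at t = %g (%s loading, N = %d%s)\n",
              attr(x, "t"), load$kind, attr(x, "n_used"),
              if (isTRUE(attr(x, "converged"))) "" else ", not converged"))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' @export
plot.dpl_profile <- function(x, fields = c("theta", "strain", "displacement", "stress"),
                             ...) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(fields)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  labs <- c(theta = expression(theta), strain = "e",
            displacement = "u", stress = expression(sigma))
  for (f in fields)
    graphics::plot(x$x, x[[f]], type = "l", xlab = "x",
                   ylab = labs[[f]], main = f, ...)
  invisible(x)
}

#' Locate abrupt changes (wavefronts) in a field profile
#'
#' Finite-speed thermomechanical waves show up as near-discontinuities in the
#' strain and stress profiles.  A grid interval is flagged when its absolute
#' first difference exceeds the mean plus three standard deviations of all
#' first differences; runs of adjacent flagged intervals are merged into one
#' jump.
#'
#' @param profile a [compute_profile()] result.
#' @param field one of `"theta"`, `"strain"`, `"displacement"`, `"stress"`.
#' @return A data frame with one row per detected jump: `x_loc` (midpoint of
#'   the steepest flagged interval), `value_before`, `value_after`,
#'   `magnitude`.  Zero rows if the profile has no outlying difference.
#' @export
detect_jumps <- function(profile, field = "strain") {
  if (!field %in% c("theta", "strain", "displacement", "stress"))
    stop_dpl("dpl_domain_error", sprintf("unknown field '%s'", field))
  v <- profile[[field]]
  x <- profile$x
  if (length(v) < 3)
    stop_dpl("dpl_domain_error", "need at least 3 grid points")
  d <- abs(diff(v))
  thr <- mean(d) + 3 * stats::sd(d)
  flagged <- which(d > thr)
  if (length(flagged) == 0)
    return(data.frame(x_loc = numeric(0), value_before = numeric(0),
                      value_after = numeric(0), magnitude = numeric(0)))
  groups <- split(flagged, cumsum(c(1, diff(flagged) > 1)))
  res <- lapply(groups, function(g) {
    i <- g[which.max(d[g])]
    lo <- min(g); hi <- max(g) + 1L
    data.frame(x_loc = (x[i] + x[i + 1]) / 2,
               value_before = v[lo], value_after = v[hi],
               magnitude = abs(v[hi] - v[lo]))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Parameter-sweep study over a loading shape parameter
#'
#' Reproduces the experiment design of the reference configuration: fix the
#' loading kind and sweep its shape parameter (`nu` for shock, `t0` for ramp,
#' `omega` for harmonic) over a list of values, computing full profiles at
#' each time.  Results are returned as one long table.
#'
#' @param kind loading kind passed to [thermal_loading()].
#' @param values numeric vector of shape-parameter values to sweep.
#' @param times dimensionless evaluation times.
#' @param p a [dpl_params()] object.
#' @param x_grid spatial grid (default 121 uniform points on `[0, L]`).
#' @param opts an [inversion_options()] object.
#' @param theta0 loading strength.
#' @param harmonic_dialect harmonic dialect (see [thermal_loading()]).
#' @param adaptive passed to [compute_profile()].
#' @return A long data frame with columns `loading`, `param_name`,
#'   `param_value`, `t`, `x`, `field`, `value`, `n_terms`, `dialect`.
#'   Deterministic for fixed options.
#' @export
run_study <- function(kind, values, times = 0.05,
                      p = dpl_params(),
                      x_grid = seq(0, p$L, length.out = 121),
                      opts = inversion_options(),
                      theta0 = 1,
                      harmonic_dialect = "as_printed",
                      adaptive = TRUE) {
  if (length(values) == 0)
    stop_dpl("dpl_domain_error", "parameter sweep must be non-empty")
  kind_full <- if (kind == "shock") "thermal_shock" else kind
  param_name <- switch(kind_full, thermal_shock = "nu", ramp = "t0",
                       harmonic = "omega")
  dialect <- if (kind_full == "harmonic") harmonic_dialect else NA_character_
  rows <- list()
  for (val in values) {
    load <- switch(kind_full,
      thermal_shock = thermal_loading("thermal_shock", theta0 = theta0, nu = val),
      ramp = thermal_loading("ramp", theta0 = theta0, t0 = val),
      harmonic = thermal_loading("harmonic", theta0 = theta0, omega = val,
                                 harmonic_dialect = harmonic_dialect))
    for (t in times) {
      pr <- compute_profile(p, load, t, x_grid, opts, adaptive = adaptive)
      for (f in c("theta", "strain", "displacement", "stress")) {
        rows[[length(rows) + 1L]] <- data.frame(
          loading = kind_full, param_name = param_name, param_value = val,
          t = t, x = pr$x, field = f, value = pr[[f]],
          n_terms = attr(pr, "n_used"), dialect = dialect)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
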