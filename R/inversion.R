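#' Options for the Riemann-sum Laplace inversion
#'
#' The Tzou Riemann-sum method evaluates the transform along the shifted
#' vertical contour `s = kappa + n*pi*i/t`, with `kappa` fixed by the product
#' `kappa*t ~ 4.7` for rapid convergence:
#' \deqn{f(t) \approx \frac{e^{\kappa t}}{t}\Big[\tfrac12 F(\kappa)
#'   + \mathrm{Re}\sum_{n=1}^{N} (-1)^n F(\kappa + n\pi i/t)\Big].}
#'
#' @param kappa_t_product the fixed product `kappa*t`, > 0; default 4.7.
#' @param n_terms number of contour terms `N` for fixed-N inversion, and the
#'   starting `N` for adaptive inversion; default 5000.
#' @param rel_tol adaptive stopping tolerance: doubling stops when successive
#'   values differ by less than `rel_tol * max(1, |value|)`; default 1e-6.
#' @param max_terms cap on `N` for adaptive doubling; default `2^20`.
#'   Discontinuous loadings (thermal shock) have slowly decaying tails and may
#'   reach the cap; the returned `converged` flag records this.
#' @param chunk internal evaluation batch size (memory/speed trade-off).
#' @return An object of class `"inversion_options"`.
#' @export
inversion_options <- function(kappa_t_product = 4.7, n_terms = 5000,
                              rel_tol = 1e-6, max_terms = 2^20,
                              chunk = 8192) {
  if (kappa_t_product <= 0) stop_dpl("dpl_invalid_parameter", "kappa_t_product must be > 0")
  if (n_terms < 1) stop_dpl("dpl_invalid_parameter", "n_terms must be >= 1")
  if (rel_tol <= 0) stop_dpl("dpl_invalid_parameter", "rel_tol must be > 0")
  structure(list(kappa_t_product = kappa_t_product,
                 n_terms = as.integer(ceiling(n_terms)),
                 rel_tol = rel_tol,
                 max_terms = as.integer(max_terms),
                 chunk = as.integer(chunk)),
            class = "inversion_options")
}

# Accumulate Re sum_{n=n_from}^{n_to} (-1)^n F(kappa + n*pi*i/t) in chunks.
# F maps a complex vector to a complex vector (same length).
sum_contour_terms <- function(F, t, kappa, n_from, n_to, chunk) {
  acc <- 0
  n <- n_from
  while (n <= n_to) {
    hi <- min(n + chunk - 1L, n_to)
    idx <- n:hi
    s <- complex(real = kappa, imaginary = idx * pi / t)
    v <- F(s)
    if (any(!is.finite(Re(v)) | !is.finite(Im(v))))
      stop_dpl("dpl_inversion_node_error",
               sprintf("transform not finite at contour node n = %d",
                       idx[which(!is.finite(Re(v)) | !is.finite(Im(v)))[1]]))
    acc <- acc + sum((-1)^idx * Re(v))
    n <- hi + 1L
  }
  acc
}

#' Riemann-sum numerical inverse Laplace transform
#'
#' Inverts a Laplace-domain scalar back to the time domain at a single time
#' `t` using the fixed-N Riemann-sum formula (see [inversion_options()]).
#' The half-weighted anchor term is `F(kappa)/2`, the standard trapezoidal
#' correction of the contour sum.
#'
#' @param F a function taking a complex vector `s` and returning the
#'   transform values (complex vector of the same length).
#' @param t time at which to evaluate, > 0.
#' @param opts an [inversion_options()] object.
#' @return The real inverse-transform value at `t`.
#' @examples
#' riemann_sum_invert(function(s) 1/s, t = 1)          # ~ 1
#' riemann_sum_invert(function(s) 1/(s + 1), t = 1)    # ~ exp(-1)
#' @export
riemann_sum_invert <- function(F, t, opts = inversion_options()) {
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t <= 0)
    stop_dpl("dpl_domain_error", "t must be a positive scalar")
  kappa <- opts$kappa_t_product / t
  half <- 0.5 * Re(F(as.complex(kappa)))
  S <- sum_contour_terms(F, t, kappa, 1L, opts$n_terms, opts$chunk)
  exp(kappa * t) / t * (half + S)
}

#' Adaptive Riemann-sum inversion with doubling convergence control
#'
#' Starts from `opts$n_terms` contour terms and doubles `N` until two
#' successive values differ by less than `opts$rel_tol * max(1, |value|)` or
#' `opts$max_terms` is reached.  The last doubling difference is reported as
#' the error estimate.
#'
#' @inheritParams riemann_sum_invert
#' @return A list: `value` (real), `n_used` (terms evaluated), `est_error`
#'   (last observed doubling difference), `converged` (logical; `FALSE` means
#'   the cap was hit first and `value` carries the cap-level truncation).
#' @export
invert_adaptive <- function(F, t, opts = inversion_options()) {
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t <= 0)
    stop_dpl("dpl_domain_error", "t must be a positive scalar")
  kappa <- opts$kappa_t_product / t
  pref <- exp(kappa * t) / t
  half <- 0.5 * Re(F(as.complex(kappa)))
  n <- opts$n_terms
  S <- sum_contour_terms(F, t, kappa, 1L, n, opts$chunk)
  value <- pref * (half + S)
  est <- Inf
  converged <- FALSE
  while (n < opts$max_terms) {
    n2 <- min(2L * n, opts$max_terms)
    S <- S + sum_contour_terms(F, t, kappa, n + 1L, n2, opts$chunk)
    new_value <- pref * (half + S)
    est <- abs(new_value - value)
    value <- new_value
    n <- n2
    if (est < opts$rel_tol * max(1, abs(value))) {
      converged <- TRUE
      break
    }
  }
  if (!converged && est < opts$rel_tol * max(1, abs(value))) converged <- TRUE
  list(value = value, n_used = n, est_error = est, converged = converged)
}
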