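#' Per-frequency coefficients of the Laplace-domain system
#'
#' After transforming the dimensionless coupled system with zero initial
#' conditions, the temperature increment and strain satisfy
#' \deqn{\theta'' - a_1 \theta = a_2 e - \tilde Q, \qquad
#'       e'' - s^2 e = \beta_3 \theta''}
#' with
#' \deqn{a_1 = \frac{(1+\tau_q s)(s+\beta_1)}{1+\tau_T s},\quad
#'       a_2 = \frac{(1+\tau_q s)\beta_2}{1+\tau_T s},\quad
#'       \tilde Q = \frac{Q}{s(1+\tau_T s)}.}
#' Eliminating either unknown gives the quartic operator `D^4 - ell*D^2 + m`
#' with `ell = a1 + s^2 + a2*beta3` and `m = a1*s^2`.
#'
#' @param s complex frequency, vector allowed; `s = 0` and the pole
#'   `1 + tau_T*s = 0` are rejected.
#' @param p a [dpl_params()] object.
#' @return An object of class `"dpl_coeffs"`: list of complex vectors
#'   `s`, `a1`, `a2`, `Q_tilde`, `ell`, `m`.
#' @export
transform_coefficients <- function(s, p) {
  s <- as.complex(s)
  if (any(s == 0))
    stop_dpl("dpl_singular_coefficient", "s = 0 is a pole of the source term")
  dT <- 1 + p$tau_T * s
  if (any(dT == 0))
    stop_dpl("dpl_singular_coefficient",
             "1 + tau_T*s = 0 is a pole of the transformed coefficients")
  fq <- (1 + p$tau_q * s) / dT
  a1 <- fq * (s + p$beta1)
  a2 <- fq * p$beta2
  Q_tilde <- p$Q / (s * dT)
  structure(list(s = s, a1 = a1, a2 = a2, Q_tilde = Q_tilde,
                 ell = a1 + s^2 + a2 * p$beta3, m = a1 * s^2),
            class = "dpl_coeffs")
}

#' Decay exponents of the Laplace-domain solution
#'
#' Solves the characteristic quartic `k^4 - ell*k^2 + m = 0`.  The quadratic
#' in `z = k^2` is solved with the cancellation-free formula (larger root from
#' the stable branch, smaller as `m` over it); the square roots are mapped to
#' the half-plane `Re(k) >= 0` and ordered by modulus, so `k1` is the slower
#' (thermal-like) and `k2` the faster (mechanical-like) decay exponent.
#'
#' @param tc a [transform_coefficients()] object.
#' @return List of complex vectors `k1`, `k2` with `|k1| <= |k2|` and
#'   `Re(k) >= 0` elementwise.
#' @export
characteristic_roots <- function(tc) {
  ell <- tc$ell; m <- tc$m
  if (any(ell == 0 & m == 0))
    stop_dpl("dpl_degenerate_roots", "ell = m = 0: degenerate quartic")
  disc <- sqrt(ell^2 - 4 * m)
  # pick the sign that avoids cancellation in ell +/- disc
  sgn <- ifelse(Re(Conj(ell) * disc) >= 0, 1 + 0i, -1 + 0i)
  zbig <- 0.5 * (ell + sgn * disc)
  zsml <- ifelse(zbig == 0, 0 + 0i, m / zbig)
  k_a <- sqrt(zbig)
  k_b <- sqrt(zsml)
  k_a <- ifelse(Re(k_a) < 0, -k_a, k_a)
  k_b <- ifelse(Re(k_b) < 0, -k_b, k_b)
  swap <- Mod(k_a) < Mod(k_b) |
    (Mod(k_a) == Mod(k_b) & Im(k_a) < Im(k_b))
  k1 <- ifelse(swap, k_a, k_b)
  k2 <- ifelse(swap, k_b, k_a)
  list(k1 = k1, k2 = k2)
}

#' Mode amplitudes from the boundary conditions
#'
#' The general Laplace-domain solution
#' \deqn{\theta = \sum_i (\varepsilon_i e^{-k_i x} + \eta_i e^{k_i x}) +
#'       \tilde Q / a_1, \qquad
#'       e = \frac{1}{a_2}\sum_i (k_i^2 - a_1)
#'       (\varepsilon_i e^{-k_i x} + \eta_i e^{k_i x})}
#' must satisfy `theta(0) = g_bar`, `theta(L) = 0` and the traction-free
#' conditions `sigma(0) = sigma(L) = 0`, i.e. `e(0) = beta3*g_bar`,
#' `e(L) = 0`.  Writing `b_i` and `c_i` for the per-mode combinations at the
#' two faces, the 4x4 linear system splits exactly into two 2x2 systems, which
#' are solved in closed form; the growing-mode amplitude is kept in the scaled
#' form `eta_i' = eta_i * exp(k_i L)` so that all subsequent exponentials have
#' non-positive real part (no overflow far up the inversion contour).  The
#' near-cancelling mode weight `w_i = k_i^2 - a_1` is recomputed from the
#' exact product identity `w_1 w_2 = -a_1 a_2 \beta_3`, which keeps the strain
#' accurate even when the thermomechanical coupling is many orders of
#' magnitude below the other coefficients.
#'
#' @param tc a [transform_coefficients()] object.
#' @param roots the [characteristic_roots()] of `tc`.
#' @param g_bar complex vector: the loading transform at `tc$s`.
#' @param p a [dpl_params()] object.
#' @return An object of class `"dpl_modes"`: complex vectors `k1`, `k2`,
#'   `w1`, `w2`, amplitudes `eps1`, `eps2`, `eta1`, `eta2` (plain) and
#'   `eta1s`, `eta2s` (scaled by `exp(-k_i L)` relative to plain), boundary
#'   data `alpha1`, `alpha2`, and the face factors `E1`, `E2`.
#' @export
boundary_amplitudes <- function(tc, roots, g_bar, p) {
  k1 <- roots$k1; k2 <- roots$k2
  L <- p$L
  w1 <- k1^2 - tc$a1
  w2 <- k2^2 - tc$a1
  # refine the smaller weight from the exact product w1*w2 = -a1*a2*beta3
  prod_w <- -tc$a1 * tc$a2 * p$beta3
  use1 <- Mod(w1) < Mod(w2)
  w1 <- ifelse(use1 & w2 != 0, prod_w / w2, w1)
  w2 <- ifelse(!use1 & w1 != 0, prod_w / w1, w2)
  dw <- w2 - w1
  bad <- Mod(dw) <= 1e-13 * (Mod(w1) + Mod(w2))
  if (any(bad))
    stop_dpl("dpl_singular_system",
             sprintf("coincident characteristic roots (k1 ~ k2); condition ~ %.3g",
                     max((Mod(w1) + Mod(w2))[bad] / pmax(Mod(dw)[bad], .Machine$double.xmin))))
  g_bar <- as.complex(g_bar)
  Qa <- tc$Q_tilde / tc$a1
  alpha1 <- g_bar - Qa
  alpha2 <- p$beta3 * g_bar
  # values of the two mode groups at x = 0 (b) and x = L (c); direct Cramer
  b1 <- (alpha1 * w2 - tc$a2 * alpha2) / dw
  b2 <- (tc$a2 * alpha2 - alpha1 * w1) / dw
  cL <- -Qa
  c1 <- cL * w2 / dw
  c2 <- -cL * w1 / dw
  E1 <- exp(-k1 * L)
  E2 <- exp(-k2 * L)
  d1 <- 1 - E1^2
  d2 <- 1 - E2^2
  if (any(Mod(d1) <= 1e-13) || any(Mod(d2) <= 1e-13))
    stop_dpl("dpl_singular_system",
             "degenerate mode (exp(-2*k*L) = 1): boundary system is singular")
  eps1 <- (b1 - c1 * E1) / d1
  eta1s <- (c1 - b1 * E1) / d1
  eps2 <- (b2 - c2 * E2) / d2
  eta2s <- (c2 - b2 * E2) / d2
  structure(list(k1 = k1, k2 = k2, w1 = w1, w2 = w2,
                 eps1 = eps1, eps2 = eps2,
                 eta1 = eta1s * E1, eta2 = eta2s * E2,
                 eta1s = eta1s, eta2s = eta2s,
                 alpha1 = alpha1, alpha2 = alpha2,
                 E1 = E1, E2 = E2, L = L),
            class = "dpl_modes")
}

#' Laplace-domain field profiles
#'
#' Evaluates the transformed temperature increment, strain, stress and
#' displacement at positions `x` for every frequency in `tc$s`.  Stress is
#' `sigma = e - beta3*theta`; displacement is recovered constant-free from the
#' transformed motion equation as `u = sigma'/s^2`, differentiating the
#' exponential modes analytically.  When `beta2 = 0` (so `a2 = 0`) the strain
#' ansatz above is undefined and the exactly decoupled problem is solved
#' instead: the conduction two-point problem for `theta`, then the motion
#' equation with `theta` as a source.
#'
#' @param x dimensionless positions in `[0, L]`.
#' @param mc a [boundary_amplitudes()] object.
#' @param tc the matching [transform_coefficients()] object.
#' @param p a [dpl_params()] object.
#' @return List of complex matrices `theta_bar`, `e_bar`, `sigma_bar`,
#'   `u_bar`, each of dimension `length(tc$s)` x `length(x)`.
#' @export
field_transforms <- function(x, mc, tc, p) {
  if (any(x < 0 | x > p$L))
    stop_dpl("dpl_domain_error", "x must lie in [0, L]")
  if (all(tc$a2 == 0)) {
    g_bar <- mc$alpha1 + tc$Q_tilde / tc$a1
    return(decoupled_field_transforms(tc$s, x, p, g_bar))
  }
  L <- p$L
  P1 <- exp(-outer(mc$k1, x))          # exp(-k1 x)
  R1 <- exp(-outer(mc$k1, L - x))      # exp(-k1 (L-x)) = scaled growing mode
  P2 <- exp(-outer(mc$k2, x))
  R2 <- exp(-outer(mc$k2, L - x))
  S1 <- mc$eps1 * P1 + mc$eta1s * R1
  S2 <- mc$eps2 * P2 + mc$eta2s * R2
  theta <- S1 + S2 + tc$Q_tilde / tc$a1
  e <- (mc$w1 * S1 + mc$w2 * S2) / tc$a2
  sigma <- e - p$beta3 * theta
  A1 <- -mc$eps1 * P1 + mc$eta1s * R1  # d/dx of mode group 1, divided by k1
  A2 <- -mc$eps2 * P2 + mc$eta2s * R2
  u <- (mc$k1 * (mc$w1 / tc$a2 - p$beta3) * A1 +
        mc$k2 * (mc$w2 / tc$a2 - p$beta3) * A2) / tc$s^2
  list(theta_bar = theta, e_bar = e, sigma_bar = sigma, u_bar = u)
}

# Exactly decoupled evaluation (beta2 = 0): theta from the conduction
# two-point problem, then e from the motion equation with theta as source.
decoupled_field_transforms <- function(s, x, p, g_bar) {
  s <- as.complex(s)
  tc <- transform_coefficients(s, p)
  a1 <- tc$a1
  if (any(a1 == 0))
    stop_dpl("dpl_degenerate_roots", "a1 = 0: conduction operator degenerate")
  res <- a1 - s^2
  if (any(Mod(res) <= 1e-13 * (Mod(a1) + Mod(s)^2)))
    stop_dpl("dpl_degenerate_roots",
             "thermal and mechanical exponents coincide (a1 = s^2)")
  L <- p$L
  kt <- sqrt(a1)
  kt <- ifelse(Re(kt) < 0, -kt, kt)
  E <- exp(-kt * L)
  Qa <- tc$Q_tilde / a1
  b <- g_bar - Qa
  cL <- -Qa
  d <- 1 - E^2
  epsT <- (b - cL * E) / d
  etaT <- (cL - b * E) / d                # scaled: eta * exp(kt L)
  P <- exp(-outer(kt, x)); R <- exp(-outer(kt, L - x))
  theta <- epsT * P + etaT * R + Qa
  r <- p$beta3 * a1 / res                 # particular-strain weight
  Em <- exp(-s * L)
  dm <- 1 - Em^2
  rhs0 <- p$beta3 * g_bar - r * (epsT + etaT * E)
  rhsL <- -r * (epsT * E + etaT)
  Fm <- (rhs0 - rhsL * Em) / dm
  Gm <- (rhsL - rhs0 * Em) / dm
  Pm <- exp(-outer(s, x)); Rm <- exp(-outer(s, L - x))
  e <- r * (epsT * P + etaT * R) + Fm * Pm + Gm * Rm
  sigma <- e - p$beta3 * theta
  u <- ((r - p$beta3) * kt * (-epsT * P + etaT * R) +
        s * (-Fm * Pm + Gm * Rm)) / s^2
  list(theta_bar = theta, e_bar = e, sigma_bar = sigma, u_bar = u)
}

# One-call evaluator: loading -> transforms of all four fields at (s, x).
# Used by the inversion driver; dispatches on the beta2 = 0 degeneracy.
transform_fields <- function(s, x, p, load) {
  g_bar <- loading_transform(load, s)
  if (p$beta2 == 0)
    return(decoupled_field_transforms(s, x, p, g_bar))
  tc <- transform_coefficients(s, p)
  roots <- characteristic_roots(tc)
  mc <- boundary_amplitudes(tc, roots, g_bar, p)
  field_transforms(x, mc, tc, p)
}
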