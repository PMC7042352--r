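# Shared fixtures for the test suite (built in code, no stored data).

# Strongly coupled synthetic parameter set: exercises the full quartic
# path with all couplings at visible magnitude.
coupled_params <- function() {
  dpl_params(beta1 = 0.5, beta2 = 0.05, beta3 = 0.1, Q = 0.1)
}

# Random points on the Riemann-sum inversion contour kappa + n*pi*i/t.
random_contour_points <- function(n, t_range = c(0.01, 1), n_max = 1e5) {
  t <- stats::runif(n, t_range[1], t_range[2])
  k <- sample.int(n_max, n, replace = TRUE)
  complex(real = 4.7 / t, imaginary = k * pi / t)
}

# Dense 4x4 complex solve of the boundary system in the plain unknowns
# (eps1, eps2, eta1, eta2): the independent oracle for boundary_amplitudes.
# Only valid while exp(k_i * L) does not overflow (moderate |s|).
dense_boundary_solve <- function(tc, roots, g_bar, p) {
  k1 <- roots$k1; k2 <- roots$k2; L <- p$L
  w1 <- k1^2 - tc$a1; w2 <- k2^2 - tc$a1
  alpha1 <- g_bar - tc$Q_tilde / tc$a1
  alpha2 <- p$beta3 * g_bar
  A <- rbind(c(1, 1, 1, 1),
             c(exp(-k1 * L), exp(-k2 * L), exp(k1 * L), exp(k2 * L)),
             c(w1, w2, w1, w2),
             c(w1 * exp(-k1 * L), w2 * exp(-k2 * L),
               w1 * exp(k1 * L), w2 * exp(k2 * L)))
  b <- c(alpha1, -tc$Q_tilde / tc$a1, tc$a2 * alpha2, 0 + 0i)
  sol <- solve(A, b)
  list(eps1 = sol[1], eps2 = sol[2], eta1 = sol[3], eta2 = sol[4])
}
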