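test_that("per-frequency coefficients match their closed forms", {
  p <- dpl_params(beta1 = 0.5, beta2 = 0.05, beta3 = 0.1, Q = 0.1,
                  tau_q = 0.03, tau_T = 0.03)
  tc <- transform_coefficients(1, p)
  expect_equal(tc$a1, 1.5 + 0i, tolerance = 1e-12)  # equal lags cancel
  p2 <- dpl_params(beta1 = 0.5, beta2 = 0.05, beta3 = 0.1, Q = 0.1)
  tc2 <- transform_coefficients(1, p2)
  expect_equal(tc2$a1, 1.02 * 1.5 / 1.04 + 0i, tolerance = 1e-12)
  expect_equal(tc2$ell, tc2$a1 + 1 + tc2$a2 * p2$beta3, tolerance = 1e-12)
  expect_equal(tc2$m, tc2$a1, tolerance = 1e-12)
  pq0 <- dpl_params(beta1 = 0.5, beta2 = 0.05, beta3 = 0.1, Q = 0)
  s <- complex(real = 2, imaginary = c(-40, 3, 700))
  expect_true(all(transform_coefficients(s, pq0)$Q_tilde == 0))
  expect_error(transform_coefficients(0, p2), class = "dpl_singular_coefficient")
  expect_error(transform_coefficients(-1 / p2$tau_T, p2),
               class = "dpl_singular_coefficient")
})

test_that("characteristic roots solve the quartic and follow the branch rules", {
  r <- characteristic_roots(list(ell = 5 + 0i, m = 4 + 0i))
  expect_equal(r$k1, 1 + 0i, tolerance = 1e-12)
  expect_equal(r$k2, 2 + 0i, tolerance = 1e-12)
  rd <- characteristic_roots(list(ell = 2 + 0i, m = 1 + 0i))
  expect_equal(rd$k1, 1 + 0i, tolerance = 1e-7)
  expect_equal(rd$k2, 1 + 0i, tolerance = 1e-7)
  expect_error(characteristic_roots(list(ell = 0 + 0i, m = 0 + 0i)),
               class = "dpl_degenerate_roots")

  set.seed(11)
  for (i in 1:50) {
    ell <- complex(real = rnorm(1, 0, 10), imaginary = rnorm(1, 0, 10))
    m <- complex(real = rnorm(1, 0, 10), imaginary = rnorm(1, 0, 10))
    r <- characteristic_roots(list(ell = ell, m = m))
    expect_true(Re(r$k1) >= 0 && Re(r$k2) >= 0)
    expect_true(Mod(r$k1) <= Mod(r$k2))
    # Vieta on z = k^2
    expect_equal(r$k1^2 + r$k2^2, ell, tolerance = 1e-9)
    expect_equal(r$k1^2 * r$k2^2, m, tolerance = 1e-9)
    # independent oracle: general polynomial root finder on the quartic
    pz <- polyroot(c(m, 0, -ell, 0, 1))
    pz <- ifelse(Re(pz) < 0, -pz, pz)
    for (k in c(r$k1, r$k2))
      expect_lt(min(Mod(pz - k)) / max(Mod(k), 1e-12), 1e-8)
  }
})

test_that("boundary amplitudes agree with a dense 4x4 solve and zero data", {
  # short domain keeps exp(k*L) moderate so the unscaled oracle system is
  # well conditioned; the implementation itself never forms those terms
  p <- dpl_params(beta1 = 0.5, beta2 = 0.05, beta3 = 0.1, Q = 0.1, L = 0.1)
  load <- thermal_loading("ramp", t0 = 0.05)
  set.seed(23)
  s_all <- complex(real = 94, imaginary = runif(20, -80, 80))
  for (s in s_all) {
    tc <- transform_coefficients(s, p)
    roots <- characteristic_roots(tc)
    gb <- loading_transform(load, s)
    mc <- boundary_amplitudes(tc, roots, gb, p)
    oracle <- dense_boundary_solve(tc, roots, gb, p)
    scale <- max(Mod(unlist(oracle)))
    expect_lt(Mod(mc$eps1 - oracle$eps1) / scale, 1e-8)
    expect_lt(Mod(mc$eps2 - oracle$eps2) / scale, 1e-8)
    expect_lt(Mod(mc$eta1 - oracle$eta1) / scale, 1e-8)
    expect_lt(Mod(mc$eta2 - oracle$eta2) / scale, 1e-8)
  }
  # homogeneous data: all amplitudes vanish
  p0 <- dpl_params(beta1 = 0.5, beta2 = 0.05, beta3 = 0.1, Q = 0)
  tc <- transform_coefficients(94 + 31i, p0)
  mc0 <- boundary_amplitudes(tc, characteristic_roots(tc), 0 + 0i, p0)
  expect_equal(Mod(c(mc0$eps1, mc0$eps2, mc0$eta1, mc0$eta2)), rep(0, 4))
})

test_that("field transforms satisfy the boundary identities by construction", {
  p <- coupled_params()
  load <- thermal_loading("thermal_shock", nu = 0.02)
  s <- complex(real = 94, imaginary = c(6.3, 628, 62832))
  tc <- transform_coefficients(s, p)
  mc <- boundary_amplitudes(tc, characteristic_roots(tc),
                            loading_transform(load, s), p)
  ft <- field_transforms(c(0, 0.1, p$L), mc, tc, p)
  gb <- loading_transform(load, s)
  expect_equal(ft$theta_bar[, 1], gb, tolerance = 1e-10)
  expect_equal(ft$e_bar[, 1], p$beta3 * gb, tolerance = 1e-10)
  expect_lt(max(Mod(ft$sigma_bar[, 1])), 1e-12 * max(Mod(gb)))
  expect_lt(max(Mod(ft$e_bar[, 3])), 1e-10 * max(Mod(gb)))
  expect_lt(max(Mod(ft$theta_bar[, 3])), 1e-10 * max(Mod(gb)))
  expect_error(field_transforms(c(-0.1), mc, tc, p), class = "dpl_domain_error")
  expect_error(field_transforms(c(0.5), mc, tc, p), class = "dpl_domain_error")
})

test_that("transformed fields satisfy the coupled ODE system pointwise", {
  p <- coupled_params()
  load <- thermal_loading("ramp", t0 = 0.05)
  set.seed(31)
  s <- random_contour_points(40)
  x <- runif(40, 0.01, p$L - 0.01)
  tc <- transform_coefficients(s, p)
  roots <- characteristic_roots(tc)
  mc <- boundary_amplitudes(tc, roots, loading_transform(load, s), p)
  for (i in seq_along(s)) {
    # analytic exponentials of the two mode groups at x[i]
    m1 <- mc$eps1[i] * exp(-mc$k1[i] * x[i]) +
      mc$eta1s[i] * exp(-mc$k1[i] * (p$L - x[i]))
    m2 <- mc$eps2[i] * exp(-mc$k2[i] * x[i]) +
      mc$eta2s[i] * exp(-mc$k2[i] * (p$L - x[i]))
    # strain equation e'' - s^2 e = beta3 * theta'' reduces, mode by mode,
    # to the quartic (k^2 - a1)(k^2 - s^2) = a2*beta3*k^2
    for (j in 1:2) {
      k <- if (j == 1) mc$k1[i] else mc$k2[i]
      w <- if (j == 1) mc$w1[i] else mc$w2[i]
      mj <- if (j == 1) m1 else m2
      lhs <- (w / tc$a2[i]) * (k^2 - s[i]^2) - p$beta3 * k^2
      scale <- Mod(w / tc$a2[i]) * (Mod(k)^2 + Mod(s[i])^2) + Mod(p$beta3 * k^2)
      expect_lt(Mod(lhs) / scale, 1e-8)
    }
    # conduction equation theta'' - a1*theta = a2*e - Q_tilde at x[i]
    th <- m1 + m2 + tc$Q_tilde[i] / tc$a1[i]
    thpp <- mc$k1[i]^2 * m1 + mc$k2[i]^2 * m2
    e <- (mc$w1[i] * m1 + mc$w2[i] * m2) / tc$a2[i]
    resid <- thpp - tc$a1[i] * th - tc$a2[i] * e + tc$Q_tilde[i]
    scale <- Mod(thpp) + Mod(tc$a1[i] * th) + Mod(tc$a2[i] * e) +
      Mod(tc$Q_tilde[i]) + 1e-300
    expect_lt(Mod(resid) / scale, 1e-8)
  }
})

test_that("displacement transform is the antiderivative of the strain", {
  p <- coupled_params()
  load <- thermal_loading("harmonic", omega = 15)
  s <- complex(real = 94, imaginary = c(62.8, 251.3))
  tc <- transform_coefficients(s, p)
  mc <- boundary_amplitudes(tc, characteristic_roots(tc),
                            loading_transform(load, s), p)
  h <- 5e-4
  for (x0 in c(0.05, 0.15, 0.25)) {
    ft <- field_transforms(c(x0 - h, x0, x0 + h), mc, tc, p)
    du <- (ft$u_bar[, 3] - ft$u_bar[, 1]) / (2 * h)
    expect_equal(du, ft$e_bar[, 2], tolerance = 1e-4)
  }
})

test_that("the beta2 = 0 limit joins the coupled path continuously", {
  pd <- dpl_params(beta1 = 0.5, beta2 = 0, beta3 = 0.1, Q = 0.1)
  pe <- dpl_params(beta1 = 0.5, beta2 = 1e-10, beta3 = 0.1, Q = 0.1)
  load <- thermal_loading("ramp", t0 = 0.05)
  s <- complex(real = 94, imaginary = c(10, 500, 5000, 2e5))
  x <- c(0, 0.07, 0.21, 0.3)
  fd <- dplskin:::transform_fields(s, x, pd, load)
  fe <- dplskin:::transform_fields(s, x, pe, load)
  for (nm in names(fd)) {
    scale <- max(Mod(fd[[nm]])) + 1e-300
    expect_lt(max(Mod(fd[[nm]] - fe[[nm]])) / scale, 1e-6)
  }
})
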