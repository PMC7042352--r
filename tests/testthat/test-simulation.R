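test_that("profiles honor the thermal and traction-free boundary conditions", {
  p <- dpl_params()
  opts <- inversion_options(n_terms = 2000, max_terms = 2^16)
  cases <- list(
    list(load = thermal_loading("thermal_shock", nu = 0), g = 1),
    list(load = thermal_loading("ramp", t0 = 0.07), g = 5 / 7))
  for (cs in cases) {
    pr <- compute_profile(p, cs$load, t = 0.05, x_grid = c(0, 0.15, p$L),
                          opts = opts)
    expect_lt(abs(pr$theta[1] - cs$g), 1e-2)
    expect_lt(abs(pr$strain[1] - p$beta3 * cs$g), 1e-2 * p$beta3)
    expect_lt(abs(pr$stress[1]), 1e-6)
    expect_lt(abs(pr$stress[3]), 1e-6)
    expect_lt(abs(pr$theta[3]), 1e-6)
  }
  expect_error(compute_profile(p, cases[[1]]$load, t = -1),
               class = "dpl_domain_error")
  expect_error(compute_profile(p, cases[[1]]$load, t = 0.05,
                               x_grid = c(0, 0.4)),
               class = "dpl_domain_error")
})

test_that("profiles are deterministic and grid-decoupled", {
  p <- dpl_params()
  load <- thermal_loading("ramp", t0 = 0.05)
  opts <- inversion_options(n_terms = 800)
  a <- compute_profile(p, load, 0.05, seq(0, 0.3, length.out = 7), opts,
                       adaptive = FALSE)
  b <- compute_profile(p, load, 0.05, seq(0, 0.3, length.out = 7), opts,
                       adaptive = FALSE)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # inversion is per-point: refining the grid leaves shared points unchanged
  fine <- compute_profile(p, load, 0.05, seq(0, 0.3, length.out = 13), opts,
                          adaptive = FALSE)
  shared <- fine$x %in% a$x
  for (f in c("theta", "strain", "displacement", "stress"))
    expect_equal(fine[[f]][shared], a[[f]], tolerance = 1e-14)
})

test_that("jump detection finds constructed and physical wavefronts", {
  # strictly linear profile: no outlying difference
  lin <- data.frame(x = seq(0, 0.3, length.out = 61))
  lin$strain <- 2 * lin$x + 1
  expect_identical(nrow(detect_jumps(lin, "strain")), 0L)
  expect_error(detect_jumps(lin, "entropy"), class = "dpl_domain_error")
  # synthetic step at x = 0.1 on a fine grid
  step <- data.frame(x = seq(0, 0.3, length.out = 241))
  step$strain <- ifelse(step$x < 0.1, 1, 0) + 0.001 * sin(40 * step$x)
  j <- detect_jumps(step, "strain")
  dom <- j[which.max(j$magnitude), ]
  expect_lt(abs(dom$x_loc - 0.1), 0.3 / 240 + 1e-9)
  expect_gt(dom$magnitude, 0.9)
  # shock loading: a single dominant interior strain jump (the wavefront)
  p <- dpl_params()
  pr <- compute_profile(p, thermal_loading("thermal_shock", nu = 0.02), 0.05,
                        opts = inversion_options(n_terms = 3000),
                        adaptive = FALSE)
  js <- detect_jumps(pr, "strain")
  expect_gte(nrow(js), 1)
  dom <- js[which.max(js$magnitude), ]
  expect_true(dom$x_loc > 0 && dom$x_loc < p$L)
  # the wavefront travels at unit speed: x ~ t - nu
  expect_lt(abs(dom$x_loc - 0.03), 0.01)
  expect_gt(dom$magnitude, 2 * sum(js$magnitude) / 3 / nrow(js))
})

test_that("parameter studies return a deterministic long table", {
  p <- dpl_params()
  xg <- seq(0, 0.3, length.out = 9)
  opts <- inversion_options(n_terms = 500)
  tab <- run_study("ramp", c(0.03, 0.07), times = 0.05, p = p, x_grid = xg,
                   opts = opts, adaptive = FALSE)
  expect_identical(nrow(tab), 2L * 9L * 4L)
  expect_setequal(unique(tab$field),
                  c("theta", "strain", "displacement", "stress"))
  expect_identical(unique(tab$param_name), "t0")
  tab2 <- run_study("ramp", c(0.03, 0.07), times = 0.05, p = p, x_grid = xg,
                    opts = opts, adaptive = FALSE)
  expect_identical(tab, tab2)
  # theta near the surface weakens as the ramp slows
  th <- subset(tab, field == "theta" & x == xg[2])
  expect_lt(th$value[th$param_value == 0.07], th$value[th$param_value == 0.03])
  expect_error(run_study("ramp", numeric(0)), class = "dpl_domain_error")
})
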