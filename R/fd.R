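#' Space-time grid for the finite-difference oracle
#'
#' @param nx number of spatial points (>= 11).
#' @param t_end final dimensionless time.
#' @param dt time step; default `dx/8`, safely inside the leapfrog CFL limit
#'   `dt <= dx` (dimensionless mechanical wave speed 1).
#' @param L tissue thickness.
#' @return An object of class `"fd_grid"`.
#' @export
fd_grid <- function(nx = 241, t_end = 0.05, dt = NULL, L = 0.3) {
  if (nx < 11) stop_dpl("dpl_invalid_parameter", "nx must be >= 11")
  dx <- L / (nx - 1)
  if (is.null(dt)) dt <- dx / 8
  if (dt <= 0) stop_dpl("dpl_invalid_parameter", "dt must be > 0")
  if (dt > dx)
    stop_dpl("dpl_fd_unstable",
             sprintf("CFL violated: dt = %g exceeds dx = %g", dt, dx))
  nt <- as.integer(ceiling(t_end / dt))
  structure(list(nx = as.integer(nx), dx = dx, dt = t_end / nt, nt = nt,
                 t_end = t_end, L = L, x = seq(0, L, length.out = nx)),
            class = "fd_grid")
}

#' Finite-difference time-domain solution of the coupled system
#'
#' Independent brute-force validator for the Laplace-domain pipeline.  The
#' dimensionless coupled system is marched in time: the dual-phase-lag
#' conduction equation implicitly (backward differences in time, with the
#' mixed third-order term `tau_T * d/dt d2/dx2 theta` as the time difference
#' of the second-difference stencil), the hyperbolic motion equation by
#' explicit leapfrog under the CFL condition `dt <= dx`.  Boundary conditions
#' are `theta(0,t) = g(t)`, `theta(L,t) = 0` and the traction-free pair
#' `sigma = 0` at both faces (imposed as `e = beta3*theta` there); all fields
#' start from rest.  Stress is recovered as `sigma = e - beta3*theta`.
#'
#' This is a correctness instrument for small instances, first-order accurate
#' in time and second-order in space, not a production PDE solver.
#'
#' @param p a [dpl_params()] object.
#' @param load a [thermal_loading()] object.
#' @param grid an [fd_grid()] object.
#' @return An object of class `"dpl_fd"`: list with the grid, final-time
#'   vectors `theta`, `strain`, `stress`, and the full space-time arrays
#'   `theta_field`, `strain_field` (rows = time levels `0..nt`).
#' @export
fd_solve <- function(p, load, grid) {
  nx <- grid$nx; dx <- grid$dx; dt <- grid$dt; nt <- grid$nt
  tau_q <- p$tau_q; tau_T <- p$tau_T
  idx <- 2:(nx - 1)
  # implicit conduction operator: (1 + tau_T/dt) D2 - c2 I on interior nodes
  c1 <- (1 + tau_T / dt) / dx^2
  c2 <- 1 / dt + tau_q / dt^2 + p$beta1 * (1 + tau_q / dt)
  ni <- nx - 2L
  M <- diag(-2 * c1 - c2, ni)
  if (ni > 1) {
    off <- cbind(1:(ni - 1), 2:ni)
    M[off] <- c1
    M[off[, 2:1, drop = FALSE]] <- c1
  }
  Minv <- solve(M)
  D2 <- function(v) (v[idx - 1] - 2 * v[idx] + v[idx + 1]) / dx^2

  th0 <- th1 <- numeric(nx)   # theta at levels n-1, n
  e0 <- e1 <- numeric(nx)     # strain at levels n-1, n
  theta_field <- matrix(0, nt + 1L, nx)
  strain_field <- matrix(0, nt + 1L, nx)
  for (n in seq_len(nt)) {
    tn1 <- n * dt
    g1 <- loading_time_value(load, tn1)
    # leapfrog strain update (uses levels n, n-1)
    e2 <- numeric(nx)
    e2[idx] <- 2 * e1[idx] - e0[idx] + dt^2 * (D2(e1) - p$beta3 * D2(th1))
    e2[1] <- p$beta3 * g1
    e2[nx] <- 0
    # implicit conduction update with the freshly updated strain
    rhs <- (tau_T / dt) * D2(th1) -
      (1 / dt + 2 * tau_q / dt^2 + p$beta1 * tau_q / dt) * th1[idx] +
      (tau_q / dt^2) * th0[idx] +
      p$beta2 * ((1 + tau_q / dt) * e2[idx] - (tau_q / dt) * e1[idx]) -
      p$Q
    # Dirichlet boundary values enter the implicit stencil
    rhs[1] <- rhs[1] - c1 * g1
    th2 <- numeric(nx)
    th2[idx] <- as.numeric(Minv %*% rhs)
    th2[1] <- g1
    th2[nx] <- 0
    if (!all(is.finite(th2)) || !all(is.finite(e2)) ||
        max(abs(e2)) > 1e8 || max(abs(th2)) > 1e8)
      stop_dpl("dpl_fd_unstable",
               sprintf("finite-difference solution blew up at step %d (t = %g)",
                       n, tn1))
    th0 <- th1; th1 <- th2
    e0 <- e1; e1 <- e2
    theta_field[n + 1L, ] <- th2
    strain_field[n + 1L, ] <- e2
  }
  structure(list(grid = grid, x = grid$x, t_end = grid$t_end,
                 theta = th1, strain = e1,
                 stress = e1 - p$beta3 * th1,
                 theta_field = theta_field, strain_field = strain_field,
                 params = p, loading = load),
            class = "dpl_fd")
}

#' @export
print.dpl_fd <- function(x, ...) {
  cat(sprintf("Finite-difference solution: nx = %d, dt = %.3g, t_end = %g (%s loading)\n",
              x$grid$nx, x$grid$dt, x$t_end, x$loading$kind))
  cat(sprintf("  max |theta| = %.4g, max |strain| = %.4g\n",
              max(abs(x$theta)), max(abs(x$strain))))
  invisible(x)
}
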