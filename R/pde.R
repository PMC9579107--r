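## Full nonlinear spatial model on a periodic 1-D grid: initial conditions,
## right-hand side, single RK4 steps and the compiled integration loop.

#' Periodic spatial grid
#'
#' @param L domain length.
#' @param n_x number of grid cells (`>= 16`).
#' @return An object of class `rt_grid` with fields `L`, `n_x`, `dx` and
#'   the cell positions `x`.
#' @export
rt_grid <- function(L = 1, n_x = 256) {
  check_scalar(L, "L"); n_x <- as.integer(n_x)
  if (L <= 0) stop_param("'L' must be positive")
  if (n_x < 16L) stop_param("'n_x' must be at least 16")
  dx <- L / n_x
  structure(list(L = L, n_x = n_x, dx = dx, x = (seq_len(n_x) - 1) * dx),
            class = "rt_grid")
}

#' @export
print.rt_grid <- function(x, ...) {
  cat(sprintf("Periodic grid: L = %g, n_x = %d, dx = %g\n", x$L, x$n_x, x$dx))
  invisible(x)
}

as_field <- function(state, grid) {
  if (is.matrix(state) && nrow(state) == 3L && ncol(state) == grid$n_x)
    return(state)
  stop_param("a field state must be a 3 x n_x matrix ",
             "(rows rho_plus, rho_0, rho_minus)")
}

params_to_cvec <- function(params) {
  r <- params$rates; tr <- params$transport
  ia <- params$interactions; cc <- params$carrying
  c(lambda_s = r$lambda_s, lambda_d = r$lambda_d, lambda_e = r$lambda_e,
    mu = r$mu, v_plus = tr$v_plus, v_minus = tr$v_minus, D = tr$D,
    kappa = ia$kappa, kappa_0 = ia$kappa_0,
    logistic = as.numeric(params$growth_mode == "logistic"),
    rho_plus_c = cc$rho_plus_c, rho_0_c = cc$rho_0_c,
    rho_minus_c = cc$rho_minus_c)
}

#' Spatial right-hand side of the model equations
#'
#' Tendency of the density fields under diffusion (2nd-order central),
#' self-advection of the movers (central), the conservative interaction
#' flux `d/dx[(d/dx U) rho]` with `U_+/- = -kappa rho_0`,
#' `U_0 = +kappa_0 rho_0`, and the kinetic term (linear `M rho` or its
#' logistic generalization).  All spatial terms are in divergence form on
#' the periodic grid, so they move mass without creating it.
#'
#' @param state a `3 x n_x` matrix (rows `rho_plus`, `rho_0`, `rho_minus`).
#' @param params an [rt_params()] object.
#' @param grid an [rt_grid()] object.
#' @return A `3 x n_x` tendency matrix.
#' @export
pde_rhs <- function(state, params, grid) {
  stopifnot(inherits(params, "rt_params"), inherits(grid, "rt_grid"))
  state <- as_field(state, grid)
  if (any(!is.finite(state)))
    stop_param("non-finite value in field state (diverged run?)")
  .pde_rhs_cpp(state, params_to_cvec(params), grid$dx)
}

#' Maximum stable time step (advective/diffusive bound)
#'
#' Conservative CFL-type estimate for the explicit scheme:
#' `dt <= min(dx / v_max, dx^2 / (2 D_eff))` with
#' `D_eff = D + (kappa + kappa_0) * max(rho_0)` accounting for the
#' interaction-induced diffusion, times a safety factor.
#'
#' @param params an [rt_params()] object.
#' @param grid an [rt_grid()] object.
#' @param state optional field used to estimate the interaction diffusion.
#' @param safety multiplicative safety factor.
#' @return The recommended maximal `dt`.
#' @export
pde_stable_dt <- function(params, grid, state = NULL, safety = 0.8) {
  tr <- params$transport; ia <- params$interactions
  rho0_max <- if (is.null(state)) 1 else max(state[2, ])
  D_eff <- tr$D + (ia$kappa + ia$kappa_0) * rho0_max
  v_max <- max(tr$v_plus, tr$v_minus)
  bounds <- c(if (v_max > 0) grid$dx / v_max,
              if (D_eff > 0) grid$dx^2 / (2 * D_eff))
  if (length(bounds) == 0) return(Inf)
  safety * min(bounds)
}

#' Single classical RK4 step
#'
#' @inheritParams pde_rhs
#' @param dt time step; must satisfy the stability bound of
#'   [pde_stable_dt()].
#' @return The advanced `3 x n_x` field.
#' @export
pde_step_rk4 <- function(state, params, grid, dt) {
  state <- as_field(state, grid)
  if (dt > pde_stable_dt(params, grid, state, safety = 1))
    stop_param("dt = ", dt, " violates the stability bound ",
               format(pde_stable_dt(params, grid, state, safety = 1)),
               "; reduce dt or refine the grid")
  k1 <- pde_rhs(state, params, grid)
  k2 <- pde_rhs(state + dt / 2 * k1, params, grid)
  k3 <- pde_rhs(state + dt / 2 * k2, params, grid)
  k4 <- pde_rhs(state + dt * k3, params, grid)
  state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Uniform stationary initial condition
#'
#' Fills the grid with the homogeneous stationary state carrying conserved
#' density `R0`: the exact linear stationary state on the balanced line
#' `lambda_s = mu`, or (in logistic mode) the fixed point of the
#' saturating kinetics found by damped Newton iteration started from the
#' linear state.
#'
#' @param params an [rt_params()] object.
#' @param grid an [rt_grid()] object.
#' @param R0 conserved density of the linear stationary state (also the
#'   Newton starting point in logistic mode).
#' @return A `3 x n_x` field matrix.
#' @export
init_uniform_stationary <- function(params, grid, R0 = 1) {
  stopifnot(inherits(params, "rt_params"), inherits(grid, "rt_grid"))
  if (params$growth_mode == "linear") {
    st <- wm_stationary(params$rates, R0)
  } else {
    st <- logistic_fixed_point(params, R0)
  }
  matrix(rep(unclass(st), grid$n_x), nrow = 3,
         dimnames = list(c("rho_plus", "rho_0", "rho_minus"), NULL))
}

## Fixed point of the logistic kinetics, by damped Newton iteration with a
## numerical Jacobian, started from the linear stationary composition.
logistic_fixed_point <- function(params, R0 = 1, tol = 1e-12, max_iter = 200) {
  parts <- rate_matrix_parts(params$rates)
  cc <- params$carrying
  f <- function(y) drop(parts$M_D %*% y) + drop(parts$M_OD %*% logistic_growth(y, cc))
  mu <- params$rates$mu; ld <- params$rates$lambda_d
  y <- if (mu + ld > 0)
    c(ld, 2 * mu, ld) / (2 * (2 * mu + ld)) * R0 else rep(R0 / 4, 3)
  for (it in seq_len(max_iter)) {
    fy <- f(y)
    if (max(abs(fy)) < tol * max(1, max(abs(y)))) break
    J <- vapply(1:3, function(j) {
      h <- 1e-7 * max(abs(y[j]), 1e-6)
      yh <- y; yh[j] <- yh[j] + h
      (f(yh) - fy) / h
    }, numeric(3))
    step <- tryCatch(solve(J, fy), error = function(e)
      stop_param("singular Jacobian in logistic fixed-point iteration"))
    lam <- 1
    repeat {
      y_new <- y - lam * step
      if (all(y_new >= 0) || lam < 1e-6) break
      lam <- lam / 2
    }
    y <- pmax(y_new, 0)
  }
  if (max(abs(f(y))) > 1e-8 * max(1, max(abs(y))))
    stop_param("logistic fixed-point iteration did not converge")
  names(y) <- c("rho_plus", "rho_0", "rho_minus")
  y
}

#' Add Gaussian noise to a field state
#'
#' Independent mean-zero Gaussian perturbations at every grid point of
#' every field, with standard deviation `amplitude` times the local density
#' (`relative = TRUE`, the default) or `amplitude` itself.  Results are
#' reproducible for a fixed `seed`; negative values produced by the noise
#' are clipped to zero.
#'
#' @param state a `3 x n_x` field matrix.
#' @param amplitude noise standard deviation (`>= 0`).
#' @param seed optional integer seed.
#' @param relative scale the noise by the local density?
#' @return The perturbed field.
#' @export
add_gaussian_noise <- function(state, amplitude = 1e-3, seed = NULL,
                               relative = TRUE) {
  check_scalar(amplitude, "amplitude")
  if (!is.null(seed)) set.seed(seed)
  sd <- if (relative) amplitude * abs(state) else amplitude
  noisy <- state + rnorm(length(state)) * sd
  pmax(noisy, 0)
}

#' Narrow Gaussian peak of settled cells
#'
#' A settled-cell density profile approximating a single initially settled
#' cell: a Gaussian of the given integrated mass centered at `center`
#' (default the middle of the box), with the movers identically zero.
#'
#' @param grid an [rt_grid()] object.
#' @param width Gaussian standard deviation; must resolve the grid
#'   (`width >= 2 dx`).
#' @param mass integrated settled density (trapezoidal mass on the grid is
#'   normalized to exactly this value).
#' @param center peak position.
#' @return A `3 x n_x` field matrix.
#' @export
init_gaussian_peak <- function(grid, width = NULL, mass = 1,
                               center = grid$L / 2) {
  stopifnot(inherits(grid, "rt_grid"))
  width <- width %||% (3 * grid$dx)
  if (width < 2 * grid$dx)
    stop_param("'width' must be at least 2 dx = ", 2 * grid$dx,
               " to be resolved on the grid")
  # periodic distance to the center
  d <- abs(grid$x - center)
  d <- pmin(d, grid$L - d)
  prof <- exp(-d^2 / (2 * width^2))
  prof <- prof * mass / (sum(prof) * grid$dx)
  out <- matrix(0, 3, grid$n_x,
                dimnames = list(c("rho_plus", "rho_0", "rho_minus"), NULL))
  out[2, ] <- prof
  out
}

#' Integrate the full spatial model
#'
#' Advances the fields with classical RK4 and the compiled right-hand
#' side, collecting snapshots every `snapshot_stride` steps.  The run ends
#' early once the pointwise change of the state over `check_every` steps
#' falls below `exit_tol` (a converged uniform or static pattern; traveling
#' waves keep changing pointwise and run to completion).  A NaN/overflow
#' aborts with the last good snapshot retained and status `"diverged"`;
#' densities below `-neg_tol` abort with status `"negative_density"`
#' (a dt/dx misconfiguration), while smaller undershoots are clipped to 0.
#'
#' @param init a `3 x n_x` field matrix.
#' @param params an [rt_params()] object.
#' @param grid an [rt_grid()] object.
#' @param dt time step (checked against [pde_stable_dt()]).
#' @param n_steps number of RK4 steps.
#' @param snapshot_stride steps between stored snapshots (0 = only first
#'   and last).
#' @param check_every steps between early-exit checks (0 disables).
#' @param exit_tol early-exit threshold on the pointwise state change.
#' @param neg_tol abort threshold for negative densities.
#' @return An object of class `rt_trajectory`: list with `times`, `x`, the
#'   `n_x x n_snapshots` matrices `rho_plus`, `rho_0`, `rho_minus`, the
#'   total mass `N` per snapshot, `status` and `steps_done`.
#' @examples
#' \donttest{
#' pre <- rt_preset("fig9")
#' g <- rt_grid(pre$params$L, 128)
#' st <- add_gaussian_noise(init_uniform_stationary(pre$params, g), seed = 1)
#' traj <- pde_integrate(st, pre$params, g, dt = 1e-3, n_steps = 2e4)
#' classify_pattern(traj, pre$params)
#' }
#' @export
pde_integrate <- function(init, params, grid, dt = 1e-4, n_steps = 1e6,
                          snapshot_stride = max(1L, round(n_steps / 50)),
                          check_every = 1000L, exit_tol = 1e-8,
                          neg_tol = 1e-8) {
  stopifnot(inherits(params, "rt_params"), inherits(grid, "rt_grid"))
  init <- as_field(init, grid)
  dt_max <- pde_stable_dt(params, grid, init, safety = 1)
  if (dt > dt_max)
    stop_param("dt = ", dt, " violates the stability bound ", format(dt_max),
               "; reduce dt or refine the grid")
  res <- .pde_integrate_cpp(init, params_to_cvec(params), grid$dx,
                            dt, as.integer(n_steps),
                            as.integer(snapshot_stride),
                            as.integer(check_every), exit_tol, neg_tol)
  traj <- structure(list(times = res$times, x = grid$x,
                         rho_plus = res$rho_plus, rho_0 = res$rho_0,
                         rho_minus = res$rho_minus, N = res$N,
                         status = res$status, steps_done = res$steps_done,
                         params = params, grid = grid, dt = dt),
                    class = "rt_trajectory")
  if (res$status %in% c("diverged", "negative_density"))
    warning("integration aborted with status '", res$status, "' after ",
            res$steps_done, " steps; last good snapshot retained")
  traj
}

#' @export
print.rt_trajectory <- function(x, ...) {
  nt <- length(x$times)
  cat(sprintf("PDE trajectory: %d snapshots on [0, %g], n_x = %d (%s)\n",
              nt, max(x$times), x$grid$n_x, x$status))
  cat(sprintf("  total mass N: %.6g -> %.6g\n", x$N[1], x$N[nt]))
  invisible(x)
}

#' Extract one snapshot of a trajectory as a data frame
#'
#' @param traj an `rt_trajectory`.
#' @param i snapshot index (default: last).
#' @return A data frame with columns `x`, `rho_plus`, `rho_0`,
#'   `rho_minus`, `total`.
#' @export
trajectory_snapshot <- function(traj, i = length(traj$times)) {
  stopifnot(inherits(traj, "rt_trajectory"))
  data.frame(x = traj$x,
             rho_plus = traj$rho_plus[, i],
             rho_0 = traj$rho_0[, i],
             rho_minus = traj$rho_minus[, i],
             total = traj$rho_plus[, i] + traj$rho_0[, i] +
               traj$rho_minus[, i])
}
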