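## Well-mixed (space-independent) population dynamics: eigenstructure of the
## kinetic matrix, stationary states on the lambda_s = mu line, and exact or
## numerical time evolution.

#' Eigenvalues of the kinetic matrix
#'
#' Closed-form eigenvalues of the cell-cycle transition matrix:
#' `E1 = -(mu + 2 lambda_e + lambda_s)`,
#' `E2 = -(mu + lambda_d + lambda_s + Lambda)/2` and
#' `E3 = -(mu + lambda_d + lambda_s - Lambda)/2`, with the discriminant
#' `Lambda = sqrt((mu + lambda_d + lambda_s)^2 + 4 lambda_d (lambda_s - mu))`.
#' `E1` and `E2` are always negative; the sign of `E3` equals the sign of
#' `lambda_s - mu`, which separates exponential growth from collapse of the
#' colony.  For non-negative rates the radicand is provably non-negative;
#' should it ever be negative the eigenvalues are returned as complex values
#' with a warning.
#'
#' @param rates an [kinetic_rates()] object.
#' @return A list with `E1`, `E2`, `E3` and `Lambda`.
#' @examples
#' wm_eigenvalues(kinetic_rates(1, 1, 1, 1))  # (-4, -3, 0), Lambda = 3
#' @export
wm_eigenvalues <- function(rates) {
  stopifnot(inherits(rates, "rt_rates"))
  ls <- rates$lambda_s; ld <- rates$lambda_d
  le <- rates$lambda_e; mu <- rates$mu
  rad <- (mu + ld + ls)^2 + 4 * ld * (ls - mu)
  if (rad < 0) {
    warning("negative discriminant: complex kinetic eigenvalues ",
            "(damped oscillations)")
    Lambda <- sqrt(as.complex(rad))
  } else Lambda <- sqrt(rad)
  list(E1 = -(mu + 2 * le + ls),
       E2 = -(mu + ld + ls + Lambda) / 2,
       E3 = -(mu + ld + ls - Lambda) / 2,
       Lambda = Lambda)
}

#' Small-growth approximation of the unstable eigenvalue
#'
#' For `lambda_d (lambda_s - mu)` small compared to
#' `mu + lambda_d + lambda_s`, the potentially unstable eigenvalue reduces
#' to `lambda_d (lambda_s - mu) / (mu + lambda_d + lambda_s)`.
#'
#' @inheritParams wm_eigenvalues
#' @return A single growth rate.
#' @export
wm_unstable_eigenvalue_approx <- function(rates) {
  stopifnot(inherits(rates, "rt_rates"))
  den <- rates$mu + rates$lambda_d + rates$lambda_s
  if (den == 0) stop_param("mu + lambda_d + lambda_s must be nonzero")
  rates$lambda_d * (rates$lambda_s - rates$mu) / den
}

wm_check_balanced <- function(rates) {
  tol <- 1e-9 * max(rates$lambda_s, rates$mu, rates$lambda_e)
  if (abs(rates$lambda_s - rates$mu) > tol)
    stop_param("a finite nonzero stationary state of the linear model ",
               "requires lambda_s = mu (got lambda_s = ", rates$lambda_s,
               ", mu = ", rates$mu, ")")
}

#' Stationary state of the balanced linear model
#'
#' On the separating line `lambda_s = mu` the linear dynamics conserve
#' `R = rho_+ + rho_- + 2 rho_0` and relax to
#' `rho_+ = rho_- = lambda_d R0 / (2 (2 mu + lambda_d))`,
#' `rho_0 = mu R0 / (2 mu + lambda_d)`, independent of how the initial
#' density `R0` was distributed among the states.
#'
#' @inheritParams wm_eigenvalues
#' @param R0 initial conserved density `2 rho_0(0) + rho_+(0) + rho_-(0)`.
#' @return A [density_triple()].
#' @export
wm_stationary <- function(rates, R0 = 1) {
  stopifnot(inherits(rates, "rt_rates"))
  check_scalar(R0, "R0")
  wm_check_balanced(rates)
  mu <- rates$mu; ld <- rates$lambda_d
  if (mu + ld == 0) return(density_triple(0, R0 / 2, 0))
  density_triple(ld * R0 / (2 * (2 * mu + ld)),
                 mu * R0 / (2 * mu + ld),
                 ld * R0 / (2 * (2 * mu + ld)))
}

wm_series <- function(times, states) {
  df <- data.frame(t = times,
                   rho_plus = states[1, ],
                   rho_0 = states[2, ],
                   rho_minus = states[3, ])
  df$N <- df$rho_plus + df$rho_0 + df$rho_minus
  df$R <- df$rho_plus + df$rho_minus + 2 * df$rho_0
  df
}

#' Exact evolution of the linear well-mixed model
#'
#' Propagates `rho(t) = exp(M t) rho(0)` with the matrix exponential of the
#' kinetic matrix (eigen-decomposition with a scaling-and-squaring
#' fall-back for defective cases).
#'
#' @param init initial density triple.
#' @param rates an [kinetic_rates()] object.
#' @param times non-negative times at which to report the state.
#' @return A data frame with columns `t`, `rho_plus`, `rho_0`, `rho_minus`,
#'   the total `N` and the weighted total `R = rho_+ + rho_- + 2 rho_0`
#'   (conserved when `lambda_s = mu`).
#' @examples
#' r <- kinetic_rates(1, 2, 1, 1)
#' wm_evolve_linear(density_triple(0, 2, 0), r, times = c(0, 1, 10))
#' @export
wm_evolve_linear <- function(init, rates, times) {
  stopifnot(inherits(rates, "rt_rates"))
  rho0 <- as_density3(init)
  times <- as.numeric(times)
  if (any(times < 0)) stop_param("'times' must be non-negative")
  M <- rate_matrix(rates)
  states <- vapply(times, function(t) {
    if (t == 0) rho0 else drop(mat_exp(M * t) %*% rho0)
  }, numeric(3))
  wm_series(times, matrix(states, nrow = 3))
}

rk4_step <- function(y, dt, f) {
  k1 <- f(y)
  k2 <- f(y + dt / 2 * k1)
  k3 <- f(y + dt / 2 * k2)
  k4 <- f(y + dt * k3)
  y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Evolution of the logistic (saturating-growth) well-mixed model
#'
#' Integrates `d rho/dt = M_D rho + M_OD R(rho)` with classical fixed-step
#' RK4, where the saturating growth vector `R(rho)` replaces `rho` in the
#' off-diagonal (growth) part of the kinetics.  If a step would drive a
#' component below `-1e-12` the step is retried with a smaller `dt`;
#' persistent failure raises an integration error.
#'
#' @param init initial density triple.
#' @param params an [rt_params()] object with `growth_mode = "logistic"`.
#' @param times non-negative, increasing report times.
#' @param dt time step (default `1e-4 / lambda_e`).
#' @return A data frame as in [wm_evolve_linear()].
#' @export
wm_evolve_logistic <- function(init, params, times, dt = NULL) {
  stopifnot(inherits(params, "rt_params"))
  if (params$growth_mode != "logistic")
    stop_param("params must have growth_mode = 'logistic'")
  rho <- as_density3(init)
  times <- as.numeric(times)
  if (any(times < 0) || is.unsorted(times))
    stop_param("'times' must be non-negative and increasing")
  dt <- dt %||% 1e-4 / params$rates$lambda_e
  parts <- rate_matrix_parts(params$rates)
  cc <- params$carrying
  f <- function(y) drop(parts$M_D %*% y) + drop(parts$M_OD %*% logistic_growth(y, cc))
  out <- matrix(NA_real_, 3, length(times))
  t_now <- 0
  for (i in seq_along(times)) {
    target <- times[i]
    while (t_now < target - 1e-14 * max(1, target)) {
      h <- min(dt, target - t_now)
      tries <- 0L
      repeat {
        cand <- rk4_step(rho, h, f)
        if (all(cand >= -1e-12)) break
        h <- h / 2; tries <- tries + 1L
        if (tries > 40L)
          stop_param("step-size collapse at t = ", format(t_now),
                     ": state = (", paste(format(rho), collapse = ", "), ")")
      }
      rho <- pmax(cand, 0)
      t_now <- t_now + h
    }
    out[, i] <- rho
  }
  wm_series(times, out)
}
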