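## Fourier-space solution of the free (non-interacting) spatial model:
## propagator, intermediate scattering function, displacement moments and
## their short- and long-time expansions with crossover times.
##
## The default initial condition throughout is a single settled cell at the
## origin, rho(x, 0) = (0, delta(x), 0), represented exactly in Fourier
## space as rho~(k, 0) = (0, 1, 0).

free_cell_check <- function(params) {
  ia <- params$interactions
  if (ia$kappa != 0 || ia$kappa_0 != 0)
    stop_param("Fourier-space solutions are available for free cells only ",
               "(kappa = kappa_0 = 0)")
}

transport_matrices <- function(params) {
  tr <- params$transport
  list(Dm = diag(c(tr$D, 0, tr$D)),
       V = diag(c(tr$v_plus, 0, -tr$v_minus)))
}

#' Fourier-space propagator of the free model
#'
#' The density transform evolves as
#' `rho~(k, t) = exp[(-k^2 D - i k V + M) t] rho~(k, 0)`, with the diagonal
#' diffusion and advection matrices `D = diag(D, 0, D)`,
#' `V = diag(v_+, 0, -v_-)` and the kinetic matrix `M`.  At `k = 0` this
#' reduces to the well-mixed propagator `exp(M t)`.
#'
#' @param k wavenumber (1/length).
#' @param t time, `>= 0`.
#' @param params an [rt_params()] object with zero interactions.
#' @return A 3x3 complex matrix.
#' @export
spectral_propagator <- function(k, t, params) {
  stopifnot(inherits(params, "rt_params"))
  free_cell_check(params)
  check_scalar(k, "k", non_negative = FALSE)
  check_scalar(t, "t")
  tm <- transport_matrices(params)
  M <- rate_matrix(params$rates)
  A <- M - k^2 * tm$Dm - 1i * k * tm$V
  mat_exp(A * t)
}

selector_index <- function(selector) {
  switch(selector, plus = 1L, settled = 2L, zero = 2L, minus = 3L,
         stop_param("unknown population selector '", selector, "'"))
}

#' Intermediate scattering function
#'
#' For the total population,
#' `F(k, t) = P~(k, t) P~(-k, 0) N(t)`, where `P~` is the transform of the
#' normalized total density; for a single population `alpha`,
#' `F_a(k, t) = rho~_a(k, t) rho~_a(-k, 0) / N_a(0)`.  At `k = 0` the ISF
#' equals the (population) cell number `N(t)` (or `N_a(t)`).  The initial
#' condition is supplied directly in Fourier space as a triple of point
#' masses at the origin, i.e. `rho~(k, 0)` is constant in `k`.
#'
#' @param k wavenumber(s).
#' @param t time(s); `k` and `t` are recycled to a common grid if one of
#'   them has length 1, otherwise evaluated pairwise.
#' @param params an [rt_params()] object with zero interactions.
#' @param init Fourier-space initial amplitudes `(rho~_+, rho~_0, rho~_-)`;
#'   the default is a single settled cell at the origin.
#' @param selector `"total"`, `"plus"`, `"settled"` or `"minus"`.
#' @return A complex vector of ISF values.
#' @export
isf <- function(k, t, params, init = c(0, 1, 0), selector = "total") {
  stopifnot(inherits(params, "rt_params"))
  free_cell_check(params)
  init <- as_density3(init)
  n <- max(length(k), length(t))
  k <- rep_len(k, n); t <- rep_len(t, n)
  if (selector == "total" && sum(init) == 0)
    stop_param("N(0) = 0: the total ISF is undefined")
  if (selector != "total" && init[selector_index(selector)] == 0)
    stop_param("population '", selector, "' is empty at t = 0; ",
               "its ISF is undefined")
  vapply(seq_len(n), function(i) {
    rho_t <- drop(spectral_propagator(k[i], t[i], params) %*% init)
    if (selector == "total") {
      # P~(k,t) P~(-k,0) N(t) with point-mass init: P~(-k,0) = N(0)/N(0) = 1
      sum(rho_t)
    } else {
      # rho~_a(k,t) rho~_a(-k,0) / N_a(0), with rho~_a(-k,0) = N_a(0)
      rho_t[selector_index(selector)]
    }
  }, complex(1))
}

## Exact k-derivatives of rho~(k, t) at k = 0.
##
## Differentiating the Fourier-space evolution equation n times in k gives a
## closed linear system for y_m = d^m rho~ / dk^m at k = 0:
##   dy_m/dt = M y_m - i m V y_{m-1} - m (m-1) D y_{m-2},
## with y_0(0) = rho~(0, 0) and y_m(0) = 0 for point-mass initial data.
## The block-triangular system is solved with one matrix exponential, so
## the moments carry no finite-difference step-size error.
moment_derivatives <- function(order, times, params, init) {
  tm <- transport_matrices(params)
  M <- rate_matrix(params$rates)
  nb <- order + 1L
  B <- matrix(0i, 3 * nb, 3 * nb)
  for (m in 0:order) {
    r <- 3 * m + 1:3
    B[r, r] <- M
    if (m >= 1) B[r, r - 3] <- -1i * m * tm$V
    if (m >= 2) B[r, r - 6] <- -m * (m - 1) * tm$Dm
  }
  y0 <- complex(3 * nb)
  y0[1:3] <- init
  vapply(times, function(t) mat_exp(B * t) %*% y0, complex(3 * nb))
}

#' Displacement moments of the free model
#'
#' Computes `<(x - x0)^n>` for the chosen population from k-derivatives of
#' the intermediate scattering function at `k = 0`,
#' `<(x - x0)^n> = i^n / N(t) * d^n F / dk^n |_{k=0}` (with `N_a(t)` for a
#' single population).  The derivatives are obtained exactly by propagating
#' the coupled linear system for `d^m rho~ / dk^m` at `k = 0`; see the
#' package vignette for the construction.
#'
#' @param orders integer vector of moment orders (`>= 1`).
#' @param times non-negative times.
#' @param params an [rt_params()] object with zero interactions.
#' @param init Fourier-space initial amplitudes (point masses at the
#'   origin); default is a single settled cell.
#' @param selector `"total"`, `"plus"`, `"settled"` or `"minus"`.
#' @return A data frame with column `t`, one column `moment_<n>` per
#'   requested order, and the population normalization `N`.
#' @examples
#' p <- rt_params(kinetic_rates(1, 1, 1, 1), transport(1, 0.9, 0.2))
#' displacement_moments(1:2, c(0.1, 1, 10), p)
#' @export
displacement_moments <- function(orders, times, params, init = c(0, 1, 0),
                                 selector = "total") {
  stopifnot(inherits(params, "rt_params"))
  free_cell_check(params)
  orders <- as.integer(orders)
  if (any(orders < 1)) stop_param("'orders' must be >= 1")
  times <- as.numeric(times)
  if (any(times < 0)) stop_param("'times' must be non-negative")
  init <- as_density3(init)
  nmax <- max(orders)
  Y <- moment_derivatives(nmax, times, params, init)
  out <- data.frame(t = times)
  idx <- if (selector == "total") 1:3 else selector_index(selector)
  Nt <- Re(colSums(Y[idx, , drop = FALSE]))
  if (selector != "total" && init[idx] == 0 && any(Nt <= 0))
    stop_param("population '", selector, "' is empty; moments undefined")
  if (any(Nt <= 0))
    stop_param("population size vanished; moments undefined")
  for (n in sort(unique(orders))) {
    dn <- colSums(Y[3 * n + idx, , drop = FALSE])
    out[[paste0("moment_", n)]] <- Re((1i)^n * dn) / Nt
  }
  out$N <- Nt
  out
}

#' Short-time expansion coefficients of the MD and MSD
#'
#' Leading and next-to-leading coefficients of the short-time expansions for
#' a single settled cell at the origin.  For the total population the mean
#' displacement starts as `lambda_d v_d t^2` and the MSD as
#' `2 D lambda_d t^2`; for the settled population both start one power of
#' `t` later (`t^3`), which is the super-ballistic regime characteristic of
#' settle-double-swim kinetics.
#'
#' @param params an [rt_params()] object with zero interactions.
#' @param selector `"total"` or `"settled"`.
#' @return A list with components `MD` and `MSD`, each a named numeric
#'   vector of coefficients of the two leading powers of `t` (names `t2`,
#'   `t3` for the total population; `t3`, `t4` for the settled one).
#' @export
short_time_coefficients <- function(params, selector = c("total", "settled")) {
  stopifnot(inherits(params, "rt_params"))
  free_cell_check(params)
  selector <- match.arg(selector)
  r <- params$rates
  ls <- r$lambda_s; ld <- r$lambda_d; mu <- r$mu
  D <- params$transport$D
  vd <- (params$transport$v_plus - params$transport$v_minus) / 2
  va <- sqrt((params$transport$v_plus^2 + params$transport$v_minus^2) / 2)
  if (selector == "total") {
    list(MD = c(t2 = ld * vd,
                t3 = -ld * vd * (2 * mu + 4 * ld + ls) / 3),
         MSD = c(t2 = 2 * D * ld,
                 t3 = -(2 / 3) * ld * (D * (2 * mu + 4 * ld + ls) - va^2)))
  } else {
    list(MD = c(t3 = ls * ld * vd / 3,
                t4 = -ls * ld * vd * (mu - ld + ls) / 6),
         MSD = c(t3 = (2 / 3) * D * ls * ld,
                 t4 = -(1 / 6) * ls * ld * (2 * D * (mu - ld + ls) - va^2)))
  }
}

#' Crossover times between short-time scaling regimes
#'
#' Each crossover time is the ratio of the absolute values of consecutive
#' short-time expansion coefficients: `t_c1 = 3 / (2 mu + 4 lambda_d +
#' lambda_s)` (MD of the total population), `t_c2 = 3 D / |D (2 mu + 4
#' lambda_d + lambda_s) - v_a^2|` (MSD), and the settled-population
#' analogues `t_c0_1 = 2 / |mu - lambda_d + lambda_s|`,
#' `t_c0_2 = 4 D / |2 D (mu - lambda_d + lambda_s) - v_a^2|`.  An exactly
#' vanishing denominator yields `Inf` for that entry.  `t_l2`, the
#' long-time crossover of the MSD from diffusive to ballistic growth, has
#' no compact closed form and is estimated numerically from the computed
#' MSD when `compute_t_l2 = TRUE` (see [msd_long_crossover()]).
#'
#' @param params an [rt_params()] object with zero interactions.
#' @param compute_t_l2 also estimate the numerical long-time MSD crossover.
#' @return A list with `t_c1`, `t_c2`, `t_c0_1`, `t_c0_2` and `t_l2`
#'   (`NA` unless requested).
#' @export
crossover_times <- function(params, compute_t_l2 = FALSE) {
  stopifnot(inherits(params, "rt_params"))
  free_cell_check(params)
  r <- params$rates
  ls <- r$lambda_s; ld <- r$lambda_d; mu <- r$mu
  D <- params$transport$D
  va <- sqrt((params$transport$v_plus^2 + params$transport$v_minus^2) / 2)
  ratio <- function(num, den) if (den == 0) Inf else num / abs(den)
  list(t_c1 = ratio(3, 2 * mu + 4 * ld + ls),
       t_c2 = ratio(3 * D, D * (2 * mu + 4 * ld + ls) - va^2),
       t_c0_1 = ratio(2, mu - ld + ls),
       t_c0_2 = ratio(4 * D, 2 * D * (mu - ld + ls) - va^2),
       t_l2 = if (compute_t_l2) msd_long_crossover(params) else NA_real_)
}

#' Long-time slope of the mean displacement
#'
#' The MD grows linearly at long times with slope
#' `4 v_d lambda_d lambda_s / (Lambda (mu - lambda_d + lambda_s + Lambda))`;
#' for equal running speeds (`v_d = 0`) the MD saturates and the slope is
#' zero.
#'
#' @param params an [rt_params()] object with zero interactions.
#' @return The asymptotic MD slope (length/time).
#' @export
md_long_time_slope <- function(params) {
  stopifnot(inherits(params, "rt_params"))
  free_cell_check(params)
  r <- params$rates
  vd <- (params$transport$v_plus - params$transport$v_minus) / 2
  if (vd == 0) return(0)
  ev <- wm_eigenvalues(r)
  Lam <- ev$Lambda
  den <- Lam * (r$mu - r$lambda_d + r$lambda_s + Lam)
  if (abs(den) == 0)
    stop_param("degenerate spectrum: long-time MD slope undefined")
  4 * vd * r$lambda_d * r$lambda_s / den
}

#' Numerical long-time crossover of the MSD
#'
#' The time at which the long-time ballistic asymptote of the MSD,
#' `(slope * t)^2` with the slope from [md_long_time_slope()], overtakes
#' the fitted intermediate diffusive asymptote `a + b t`.  The diffusive
#' asymptote is fitted by least squares on log-spaced samples of the
#' computed MSD restricted to the window where its local log-log slope is
#' within `0.15` of 1.  Returns `Inf` for equal running speeds (no
#' ballistic regime).  This is a numerical surrogate for a closed form
#' that is too unwieldy to state.
#'
#' @param params an [rt_params()] object with zero interactions.
#' @param t_range range of times scanned (log-spaced).
#' @param n_points number of samples.
#' @return The crossover time (possibly `Inf`).
#' @export
msd_long_crossover <- function(params, t_range = c(1, 1e5), n_points = 60) {
  cb <- md_long_time_slope(params)^2
  if (cb == 0) return(Inf)
  ts <- exp(seq(log(t_range[1]), log(t_range[2]), length.out = n_points))
  msd <- displacement_moments(2, ts, params)$moment_2
  lsl <- diff(log(msd)) / diff(log(ts))
  mid <- 0.5 * (ts[-1] + ts[-n_points])
  in_diff <- abs(lsl - 1) < 0.15
  if (!any(in_diff))
    stop_param("no diffusive window found in t_range; widen the range")
  sel <- ts %in% c(ts[-1][in_diff], ts[-n_points][in_diff])
  fit <- lm(msd[sel] ~ ts[sel])
  a <- coef(fit)[[1]]; b <- coef(fit)[[2]]
  # a + b t = cb t^2, positive root
  (b + sqrt(b^2 + 4 * cb * a)) / (2 * cb)
}
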