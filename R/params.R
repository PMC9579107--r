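## Parameter containers and algebraic building blocks shared by all modules.
##
## Unit conventions: the package works in nondimensional units in which the
## tumbling rate lambda_e sets the unit of time and the domain length L the
## unit of length; densities are dimensionless.  Presets are stored in these
## units; `params_from_si()` converts a parameter set quoted in SI units.
## Species ordering is (rho_+, rho_0, rho_-) everywhere.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, non_negative = TRUE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_param("'", name, "' must be a single non-missing number")
  if (finite && !is.finite(x))
    stop_param("'", name, "' must be finite")
  if (non_negative && x < 0)
    stop_param("'", name, "' must be non-negative (got ", format(x), ")")
  as.numeric(x)
}

#' Kinetic rates of the three-state cell cycle
#'
#' Bundles the four kinetic rates of the model: settling of movers into the
#' sedentary state (`lambda_s`), doubling of sedentary cells into a pair of
#' opposite movers (`lambda_d`), directional exchange (tumbling, `lambda_e`)
#' and death of movers (`mu`).  All rates are in units of inverse time;
#' in the package's nondimensional convention `lambda_e = 1`.
#'
#' @param lambda_s settling rate (1/time), `>= 0`.
#' @param lambda_d doubling rate (1/time), `>= 0`.
#' @param lambda_e tumbling/exchange rate (1/time), `> 0`.
#' @param mu death rate of moving cells (1/time), `>= 0`.
#' @return An object of class `rt_rates`.
#' @examples
#' kinetic_rates(lambda_s = 1, lambda_d = 1, lambda_e = 1, mu = 1)
#' @export
kinetic_rates <- function(lambda_s, lambda_d, lambda_e = 1, mu = 0) {
  r <- list(
    lambda_s = check_scalar(lambda_s, "lambda_s"),
    lambda_d = check_scalar(lambda_d, "lambda_d"),
    lambda_e = check_scalar(lambda_e, "lambda_e"),
    mu       = check_scalar(mu, "mu")
  )
  if (r$lambda_e <= 0)
    stop_param("'lambda_e' must be positive: it sets the unit of time")
  structure(r, class = "rt_rates")
}

#' Transport coefficients of the moving populations
#'
#' @param v_plus speed of right-movers (length/time), `>= 0`.
#' @param v_minus speed of left-movers (length/time), `>= 0`.
#' @param D diffusivity of the movers (length^2/time), `>= 0`; sedentary
#'   cells do not diffuse.
#' @return An object of class `rt_transport`.
#' @export
transport <- function(v_plus, v_minus, D) {
  structure(list(
    v_plus  = check_scalar(v_plus, "v_plus"),
    v_minus = check_scalar(v_minus, "v_minus"),
    D       = check_scalar(D, "D")
  ), class = "rt_transport")
}

#' Density-mediated interaction strengths
#'
#' `kappa` is the strength of the attraction of movers towards regions rich
#' in settled cells; `kappa_0` is the self-repulsion among settled cells
#' (overcrowding avoidance).  Both enter the flux term
#' `d/dx [ (d/dx U) rho ]` and carry units of length^2/time per unit density.
#'
#' @param kappa attraction strength, `>= 0`.
#' @param kappa_0 settled-cell self-repulsion strength, `>= 0`.
#' @return An object of class `rt_interactions`.
#' @export
interactions <- function(kappa = 0, kappa_0 = 0) {
  structure(list(
    kappa   = check_scalar(kappa, "kappa"),
    kappa_0 = check_scalar(kappa_0, "kappa_0")
  ), class = "rt_interactions")
}

#' Carrying capacities for logistic growth
#'
#' Componentwise saturation densities of the logistic growth term.  Infinite
#' entries reproduce the linear-growth limit for that component.
#'
#' @param rho_plus_c,rho_0_c,rho_minus_c carrying capacities (`> 0`, may be
#'   `Inf`).
#' @return An object of class `rt_carrying`.
#' @export
carrying_capacity <- function(rho_plus_c = Inf, rho_0_c = Inf,
                              rho_minus_c = Inf) {
  cc <- list(
    rho_plus_c  = check_scalar(rho_plus_c, "rho_plus_c", finite = FALSE),
    rho_0_c     = check_scalar(rho_0_c, "rho_0_c", finite = FALSE),
    rho_minus_c = check_scalar(rho_minus_c, "rho_minus_c", finite = FALSE)
  )
  if (any(unlist(cc) <= 0))
    stop_param("carrying capacities must be strictly positive")
  structure(cc, class = "rt_carrying")
}

#' Full model parameter set
#'
#' Collects rates, transport coefficients, interaction strengths and
#' carrying capacities, together with the growth mode.  In `"linear"` mode
#' the carrying capacities are treated as infinite; `"logistic"` mode
#' requires at least one finite carrying capacity and bounds the growth of
#' the populations.
#'
#' @param rates an [kinetic_rates()] object.
#' @param transport a [transport()] object.
#' @param interactions an [interactions()] object (defaults to free cells).
#' @param carrying a [carrying_capacity()] object.
#' @param growth_mode `"linear"` or `"logistic"`.
#' @param L domain length (length units), used by the spatial solver.
#' @return An object of class `rt_params`.
#' @examples
#' p <- rt_params(kinetic_rates(1, 1, 1, 1), transport(1, 0.9, 0.2))
#' rate_matrix(p$rates)
#' @export
rt_params <- function(rates, transport, interactions = rtcycle::interactions(),
                      carrying = carrying_capacity(),
                      growth_mode = c("linear", "logistic"), L = 1) {
  growth_mode <- match.arg(growth_mode)
  stopifnot(inherits(rates, "rt_rates"), inherits(transport, "rt_transport"),
            inherits(interactions, "rt_interactions"),
            inherits(carrying, "rt_carrying"))
  L <- check_scalar(L, "L")
  if (L <= 0) stop_param("'L' must be positive")
  if (growth_mode == "linear") {
    carrying <- carrying_capacity(Inf, Inf, Inf)
  } else if (all(!is.finite(unlist(carrying)))) {
    stop_param("growth_mode = 'logistic' requires a finite carrying capacity")
  }
  structure(list(rates = rates, transport = transport,
                 interactions = interactions, carrying = carrying,
                 growth_mode = growth_mode, L = L),
            class = "rt_params")
}

#' @export
print.rt_params <- function(x, ...) {
  r <- x$rates; tr <- x$transport; ia <- x$interactions; cc <- x$carrying
  cat("Three-state run-and-tumble model parameters\n")
  cat(sprintf("  rates:        lambda_s = %g, lambda_d = %g, lambda_e = %g, mu = %g\n",
              r$lambda_s, r$lambda_d, r$lambda_e, r$mu))
  cat(sprintf("  transport:    v_plus = %g, v_minus = %g, D = %g\n",
              tr$v_plus, tr$v_minus, tr$D))
  cat(sprintf("  interactions: kappa = %g, kappa_0 = %g\n", ia$kappa, ia$kappa_0))
  cat(sprintf("  growth:       %s", x$growth_mode))
  if (x$growth_mode == "logistic")
    cat(sprintf(" (rho_c = %g, %g, %g)", cc$rho_plus_c, cc$rho_0_c, cc$rho_minus_c))
  cat(sprintf("\n  domain:       L = %g\n", x$L))
  invisible(x)
}

#' Density triple (rho_+, rho_0, rho_-)
#'
#' A non-negative vector of the three population densities, ordered as
#' right-movers, sedentary cells, left-movers.
#'
#' @param rho_plus,rho_0,rho_minus densities, `>= 0`.
#' @return A named numeric vector of class `rt_density`.
#' @export
density_triple <- function(rho_plus, rho_0, rho_minus) {
  v <- c(rho_plus = check_scalar(rho_plus, "rho_plus"),
         rho_0 = check_scalar(rho_0, "rho_0"),
         rho_minus = check_scalar(rho_minus, "rho_minus"))
  structure(v, class = c("rt_density", "numeric"))
}

as_density3 <- function(x) {
  if (inherits(x, "rt_density")) return(unclass(x))
  x <- as.numeric(x)
  if (length(x) != 3L || anyNA(x))
    stop_param("a density triple must have exactly 3 non-missing components")
  names(x) <- c("rho_plus", "rho_0", "rho_minus")
  x
}

#' Kinetic transition matrix of the cell cycle
#'
#' Builds the 3x3 rate matrix `M` acting on the density vector
#' `(rho_+, rho_0, rho_-)`: movers settle at `lambda_s`, tumble at
#' `lambda_e` and die at `mu`; sedentary cells double at `lambda_d` into one
#' right- and one left-mover.  Its column sums are `(-mu, +lambda_d, -mu)`,
#' so the total cell number changes only through death of movers and
#' doubling of settled cells.
#'
#' @param rates an [kinetic_rates()] object.
#' @return A 3x3 numeric matrix.
#' @seealso [rate_matrix_parts()] for the diagonal/off-diagonal split used
#'   by the logistic growth model.
#' @export
rate_matrix <- function(rates) {
  stopifnot(inherits(rates, "rt_rates"))
  ls <- rates$lambda_s; ld <- rates$lambda_d
  le <- rates$lambda_e; mu <- rates$mu
  matrix(c(
    -(ls + le + mu), ld,  le,
    ls,             -ld,  ls,
    le,              ld, -(ls + le + mu)
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("rho_plus", "rho_0", "rho_minus"),
                  c("rho_plus", "rho_0", "rho_minus")))
}

#' Diagonal / off-diagonal split of the kinetic matrix
#'
#' Returns `M_D` (decay part, diagonal) and `M_OD` (growth part,
#' off-diagonal) with `M = M_D + M_OD`.  The logistic model applies the
#' saturating growth vector only through `M_OD`.
#'
#' @inheritParams rate_matrix
#' @return A list with matrices `M_D`, `M_OD` and `M`.
#' @export
rate_matrix_parts <- function(rates) {
  M <- rate_matrix(rates)
  M_D <- diag(diag(M))
  dimnames(M_D) <- dimnames(M)
  list(M_D = M_D, M_OD = M - M_D, M = M)
}

#' Logistic growth vector
#'
#' Componentwise saturating growth `rho_a (1 - rho_a / rho_{a,c})`.  With
#' infinite carrying capacities (linear mode) the state is returned
#' unchanged.
#'
#' @param state a density triple (vector of length 3).
#' @param carrying a [carrying_capacity()] object.
#' @return A numeric vector of length 3.
#' @export
logistic_growth <- function(state, carrying) {
  stopifnot(inherits(carrying, "rt_carrying"))
  rho <- as_density3(state)
  cc <- unlist(carrying, use.names = FALSE)
  out <- rho * (1 - rho / cc)
  out[!is.finite(cc)] <- rho[!is.finite(cc)]
  names(out) <- names(rho)
  out
}

#' Derived speed scales
#'
#' Computes the drift speed `v_d = (v_+ - v_-)/2`, the quadratic-mean speed
#' `v_a = sqrt((v_+^2 + v_-^2)/2)`, the dimensionless maximum speed
#' `v_m = max(v_+, v_-)/sqrt(D lambda_e)` and the reduced difference speed
#' `v_r = (v_+ - v_-)/(v_+ + v_-)`.
#'
#' @param transport a [transport()] object.
#' @param lambda_e tumbling rate used to nondimensionalize `v_m`.
#' @return A list with `v_d`, `v_a`, `v_m`, `v_r`.
#' @export
derived_speeds <- function(transport, lambda_e = 1) {
  stopifnot(inherits(transport, "rt_transport"))
  vp <- transport$v_plus; vm <- transport$v_minus; D <- transport$D
  check_scalar(lambda_e, "lambda_e")
  v_m <- if (D > 0 && lambda_e > 0) max(vp, vm) / sqrt(D * lambda_e) else {
    if (max(vp, vm) == 0) 0 else
      stop_param("v_m is undefined for D = 0 (or lambda_e = 0) with nonzero speeds")
  }
  v_r <- if (vp + vm > 0) (vp - vm) / (vp + vm) else
    stop_param("v_r is undefined when v_plus + v_minus = 0")
  list(v_d = (vp - vm) / 2,
       v_a = sqrt((vp^2 + vm^2) / 2),
       v_m = v_m,
       v_r = v_r)
}

#' Map dimensionless speeds (v_r, v_m) back to running speeds
#'
#' Inverts the definitions of the reduced difference speed `v_r` and the
#' dimensionless maximum speed `v_m` for `v_r >= 0` (so that
#' `v_+ >= v_-`): `v_+ = v_m sqrt(D lambda_e)` and
#' `v_- = v_+ (1 - v_r)/(1 + v_r)`.
#'
#' @param v_r reduced difference speed in `[0, 1)`.
#' @param v_m dimensionless maximum speed, `> 0`.
#' @param D mover diffusivity.
#' @param lambda_e tumbling rate.
#' @return A list with `v_plus` and `v_minus`.
#' @export
speeds_from_vr_vm <- function(v_r, v_m, D, lambda_e = 1) {
  check_scalar(v_r, "v_r"); check_scalar(v_m, "v_m")
  if (v_r < 0 || v_r >= 1) stop_param("'v_r' must lie in [0, 1)")
  v_plus <- v_m * sqrt(D * lambda_e)
  list(v_plus = v_plus, v_minus = v_plus * (1 - v_r) / (1 + v_r))
}

#' Convert a parameter set quoted in SI units to model units
#'
#' Nondimensionalizes rates by the tumbling rate `lambda_e`, lengths by the
#' domain length `L` and densities by a reference density, so that
#' internally `lambda_e = 1` and `L = 1`.
#'
#' @param lambda_s,lambda_d,lambda_e,mu rates in 1/s.
#' @param v_plus,v_minus speeds in m/s.
#' @param D diffusivity in m^2/s.
#' @param L domain length in m.
#' @param kappa,kappa_0 interaction strengths in units of `1/lambda_e`
#'   (per unit dimensionless density), passed through unchanged.
#' @param carrying carrying capacities (dimensionless densities).
#' @param growth_mode `"linear"` or `"logistic"`.
#' @return An [rt_params()] object in nondimensional units.
#' @export
params_from_si <- function(lambda_s, lambda_d, lambda_e, mu,
                           v_plus, v_minus, D, L,
                           kappa = 0, kappa_0 = 0,
                           carrying = carrying_capacity(),
                           growth_mode = "linear") {
  rt_params(
    rates = kinetic_rates(lambda_s / lambda_e, lambda_d / lambda_e, 1,
                          mu / lambda_e),
    transport = transport(v_plus / (L * lambda_e), v_minus / (L * lambda_e),
                          D / (L^2 * lambda_e)),
    interactions = interactions(kappa, kappa_0),
    carrying = carrying,
    growth_mode = growth_mode,
    L = 1
  )
}
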