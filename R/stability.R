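## Linear stability of the homogeneous stationary state with attraction
## (kappa) and settled-cell self-repulsion (kappa_0): Fourier-space
## Jacobian, dispersion branches, stability conditions, largest unstable
## wavenumber and the separatrix fit in the (v_r, v_m) plane.

#' Homogeneous stationary state used for linearization
#'
#' Symmetric homogeneous state `(rho_hat_+, rho_hat_0, rho_hat_-)` with
#' `rho_hat_+ = rho_hat_-` and the stationary composition ratio
#' `rho_hat_0 / rho_hat_+ = 2 mu / lambda_d`.  Either construct it from an
#' explicit `rho_plus` and `rho_0`, or use [homogeneous_state_from_R()] to
#' take the stationary state carrying a conserved density `R`.
#'
#' @param rho_plus common density of the two moving populations, `> 0`.
#' @param rho_0 density of the settled population, `> 0`.
#' @return An object of class `rt_hstate`.
#' @export
homogeneous_state <- function(rho_plus, rho_0) {
  structure(list(rho_hat_plus = check_scalar(rho_plus, "rho_plus"),
                 rho_hat_0 = check_scalar(rho_0, "rho_0"),
                 rho_hat_minus = check_scalar(rho_plus, "rho_plus")),
            class = "rt_hstate")
}

#' @rdname homogeneous_state
#' @param rates an [kinetic_rates()] object on the balanced line
#'   `lambda_s = mu`.
#' @param R conserved density `rho_+ + rho_- + 2 rho_0` carried by the
#'   state; the package default normalization is `R = 1`.
#' @export
homogeneous_state_from_R <- function(rates, R = 1) {
  st <- wm_stationary(rates, R0 = R)
  homogeneous_state(st[["rho_plus"]], st[["rho_0"]])
}

#' @export
print.rt_hstate <- function(x, ...) {
  cat(sprintf("Homogeneous state: rho_hat_+/- = %g, rho_hat_0 = %g (R = %g)\n",
              x$rho_hat_plus, x$rho_hat_0,
              2 * x$rho_hat_0 + 2 * x$rho_hat_plus))
  invisible(x)
}

#' Fourier-space Jacobian of the linearized interacting model
#'
#' The linear operator `J(k)` governing a plane-wave perturbation
#' `delta rho ~ exp(i k x)` about the homogeneous state: transport
#' contributes `-i k v_+/- - D k^2` on the mover diagonal, the attraction
#' couples movers to the settled perturbation with `+kappa k^2 rho_hat_+/-`,
#' and the settled-cell self-repulsion adds `-kappa_0 rho_hat_0 k^2` to the
#' settled diagonal.  `J(0)` equals the kinetic matrix exactly.
#'
#' @param k wavenumber.
#' @param params an [rt_params()] object.
#' @param hs an [homogeneous_state()] object.
#' @return A 3x3 complex matrix.
#' @export
fourier_jacobian <- function(k, params, hs) {
  stopifnot(inherits(params, "rt_params"), inherits(hs, "rt_hstate"))
  r <- params$rates; tr <- params$transport; ia <- params$interactions
  ls <- r$lambda_s; ld <- r$lambda_d; le <- r$lambda_e; mu <- r$mu
  k2 <- k^2
  matrix(c(
    -1i * k * tr$v_plus - tr$D * k2 - (ls + le + mu),
    ld + ia$kappa * k2 * hs$rho_hat_plus,
    le + 0i,
    ls + 0i,
    -ld - ia$kappa_0 * hs$rho_hat_0 * k2,
    ls + 0i,
    le + 0i,
    ld + ia$kappa * k2 * hs$rho_hat_minus,
    1i * k * tr$v_minus - tr$D * k2 - (ls + le + mu)
  ), nrow = 3, byrow = TRUE)
}

## Largest real part among the three dispersion branches at one k.
s1_re_max <- function(k, params, hs) {
  max(Re(eigen(fourier_jacobian(k, params, hs), only.values = TRUE)$values))
}

#' Dispersion branches of the linearized system
#'
#' Eigenvalues `s_i(k)` of the Fourier-space Jacobian on a wavenumber grid.
#' Branches are continued across the grid by minimal-distance matching (so
#' crossings do not scramble them) and labeled so that branch 1 starts at
#' the kinetic eigenvalue `E3` at `k = 0`, the only branch whose real part
#' can become positive.  Eigenvalues are obtained from a numerical
#' eigen-decomposition of `J(k)` rather than a closed-form cubic, for
#' robustness.
#'
#' @param k numeric vector of wavenumbers (typically starting at 0).
#' @param params an [rt_params()] object.
#' @param hs an [homogeneous_state()] object.
#' @return A data frame of class `rt_dispersion` with columns `k` and
#'   complex `s1`, `s2`, `s3`.
#' @export
dispersion_branches <- function(k, params, hs) {
  stopifnot(inherits(params, "rt_params"), inherits(hs, "rt_hstate"))
  k <- as.numeric(k)
  if (any(k < 0)) stop_param("'k' must be non-negative")
  vals <- matrix(0i, length(k), 3)
  prev <- NULL
  for (i in seq_along(k)) {
    ev <- eigen(fourier_jacobian(k[i], params, hs), only.values = TRUE)$values
    if (is.null(prev)) {
      ev <- ev[order(Re(ev), decreasing = TRUE)]
    } else {
      # nearest-match assignment to the previous k (3! = 6 permutations)
      perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                    c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      cost <- vapply(perms, function(p) sum(Mod(ev[p] - prev)), numeric(1))
      ev <- ev[perms[[which.min(cost)]]]
    }
    vals[i, ] <- ev
    prev <- ev
  }
  out <- data.frame(k = k)
  out$s1 <- vals[, 1]; out$s2 <- vals[, 2]; out$s3 <- vals[, 3]
  class(out) <- c("rt_dispersion", "data.frame")
  out
}

#' Limits of the leading dispersion branch
#'
#' `s1(0)` equals the kinetic eigenvalue `E3` (exponential growth or decay
#' of the total population).  The large-`k` behavior depends on the
#' settled-cell self-repulsion: for `kappa_0 = 0` and `D > 0` the branch
#' saturates at `2 kappa rho_hat_+ lambda_s / D - lambda_d`; for
#' `kappa_0 > 0` it decays as `-kappa_0 rho_hat_0 k^2`, so sufficiently
#' short wavelengths are always damped; for `D = 0` with `kappa_0 = 0` the
#' branch grows linearly in `k` and the system is always unstable.
#'
#' @inheritParams dispersion_branches
#' @return A list with `s1_at_0`, `large_k` (one of `"saturates"`,
#'   `"quadratic_decay"`, `"unbounded_linear_growth"`) and `large_k_value`
#'   (the saturation value, or the coefficient of `-k^2`).
#' @export
s1_limits <- function(params, hs) {
  stopifnot(inherits(params, "rt_params"), inherits(hs, "rt_hstate"))
  r <- params$rates; ia <- params$interactions; D <- params$transport$D
  s1_0 <- wm_eigenvalues(r)$E3
  if (ia$kappa_0 > 0) {
    list(s1_at_0 = s1_0, large_k = "quadratic_decay",
         large_k_value = ia$kappa_0 * hs$rho_hat_0)
  } else if (D > 0) {
    list(s1_at_0 = s1_0, large_k = "saturates",
         large_k_value = 2 * ia$kappa * hs$rho_hat_plus * r$lambda_s / D -
           r$lambda_d)
  } else {
    list(s1_at_0 = s1_0, large_k = "unbounded_linear_growth",
         large_k_value = Inf)
  }
}

#' Stability verdict for the homogeneous state
#'
#' In `"endpoints"` mode checks the two necessary conditions obtained from
#' the `k -> 0` and `k -> Inf` limits of the leading branch:
#' `mu >= lambda_s` and (for `kappa_0 = 0`)
#' `lambda_d >= 2 kappa rho_hat_+ lambda_s / D`; with `kappa_0 > 0` short
#' wavelengths are always damped and only the first condition remains as an
#' endpoint.  `"full_scan"` additionally scans `Re s1(k)` on a dense
#' log-spaced grid, catching band instabilities at intermediate `k` that
#' the endpoints miss.
#'
#' @inheritParams dispersion_branches
#' @param mode `"endpoints"` or `"full_scan"`.
#' @param k_max largest wavenumber scanned in `"full_scan"` mode.
#' @param n_grid number of scan points.
#' @param tol positivity tolerance on `Re s1` (the balanced case
#'   `lambda_s = mu` has `s1(0) = 0` exactly).
#' @return A list with logical `stable`, the character vector `failed`
#'   naming violated conditions, and (in full-scan mode) `k_unstable`, a
#'   wavenumber with `Re s1 > 0` if one was found.
#' @export
is_stable <- function(params, hs, mode = c("endpoints", "full_scan"),
                      k_max = 1e3, n_grid = 400, tol = 1e-10) {
  stopifnot(inherits(params, "rt_params"), inherits(hs, "rt_hstate"))
  mode <- match.arg(mode)
  r <- params$rates; ia <- params$interactions; D <- params$transport$D
  failed <- character(0)
  if (r$mu < r$lambda_s - tol) failed <- c(failed, "growth (mu >= lambda_s)")
  if (ia$kappa_0 == 0) {
    if (D == 0) {
      if (ia$kappa > 0 && r$lambda_s > 0)
        failed <- c(failed, "short-wavelength (D = 0: unbounded growth in k)")
    } else if (r$lambda_d < 2 * ia$kappa * hs$rho_hat_plus * r$lambda_s / D - tol)
      failed <- c(failed, "short-wavelength (lambda_d >= 2 kappa rho_hat_+ lambda_s / D)")
  }
  res <- list(stable = length(failed) == 0, failed = failed)
  if (mode == "full_scan") {
    ks <- c(0, exp(seq(log(1e-3), log(k_max), length.out = n_grid)))
    svals <- vapply(ks, s1_re_max, numeric(1), params = params, hs = hs)
    bad <- svals > tol
    if (any(bad)) {
      res$stable <- FALSE
      res$k_unstable <- ks[which.max(svals)]
      if (length(failed) == 0)
        res$failed <- "band instability at intermediate k"
    } else res$k_unstable <- NA_real_
  }
  res
}

#' Largest unstable wavenumber
#'
#' The largest root `k_r` of `Re s1(k) = 0`: short-wavelength instabilities
#' exist only below `k_r`, so the smallest unstable structure has size
#' `l = 2 pi / k_r` and a periodic box of length `L` can develop patterns
#' only if `k_r > 2 pi / L`.  Requires `kappa_0 > 0` so that `Re s1 < 0` at
#' large `k` and the root is well defined.  Found by sign-change bracketing
#' on a dense grid followed by bisection.
#'
#' @inheritParams dispersion_branches
#' @param k_max upper end of the search interval.
#' @param n_grid number of grid points for bracketing.
#' @param rel_tol relative bisection tolerance.
#' @return A list with `k_r` (and `l = 2 pi / k_r`), or `k_r = NA` if
#'   `Re s1 < 0` on the whole grid (stable at all wavelengths).
#' @export
largest_unstable_root <- function(params, hs, k_max = 400, n_grid = 2000,
                                  rel_tol = 1e-8) {
  stopifnot(inherits(params, "rt_params"), inherits(hs, "rt_hstate"))
  if (params$interactions$kappa_0 <= 0)
    stop_param("largest_unstable_root() requires kappa_0 > 0 so that ",
               "Re s1(k) is negative at large k")
  ks <- seq(k_max / n_grid, k_max, length.out = n_grid)
  svals <- vapply(ks, s1_re_max, numeric(1), params = params, hs = hs)
  if (svals[n_grid] > 0)
    stop_param("Re s1 > 0 at k_max = ", k_max, "; enlarge the search interval")
  down <- which(svals[-n_grid] >= 0 & svals[-1] < 0)
  if (length(down) == 0) return(list(k_r = NA_real_, l = NA_real_))
  i <- max(down)
  lo <- ks[i]; hi <- ks[i + 1]
  while ((hi - lo) > rel_tol * hi) {
    mid <- (lo + hi) / 2
    if (s1_re_max(mid, params, hs) >= 0) lo <- mid else hi <- mid
  }
  k_r <- (lo + hi) / 2
  list(k_r = k_r, l = 2 * pi / k_r)
}

#' Theoretical separatrix in the (v_r, v_m) plane and its quadratic fit
#'
#' For each reduced difference speed `v_r`, bisects on the dimensionless
#' maximum speed `v_m` for the point where the largest unstable wavenumber
#' `k_r` equals the box wavenumber `k0 = 2 pi / L`: below the separatrix
#' the smallest unstable structure fits in the box and patterns can form.
#' The resulting curve `v_m^f(v_r)` is fitted by least squares to
#' `c0 + c1 v_r + c2 v_r^2`.
#'
#' @param params an [rt_params()] object (its speeds are overridden along
#'   the scan via [speeds_from_vr_vm()]).
#' @param hs an [homogeneous_state()] object.
#' @param v_r numeric vector of reduced difference speeds in `[0, 1)`.
#' @param vm_bracket search interval for `v_m`.
#' @param vm_tol absolute bisection tolerance on `v_m`.
#' @param k_max,n_grid passed to [largest_unstable_root()].
#' @return An object of class `rt_separatrix`: a list with the fit
#'   `coefficients` (`c0`, `c1`, `c2`), their standard errors `se`, the
#'   separatrix `points` and the `lm` fit object.
#' @examples
#' \donttest{
#' pre <- rt_preset("fig8")
#' sep <- separatrix_fit(pre$params, pre$hs, v_r = seq(0, 0.9, 0.3))
#' sep$coefficients
#' }
#' @export
separatrix_fit <- function(params, hs, v_r = (0:20) / 21,
                           vm_bracket = c(0.1, 20), vm_tol = 1e-4,
                           k_max = 400, n_grid = 1500) {
  stopifnot(inherits(params, "rt_params"), inherits(hs, "rt_hstate"))
  D <- params$transport$D; le <- params$rates$lambda_e
  k0 <- 2 * pi / params$L
  objective <- function(v_r_i, v_m_i) {
    sp <- speeds_from_vr_vm(v_r_i, v_m_i, D, le)
    p2 <- params
    p2$transport <- transport(sp$v_plus, sp$v_minus, D)
    kr <- largest_unstable_root(p2, hs, k_max = k_max, n_grid = n_grid,
                                rel_tol = 1e-6)$k_r
    if (is.na(kr)) -k0 else kr - k0
  }
  vm_sep <- vapply(v_r, function(vr) {
    lo <- vm_bracket[1]; hi <- vm_bracket[2]
    flo <- objective(vr, lo)
    fhi <- objective(vr, hi)
    if (flo * fhi > 0)
      stop_param("no k_r = 2 pi / L crossing for v_m in [", lo, ", ", hi,
                 "] at v_r = ", vr, "; adjust 'vm_bracket'")
    while ((hi - lo) > vm_tol) {
      mid <- (lo + hi) / 2
      if (objective(vr, mid) * flo > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  pts <- data.frame(v_r = v_r, v_m = vm_sep)
  fit <- lm(v_m ~ v_r + I(v_r^2), data = pts)
  cf <- setNames(coef(fit), c("c0", "c1", "c2"))
  se <- setNames(sqrt(diag(vcov(fit))), c("c0", "c1", "c2"))
  structure(list(coefficients = cf, se = se, points = pts, fit = fit),
            class = "rt_separatrix")
}

#' @export
print.rt_separatrix <- function(x, ...) {
  cf <- x$coefficients; se <- x$se
  cat("Separatrix fit v_m(v_r) = c0 + c1 v_r + c2 v_r^2\n")
  cat(sprintf("  c0 = %.4f +/- %.4f\n  c1 = %.4f +/- %.4f\n  c2 = %.4f +/- %.4f\n",
              cf[1], se[1], cf[2], se[2], cf[3], se[3]))
  cat("  fitted on", nrow(x$points), "separatrix points\n")
  invisible(x)
}
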