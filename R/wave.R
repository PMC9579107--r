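## Classification of long-time PDE solutions (uniform / static wave /
## traveling wave), wave-speed measurement by periodic cross-correlation,
## and the non-equilibrium state diagram in the (v_r, v_m) plane.

field_matrix <- function(traj, species) {
  switch(species,
         total = traj$rho_plus + traj$rho_0 + traj$rho_minus,
         plus = traj$rho_plus, settled = traj$rho_0, minus = traj$rho_minus,
         stop_param("unknown species '", species, "'"))
}

## Circular shift (in grid cells, sub-grid precision) that maps profile a
## onto profile b, via the FFT cross-correlation and parabolic
## interpolation of the correlation peak.  Positive = rightward.
profile_shift <- function(a, b) {
  n <- length(a)
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE)) / n
  p <- which.max(cc)
  cm <- cc[if (p == 1) n else p - 1]
  cp <- cc[if (p == n) 1 else p + 1]
  den <- cm - 2 * cc[p] + cp
  frac <- if (den != 0) 0.5 * (cm - cp) / den else 0
  s <- (p - 1) + frac
  # y_s = sum_j a_j b_{j-s} peaks at s = -shift; map to (-n/2, n/2]
  s <- -s
  if (s <= -n / 2) s <- s + n
  if (s > n / 2) s <- s - n
  s
}

#' Wave speed from late-time snapshots
#'
#' Estimates the translation speed of a steady density pattern from the
#' circular cross-correlation shift between pairs of consecutive late-time
#' snapshots (sub-grid precision via parabolic interpolation of the
#' correlation peak), averaged over the pairs, and divided by
#' `sqrt(D lambda_e)` to give the dimensionless wave speed `v_s`.
#' Positive speeds move rightward.
#'
#' @param traj an `rt_trajectory` from [pde_integrate()].
#' @param params parameter set supplying `D` and `lambda_e` (defaults to
#'   the trajectory's own).
#' @param species profile used for the correlation: `"total"` (default,
#'   most robust) or one of `"plus"`, `"settled"`, `"minus"`.
#' @param n_pairs number of late snapshot pairs averaged.
#' @param amplitude_threshold relative amplitude below which the profile is
#'   considered structureless and the speed undefined.
#' @return A list with the dimensionless speed `v_s`, its standard
#'   deviation over pairs `sd`, and the dimensional speed `u`.
#' @export
wave_speed <- function(traj, params = traj$params, species = "total",
                       n_pairs = 5, amplitude_threshold = 1e-2) {
  stopifnot(inherits(traj, "rt_trajectory"))
  prof <- field_matrix(traj, species)
  ns <- ncol(prof)
  if (ns < 2) stop_param("need at least two snapshots to measure a speed")
  n_pairs <- min(n_pairs, ns - 1)
  idx <- (ns - n_pairs):ns
  fin <- prof[, ns]
  amp <- (max(fin) - min(fin)) / mean(fin)
  if (!is.finite(amp) || amp < amplitude_threshold)
    stop_param("final profile amplitude ", format(amp),
               " is below the threshold; wave speed undefined")
  dx <- traj$grid$dx
  speeds <- vapply(seq_len(length(idx) - 1), function(j) {
    i1 <- idx[j]; i2 <- idx[j + 1]
    dt <- traj$times[i2] - traj$times[i1]
    profile_shift(prof[, i1], prof[, i2]) * dx / dt
  }, numeric(1))
  D <- params$transport$D; le <- params$rates$lambda_e
  if (D * le <= 0) stop_param("v_s requires D > 0 and lambda_e > 0")
  u <- mean(speeds)
  list(v_s = u / sqrt(D * le), sd = stats::sd(speeds) / sqrt(D * le), u = u)
}

#' Classify the long-time pattern of a trajectory
#'
#' Computes the relative amplitude `(max - min)/mean` of the total density
#' in the final snapshot and assigns `"uniform"` when it is below
#' `amplitude_threshold`; otherwise measures the wave speed and assigns
#' `"static_wave"` (`|v_s|` below `speed_tol`) or `"traveling_wave"`.
#' A run whose pattern amplitude is still changing appreciably between the
#' last snapshots (and is not an early-exit converged state) is flagged
#' `"inconclusive"` with diagnostics.
#'
#' @param traj an `rt_trajectory`.
#' @param params parameter set supplying `D` and `lambda_e`.
#' @param amplitude_threshold relative amplitude separating noise-floor
#'   relaxation from genuine patterns.
#' @param speed_tol dimensionless speed below which a wave counts as
#'   static.
#' @param n_pairs snapshot pairs used for the speed measurement.
#' @return An object of class `rt_verdict`: list with `class`,
#'   `amplitude`, `v_s` (NA for uniform) and `diagnostics`.
#' @export
classify_pattern <- function(traj, params = traj$params,
                             amplitude_threshold = 1e-2, speed_tol = 1e-2,
                             n_pairs = 5) {
  stopifnot(inherits(traj, "rt_trajectory"))
  tot <- field_matrix(traj, "total")
  ns <- ncol(tot)
  amp_of <- function(i) {
    v <- tot[, i]
    (max(v) - min(v)) / mean(v)
  }
  amp <- amp_of(ns)
  diagnostics <- list(status = traj$status, amplitude_prev = NA_real_)
  if (amp < amplitude_threshold) {
    verdict <- list(class = "uniform", amplitude = amp, v_s = NA_real_,
                    diagnostics = diagnostics)
    return(structure(verdict, class = "rt_verdict"))
  }
  if (ns >= 2) {
    amp_prev <- amp_of(ns - 1)
    diagnostics$amplitude_prev <- amp_prev
    drift <- abs(amp - amp_prev) / max(amp, amplitude_threshold)
    if (traj$status != "converged_early" && drift > 0.5) {
      verdict <- list(class = "inconclusive", amplitude = amp,
                      v_s = NA_real_, diagnostics = diagnostics)
      return(structure(verdict, class = "rt_verdict"))
    }
  }
  ws <- wave_speed(traj, params, n_pairs = n_pairs,
                   amplitude_threshold = amplitude_threshold)
  cls <- if (abs(ws$v_s) < speed_tol) "static_wave" else "traveling_wave"
  structure(list(class = cls, amplitude = amp, v_s = ws$v_s,
                 diagnostics = c(diagnostics, list(v_s_sd = ws$sd))),
            class = "rt_verdict")
}

#' @export
print.rt_verdict <- function(x, ...) {
  cat(sprintf("Pattern verdict: %s (amplitude %.3g", x$class, x$amplitude))
  if (!is.na(x$v_s)) cat(sprintf(", v_s = %.3g", x$v_s))
  cat(")\n")
  invisible(x)
}

#' Non-equilibrium state diagram and its separatrix fit
#'
#' For each reduced difference speed `v_r`, locates the wave/no-wave
#' transition in the dimensionless maximum speed `v_m` by bisection on the
#' outcome of full PDE runs: each run starts from the uniform stationary
#' state carrying density `R0` plus Gaussian noise and is classified by
#' the steady-state amplitude threshold (waves form below the transition,
#' the uniform state survives above it).  The transition points are fitted
#' by least squares to `v_m^f(v_r) = c0 + c1 v_r + c2 v_r^2`, and the
#' dimensionless wave speed `v_s` is recorded across the wave cells.
#'
#' Two classification protocols are available.  `"threshold"` calls a run a
#' wave when its final amplitude exceeds `amplitude_threshold`, which
#' presumes the run is long enough for unstable modes to saturate.
#' `"growth"` (the default) fits the exponential rate of the fundamental
#' box mode `k0 = 2 pi / L` of the total density over the second half of
#' the run and marks the cell unstable when the rate is positive.  The
#' sign change of that rate is precisely the separatrix condition
#' `k_r = k0`, so the growth protocol locates the transition without
#' requiring the pattern to saturate, which makes short scans feasible;
#' see the package vignette.
#'
#' @param params an [rt_params()] object (speeds overridden along the
#'   scan).
#' @param grid an [rt_grid()] object.
#' @param v_r reduced difference speeds scanned, in `[0, 1)`.
#' @param vm_bracket bisection bracket in `v_m`; the lower end must give a
#'   wave and the upper end a uniform state.
#' @param depth bisection depth per `v_r` value.
#' @param dt,n_steps time step and step budget per PDE run.
#' @param n_x grid resolution used for the runs (overrides `grid$n_x`).
#' @param R0 conserved density of the background state.
#' @param noise_amplitude relative amplitude of the initial Gaussian noise.
#' @param seed base seed; each run derives its own reproducible stream.
#' @param amplitude_threshold pattern threshold for the classification.
#' @param classify `"growth"` or `"threshold"` (see Details).
#' @return An object of class `rt_state_diagram`: list with the fit
#'   `coefficients` and `se`, the transition `points`, and `cells`, a data
#'   frame of every evaluated run (`v_r`, `v_m`, `amplitude`, `class`,
#'   `v_s`).
#' @export
state_diagram <- function(params, grid, v_r = seq(0, 0.8, 0.2),
                          vm_bracket = c(1, 6), depth = 5,
                          dt = 1e-4, n_steps = 2e5, n_x = grid$n_x,
                          R0 = 1, noise_amplitude = 1e-3, seed = 0,
                          amplitude_threshold = 1e-2,
                          classify = c("growth", "threshold")) {
  classify <- match.arg(classify)
  stopifnot(inherits(params, "rt_params"), inherits(grid, "rt_grid"))
  g <- rt_grid(grid$L, n_x)
  D <- params$transport$D; le <- params$rates$lambda_e
  cells <- list(); run <- 0L

  eval_cell <- function(vr, vm) {
    run <<- run + 1L
    sp <- speeds_from_vr_vm(vr, vm, D, le)
    p2 <- params
    p2$transport <- transport(sp$v_plus, sp$v_minus, D)
    st <- init_uniform_stationary(p2, g, R0)
    st <- add_gaussian_noise(st, noise_amplitude,
                             seed = (seed + 97L * run) %% .Machine$integer.max)
    traj <- pde_integrate(st, p2, g, dt = dt, n_steps = n_steps,
                          check_every = 1000L)
    tot <- field_matrix(traj, "total")
    ns <- ncol(tot)
    amp_of <- function(i) (max(tot[, i]) - min(tot[, i])) / mean(tot[, i])
    amp <- amp_of(ns)
    rate <- NA_real_
    is_wave <- if (classify == "threshold") {
      amp >= amplitude_threshold
    } else {
      # growth rate of the fundamental box mode over the late half
      late <- which(traj$times >= traj$times[ns] / 2)
      a1 <- vapply(late, function(i) Mod(fft(tot[, i])[2]), numeric(1))
      rate <- coef(lm(log(pmax(a1, 1e-300)) ~ traj$times[late]))[[2]]
      rate > 0
    }
    v_s <- NA_real_
    cls <- "uniform"
    if (is_wave) {
      ws <- tryCatch(wave_speed(traj, p2, amplitude_threshold = 0),
                     error = function(e) NULL)
      if (is.null(ws)) cls <- "wave" else {
        v_s <- ws$v_s
        cls <- if (abs(v_s) < 1e-2) "static_wave" else "traveling_wave"
      }
    }
    cells[[length(cells) + 1L]] <<-
      data.frame(v_r = vr, v_m = vm, amplitude = amp, class = cls,
                 v_s = v_s, growth_rate = rate)
    list(wave = is_wave, rate = rate)
  }

  vm_tr <- vapply(v_r, function(vr) {
    lo <- vm_bracket[1]; hi <- vm_bracket[2]
    rlo <- eval_cell(vr, lo)
    if (!rlo$wave)
      stop_param("no wave at the lower bracket v_m = ", lo, " for v_r = ",
                 vr, "; widen 'vm_bracket'")
    rhi <- eval_cell(vr, hi)
    if (rhi$wave)
      stop_param("wave persists at the upper bracket v_m = ", hi,
                 " for v_r = ", vr, "; widen 'vm_bracket'")
    for (d in seq_len(depth)) {
      mid <- (lo + hi) / 2
      rmid <- eval_cell(vr, mid)
      if (rmid$wave) { lo <- mid; rlo <- rmid } else { hi <- mid; rhi <- rmid }
    }
    # secant refinement of the rate's zero crossing inside the final bracket
    if (classify == "growth" && is.finite(rlo$rate) && is.finite(rhi$rate) &&
        rlo$rate > 0 && rhi$rate < 0) {
      lo + rlo$rate * (hi - lo) / (rlo$rate - rhi$rate)
    } else (lo + hi) / 2
  }, numeric(1))

  pts <- data.frame(v_r = v_r, v_m = vm_tr)
  fit <- lm(v_m ~ v_r + I(v_r^2), data = pts)
  cf <- setNames(coef(fit), c("c0", "c1", "c2"))
  se <- setNames(sqrt(diag(vcov(fit))), c("c0", "c1", "c2"))
  structure(list(coefficients = cf, se = se, points = pts,
                 cells = do.call(rbind, cells), fit = fit),
            class = "rt_state_diagram")
}

#' @export
print.rt_state_diagram <- function(x, ...) {
  cf <- x$coefficients
  cat("Non-equilibrium state diagram\n")
  cat(sprintf("  separatrix fit: v_m = %.3f %+.3f v_r %+.3f v_r^2\n",
              cf[1], cf[2], cf[3]))
  cat(sprintf("  %d PDE runs over %d v_r values\n",
              nrow(x$cells), nrow(x$points)))
  invisible(x)
}
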