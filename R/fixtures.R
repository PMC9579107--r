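## Programmatic generation of small reproducible field-state fixtures,
## mainly in support of validating the wave-speed estimator against a
## pattern translated at a known, imposed speed.

#' Generate reproducible field-state fixtures
#'
#' Builds small synthetic field states or trajectories for testing and
#' demonstrations: `"uniform"` (the stationary background), `"noisy"`
#' (background plus seeded Gaussian noise), `"peak"` (a narrow settled-cell
#' Gaussian) and `"translated_wave"` (a fixed non-uniform profile rigidly
#' translated at an imposed speed across the snapshots, as an exact ground
#' truth for [wave_speed()]).
#'
#' @param kind one of `"uniform"`, `"noisy"`, `"peak"`,
#'   `"translated_wave"`.
#' @param params an [rt_params()] object.
#' @param grid an [rt_grid()] object.
#' @param seed integer seed for the noisy fixture.
#' @param R0 background conserved density.
#' @param speed imposed translation speed (length/time) for
#'   `"translated_wave"`.
#' @param n_snapshots number of snapshots of the translated trajectory.
#' @param dt_snapshot time between snapshots.
#' @return A `3 x n_x` field matrix, or an `rt_trajectory` for
#'   `"translated_wave"`.
#' @export
generate_fixture <- function(kind = c("uniform", "noisy", "peak",
                                      "translated_wave"),
                             params, grid, seed = 0, R0 = 1, speed = 0.05,
                             n_snapshots = 6, dt_snapshot = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "rt_params"), inherits(grid, "rt_grid"))
  switch(kind,
    uniform = init_uniform_stationary(params, grid, R0),
    noisy = add_gaussian_noise(init_uniform_stationary(params, grid, R0),
                               amplitude = 1e-3, seed = seed),
    peak = init_gaussian_peak(grid, mass = R0 / 2),
    translated_wave = {
      base <- init_uniform_stationary(params, grid, R0)
      # smooth single-bump profile on top of the background
      bump <- 0.5 * (1 + cos(2 * pi * (grid$x / grid$L - 0.5)))^2
      times <- (seq_len(n_snapshots) - 1) * dt_snapshot
      shift_profile <- function(prof, d) {
        # exact periodic translation via the FFT shift theorem
        n <- length(prof)
        ks <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * 2 * pi / grid$L
        Re(fft(fft(prof) * exp(-1i * ks * d), inverse = TRUE)) / n
      }
      snaps <- lapply(times, function(t) {
        prof <- shift_profile(bump, speed * t)
        rbind(base[1, ] * (1 + prof), base[2, ] * (1 + prof),
              base[3, ] * (1 + prof))
      })
      structure(list(
        times = times, x = grid$x,
        rho_plus = vapply(snaps, function(s) s[1, ], numeric(grid$n_x)),
        rho_0 = vapply(snaps, function(s) s[2, ], numeric(grid$n_x)),
        rho_minus = vapply(snaps, function(s) s[3, ], numeric(grid$n_x)),
        N = vapply(snaps, function(s) sum(s) * grid$dx, numeric(1)),
        status = "fixture", steps_done = 0L,
        params = params, grid = grid, dt = dt_snapshot),
        class = "rt_trajectory")
    })
}
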