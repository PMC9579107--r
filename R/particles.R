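## Stochastic particle-level simulation of the three-state process.  Serves
## as an independent check of the Fourier-space moments: the continuum model
## is the master equation of exactly this jump-drift-diffusion process.

#' Simulate the three-state process at the particle level
#'
#' Event-driven simulation of `n0` independent lineages started at the
#' origin: movers drift at `+v_+` / `-v_-` with diffusivity `D`, tumble at
#' `lambda_e`, settle at `lambda_s` and die at `mu`; settled cells double
#' at `lambda_d` into one right- and one left-mover at their position.
#' Event times are exponential and diffusive increments Gaussian, so the
#' sample paths are exact in distribution.  Randomness flows through R's
#' RNG: use `set.seed()` (or the `seed` argument) for reproducibility.
#'
#' @param params an [rt_params()] object with zero interactions.
#' @param n0 number of initial cells (independent lineages).
#' @param times observation times, increasing.
#' @param init_species `"settled"`, `"plus"` or `"minus"`.
#' @param seed optional integer seed.
#' @return A list of class `rt_particles`, one element per observation
#'   time: a data frame with the position `x`, `species`
#'   (`0` right-mover, `1` settled, `2` left-mover) and founding lineage
#'   `ancestor` of every cell alive at that time.
#' @export
simulate_particles <- function(params, n0, times,
                               init_species = c("settled", "plus", "minus"),
                               seed = NULL) {
  stopifnot(inherits(params, "rt_params"))
  free_cell_check(params)
  init_species <- match.arg(init_species)
  times <- as.numeric(times)
  if (any(times <= 0) || is.unsorted(times, strictly = TRUE))
    stop_param("'times' must be positive and strictly increasing")
  if (!is.null(seed)) set.seed(seed)
  r <- params$rates; tr <- params$transport
  isp <- c(settled = 1L, plus = 0L, minus = 2L)[[init_species]]
  sim <- .particles_cpp(as.integer(n0), isp, times,
                        r$lambda_s, r$lambda_d, r$lambda_e, r$mu,
                        tr$v_plus, tr$v_minus, tr$D)
  structure(list(times = times, observations = sim, n0 = as.integer(n0)),
            class = "rt_particles")
}

#' @export
print.rt_particles <- function(x, ...) {
  cat("Particle-level simulation:", x$n0, "founding cells,",
      length(x$times), "observation times\n")
  counts <- vapply(x$observations, nrow, integer(1))
  cat("  cells alive:", paste(sprintf("t=%g: %d", x$times, counts),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Displacement moments from a particle simulation
#'
#' Monte-Carlo estimate of `<(x - x0)^n>` with a standard error that
#' accounts for the correlation of cells descending from the same founder:
#' per-lineage sums enter a ratio estimator whose variance follows from the
#' delta method over independent lineages.
#'
#' @param sim an `rt_particles` object from [simulate_particles()].
#' @param order moment order `n >= 1`.
#' @param selector `"total"`, `"plus"`, `"settled"` or `"minus"`.
#' @return A data frame with columns `t`, `moment`, `se` and the number of
#'   contributing cells `n_cells`.
#' @export
particle_moments <- function(sim, order, selector = "total") {
  stopifnot(inherits(sim, "rt_particles"))
  order <- as.integer(order)
  if (order < 1) stop_param("'order' must be >= 1")
  sp_code <- c(total = -1L, plus = 0L, settled = 1L, minus = 2L)
  if (!selector %in% names(sp_code))
    stop_param("unknown population selector '", selector, "'")
  want <- sp_code[[selector]]
  rows <- lapply(seq_along(sim$times), function(i) {
    ob <- sim$observations[[i]]
    if (want >= 0L) ob <- ob[ob$species == want, , drop = FALSE]
    n <- nrow(ob)
    if (n == 0L)
      return(data.frame(t = sim$times[i], moment = NA_real_, se = NA_real_,
                        n_cells = 0L))
    g <- ob$x^order
    m <- mean(g)
    # lineage-clustered variance of the ratio estimator sum(g)/n
    Sa <- tapply(g, ob$ancestor, sum)
    na <- tapply(g, ob$ancestor, length)
    v <- sum((Sa - m * na)^2) / n^2
    data.frame(t = sim$times[i], moment = m, se = sqrt(v), n_cells = n)
  })
  do.call(rbind, rows)
}
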