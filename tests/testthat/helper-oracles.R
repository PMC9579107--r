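# Shared fixtures and small independent oracles used across the tests.

params_fig4 <- function() rt_preset("fig4")$params
params_fig4_equal <- function() rt_preset("fig4_equal")$params

rates_ones <- function() kinetic_rates(1, 1, 1, 1)

# independent fixed-step RK4 integrator for small (possibly complex) linear
# or nonlinear systems dy/dt = f(y); deliberately separate from the package
# propagation paths
rk4_integrate <- function(y0, f, t_end, dt) {
  y <- y0
  t <- 0
  n <- ceiling(t_end / dt)
  dt <- t_end / n
  for (i in seq_len(n)) {
    k1 <- f(y)
    k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# log-log slope of a moment series over a time window
loglog_slope <- function(params, order, selector, t1, t2, n = 12) {
  ts <- exp(seq(log(t1), log(t2), length.out = n))
  m <- displacement_moments(order, ts, params,
                            selector = selector)[[paste0("moment_", order)]]
  unname(coef(lm(log(m) ~ log(ts)))[2])
}

# random non-negative rate sets for property-style loops
random_rates <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    v <- runif(4, 0, 3)
    kinetic_rates(v[1], v[2], max(v[3], 0.1), v[4])
  })
}
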