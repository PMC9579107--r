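test_that("uniform free-cell tendency reduces to the well-mixed kinetics", {
  p <- rt_params(kinetic_rates(1, 2, 1, 0.5), transport(1, 0.9, 0.2))
  g <- rt_grid(1, 64)
  rho <- c(0.3, 0.4, 0.1)
  st <- matrix(rho, 3, g$n_x)
  tend <- pde_rhs(st, p, g)
  expected <- unname(drop(rate_matrix(p$rates) %*% rho))
  for (i in c(1, 20, 64))
    expect_equal(unname(tend[, i]), expected, tolerance = 1e-12)
  # logistic analogue
  pl <- rt_params(kinetic_rates(1, 2, 1, 0.5), transport(1, 0.9, 0.2),
                  carrying = carrying_capacity(1, 1, 1),
                  growth_mode = "logistic")
  parts <- rate_matrix_parts(pl$rates)
  exp_l <- unname(drop(parts$M_D %*% rho) +
                    drop(parts$M_OD %*% logistic_growth(rho, pl$carrying)))
  expect_equal(unname(pde_rhs(st, pl, g)[, 10]), exp_l, tolerance = 1e-12)
})

test_that("transport and interactions move mass without creating it", {
  pre <- rt_preset("fig9")
  p <- pre$params
  g <- rt_grid(1, 128)
  set.seed(21)
  st <- matrix(abs(rnorm(3 * 128, 0.3, 0.1)), 3, 128)
  # subtract the kinetic part: what remains is pure transport + interaction
  tend <- pde_rhs(st, p, g)
  kin <- rate_matrix(p$rates) %*% st
  flux_part <- tend - kin
  expect_equal(max(abs(rowSums(flux_part) * g$dx)), 0, tolerance = 1e-12)
  # linear-mode budget: dR/dt = (lambda_s - mu) * integral(rho_+ + rho_-)
  R_dot <- sum((tend[1, ] + tend[3, ] + 2 * tend[2, ])) * g$dx
  expect_equal(R_dot,
               (p$rates$lambda_s - p$rates$mu) *
                 sum(st[1, ] + st[3, ]) * g$dx,
               tolerance = 1e-10)
})

test_that("compiled and R-level single steps agree and converge at 4th
           order", {
  pre <- rt_preset("fig9")
  p <- pre$params
  g <- rt_grid(1, 64)
  st <- init_gaussian_peak(g, width = 0.05, mass = 0.1)
  st[1, ] <- 0.1; st[3, ] <- 0.12
  s_r <- pde_step_rk4(st, p, g, 1e-4)
  traj <- pde_integrate(st, p, g, dt = 1e-4, n_steps = 1, check_every = 0)
  s_c <- rbind(traj$rho_plus[, 2], traj$rho_0[, 2], traj$rho_minus[, 2])
  expect_equal(s_c, s_r, tolerance = 1e-13, ignore_attr = TRUE)
  # dt-halving on a smooth state reduces the one-interval error ~16x
  T_end <- 0.02
  run <- function(dt) {
    tr <- pde_integrate(st, p, g, dt = dt, n_steps = round(T_end / dt),
                        check_every = 0)
    ns <- length(tr$times)
    rbind(tr$rho_plus[, ns], tr$rho_0[, ns], tr$rho_minus[, ns])
  }
  ref <- run(2.5e-5)
  e1 <- max(abs(run(2e-4) - ref))
  e2 <- max(abs(run(1e-4) - ref))
  expect_gt(e1 / e2, 10)
  expect_lt(e1 / e2, 24)
})

test_that("the exact uniform stationary state is a fixed point", {
  p <- rt_params(kinetic_rates(0.5, 1, 1, 0.5), transport(0.7, 0.7, 0.1))
  g <- rt_grid(1, 32)
  st <- init_uniform_stationary(p, g, R0 = 2)
  s2 <- pde_step_rk4(st, p, g, 1e-3)
  expect_equal(s2, st, tolerance = 1e-14)
})

test_that("stability bound is enforced, divergence is caught", {
  p <- rt_params(kinetic_rates(1, 1, 1, 1), transport(1, 1, 0.5))
  g <- rt_grid(1, 128)
  st <- init_uniform_stationary(p, g)
  expect_error(pde_integrate(st, p, g, dt = 0.1, n_steps = 10),
               "stability bound")
  expect_error(pde_step_rk4(st, p, g, 0.1), "stability bound")
})

test_that("initial conditions are reproducible and well normalized", {
  pre <- rt_preset("fig9")
  g <- rt_grid(1, 128)
  st <- init_uniform_stationary(pre$params, g, pre$R0)
  expect_equal(sum((st[1, ] + st[3, ] + 2 * st[2, ]) * g$dx), pre$R0,
               tolerance = 1e-12)
  n1 <- add_gaussian_noise(st, 1e-3, seed = 4)
  n2 <- add_gaussian_noise(st, 1e-3, seed = 4)
  expect_identical(n1, n2)
  expect_false(identical(n1, add_gaussian_noise(st, 1e-3, seed = 5)))
  expect_identical(add_gaussian_noise(st, 0, seed = 1), st)
  # noise has zero mean within statistical accuracy
  big <- add_gaussian_noise(matrix(1, 3, 4000), 1e-2, seed = 6)
  expect_lt(abs(mean(big) - 1), 3 * 1e-2 / sqrt(12000))
  expect_error(add_gaussian_noise(st, -1), "non-negative")
  # Gaussian peak: mass, centering, empty movers
  pk <- init_gaussian_peak(g, width = 0.03, mass = 0.7)
  expect_equal(sum(pk[2, ]) * g$dx, 0.7, tolerance = 1e-10)
  expect_equal(g$x[which.max(pk[2, ])], 0.5, tolerance = g$dx)
  expect_true(all(pk[c(1, 3), ] == 0))
  expect_error(init_gaussian_peak(g, width = g$dx), "2 dx")
})

test_that("with free cells a uniform PDE run equals the exact ODE solution", {
  p <- rt_params(kinetic_rates(1, 2, 1, 0.5), transport(1, 0.9, 0.2))
  g <- rt_grid(1, 64)
  st <- matrix(c(0.3, 0.4, 0.1), 3, g$n_x)
  traj <- pde_integrate(st, p, g, dt = 5e-4, n_steps = 2e4,
                        check_every = 0)
  ns <- length(traj$times)
  ode <- wm_evolve_linear(c(0.3, 0.4, 0.1), p$rates, times = 10)
  got <- c(traj$rho_plus[1, ns], traj$rho_0[1, ns], traj$rho_minus[1, ns])
  expect_equal(got, unname(unlist(ode[1, 2:4])), tolerance = 1e-8)
})

test_that("a seeded linear eigenmode grows at the dispersion-relation rate", {
  pre <- rt_preset("fig9")
  p <- pre$params; hs <- pre$hs
  g <- rt_grid(1, 128)
  k <- 2 * (2 * pi / p$L)
  ev <- eigen(fourier_jacobian(k, p, hs))
  i1 <- which.max(Re(ev$values))
  s1 <- ev$values[i1]
  bg <- init_uniform_stationary(p, g, pre$R0)
  pert <- vapply(g$x, function(x) Re(ev$vectors[, i1] * exp(1i * k * x)),
                 numeric(3))
  traj <- pde_integrate(bg + 1e-6 * pert, p, g, dt = 1e-4, n_steps = 5e4,
                        snapshot_stride = 5e3, check_every = 0)
  tot <- traj$rho_plus + traj$rho_0 + traj$rho_minus
  amps <- apply(tot, 2, function(v) Mod(fft(v)[3]))
  rate <- unname(coef(lm(log(amps) ~ traj$times))[2])
  expect_equal(rate, Re(s1), tolerance = 0.05 * abs(Re(s1)))
})

test_that("early exit triggers on converged states and statuses are
           reported", {
  p <- rt_params(kinetic_rates(0.5, 1, 1, 0.5), transport(0.5, 0.5, 0.1))
  g <- rt_grid(1, 32)
  st <- init_uniform_stationary(p, g)
  traj <- pde_integrate(st, p, g, dt = 1e-3, n_steps = 1e5,
                        check_every = 500)
  expect_equal(traj$status, "converged_early")
  expect_lt(traj$steps_done, 1e5)
})
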