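test_that("spectral propagator reduces to the well-mixed propagator and the
           identity", {
  p <- params_fig4()
  M <- rate_matrix(p$rates)
  P0 <- spectral_propagator(0, 1.3, p)
  skip_if_not_installed("Matrix")
  expect_equal(Re(P0), as.matrix(Matrix::expm(M * 1.3)),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(max(Mod(Im(P0))), 0, tolerance = 1e-12)
  expect_equal(spectral_propagator(2.2, 0, p), diag(3) + 0i,
               ignore_attr = TRUE)
})

test_that("spectral propagator agrees with direct RK4 integration in k-space", {
  p <- params_fig4()
  M <- rate_matrix(p$rates)
  A <- M - 3.1^2 * diag(c(0.2, 0, 0.2)) - 1i * 3.1 * diag(c(1, 0, -0.9))
  init <- c(0, 1, 0) + 0i
  oracle <- rk4_integrate(init, function(y) drop(A %*% y), 0.8, dt = 1e-4)
  got <- drop(spectral_propagator(3.1, 0.8, p) %*% init)
  expect_equal(unname(got), unname(oracle), tolerance = 1e-8)
  # conjugation symmetry in k
  expect_equal(spectral_propagator(-3.1, 0.8, p),
               Conj(spectral_propagator(3.1, 0.8, p)), tolerance = 1e-12)
})

test_that("propagator and moments refuse interacting parameter sets", {
  p <- rt_params(rates_ones(), transport(1, 1, 0.2),
                 interactions = interactions(kappa = 0.5))
  expect_error(spectral_propagator(1, 1, p), "free cells")
  expect_error(displacement_moments(1, 1, p), "free cells")
})

test_that("ISF normalization and symmetry", {
  p <- params_fig4()
  ts <- c(0.2, 1, 4)
  # k = 0: ISF equals the population size
  N <- displacement_moments(1, ts, p)$N
  expect_equal(Re(isf(0, ts, p)), N, tolerance = 1e-10)
  N0 <- displacement_moments(1, ts, p, selector = "settled")$N
  expect_equal(Re(isf(0, ts, p, selector = "settled")), N0,
               tolerance = 1e-10)
  # equal speeds and symmetric init: ISF is purely real
  pe <- params_fig4_equal()
  vals <- isf(2.5, ts, pe)
  expect_equal(max(abs(Im(vals))), 0, tolerance = 1e-12)
  # unequal speeds: imaginary part appears (odd moments exist)
  expect_gt(max(abs(Im(isf(2.5, ts, p)))), 1e-6)
  # large k: density correlations decay on small length scales
  expect_lt(Mod(isf(40, 10, pe)), 1e-3 * N[3])
  expect_error(isf(1, 1, p, init = c(1, 0, 0), selector = "settled"),
               "empty")
})

test_that("moments match the closed-form short-time coefficients", {
  p <- params_fig4()
  co_t <- short_time_coefficients(p, "total")
  co_s <- short_time_coefficients(p, "settled")
  expect_equal(unname(co_t$MD["t2"]), 0.05)   # lambda_d v_d
  expect_equal(unname(co_s$MSD["t3"]), 2 / 15)  # (2/3) D lambda_s lambda_d
  ts <- c(1e-4, 3e-4)
  m <- displacement_moments(1:2, ts, p)
  ms <- displacement_moments(1:2, ts, p, selector = "settled")
  for (i in seq_along(ts)) {
    t <- ts[i]
    expect_equal(m$moment_1[i],
                 co_t$MD[["t2"]] * t^2 + co_t$MD[["t3"]] * t^3,
                 tolerance = 1e-3)
    expect_equal(m$moment_2[i],
                 co_t$MSD[["t2"]] * t^2 + co_t$MSD[["t3"]] * t^3,
                 tolerance = 1e-3)
    expect_equal(ms$moment_1[i],
                 co_s$MD[["t3"]] * t^3 + co_s$MD[["t4"]] * t^4,
                 tolerance = 1e-3)
    expect_equal(ms$moment_2[i],
                 co_s$MSD[["t3"]] * t^3 + co_s$MSD[["t4"]] * t^4,
                 tolerance = 1e-3)
  }
})

test_that("odd moments vanish under left/right symmetry", {
  pe <- params_fig4_equal()
  m <- displacement_moments(1, c(0.01, 0.5, 3, 20), pe)
  expect_equal(m$moment_1, rep(0, 4), tolerance = 1e-12)
})

test_that("settled MSD is quartic at short times when D = 0", {
  p <- rt_params(rates_ones(), transport(1, 0.9, 0))
  co <- short_time_coefficients(p, "settled")
  expect_equal(unname(co$MSD["t3"]), 0)
  sl <- loglog_slope(p, 2, "settled", 1e-3, 1e-2)
  expect_equal(sl, 4, tolerance = 0.1)
})

test_that("crossover times follow the coefficient-ratio formulas", {
  p <- params_fig4_equal()  # all rates = 1, D = 0.2, v_a = 1
  ct <- crossover_times(p)
  expect_equal(ct$t_c1, 3 / 7, tolerance = 1e-12)
  expect_equal(ct$t_c2, 1.5, tolerance = 1e-12)
  expect_equal(ct$t_c0_1, 2, tolerance = 1e-12)
  expect_equal(ct$t_c0_2, 4 / 3, tolerance = 1e-12)
  # degenerate denominator is flagged as Inf
  p0 <- rt_params(kinetic_rates(1, 1, 1, 0), transport(0, 0, 0))
  expect_equal(crossover_times(p0)$t_c0_1, Inf)
})

test_that("long-time MD slope matches its closed form and the numerics", {
  p <- params_fig4()
  expect_equal(md_long_time_slope(p), 1 / 60)
  expect_equal(md_long_time_slope(params_fig4_equal()), 0)
  m <- displacement_moments(1, c(50, 100), p)
  slope_num <- diff(m$moment_1) / 50
  expect_equal(slope_num, 1 / 60, tolerance = 0.01)
})

test_that("long-time MSD crossover is finite for unequal speeds only", {
  p <- params_fig4()
  tl2 <- msd_long_crossover(p)
  expect_gt(tl2, 10)
  expect_true(is.finite(tl2))
  # at the crossover the ballistic asymptote matches the MSD within a factor
  msd_at <- displacement_moments(2, tl2, p)$moment_2
  expect_equal(md_long_time_slope(p)^2 * tl2^2 / msd_at, 0.5,
               tolerance = 0.35)
  expect_equal(msd_long_crossover(params_fig4_equal()), Inf)
})

test_that("headline scaling exponents", {
  p <- params_fig4()
  # settled-population MSD: super-ballistic t^3 at early times
  expect_equal(loglog_slope(p, 2, "settled", 1e-3, 1e-2), 3, tolerance = 0.1)
  # total MSD long-time: ballistic for unequal speeds, diffusive for equal
  expect_equal(loglog_slope(p, 2, "total", 1e5, 1e6), 2, tolerance = 0.05)
  expect_equal(loglog_slope(params_fig4_equal(), 2, "total", 1e3, 1e4), 1,
               tolerance = 0.05)
  # population growth/decay does not change the scalings
  pg <- rt_params(kinetic_rates(1.3, 1, 1, 1), transport(1, 0.9, 0.2))
  expect_equal(loglog_slope(pg, 2, "settled", 1e-3, 1e-2), 3,
               tolerance = 0.1)
  pd <- rt_params(kinetic_rates(1, 1, 1, 1.3), transport(1, 0.9, 0.2))
  expect_equal(loglog_slope(pd, 2, "settled", 1e-3, 1e-2), 3,
               tolerance = 0.1)
})
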