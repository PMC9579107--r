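hs_unit <- function() homogeneous_state(1, 2)  # rates all equal: rho0 = 2 rho+

test_that("homogeneous state keeps the stationary composition ratios", {
  r <- kinetic_rates(0.1, 0.1, 1, 0.1)
  hs <- homogeneous_state_from_R(r, R = 1)
  expect_equal(hs$rho_hat_plus, hs$rho_hat_minus)
  expect_equal(hs$rho_hat_0 / hs$rho_hat_plus, 2 * r$mu / r$lambda_d)
  expect_equal(2 * hs$rho_hat_0 + 2 * hs$rho_hat_plus, 1)
})

test_that("Fourier-space Jacobian has the correct limits", {
  pre <- rt_preset("fig8")
  p <- pre$params; hs <- pre$hs
  expect_equal(fourier_jacobian(0, p, hs), rate_matrix(p$rates) + 0i,
               ignore_attr = TRUE)
  # free cells: J(k) equals the free-cell Fourier operator
  pf <- rt_params(rates_ones(), transport(1, 0.9, 0.2))
  A <- rate_matrix(pf$rates) - 2.3^2 * diag(c(0.2, 0, 0.2)) -
    1i * 2.3 * diag(c(1, 0, -0.9))
  expect_equal(fourier_jacobian(2.3, pf, hs_unit()), A, ignore_attr = TRUE)
})

test_that("Jacobian matches a numerical linearization of the PDE operator", {
  # apply the discrete spatial operator to hs + eps * e_j exp(ikx) and
  # project back onto exp(ikx); on a fine grid this reproduces J(k)
  pre <- rt_preset("fig9")
  p <- pre$params; hs <- pre$hs
  g <- rt_grid(1, 4096)
  k <- 2 * pi * 3
  base <- matrix(c(hs$rho_hat_plus, hs$rho_hat_0, hs$rho_hat_minus), 3,
                 g$n_x)
  eps <- 1e-7
  phase <- exp(1i * k * g$x)
  J_num <- matrix(0i, 3, 3)
  f0 <- pde_rhs(base, p, g)
  for (j in 1:3) {
    pert <- matrix(0, 3, g$n_x)
    pert[j, ] <- Re(phase)
    fr <- (pde_rhs(base + eps * pert, p, g) - f0) / eps
    pert[j, ] <- Im(phase)
    fi <- (pde_rhs(base + eps * pert, p, g) - f0) / eps
    # response to the complex mode e_j exp(ikx)
    resp <- fr + 1i * fi
    J_num[, j] <- (resp %*% Conj(phase)) / g$n_x
  }
  expect_equal(J_num, fourier_jacobian(k, p, hs), tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("dispersion branches are eigenvalues, conjugate-symmetric in k,
           and anchored at E3", {
  pre <- rt_preset("fig9")
  p <- pre$params; hs <- pre$hs
  ks <- seq(0, 60, length.out = 40)
  db <- dispersion_branches(ks, p, hs)
  expect_equal(Re(db$s1[1]), wm_eigenvalues(p$rates)$E3, tolerance = 1e-10)
  for (i in c(5, 20, 40)) {
    J <- fourier_jacobian(ks[i], p, hs)
    ev <- eigen(J, only.values = TRUE)$values
    for (s in c(db$s1[i], db$s2[i], db$s3[i])) {
      expect_lt(min(Mod(ev - s)), 1e-10 * max(Mod(J)) + 1e-12)
    }
    Jm <- fourier_jacobian(-ks[i], p, hs)
    ev_m <- eigen(Jm, only.values = TRUE)$values
    ev_p <- eigen(J, only.values = TRUE)$values
    expect_equal(sort(Re(ev_m)), sort(Re(ev_p)), tolerance = 1e-10)
    expect_equal(sort(Im(ev_m)), sort(-Im(ev_p)), tolerance = 1e-10)
  }
})

test_that("large-k behavior of the secondary branches is advective-diffusive", {
  p <- rt_params(rates_ones(), transport(1, 1, 0.5))
  db <- dispersion_branches(c(200, 400), p, hs_unit())
  for (col in c("s2", "s3")) {
    s <- db[[col]]
    expect_equal(Re(s[2]) / Re(s[1]), 4, tolerance = 0.05)  # -D k^2
  }
  im_all <- sort(abs(Im(c(db$s1[2], db$s2[2], db$s3[2]))), decreasing = TRUE)
  expect_equal(im_all[1] / 400, 1, tolerance = 0.05)  # Im ~ v k
})

test_that("limits of the leading branch match the dispersion relation", {
  pre7 <- rt_preset("fig7")
  lim <- s1_limits(pre7$params, pre7$hs)
  expect_equal(lim$s1_at_0, 0)
  expect_equal(lim$large_k, "saturates")
  expect_equal(lim$large_k_value, 0)  # D = 2 v+^2: exactly marginal
  # saturation value reached numerically at large k
  p_sat <- rt_params(rates_ones(), transport(1, 1, 4),
                     interactions = interactions(kappa = 1))
  lim2 <- s1_limits(p_sat, hs_unit())
  s_num <- Re(eigen(fourier_jacobian(1e3, p_sat, hs_unit()),
                    only.values = TRUE)$values)
  expect_equal(max(s_num), lim2$large_k_value, tolerance = 0.01)
  # kappa_0 > 0 with D > kappa_0 rho_0: settled branch decays as
  # -kappa_0 rho_0 k^2 and dominates at large k
  p_rep <- rt_params(rates_ones(), transport(1, 1, 2),
                     interactions = interactions(kappa = 1, kappa_0 = 0.05))
  lim3 <- s1_limits(p_rep, hs_unit())
  expect_equal(lim3$large_k, "quadratic_decay")
  s_num3 <- max(Re(eigen(fourier_jacobian(1e3, p_rep, hs_unit()),
                         only.values = TRUE)$values))
  expect_equal(s_num3 / 1e6, -lim3$large_k_value, tolerance = 0.01)
  # D = 0 without repulsion: always unstable
  p_d0 <- rt_params(rates_ones(), transport(1, 1, 0),
                    interactions = interactions(kappa = 1))
  expect_equal(s1_limits(p_d0, hs_unit())$large_k,
               "unbounded_linear_growth")
})

test_that("stability conditions behave as endpoints plus a full scan", {
  hs <- hs_unit()
  # kappa = 0 and mu >= lambda_s: stable
  p_free <- rt_params(rates_ones(), transport(1, 1, 0.2))
  expect_true(is_stable(p_free, hs, "full_scan")$stable)
  # mu < lambda_s: unstable through the growth condition
  p_grow <- rt_params(kinetic_rates(2, 1, 1, 1), transport(1, 1, 0.2),
                      interactions = interactions(kappa = 0.1))
  v <- is_stable(p_grow, hs, "endpoints")
  expect_false(v$stable)
  expect_match(v$failed[1], "mu >= lambda_s")
  expect_false(is_stable(p_grow, hs, "full_scan")$stable)
  # marginal endpoint case: D = 2 v+^2 with kappa = 1; full scan stays
  # non-positive for all k
  pre7 <- rt_preset("fig7")
  expect_true(is_stable(pre7$params, pre7$hs, "full_scan")$stable)
  # violated short-wavelength endpoint is confirmed by the scan
  p_bad <- rt_params(rates_ones(), transport(1, 1, 0.5),
                     interactions = interactions(kappa = 1))
  e <- is_stable(p_bad, hs, "endpoints")
  expect_false(e$stable)
  f <- is_stable(p_bad, hs, "full_scan")
  expect_false(f$stable)
  expect_true(is.finite(f$k_unstable))
})

test_that("largest unstable root agrees with a brute-force dense scan", {
  pre <- rt_preset("fig9")
  p <- pre$params; hs <- pre$hs
  root <- largest_unstable_root(p, hs)
  expect_false(is.na(root$k_r))
  expect_equal(root$l, 2 * pi / root$k_r)
  # dense scan oracle
  ks <- seq(1e-3, 50, length.out = 1e5)
  sv <- vapply(ks, function(k)
    max(Re(eigen(fourier_jacobian(k, p, hs), only.values = TRUE)$values)),
    numeric(1))
  i <- max(which(sv >= 0))
  expect_equal(root$k_r, ks[i], tolerance = 1e-3)
  # a stable parameter set has no root
  p_st <- rt_params(kinetic_rates(0.1, 0.1, 1, 0.2),
                    transport(0.1, 0.1, 0.001),
                    interactions = interactions(0.01, 0.05))
  expect_true(is.na(largest_unstable_root(p_st, hs)$k_r))
  expect_error(largest_unstable_root(params_fig4(), hs), "kappa_0 > 0")
})

test_that("separatrix bisection matches spot checks and mirror symmetry", {
  pre <- rt_preset("fig8")
  p <- pre$params; hs <- pre$hs
  sep <- separatrix_fit(p, hs, v_r = c(0, 0.3, 0.6), n_grid = 800)
  expect_equal(nrow(sep$points), 3)
  # at each separatrix point the largest root sits at k0 = 2 pi / L
  for (i in 1:3) {
    sp <- speeds_from_vr_vm(sep$points$v_r[i], sep$points$v_m[i],
                            p$transport$D, 1)
    p2 <- p
    p2$transport <- transport(sp$v_plus, sp$v_minus, p$transport$D)
    kr <- largest_unstable_root(p2, hs)$k_r
    expect_equal(kr, 2 * pi, tolerance = 1e-2)
  }
  # exchanging v_+ and v_- mirrors the dispersion relation
  sp <- speeds_from_vr_vm(0.4, 3, p$transport$D, 1)
  pa <- p; pa$transport <- transport(sp$v_plus, sp$v_minus, p$transport$D)
  pb <- p; pb$transport <- transport(sp$v_minus, sp$v_plus, p$transport$D)
  ka <- largest_unstable_root(pa, hs)$k_r
  kb <- largest_unstable_root(pb, hs)$k_r
  expect_equal(ka, kb, tolerance = 1e-8)
})
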