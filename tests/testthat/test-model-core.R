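test_that("effective strain resolves the applied strain along the cell axis", {
  expect_equal(effective_strain(0, 0.1, 0), 0.1)
  expect_equal(effective_strain(pi / 2, 0.1, 0), 0, tolerance = 1e-12)
  expect_equal(effective_strain(pi / 2, 0.1, 0.5), -0.05)

  # zero-strain direction for an incompressible substrate, located
  # independently by root bisection of cos^2 - nu sin^2
  root <- uniroot(function(th) cos(th)^2 - 0.5 * sin(th)^2, c(0.1, 1.5),
                  tol = 1e-12)$root
  expect_equal(root, atan(sqrt(2)), tolerance = 1e-9)
  expect_equal(effective_strain(atan(sqrt(2)), 0.1, 0.5), 0, tolerance = 1e-12)

  # even and pi-periodic in theta
  th <- seq(-pi, pi, length.out = 41)
  expect_equal(effective_strain(th, 0.1, 0.3), effective_strain(-th, 0.1, 0.3))
  expect_equal(effective_strain(th, 0.1, 0.3),
               effective_strain(th + pi, 0.1, 0.3))
})

test_that("stiffening factor follows the 3/2 power law above the threshold", {
  expect_equal(stiffening_factor(0.02, 0.04), 1)
  expect_equal(stiffening_factor(0.04, 0.04), 1)   # continuous at threshold
  expect_equal(stiffening_factor(0.16, 0.04), 8)   # 4^(3/2)
  expect_equal(stiffening_factor(0.16, Inf), 1)    # linear substrate

  eps <- seq(-0.3, 0.3, length.out = 101)
  s <- stiffening_factor(eps, 0.04)
  expect_true(all(s >= 1))
  expect_equal(s, rev(s))  # even in strain
  # continuity across the threshold
  expect_equal(stiffening_factor(0.04 + 1e-9, 0.04), 1, tolerance = 1e-6)
})

test_that("filament force is the motor force plus a Maxwell branch", {
  p <- model_params()
  tau <- seq(0, 100, by = 0.05)

  # static stretch: force is exactly the motor force, any amplitude
  expect_equal(filament_force(tau, stretch_protocol(0.3, 0), 0, p),
               rep(1, length(tau)))
  # perpendicular cell with nu = 0 feels nothing
  expect_equal(filament_force(tau, stretch_protocol(0.1, 1), pi / 2, p),
               rep(1, length(tau)))

  for (wf in c("sine", "cosine")) {
    pr <- stretch_protocol(0.1, 1, waveform = wf)
    num <- filament_force(tau, pr, 0, p, fv0 = 0, method = "numeric")
    cl <- filament_force(tau, pr, 0, p, method = "closed")
    late <- tau > 20 / p$gamma
    expect_lt(max(abs(num[late] - cl[late])), 1e-6)
  }

  # steady-periodic oscillation amplitude, sine waveform:
  # k_hat * eps_a * Omega / sqrt(gamma^2 + Omega^2)
  pr <- stretch_protocol(0.1, 1, waveform = "sine")
  om <- pr$omega
  cl <- filament_force(seq(900, 950, by = 0.01), pr, 0, p, method = "closed")
  amp_expected <- p$k_hat * 0.1 * om / sqrt(p$gamma^2 + om^2)
  expect_equal((max(cl) - min(cl)) / 2, amp_expected, tolerance = 1e-4)
  expect_equal(amp_expected, 1.343, tolerance = 1e-3)

  # spring-dominated limit: amplitude -> k_hat * eps_a as Omega -> Inf
  pr_fast <- stretch_protocol(0.1, 1000, waveform = "sine")
  cl <- filament_force(seq(0, 0.1, by = 1e-5), pr_fast, 0, p, method = "closed")
  expect_equal((max(cl) - min(cl)) / 2, p$k_hat * 0.1, tolerance = 1e-4)
})

test_that("bond energy reduction combines baseline, reinforcement and load", {
  p <- model_params()
  expect_equal(energy_reduction(0.7, 0, 1, 1, p), -5)     # no filaments: g0
  expect_equal(energy_reduction(0.4, 0.8, 1, 1, p), -0.4) # u = 2
  expect_equal(energy_reduction(0.4, 0.4, 1, 1, p), -2.1) # u = 1
  # stiffening relieves the elastic penalty
  expect_gt(energy_reduction(0.4, 0.8, 1, 4, p),
            energy_reduction(0.4, 0.8, 1, 1, p))
  # degenerate state: filaments without bonds
  expect_error(energy_reduction(1e-9, 0.5, 1, 1, p),
               class = "cellreorient_detached")
})

test_that("kinetic right-hand side has the expected structure", {
  p <- model_params()
  static <- stretch_protocol(0, 0)

  # saturation: no formation left at xi = 1
  d1 <- kinetics_rhs(list(xi = 1, zeta = 0.5, fv = 0), 0, 0, static, p)
  expect_lte(d1[["dxi"]], 0)

  # both derivatives vanish at the static fixed point
  ss <- steady_state_densities(p)
  d2 <- kinetics_rhs(list(xi = ss$xi_ss, zeta = ss$zeta_ss, fv = 0),
                     0, 0, static, p)
  expect_equal(unname(d2), c(0, 0), tolerance = 1e-12)

  # quasi-steady filament ratio: dzeta = 0 on the line zeta = (c/d) xi
  d3 <- kinetics_rhs(list(xi = 0.3, zeta = 0.3 * p$c / p$d, fv = 0),
                     0, 0, static, p)
  expect_equal(d3[["dzeta"]], 0, tolerance = 1e-12)
})

test_that("closed-form steady state matches values and decays with compliance", {
  expect_equal(steady_state_densities(model_params())$xi_ss,
               1 / (1 + exp(0.4)), tolerance = 1e-12)
  expect_equal(steady_state_densities(model_params())$zeta_ss,
               2 / (1 + exp(0.4)), tolerance = 1e-12)
  expect_equal(steady_state_densities(model_params(beta = 0))$xi_ss,
               1 / (1 + exp(-2)), tolerance = 1e-12)
  # Rho-inhibited: u_ss = 1, G_ss = -2.1
  expect_equal(steady_state_densities(model_params(c = 0.1))$xi_ss,
               1 / (1 + exp(2.1)), tolerance = 1e-12)

  betas <- seq(0, 3, by = 0.05)
  xi <- vapply(betas, function(b) {
    steady_state_densities(model_params(beta = b))$xi_ss
  }, numeric(1))
  expect_true(all(diff(xi) < 0))  # strictly decreasing in compliance
  expect_equal(xi[1], 1 / (1 + exp(-(-5 + 3.5 * 2))), tolerance = 1e-12)
})

test_that("steady state agrees with direct integration of the kinetics", {
  # independent route: integrate kinetics_rhs with deSolve from scratch
  p <- model_params()
  static <- stretch_protocol(0, 0)
  f <- function(t, y, parms) {
    list(unname(kinetics_rhs(list(xi = y[1], zeta = y[2], fv = 0),
                             t, 0, static, parms)))
  }
  for (b in c(0, 0.3, 0.6)) {
    pb <- model_params(beta = b)
    out <- deSolve::ode(c(0.3, 0), seq(0, 400, by = 1), f, pb,
                        rtol = 1e-8, atol = 1e-10)
    expect_equal(out[nrow(out), 2], steady_state_densities(pb)$xi_ss,
                 tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("fixed-point stability flips on soft substrates", {
  cl_stiff <- classify_fixed_point(model_params(beta = 0.6))
  cl_soft <- classify_fixed_point(model_params(beta = 1.1))
  expect_identical(cl_stiff$label, "stable")
  expect_identical(cl_soft$label, "unstable")
  expect_true(all(Re(cl_stiff$eigenvalues) < 0))
  expect_gt(max(Re(cl_soft$eigenvalues)), 0)

  # reinforcement-feedback compliance threshold: beta* = a d / (2c)
  expect_equal(critical_beta(model_params()), 0.875)
  expect_equal(critical_beta(model_params(c = 0.1)), 1.75)

  # the eigenvalue transition lies between the feedback threshold and the
  # soft regime shown to collapse
  bt <- stability_transition_beta(model_params(), lower = 0.6, upper = 1.1)
  expect_gt(bt, critical_beta(model_params()))
  expect_lt(bt, 1.1)
})
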