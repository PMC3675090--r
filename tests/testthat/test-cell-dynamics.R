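test_that("static trajectories converge to the closed-form steady state", {
  p <- model_params()
  tr <- integrate_cell(0, stretch_protocol(0, 0), p, tau_end = 500)
  ss <- steady_state_densities(p)
  expect_false(attr(tr, "collapsed"))
  expect_equal(tr$xi[nrow(tr)], ss$xi_ss, tolerance = 1e-4)
  expect_equal(tr$zeta[nrow(tr)], ss$zeta_ss, tolerance = 1e-4)
  expect_equal(tr$f_hat, rep(1, nrow(tr)))  # static: motor force only
  # density bounds hold along the trajectory
  expect_true(all(tr$xi >= 0 & tr$xi <= 1))
  expect_true(all(tr$zeta >= 0 & tr$zeta <= max(0, p$c / p$d) + 1e-9))
})

test_that("densities collapse on a soft substrate and are held at zero", {
  tr <- integrate_cell(0, stretch_protocol(0, 0), model_params(beta = 1.1),
                       tau_end = 300)
  expect_true(attr(tr, "collapsed"))
  ct <- attr(tr, "collapse_time")
  expect_gt(ct, 20)
  expect_lt(ct, 100)
  expect_equal(tr$xi[nrow(tr)], 0)
  expect_equal(tr$zeta[nrow(tr)], 0)
  expect_lt(max(tr$xi[tr$tau > ct]), 0.01)
})

test_that("a perpendicular cell on a nu=0 substrate is trajectory-identical to the static case", {
  p <- model_params()
  tr_stretch <- integrate_cell(pi / 2, stretch_protocol(0.1, 1), p,
                               tau_end = 300)
  tr_static <- integrate_cell(0, stretch_protocol(0, 0), p, tau_end = 300)
  expect_identical(tr_stretch$xi, tr_static$xi)
  expect_identical(tr_stretch$zeta, tr_static$zeta)
})

test_that("long-time average density is symmetric under angle reflection", {
  p <- model_params()
  pr <- stretch_protocol(0.1, 1)
  th <- 70 * pi / 180
  z0 <- long_time_average_density(th, pr, p)
  expect_equal(as.numeric(long_time_average_density(-th, pr, p)),
               as.numeric(z0))
  expect_equal(as.numeric(long_time_average_density(pi - th, pr, p)),
               as.numeric(z0))
})

test_that("stiffening is inert below the critical strain", {
  pr <- stretch_protocol(0.02, 1)  # amplitude below eps_c = 0.04
  tr_nl <- integrate_cell(0, pr, model_params(eps_c = 0.04), tau_end = 200)
  tr_lin <- integrate_cell(0, pr, model_params(eps_c = Inf), tau_end = 200)
  expect_identical(tr_nl$xi, tr_lin$xi)
  expect_identical(tr_nl$zeta, tr_lin$zeta)
})

test_that("increasing amplitude never increases the parallel filament density", {
  p <- model_params()
  zb <- vapply(c(0.01, 0.04, 0.10), function(a) {
    as.numeric(long_time_average_density(0, stretch_protocol(a, 1), p))
  }, numeric(1))
  expect_true(all(diff(zb) <= 1e-6))
  expect_equal(zb[3], 0)  # 10% at 1 Hz parallel: collapse
})

test_that("parallel cells collapse at 10%/1Hz while perpendicular cells persist", {
  p <- model_params()
  pr <- stretch_protocol(0.1, 1)
  tr_par <- integrate_cell(0, pr, p, tau_end = 300)
  expect_true(attr(tr_par, "collapsed"))
  zb_perp <- long_time_average_density(pi / 2, pr, p)
  expect_true(attr(zb_perp, "stable"))
  expect_equal(as.numeric(zb_perp), steady_state_densities(p)$zeta_ss,
               tolerance = 1e-3)
})

test_that("every orientation either sustains filaments or collapses outright", {
  tab <- table_normal_1hz()
  expect_true(all(tab$zeta_bar > 0.05 | tab$zeta_bar == 0))
  expect_true(all(tab$stable == (tab$zeta_bar > 0)))
  # collapsed orientations record their detachment time
  expect_true(all(is.na(tab$collapse_time) == tab$stable))
})

test_that("quasi-static protocols are averaged over a full cycle automatically", {
  p <- model_params()
  zb <- long_time_average_density(pi / 2, stretch_protocol(0.1, 0.01), p)
  # perpendicular, nu = 0: identical to the static steady state
  expect_equal(as.numeric(zb), steady_state_densities(p)$zeta_ss,
               tolerance = 1e-3)
})

test_that("angle sweep reports the preferred orientation", {
  sw <- angle_sweep(stretch_protocol(0, 0), model_params(),
                    thetas = c(0, pi / 4, pi / 2), tau_end = 300)
  expect_s3_class(sw, "angle_sweep")
  expect_equal(nrow(sw), 3)
  # static substrate: all orientations equivalent and stable
  expect_true(all(sw$stable))
  expect_lt(diff(range(sw$zeta_bar)), 1e-6)
})
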