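test_that("homogeneous balance reproduces the ansatz order", {
  expect_identical(balance_order(3, 2), 1L)
  expect_identical(balance_order(2, 2), 2L)
  expect_error(balance_order(5, 2), "non-integer")
})

test_that("the built chi-power system equals the printed one term-for-term", {
  built <- build_power_system()
  printed <- power_system_printed()
  for (eq in c("eq3", "eq2", "eq1", "eq0"))
    expect_true(mvp_is_zero(mvp_sub(built[[eq]], printed[[eq]])))
  # structural invariants of the system
  expect_false("eta0" %in% mvp_vars(built$eq3))
  expect_false("c4" %in% mvp_vars(built$eq0))
  # golden text rendering (deterministic monomial order)
  expect_identical(
    power_system_text(built),
    paste0("(chi)^3: -2*Phi1*eta1^3 + 4*c4*dc*eta1 = 0\n",
           "(chi)^2: -6*Phi1*eta0*eta1^2 - 2*Phi2*eta1^2 + 3*c3*dc*eta1 = 0\n",
           "(chi)^1: -6*Phi1*eta0^2*eta1 - 4*Phi2*eta0*eta1 - 2*Phi3*eta1 + 2*c2*dc*eta1 = 0\n",
           "(chi)^0: -2*Phi1*eta0^3 - 2*Phi2*eta0^2 - 2*Phi3*eta0 + c1*dc*eta1 = 0"))
})

test_that("degenerate quartics collapse the cubic equation as expected", {
  built <- build_power_system()
  # with c4 = 0 the cubic line forces eta1 = 0
  vals <- list(dc = 3, c1 = 0.3, c2 = 0.7, c3 = 0.2, c4 = 0,
               eta0 = 0.4, eta1 = 1.3, Phi1 = 2, Phi2 = 1, Phi3 = 0.5)
  expect_equal(mvp_eval(built$eq3, vals), -2 * 1.3^3 * 2)
})

test_that("closed-form coefficients annihilate the top two equations exactly", {
  expect_true(eta_annihilation_check())
  # and numerically, over seeded random instantiations
  sys <- build_power_system()
  set.seed(11)
  for (i in 1:30) {
    fr <- wave_frame(runif(1, 0.2, 2), runif(1, 2.5, 4), runif(1, 0.2, 1))
    ph <- reduced_coefficients(Phi1 = runif(1, 0.5, 3),
                               Phi2 = runif(1, -2, 2), Lambda1 = fr$Lambda1)
    cf <- gee_from_riccati(runif(1, 0.3, 2), runif(1, 0.3, 2),
                           runif(1, 0.1, 0.8))
    for (eta in solve_eta(fr, ph, cf)) {
      ev <- power_system_eval(sys, fr, ph, cf, eta$eta0, eta$eta1)
      scale <- abs(fr$delta_c) + abs(ph$Phi1) + 1
      expect_lt(Mod(ev[["eq3"]]) / scale, 1e-12)
      expect_lt(Mod(ev[["eq2"]]) / scale, 1e-12)
    }
  }
})

test_that("series coefficients match the printed closed form", {
  # trivial configuration: every eta0 numerator term vanishes
  fr <- wave_frame(xi = 0, zeta = 1, Lambda1 = 5)
  ph <- reduced_coefficients(Phi1 = 2, Phi2 = 0, Lambda1 = 5)
  cf <- structure(c(c0 = 0, c1 = 0, c2 = 0, c3 = 0, c4 = 1),
                  class = "gee_coefficients")
  pair <- solve_eta(fr, ph, cf)
  expect_equal(pair[[1]]$eta1, -1)
  expect_equal(pair[[2]]$eta1, 1)
  expect_equal(pair[[1]]$eta0, 0)
  # published figure-2 caption values
  fr <- fig2_frame(); ph <- fig2_phis()
  cf <- gee_from_riccati(1, 1, 0.01)
  expect_equal(unclass(cf)[c("c3", "c4")], c(c3 = 0.02, c4 = 1e-4))
  pair <- solve_eta(fr, ph, cf)
  expect_equal(pair[[1]]$eta1, -sqrt(0.003))
  expect_equal(pair[[1]]$eta1, -0.054772256, tolerance = 1e-7)
  e1 <- pair[[1]]$eta1
  expect_equal(pair[[1]]$eta0, (0.9 - 2 * e1) / (6 * e1))
  # branch antisymmetry
  expect_equal(pair[[1]]$eta1, -pair[[2]]$eta1)
  # negative radicand: flagged complex, not an error
  frn <- wave_frame(xi = 2, zeta = 1, Lambda1 = 1)
  pc <- solve_eta(frn, ph, cf)
  expect_true(pc[[1]]$complex_amplitude)
  expect_true(is.complex(pc[[1]]$eta1))
  # preconditions
  expect_error(solve_eta(fr, ph, structure(c(c0 = 0, c1 = 0, c2 = 0, c3 = 0,
                                             c4 = 0),
                                           class = "gee_coefficients")),
               "c4 = 0")
  expect_error(wave_frame(1, 1, 1), "nonzero")
})

test_that("the linear equation determines Phi3 and the constant one is audited", {
  fr <- generic_frame()
  ph <- reduced_coefficients(Phi1 = 1, Phi2 = 1, Lambda1 = 1)
  # c2 = 0 and eta0 = 0 give implied_Phi3 = 0; c1 = 0 then zeroes chi^0
  cf <- structure(c(c0 = 0, c1 = 0, c2 = 0, c3 = 0, c4 = 1),
                  class = "gee_coefficients")
  ph0 <- reduced_coefficients(Phi1 = 1, Phi2 = 0, Lambda1 = 1)
  eta <- solve_eta(fr, ph0, cf)[[1]]
  expect_equal(eta$eta0, 0)
  ic <- implied_constraints(eta, fr, ph0, cf)
  expect_equal(ic$implied_Phi3, 0)
  expect_equal(ic$constant_term_residual, 0)
  # figure-2 parameter set: the implied value zeroes eq1, the chi^0
  # residual is an honest nonzero finding
  cf2 <- gee_from_riccati(1, 1, 0.01)
  fr2 <- fig2_frame(); ph2 <- fig2_phis()
  eta2 <- solve_eta(fr2, ph2, cf2)[[1]]
  ic2 <- implied_constraints(eta2, fr2, ph2, cf2)
  sys <- build_power_system()
  ph2$Phi3 <- ic2$implied_Phi3
  ev <- power_system_eval(sys, fr2, ph2, cf2, eta2$eta0, eta2$eta1)
  expect_lt(abs(ev[["eq1"]]), 1e-12)
  expect_equal(ev[["eq0"]], ic2$constant_term_residual, tolerance = 1e-12)
  expect_gt(abs(ic2$constant_term_residual), 1)   # genuinely inconsistent here
})
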