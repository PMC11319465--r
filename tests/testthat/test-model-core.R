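test_that("coupled-system coefficients match direct arithmetic", {
  cf <- compute_lambda(unit_params())
  expect_equal(cf$kappa, 1)
  expect_equal(cf$Lambda5, 4)
  expect_equal(cf$Lambda10, 4)
  expect_equal(cf$Lambda4, -2)
  expect_equal(cf$Lambda9, -2)
  expect_equal(cf$Lambda3, 2 * sqrt(2))
  expect_equal(cf$Lambda8, sqrt(2))
  # printed identities
  expect_equal(cf$Lambda3, 2 * cf$Lambda8)
  expect_equal(cf$Lambda4, cf$Lambda9)
  expect_equal(cf$Lambda5, cf$Lambda10)
})

test_that("rigidity off zeroes every membrane-driven coefficient", {
  p <- physical_params(a0 = 1, h = 1, omega = 0, g = 1, Z = 1,
                       Gamma = 1, Delta = 1)
  cf <- compute_lambda(p)
  for (k in c(2, 3, 4, 5, 8, 9, 10, 11))
    expect_equal(cf[[sprintf("Lambda%d", k)]], 0)
  expect_equal(cf$kappa, 0)
})

test_that("wave-speed sign branches only enter squared", {
  p <- physical_params(a0 = 1, h = 1, omega = 1, g = 2, Z = 2,
                       Gamma = 1, Delta = 1)
  plus <- compute_lambda(p, sign1 = 1)
  minus <- compute_lambda(p, sign1 = -1)
  expect_equal(plus$Lambda1, 2)
  expect_equal(minus$Lambda1, -2)
  expect_equal(plus$Lambda1^2, minus$Lambda1^2)
  # the solution field is invariant under the flip
  mk <- function(cf) {
    ph <- compute_phi(cf, p)
    make_solution(solution_spec(1, fig2_aux(),
                                wave_frame(1, 4, ph$Lambda1), ph))
  }
  r <- seq(-3, 3, length.out = 11)
  expect_equal(mk(plus)$profile(r), mk(minus)$profile(r))
})

test_that("domain errors name the offending field", {
  expect_error(physical_params(a0 = 1, h = 0, omega = 1, g = 1, Z = 1,
                               Gamma = 1, Delta = 1), "'h'")
  expect_error(physical_params(a0 = 1, h = 1, omega = 1, g = 1, Z = 1,
                               Gamma = 1, Delta = -2), "'Delta'")
})

test_that("reduced coefficients match the printed closed forms", {
  p <- unit_params(b0 = 1)
  ph <- compute_phi(compute_lambda(p), p)
  expect_equal(ph$Phi2, 6 * sqrt(2))
  expect_equal(ph$Phi3, 4)            # -2k/a0 + 6k/h at unit parameters
  expect_true(all(ph$checks$agree))
  # every quadratic term carries b0
  p0 <- unit_params(b0 = 0)
  expect_equal(compute_phi(compute_lambda(p0), p0)$Phi2, 0)
  # reduction preconditions are enforced
  pbad <- physical_params(a0 = 1, h = 1, omega = 1, g = 1, Z = 2,
                          Gamma = 1, Delta = 1)
  expect_error(compute_phi(compute_lambda(pbad), pbad), "Z = g")
  pb1 <- unit_params(); pb1$b1 <- 2
  expect_error(compute_phi(compute_lambda(pb1), pb1), "b1")
})

test_that("composition route reproduces the closed forms across random draws", {
  set.seed(7)
  for (i in 1:200) {
    gv <- runif(1, -2, 2)
    p <- physical_params(a0 = runif(1, 0.2, 3), h = runif(1, 0.2, 3),
                         omega = runif(1, -2, 2), g = gv,
                         Z = gv, Gamma = runif(1, 0.2, 3),
                         Delta = runif(1, 0.2, 3), b0 = runif(1, -2, 2))
    cf <- compute_lambda(p)
    ph <- compute_phi(cf, p)
    kappa <- cf$kappa
    expect_equal(ph$Phi2, 6 * sqrt(2) * p$b0 * kappa / p$h^2,
                 tolerance = 1e-12)
    expect_equal(ph$Phi3, -2 * kappa / p$a0 + 6 * kappa / p$h,
                 tolerance = 1e-12)
  }
})

test_that("transverse reconstruction is the affine map and keeps the mask", {
  expect_equal(reconstruct_transverse(rep(0, 5), b0 = 2, b1 = 3), rep(3, 5))
  expect_equal(reconstruct_transverse(1:4, b0 = 1, b1 = 0), 1:4)
  expect_equal(reconstruct_transverse(2, b0 = 3, b1 = sqrt(2) / sqrt(2) * 1), 7)
  th <- c(1 + 0i, NA)
  attr(th, "singular") <- c(FALSE, TRUE)
  out <- reconstruct_transverse(th, 2, 1)
  expect_identical(attr(out, "singular"), c(FALSE, TRUE))
})

test_that("key-value config files round-trip into parameters", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# lattice", "a0 = 1.5", "h = 2", "omega = 0.3",
               "g = 1.1", "Z = 1.1", "Gamma = 0.8", "Delta = 1.2",
               "b0 = 0.5"), f)
  p <- read_params_file(f)
  expect_s3_class(p, "physical_params")
  expect_equal(p$a0, 1.5)
  expect_equal(p$b1, 2 / sqrt(2))
  writeLines(c("a0 = 1", "bogus = 2"), f)
  expect_error(read_params_file(f), "unknown key")
})

test_that("coefficient reports serialize to parseable JSON", {
  p <- unit_params()
  cf <- compute_lambda(p)
  ph <- compute_phi(cf, p)
  f <- withr::local_tempfile(fileext = ".json")
  write_coefficient_report(p, cf, ph, f)
  rep <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(rep$phi$Phi3, 4)
  expect_length(rep$corrections, 3)
})
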