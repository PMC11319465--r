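test_that("squared-trinomial expansion fixes the quartic coefficients", {
  g <- gee_from_riccati(1, 1, 0.01)
  expect_equal(unclass(g), c(c0 = 1, c1 = 2, c2 = 1.02, c3 = 0.02, c4 = 1e-4))
  expect_equal(unclass(gee_from_riccati(0, 0, 1)),
               c(c0 = 0, c1 = 0, c2 = 0, c3 = 0, c4 = 1))
  # sigma = 1 hides the cubic/square discrepancy
  expect_equal(gee_from_riccati(1, 2, 3)[["c0"]],
               gee_from_riccati(1, 2, 3, paper_literal = TRUE)[["c0"]])
  expect_equal(gee_from_riccati(2, 1, 1, paper_literal = TRUE)[["c0"]], 8)
  expect_equal(gee_from_riccati(2, 1, 1)[["c0"]], 4)
})

test_that("selected evaluations match hand arithmetic", {
  p <- aux_params(sigma = 1, mu = 1, rho = 0.01)
  sel <- chi_selector(1, 1, 1)
  expect_equal(as.vector(eval_chi(sel, p, 0)), -50 + 0i)   # -mu/(2*rho)
  # tanh -> 1 asymptote
  expect_equal(as.numeric(Re(eval_chi(sel, p, 500))), -(1 + sqrt(0.96)) / 0.02,
               tolerance = 1e-10)
  # trigonometric counterpart at the origin
  p2 <- aux_params(sigma = 1, mu = 1, rho = 10)
  expect_equal(as.vector(eval_chi(chi_selector(1, 2, 13), p2, 0)),
               as.complex(-1 / 20))
  # Jacobi row 1 at the hyperbolic limit
  x <- seq(-2, 2, length.out = 9)
  v <- eval_chi(chi_selector(4, 1, 1), aux_params(q = 1), x)
  expect_equal(as.numeric(Re(v)), 1 / cosh(x), tolerance = 1e-12)
})

test_that("regime violations raise errors naming the inequality", {
  sel <- chi_selector(1, 1, 1)
  expect_error(eval_chi(sel, aux_params(sigma = 1, mu = 1, rho = 1), 0),
               "mu\\^2 - 4\\*rho\\*sigma > 0")
  expect_error(chi_selector(1, 1, 99), "no catalogue entry")
  expect_error(eval_chi(chi_selector(2, 1, 1),
                        aux_params(sigma = 1, rho = 1), 0), "rho\\*sigma < 0")
})

test_that("poles are flagged singular, never returned as values", {
  sel <- chi_selector(1, 1, 2)   # coth form: pole at the origin
  p <- aux_params(sigma = 1, mu = 1, rho = 0.01)
  v <- eval_chi(sel, p, c(-1, -1e-14, 0, 1e-14, 1))
  sing <- attr(v, "singular")
  expect_identical(sing, c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_true(all(is.na(v[sing])))
  expect_true(all(is.finite(Re(v[!sing]))))
})

test_that("every catalogued form satisfies its own quartic", {
  # light sweep (3 draws); the acceptance suite runs the full 20-draw audit
  reg <- chi_entries(1:3)
  for (i in seq_len(nrow(reg))) {
    sel <- chi_selector(reg$case_id[i], reg$type_id[i], reg$index[i])
    for (p in draw_aux_params(sel, n = 3, seed = 500 + i)) {
      r <- aux_ode_residual(sel, p)
      expect_lt(r$max, 1e-8)
    }
  }
  for (i in seq_len(nrow(chi_entries(4)))) {
    row <- chi_entries(4)[i, ]
    r <- aux_ode_residual(chi_selector(4, row$type_id, row$index),
                          aux_params(q = 0.45, branch_signs = 1L))
    expect_lt(r$max, 1e-8)
  }
  r5 <- aux_ode_residual(chi_selector(5, 1, 1),
                         aux_params(c0 = 0.5, c1 = -0.3, c3 = 1.2))
  expect_lt(r5$max, 1e-6)   # Weierstrass route is itself numerical
})

test_that("the printed cubic constant term fails the quartic where sigma != 1", {
  sel <- chi_selector(1, 1, 1)
  p <- aux_params(sigma = 2, mu = 1, rho = -0.25)
  good <- aux_ode_residual(sel, p, coeffs = gee_from_riccati(2, 1, -0.25))
  bad <- aux_ode_residual(sel, p,
                          coeffs = gee_from_riccati(2, 1, -0.25,
                                                    paper_literal = TRUE))
  expect_lt(good$max, 1e-9)
  expect_gt(bad$max, 1e-3)
})

test_that("branch enumeration never raises on valid regimes", {
  reg <- chi_entries(1:2)
  reg <- reg[reg$n_branch > 0, ]
  for (i in seq_len(nrow(reg))) {
    sel <- chi_selector(reg$case_id[i], reg$type_id[i], reg$index[i])
    base <- draw_aux_params(sel, n = 1, seed = 900 + i)[[1]]
    combos <- expand.grid(rep(list(c(-1L, 1L)), reg$n_branch[i]))
    for (j in seq_len(nrow(combos))) {
      base$branch_signs <- as.integer(combos[j, ])
      v <- eval_chi(sel, base, seq(-2, 2, length.out = 7))
      expect_length(v, 7)
    }
  }
})

test_that("modulus limits reproduce the elementary-function tables", {
  x <- seq(-3, 3, length.out = 41)
  # named rows of the limit tables (paper letter r = standard s)
  expect_identical(jef_degenerate(chi_selector(4, 2, 3), 1)$label, "sech")
  expect_identical(jef_degenerate(chi_selector(4, 2, 3), 0)$label, "cos")
  expect_identical(jef_degenerate(chi_selector(4, 3, 4), 0)$label, "1")
  reg <- chi_entries(4)
  for (i in seq_len(nrow(reg))) {
    sel <- chi_selector(4, reg$type_id[i], reg$index[i])
    for (qv in c(1, 0)) {
      deg <- jef_degenerate(sel, qv)
      v1 <- eval_chi(sel, aux_params(q = qv, branch_signs = 1L), x)
      v2 <- deg$fn(x, branch = 1)
      keep <- !attr(v1, "singular")
      expect_lt(max(Mod(as.complex(v1)[keep] - as.complex(v2)[keep])), 1e-10)
    }
    # continuity toward the hyperbolic limit, relative to the limit size
    # (the unbounded entries differ by ~5e-4 in absolute terms at rho = 3;
    # that is the true analytic gap at q = 1 - 1e-6, not evaluator error)
    deg <- jef_degenerate(sel, 1)
    v1 <- eval_chi(sel, aux_params(q = 1 - 1e-6, branch_signs = 1L), x)
    v2 <- as.complex(deg$fn(x, branch = 1))
    keep <- !attr(v1, "singular")
    rel <- Mod(as.complex(v1)[keep] - v2[keep]) / (1 + Mod(v2[keep]))
    expect_lt(max(rel), 1e-4)
  }
  expect_error(jef_degenerate(chi_selector(1, 1, 1), 1), "Case-4")
  expect_error(jef_degenerate(chi_selector(4, 1, 1), 0.5), "exactly 0 or 1")
})

test_that("the registry manifest serializes and covers all cases", {
  reg <- chi_registry()
  expect_equal(sum(reg$case_id == 1), 24)
  expect_equal(sum(reg$case_id == 2), 12)
  expect_equal(sum(reg$case_id == 3), 10)
  expect_equal(sum(reg$case_id == 4), 16)
  expect_equal(sum(reg$case_id == 5), 1)
  f <- withr::local_tempfile(fileext = ".json")
  chi_manifest_json(f)
  m <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(nrow(m), nrow(reg))
})
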