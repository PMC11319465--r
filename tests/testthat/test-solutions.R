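test_that("the family registry is exhaustive and correctly wired", {
  reg <- solution_registry()
  expect_equal(nrow(reg), 94)
  expect_equal(max(reg$family_index), 94)
  expect_equal(sum(reg$degenerate), 32)
  expect_equal(sum(reg$limit == "q1"), 16)
  expect_equal(sum(reg$limit == "q0"), 16)
  expect_equal(range(reg$family_index[reg$case_id == 1]), c(1, 24))
  expect_equal(range(reg$family_index[reg$case_id == 2]), c(25, 36))
  expect_equal(range(reg$family_index[reg$case_id == 3]), c(37, 46))
  expect_equal(range(reg$family_index[reg$case_id == 4]), c(47, 94))
  # every non-degenerate family resolves to a catalogue entry
  for (i in which(!reg$degenerate))
    expect_s3_class(chi_selector(reg$case_id[i], reg$type_id[i],
                                 reg$chi_index[i]), "chi_selector")
})

test_that("every family constructs with at least one valid parameter set", {
  reg <- solution_registry()
  frame <- generic_frame()
  phis <- reduced_coefficients(Phi1 = 1, Phi2 = 1, Lambda1 = 1)
  for (i in seq_len(nrow(reg))) {
    fam <- reg$family_index[i]
    if (reg$degenerate[i]) {
      aux <- aux_params(q = if (reg$limit[i] == "q1") 1 else 0,
                        branch_signs = 1L)
    } else {
      sel <- chi_selector(reg$case_id[i], reg$type_id[i], reg$chi_index[i])
      aux <- draw_aux_params(sel, n = 1, seed = 300 + fam)[[1]]
    }
    sol <- make_solution(solution_spec(fam, aux, frame, phis))
    expect_s3_class(sol, "dna_solution")
    v <- sol$theta(0.3, 0.2)
    expect_length(v, 1)
  }
})

test_that("solutions are traveling waves: constant along characteristics", {
  frame <- fig2_frame()
  phis <- fig2_phis()
  for (fam in c(1, 3, 8, 13, 25, 47)) {
    reg <- solution_registry()
    row <- reg[reg$family_index == fam, ]
    aux <- if (row$case_id == 4) aux_params(q = 0.6, branch_signs = 1L)
           else if (row$case_id == 2) aux_params(sigma = 1, rho = -0.3,
                                                 branch_signs = c(1L, 1L))
           else if (row$type_id == 2) aux_params(sigma = 1, mu = 1, rho = 10)
           else fig2_aux()
    sol <- make_solution(solution_spec(fam, aux, frame, phis))
    s <- c(-1.2, 0.4, 2.2); a <- 0.77
    expect_equal(sol$theta(s + a, 1), sol$theta(s, 1 + a * frame$xi / frame$zeta),
                 tolerance = 1e-12)
    # fixed rho0: equal wherever xi*s + zeta*t = rho0
    expect_equal(sol$theta(4, 0.25), sol$theta(0, 0.25 + 4 / 4),
                 tolerance = 1e-12)
  }
})

test_that("the amplitude branches pair to twice the mean background", {
  frame <- fig2_frame(); phis <- fig2_phis()
  reg <- solution_registry()
  fams <- c(1, 2, 5, 8, 13, 20, 37, 41, 47, 56)
  for (fam in fams) {
    row <- reg[reg$family_index == fam, ]
    aux <- if (row$case_id == 4) aux_params(q = 0.6, branch_signs = 1L)
           else if (row$case_id == 3)
             draw_aux_params(chi_selector(row$case_id, row$type_id,
                                          row$chi_index), 1, seed = fam)[[1]]
           else if (row$case_id == 1 && row$type_id == 2)
             aux_params(sigma = 1, mu = 1, rho = 10)
           else fig2_aux()
    sm <- make_solution(solution_spec(fam, aux, frame, phis, branch = -1))
    sp <- make_solution(solution_spec(fam, aux, frame, phis, branch = 1))
    r <- seq(-2, 2, length.out = 9)
    vm <- sm$profile(r); vp <- sp$profile(r)
    keep <- !attr(vm, "singular") & !attr(vp, "singular")
    expect_equal(as.vector(vm)[keep] + as.vector(vp)[keep],
                 rep(as.complex(sm$eta$eta0 + sp$eta$eta0), sum(keep)),
                 tolerance = 1e-10)
  }
})

test_that("grid evaluation masks singular rows and flags constants", {
  frame <- fig2_frame(); phis <- fig2_phis()
  sol <- make_solution(solution_spec(2, fig2_aux(), frame, phis))  # coth pole
  fld <- eval_grid(sol, s_range = c(-4, 4), t_range = c(0, 1e-18),
                   ns = 81, nt = 2)
  # the pole line xi*s + zeta*t = 0 crosses s = 0; nearby cells masked or huge
  expect_true(all(is.na(fld$values[fld$singular])))
  comp <- field_component(fld, "re")
  expect_true(all(is.na(comp[fld$singular])))
  # constant degenerate family (dn -> 1 limit): constant field
  solc <- make_solution(solution_spec(82, aux_params(q = 0),
                                      frame, phis))
  fldc <- eval_grid(solc, c(-2, 2), c(0, 1), 11, 5)
  expect_equal(max(Mod(fldc$values)) - min(Mod(fldc$values)), 0)
  # the q->1 sech family equals eta0 + eta1*sech directly
  sol63 <- make_solution(solution_spec(63, aux_params(q = 1), frame, phis))
  r <- seq(-2, 2, length.out = 11)
  expect_equal(as.complex(sol63$profile(r)),
               as.complex(sol63$eta$eta0 + sol63$eta$eta1 / cosh(r)),
               tolerance = 1e-12)
})

test_that("regime validation lists each violated printed constraint", {
  frame <- fig2_frame(); phis <- fig2_phis()
  ok <- solution_spec(1, fig2_aux(), frame, phis)
  expect_length(validate_regime(ok), 0)
  bad <- solution_spec(1, aux_params(sigma = 1, mu = 0, rho = 0.01),
                       frame, phis)
  expect_true("mu*rho != 0" %in% validate_regime(bad))
  case2 <- solution_spec(25, aux_params(sigma = 1, rho = 1), frame, phis)
  expect_true("rho*sigma < 0" %in% validate_regime(case2))
  expect_error(make_solution(case2), "rho\\*sigma < 0")
})

test_that("grid export writes delimited text plus a JSON sidecar", {
  sol <- make_solution(solution_spec(1, fig2_aux(), fig2_frame(), fig2_phis()))
  fld <- eval_grid(sol, c(-2, 2), c(0, 1), ns = 11, nt = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  export_grid(fld, f)
  df <- utils::read.delim(f)
  expect_identical(names(df), c("s", "t", "re", "im", "abs", "singular"))
  expect_equal(nrow(df), 11 * 5)
  side <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(side$family_index, 1)
  expect_equal(side$frame$zeta, 4)
})
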