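# Audit engine: quantifies how well every catalogued family satisfies the
# reduced ODE and the governing PDE.
#
# The closed-form series pair annihilates only the cubic and quadratic
# chi-power equations; the linear equation fixes the linear coefficient
# (implied Phi3) and the constant equation is then a residual that vanishes
# only on a parameter subvariety. The audit therefore reports two
# instantiations per family: the default parameter set (constant-term
# residual reported as a finding), and a "consistent" set where the
# quadratic coefficient Phi2 is moved to a root of the constant equation, on
# which the family is an exact solution and the discretized PDE residual
# must converge at second order.

#' Quadratic coefficient at which the constant-term equation is satisfied
#'
#' The closed-form series pair leaves the constant chi-power equation as a
#' residual; as a function of `Phi2` that residual is a cubic with leading
#' coefficient `2/(27*Phi1^2)`, so a real root exists whenever the amplitude
#' is real. For amplitude-degenerate families (`c4 = 0`) the condition
#' reduces to `Phi2^2 = -9*Phi1*delta_c*c2`. At the returned value the
#' family solves the reduced equation exactly.
#'
#' @param frame a [wave_frame()].
#' @param phis a `reduced_coefficients` (only `Phi1` enters).
#' @param coeffs a `gee_coefficients` vector.
#' @param branch amplitude branch (+1 or -1).
#' @return the smallest-magnitude real root, or `NA` when none exists
#'   (complex amplitude).
#' @export
consistent_phi2 <- function(frame, phis, coeffs, branch = -1) {
  cs <- unclass(coeffs)
  dc <- frame$delta_c; P1 <- phis$Phi1
  if (cs[["c4"]] == 0) {
    rad <- -9 * P1 * dc * cs[["c2"]]
    if (rad < 0) return(NA_real_)
    return(sqrt(rad))
  }
  rad <- 2 * dc * cs[["c4"]] / P1
  eta1 <- if (rad < 0) branch * sqrt(as.complex(rad)) else branch * sqrt(rad)
  A <- dc * cs[["c3"]] / (2 * eta1 * P1)
  B <- -1 / (3 * P1)
  # g(Phi2) = dc*c1*eta1 - 2*u*(dc*c2 - 2*P1*u^2 - u*Phi2), u = A + B*Phi2
  u  <- c(A, B)                       # ascending coefficients
  pmul <- function(a, b) {
    out <- rep(0 + 0i, length(a) + length(b) - 1)
    for (i in seq_along(a)) for (j in seq_along(b))
      out[i + j - 1] <- out[i + j - 1] + a[i] * b[j]
    out
  }
  padd <- function(a, b) {
    n <- max(length(a), length(b))
    a <- c(a, rep(0, n - length(a))); b <- c(b, rep(0, n - length(b)))
    a + b
  }
  u2 <- pmul(u, u)
  h <- padd(c(dc * cs[["c2"]]), padd(-2 * P1 * u2, -pmul(u, c(0, 1))))
  g <- padd(c(dc * cs[["c1"]] * eta1), -2 * pmul(u, h))
  r <- polyroot(g)
  realish <- r[abs(Im(r)) < 1e-8 * pmax(1, Mod(r))]
  if (length(realish) == 0L) return(NA_real_)
  # deterministic choice: smallest magnitude, ties by real part
  realish <- realish[order(Mod(realish), Re(realish))]
  Re(realish[1])
}

#' Residual of a solution family against the reduced ODE
#'
#' Evaluates `|delta_c*Y'' - Phi1*Y^3 - Phi2*Y^2 - Phi3*Y|`, normalized by
#' `1 + sum(|terms|)`, along the traveling coordinate. The second derivative
#' is computed two ways: (a) in closed form through the auxiliary quartic,
#' `Y'' = eta1*(c1 + 2*c2*chi + 3*c3*chi^2 + 4*c4*chi^3)/2`, and (b) by a
#' 4th-order central difference; both are reported.
#'
#' @param sol a [make_solution()] result.
#' @param points traveling-coordinate sample values (default: 41 points in
#'   `[-3, 3]`, widened by the reciprocal frequency for slowly varying
#'   families).
#' @param Phi3 linear coefficient; defaults to the value implied by the
#'   linear chi-power equation.
#' @return list with `closed` and `numeric` summaries (`max`, `mean`) and
#'   `n_used`.
#' @export
ode_residual <- function(sol, points = NULL, Phi3 = NULL) {
  stopifnot(inherits(sol, "dna_solution"))
  if (is.null(Phi3)) Phi3 <- sol$implied_Phi3
  frame <- sol$spec$frame; phis <- sol$spec$phis
  cs <- unclass(sol$coeffs)
  chi_fn <- sol$chi
  eta0 <- sol$eta$eta0; eta1 <- sol$eta$eta1

  val <- function(x) {
    r <- chi_fn(x)
    v <- as.complex(r$v); v[r$d < .SING_DEN_TOL] <- NA_complex_
    v
  }
  freq <- if (sol$spec$row$degenerate) 1 else .chi_freq_sol(sol)
  if (is.null(points)) points <- seq(-3, 3, length.out = 41) / min(1, freq)
  h <- 2e-3 / freq
  chi0 <- val(points)
  dmin <- chi_fn(points)$d
  ok <- !is.na(chi0)
  for (o in c(-2, -1, 1, 2)) {
    r <- chi_fn(points + o * h)
    dmin <- pmin(dmin, r$d)
    ok <- ok & !is.na(as.complex(r$v))
  }
  pts <- points[ok & dmin > 0.3]
  if (!length(pts)) stop("all sample points are singular")
  chi <- val(pts)
  Y <- eta0 + eta1 * chi
  Ypp_closed <- eta1 * (cs[["c1"]] + 2 * cs[["c2"]] * chi +
                          3 * cs[["c3"]] * chi^2 + 4 * cs[["c4"]] * chi^3) / 2
  prof <- function(x) eta0 + eta1 * val(x)
  Ypp_num <- (-prof(pts + 2 * h) + 16 * prof(pts + h) - 30 * prof(pts) +
                16 * prof(pts - h) - prof(pts - 2 * h)) / (12 * h^2)
  rhs <- phis$Phi1 * Y^3 + phis$Phi2 * Y^2 + Phi3 * Y
  summarize <- function(Ypp) {
    lhs <- frame$delta_c * Ypp
    den <- 1 + Mod(lhs) + Mod(phis$Phi1 * Y^3) + Mod(phis$Phi2 * Y^2) +
      Mod(Phi3 * Y)
    res <- Mod(lhs - rhs) / den
    list(max = max(res), mean = mean(res))
  }
  list(closed = summarize(Ypp_closed), numeric = summarize(Ypp_num),
       n_used = length(pts))
}

.chi_freq_sol <- function(sol) {
  row <- sol$spec$row
  sel <- chi_selector(row$case_id, row$type_id, row$chi_index)
  .chi_freq(sel, sol$spec$aux)
}

#' Finite-difference residual of a solution against the governing PDE
#'
#' Discretizes `Theta_tt - Lambda1^2*Theta_ss - Phi1*Theta^3 - Phi2*Theta^2 -
#' Phi3*Theta` with second-order central differences on the given grid and
#' reports the maximum and mean residual magnitude, excluding a 2-cell margin
#' around masked (singular) cells and the grid boundary.
#'
#' @param sol a [make_solution()] result.
#' @param s_range,t_range grid extents.
#' @param ns,nt grid sizes.
#' @param Phi3 linear coefficient (defaults to the implied value).
#' @param buffer pole-buffer denominator cutoff; `pde_buffer()` gives the
#'   grid-aware default.
#' @return list with `max`, `mean`, `frac_used`, `frac_nonsingular`, `ds`,
#'   `dt`.
#' @export
pde_residual <- function(sol, s_range = c(-2, 2), t_range = c(0, 1),
                         ns = 97, nt = 49, Phi3 = NULL, buffer = NULL) {
  stopifnot(inherits(sol, "dna_solution"), ns >= 5, nt >= 5)
  if (is.null(Phi3)) Phi3 <- sol$implied_Phi3
  frame <- sol$spec$frame; phis <- sol$spec$phis
  s_axis <- seq(s_range[1], s_range[2], length.out = ns)
  t_axis <- seq(t_range[1], t_range[2], length.out = nt)
  rho <- outer(s_axis * frame$xi, t_axis * frame$zeta, `+`)
  r <- sol$chi(as.numeric(rho))
  v <- sol$eta$eta0 + sol$eta$eta1 * as.complex(r$v)
  sing <- !is.finite(Re(v)) | !is.finite(Im(v)) | r$d < .SING_DEN_TOL
  Th <- matrix(v, ns, nt)
  D <- matrix(r$d, ns, nt)
  ds <- diff(s_axis[1:2]); dt <- diff(t_axis[1:2])
  i <- 2:(ns - 1); j <- 2:(nt - 1)
  Tss <- (Th[i + 1, j] - 2 * Th[i, j] + Th[i - 1, j]) / ds^2
  Ttt <- (Th[i, j + 1] - 2 * Th[i, j] + Th[i, j - 1]) / dt^2
  Tc <- Th[i, j]
  R <- Ttt - frame$Lambda1^2 * Tss -
    (phis$Phi1 * Tc^3 + phis$Phi2 * Tc^2 + Phi3 * Tc)
  # pole buffer: cells whose composing denominators fall below `buffer` are
  # excluded. The default adds to the base cutoff 0.3 the maximal variation
  # of the denominator across a stencil of THIS grid; a convergence study
  # must instead fix one buffer from its coarsest grid (pde_convergence does)
  # so the usable region is resolution-independent and the order estimate is
  # not contaminated by approach to the poles. A 2-cell margin is further
  # grown around hard-masked (singular) cells.
  if (is.null(buffer)) buffer <- pde_buffer(sol, s_range, t_range, ns, nt)
  grow <- function(m) {
    g <- m
    g[-1, ] <- g[-1, ] | m[-nrow(m), ]
    g[-nrow(m), ] <- g[-nrow(m), ] | m[-1, ]
    g[, -1] <- g[, -1] | m[, -ncol(m)]
    g[, -ncol(m)] <- g[, -ncol(m)] | m[, -1]
    g
  }
  bad2 <- grow(grow(matrix(sing, ns, nt)))[i, j]
  use <- !bad2 & D[i, j] >= buffer & is.finite(Mod(R))
  if (!any(use)) stop("no usable interior cells on this grid")
  res <- Mod(R[use])
  list(max = max(res), mean = mean(res), frac_used = mean(use),
       frac_nonsingular = 1 - mean(sing), ds = ds, dt = dt)
}

#' @rdname pde_residual
#' @export
pde_buffer <- function(sol, s_range = c(-2, 2), t_range = c(0, 1),
                       ns = 97, nt = 49) {
  freq <- if (sol$spec$row$degenerate) 1 else .chi_freq_sol(sol)
  frame <- sol$spec$frame
  ds <- diff(s_range) / (ns - 1); dt <- diff(t_range) / (nt - 1)
  0.3 + 1.2 * freq * (abs(frame$xi) * ds + abs(frame$zeta) * dt)
}

#' Convergence order of the PDE residual under grid halving
#'
#' @inheritParams pde_residual
#' @return list with the two residual summaries (`coarse`, `fine`) and the
#'   observed `order` (`NA` when the residual is already at roundoff, as for
#'   constant exact solutions, or when fewer than 90 percent of cells are
#'   usable on either grid).
#' @export
pde_convergence <- function(sol, s_range = c(-2, 2), t_range = c(0, 1),
                            ns = 97, nt = 49, Phi3 = NULL) {
  buf <- pde_buffer(sol, s_range, t_range, ns, nt)
  r1 <- pde_residual(sol, s_range, t_range, ns, nt, Phi3, buffer = buf)
  r2 <- pde_residual(sol, s_range, t_range, 2 * ns - 1, 2 * nt - 1, Phi3,
                     buffer = buf)
  order <- if (r1$frac_nonsingular < 0.9 || r2$frac_nonsingular < 0.9 ||
               r1$mean < 1e-12) NA_real_ else log2(r1$mean / r2$mean)
  list(coarse = r1, fine = r2, order = order)
}

# Default audit frame/coefficients for non-caption families.
.audit_defaults <- function() {
  list(frame = wave_frame(xi = 1, zeta = 2, Lambda1 = 1),
       Phi1 = 1, Phi2 = 1)
}

#' Audit the complete solution catalogue
#'
#' For every registry family this runs the full consistency chain: the
#' auxiliary-ODE residual of its chi (Cases 1-3 and the Jacobi/degenerate
#' forms), the exact annihilation status of the cubic/quadratic equations,
#' the implied linear coefficient and constant-term residual at the default
#' parameters, and — at the Phi2 root of the constant equation, where the
#' family is exactly consistent — the closed-form ODE residual and the
#' finite-difference PDE residual with its observed convergence order.
#' Figure-caption parameter sets are used where available, otherwise seeded
#' random valid draws.
#'
#' @param seed integer seed controlling all random draws (per-family seeds
#'   are derived from it; the audit is deterministic given `seed`).
#' @param families registry family indices to audit (default: all).
#' @return object of class `verification_report`.
#' @export
audit_catalogue <- function(seed = 1, families = solution_registry()$family_index) {
  reg <- solution_registry()
  caption <- .figure_family_map()
  sym_ok <- eta_annihilation_check()
  defaults <- .audit_defaults()
  chi_reg <- chi_registry()

  recs <- vector("list", length(families))
  for (k in seq_along(families)) {
    fam <- families[k]
    row <- reg[reg$family_index == fam, , drop = FALSE]
    src <- if (fam %in% names(caption)) "caption" else "random"
    if (src == "caption") {
      cfg <- figure_config(caption[[as.character(fam)]])
      aux <- cfg$aux; frame <- cfg$frame
      Phi1 <- cfg$phis$Phi1; Phi2 <- cfg$phis$Phi2
    } else {
      frame <- defaults$frame; Phi1 <- defaults$Phi1; Phi2 <- defaults$Phi2
      if (row$degenerate) {
        aux <- aux_params(q = if (row$limit == "q1") 1 else 0,
                          branch_signs = 1L)
      } else {
        sel <- chi_selector(row$case_id, row$type_id, row$chi_index)
        aux <- draw_aux_params(sel, n = 1, seed = seed + fam)[[1]]
      }
    }
    phis <- reduced_coefficients(Phi1 = Phi1, Phi2 = Phi2, Lambda1 = frame$Lambda1)
    spec <- solution_spec(fam, aux, frame, phis, branch = -1)
    viol <- validate_regime(spec)
    sol <- tryCatch(make_solution(spec, strict = src != "caption"),
                    error = function(e) e)
    if (inherits(sol, "error")) {
      recs[[k]] <- data.frame(
        family_index = fam, case_id = row$case_id, type_id = row$type_id,
        chi_index = row$chi_index, degenerate = row$degenerate,
        limit = row$limit, source = src, regime_violations = length(viol),
        aux_residual = NA_real_, mu_sign = NA_integer_,
        eq32_annihilated = sym_ok, implied_Phi3 = NA_real_,
        implied_Phi3_im = NA_real_,
        chi0_residual = NA_real_, phi2_consistent = NA_real_,
        chi0_residual_consistent = NA_real_, ode_residual_closed = NA_real_,
        ode_residual_numeric = NA_real_, pde_mean_coarse = NA_real_,
        pde_mean_fine = NA_real_, conv_order = NA_real_,
        amplitude_degenerate = NA, corrected = NA, flagged = row$flagged,
        error = conditionMessage(sol), stringsAsFactors = FALSE)
      next
    }

    # auxiliary-ODE residual of the family's chi against its own coefficients
    aux_res <- if (row$degenerate) {
      .degenerate_aux_residual(row, sol)
    } else {
      sel <- chi_selector(row$case_id, row$type_id, row$chi_index)
      r <- aux_ode_residual(sel, aux, check_regime = src != "caption")
      r$max
    }
    mu_sign <- sol$mu_sign

    # consistent instantiation: Phi2 at a root of the constant equation
    p2 <- consistent_phi2(frame, phis, sol$coeffs, branch = -1)
    if (is.finite(p2)) {
      phis_c <- reduced_coefficients(Phi1 = Phi1, Phi2 = p2,
                                     Lambda1 = frame$Lambda1)
      sol_c <- make_solution(solution_spec(fam, aux, frame, phis_c, branch = -1),
                             strict = src != "caption")
      chi0_c <- Mod(sol_c$chi0_residual)
      oc <- tryCatch(ode_residual(sol_c), error = function(e) NULL)
      # resolve the family's own length scale: at least 16 grid points per
      # unit of variation of the traveling coordinate, then refine (bounded)
      # until the two-grid order estimate reaches the asymptotic range — a
      # convergence study is only meaningful there
      fq <- if (row$degenerate) 1 else
        .chi_freq(chi_selector(row$case_id, row$type_id, row$chi_index), aux)
      ns_g <- min(641, max(97, ceiling(4 * abs(frame$xi) * 16 * fq) + 1))
      nt_g <- min(321, max(49, ceiling(1 * abs(frame$zeta) * 16 * fq) + 1))
      pc <- NULL
      for (try in 1:3) {
        pc_try <- tryCatch(pde_convergence(sol_c, ns = ns_g, nt = nt_g),
                           error = function(e) NULL)
        if (!is.null(pc_try)) pc <- pc_try
        if (is.null(pc_try) || is.na(pc_try$order) ||
            (pc_try$order >= 1.7 && pc_try$order <= 2.3)) break
        ns_g <- 2 * ns_g - 1; nt_g <- 2 * nt_g - 1
      }
    } else {
      chi0_c <- NA_real_; oc <- NULL; pc <- NULL
    }

    chir <- chi_reg[chi_reg$case_id == row$case_id &
                      chi_reg$type_id == row$type_id &
                      chi_reg$index == row$chi_index, , drop = FALSE]
    recs[[k]] <- data.frame(
      family_index = fam, case_id = row$case_id, type_id = row$type_id,
      chi_index = row$chi_index, degenerate = row$degenerate,
      limit = row$limit, source = src, regime_violations = length(viol),
      aux_residual = aux_res, mu_sign = if (is.na(mu_sign)) NA_integer_ else mu_sign,
      eq32_annihilated = sym_ok, implied_Phi3 = Re(sol$implied_Phi3),
      implied_Phi3_im = Im(as.complex(sol$implied_Phi3)),
      chi0_residual = Mod(sol$chi0_residual), phi2_consistent = p2,
      chi0_residual_consistent = chi0_c,
      ode_residual_closed = if (is.null(oc)) NA_real_ else oc$closed$max,
      ode_residual_numeric = if (is.null(oc)) NA_real_ else oc$numeric$max,
      pde_mean_coarse = if (is.null(pc)) NA_real_ else pc$coarse$mean,
      pde_mean_fine = if (is.null(pc)) NA_real_ else pc$fine$mean,
      conv_order = if (is.null(pc)) NA_real_ else pc$order,
      amplitude_degenerate = sol$amplitude_degenerate,
      corrected = nrow(chir) == 1 && chir$corrected,
      flagged = row$flagged, error = "", stringsAsFactors = FALSE)
  }
  fam_df <- do.call(rbind, recs)

  corrections <- .corrections_record()
  structure(list(schema_version = "1.0", seed = seed, families = fam_df,
                 corrections = corrections,
                 eq32_annihilated = sym_ok),
            class = "verification_report")
}

# Residual of a degenerate elementary form against its limiting triple.
.degenerate_aux_residual <- function(row, sol) {
  cs <- unclass(sol$coeffs)
  fn <- function(x) {
    r <- sol$chi(x)
    v <- as.complex(r$v); v[r$d < .SING_DEN_TOL] <- NA_complex_
    v
  }
  pts <- seq(-3, 3, length.out = 41)
  h <- 2e-3
  dmin <- sol$chi(pts)$d
  ok <- !is.na(fn(pts))
  for (o in c(-3, -2, -1, 1, 2, 3)) {
    r <- sol$chi(pts + o * h)
    dmin <- pmin(dmin, r$d)
    ok <- ok & !is.na(as.complex(r$v))
  }
  pts <- pts[ok & dmin > 0.3]
  if (!length(pts)) return(NA_real_)
  chi <- fn(pts)
  d <- .num_deriv(fn, pts, h)
  quart <- cs[["c0"]] + cs[["c1"]] * chi + cs[["c2"]] * chi^2 +
    cs[["c3"]] * chi^3 + cs[["c4"]] * chi^4
  max(Mod(d^2 - quart) / (1 + Mod(quart)))
}

# Corrections applied across the pipeline, with the constant-term discrepancy
# of the squared-trinomial expansion evaluated both ways.
.corrections_record <- function() {
  sel <- chi_selector(1, 1, 1)
  p <- aux_params(sigma = 2, mu = 1, rho = -0.25)
  r_sq <- aux_ode_residual(sel, p, coeffs = gee_from_riccati(2, 1, -0.25))
  r_cu <- aux_ode_residual(sel, p,
                           coeffs = gee_from_riccati(2, 1, -0.25, paper_literal = TRUE))
  reg <- chi_registry()
  sreg <- solution_registry()
  list(
    c0_expansion = list(
      statement = "expansion of the squared trinomial forces c0 = sigma^2; the printed sigma^3 is kept for audit",
      residual_with_sigma2 = r_sq$max,
      residual_with_sigma3 = r_cu$max,
      sigma_used = 2
    ),
    substitutions = c(
      "delta = Delta: the undeclared denominator symbol is the mass density",
      "y = h: the undefined symbol in the linear coupled coefficient is the strand separation",
      "Lambda7 = -2*kappa/a0: omitted from the printed coefficient list; derived from reduction consistency",
      "printed Phi1 closed form kappa*(-2+4*b0^2)/h^3 is dimensionally inconsistent; the coefficient composition is authoritative"
    ),
    chi_catalogue = reg[reg$corrected, c("case_id", "type_id", "index", "note")],
    solution_forms = sreg[sreg$flagged, c("family_index", "note")]
  )
}

#' @export
print.verification_report <- function(x, ...) {
  f <- x$families
  cat(sprintf("Catalogue audit (seed %d): %d families\n", x$seed, nrow(f)))
  cat(sprintf("  cubic/quadratic equations annihilated exactly: %s\n",
              x$eq32_annihilated))
  cat(sprintf("  auxiliary-ODE residual: max %.3g (over %d families)\n",
              max(f$aux_residual, na.rm = TRUE), sum(!is.na(f$aux_residual))))
  cat(sprintf("  consistent-mode closed ODE residual: max %.3g\n",
              max(f$ode_residual_closed, na.rm = TRUE)))
  ord <- f$conv_order[!is.na(f$conv_order)]
  cat(sprintf("  PDE convergence order: median %.2f over %d families\n",
              stats::median(ord), length(ord)))
  cat(sprintf("  corrections recorded: %d catalogue, %d solution forms\n",
              nrow(x$corrections$chi_catalogue),
              nrow(x$corrections$solution_forms)))
  invisible(x)
}

#' Serialize a verification report
#'
#' @param report a `verification_report`.
#' @param path output path (`.json`); a sibling `.csv` with the per-family
#'   table is written when `csv = TRUE`.
#' @param csv also write the CSV summary table.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, csv = TRUE) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  if (csv)
    utils::write.csv(report$families, sub("\\.json$", ".csv", path),
                     row.names = FALSE)
  invisible(path)
}

#' Read back a serialized verification report
#'
#' @param path JSON path written by [write_report()].
#' @return list mirroring the report structure.
#' @export
read_report <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
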