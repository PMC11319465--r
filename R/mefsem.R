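# Derivation machinery for the reduced wave equation
#   (zeta^2 - xi^2*Lambda1^2) * Y'' - Phi1*Y^3 - Phi2*Y^2 - Phi3*Y = 0
# under the finite series ansatz Y = eta0 + eta1*chi with chi obeying the
# quartic first-order auxiliary equation. The chi-power system, its
# closed-form solution for (eta0, eta1), and the two constraints the solution
# leaves implicit are all constructed exactly (see R/mvp.R).

#' Traveling-wave frame
#'
#' @param xi spatial wavenumber.
#' @param zeta temporal frequency.
#' @param Lambda1 wave-speed coefficient of the reduced equation.
#' @return object of class `wave_frame` with `delta_c = zeta^2 -
#'   xi^2*Lambda1^2` (required nonzero).
#' @export
wave_frame <- function(xi, zeta, Lambda1) {
  delta_c <- zeta^2 - xi^2 * Lambda1^2
  if (delta_c == 0)
    stop("degenerate frame: zeta^2 - xi^2*Lambda1^2 must be nonzero")
  structure(list(xi = xi, zeta = zeta, Lambda1 = Lambda1, delta_c = delta_c),
            class = "wave_frame")
}

#' Homogeneous balance order
#'
#' Balances the highest-order linear derivative term against the highest
#' nonlinearity: `degree*M = M + order`, i.e. `M = order/(degree-1)`. For the
#' cubic nonlinearity and second derivative of the reduced equation this is
#' `3M = M + 2`, giving `M = 1`.
#'
#' @param nonlinearity_degree polynomial degree of the strongest nonlinear
#'   term (>= 2).
#' @param derivative_order order of the highest derivative (>= 1).
#' @return integer `M`; errors when the balance is non-integral (method
#'   inapplicable as stated).
#' @examples
#' balance_order(3, 2)  # 1
#' @export
balance_order <- function(nonlinearity_degree, derivative_order) {
  stopifnot(nonlinearity_degree >= 2, derivative_order >= 1,
            nonlinearity_degree == round(nonlinearity_degree),
            derivative_order == round(derivative_order))
  M <- derivative_order / (nonlinearity_degree - 1)
  if (M != round(M))
    stop(sprintf("homogeneous balance gives non-integer order M = %g; the finite series ansatz does not apply",
                 M))
  as.integer(M)
}

# Symbol table used by the exact polynomial construction.
.sys_vars <- function() {
  list(dc = mvp_var("dc"),
       c1 = mvp_var("c1"), c2 = mvp_var("c2"),
       c3 = mvp_var("c3"), c4 = mvp_var("c4"),
       e0 = mvp_var("eta0"), e1 = mvp_var("eta1"),
       P1 = mvp_var("Phi1"), P2 = mvp_var("Phi2"), P3 = mvp_var("Phi3"))
}

#' Build the chi-power algebraic system
#'
#' Substitutes the order-1 ansatz into the reduced equation, eliminates
#' `chi''` via the auxiliary quartic (`chi'' = (c1 + 2*c2*chi + 3*c3*chi^2 +
#' 4*c4*chi^3)/2`), multiplies by 2 and collects powers of chi. The four
#' coefficient polynomials (in `dc = zeta^2 - xi^2*Lambda1^2`, `c1..c4`,
#' `eta0`, `eta1`, `Phi1..Phi3`) are returned exactly; setting each to zero
#' is the algebraic system the expansion method solves.
#'
#' @param symbolic if `TRUE` (default) return the polynomial system; numeric
#'   instantiation is done with [mvp_eval()] or [power_system_eval()].
#' @return object of class `power_system`: list with elements `eq3`, `eq2`,
#'   `eq1`, `eq0` (class `mvp`).
#' @export
build_power_system <- function(symbolic = TRUE) {
  v <- .sys_vars()
  # 2*dc*Y'' with Y'' = eta1*chi'': contributes dc*eta1*(c1 + 2c2 x + 3c3 x^2 + 4c4 x^3)
  # minus 2*(Phi1*Y^3 + Phi2*Y^2 + Phi3*Y) expanded in x = chi.
  de <- mvp_mul(v$dc, v$e1)
  e0 <- v$e0; e1 <- v$e1
  # Y^2 = e0^2 + 2 e0 e1 x + e1^2 x^2 ; Y^3 = e0^3 + 3 e0^2 e1 x + 3 e0 e1^2 x^2 + e1^3 x^3
  y2 <- list(mvp_pow(e0, 2), mvp_scale(mvp_mul(e0, e1), 2), mvp_pow(e1, 2))
  y3 <- list(mvp_pow(e0, 3), mvp_scale(mvp_mul(mvp_pow(e0, 2), e1), 3),
             mvp_scale(mvp_mul(e0, mvp_pow(e1, 2)), 3), mvp_pow(e1, 3))
  nl <- vector("list", 4)  # coefficient of chi^k, k = 0..3, of 2*(P1 Y^3 + P2 Y^2 + P3 Y)
  for (k in 0:3) {
    term <- mvp_const(0)
    term <- mvp_add(term, mvp_mul(v$P1, y3[[k + 1]]))
    if (k <= 2) term <- mvp_add(term, mvp_mul(v$P2, y2[[k + 1]]))
    if (k <= 1) term <- mvp_add(term, mvp_mul(v$P3, if (k == 0) e0 else e1))
    nl[[k + 1]] <- mvp_scale(term, 2)
  }
  lin <- list(mvp_mul(de, v$c1), mvp_scale(mvp_mul(de, v$c2), 2),
              mvp_scale(mvp_mul(de, v$c3), 3), mvp_scale(mvp_mul(de, v$c4), 4))
  eqs <- lapply(0:3, function(k) mvp_sub(lin[[k + 1]], nl[[k + 1]]))
  structure(list(eq0 = eqs[[1]], eq1 = eqs[[2]], eq2 = eqs[[3]], eq3 = eqs[[4]]),
            class = "power_system")
}

#' The chi-power system exactly as printed
#'
#' Hand-transcribed coefficient polynomials of the published system, used as
#' the golden reference that [build_power_system()] must reproduce
#' term-for-term.
#'
#' @return a `power_system` object.
#' @export
power_system_printed <- function() {
  v <- .sys_vars()
  S <- function(...) {
    terms <- list(...)
    out <- mvp_const(0)
    for (t in terms) out <- mvp_add(out, t)
    out
  }
  P <- function(s, ...) {
    f <- mvp_const(s)
    for (p in list(...)) f <- mvp_mul(f, p)
    f
  }
  eq3 <- S(P(4, v$dc, v$c4, v$e1), P(-2, mvp_pow(v$e1, 3), v$P1))
  eq2 <- S(P(3, v$dc, v$c3, v$e1), P(-6, v$e0, mvp_pow(v$e1, 2), v$P1),
           P(-2, mvp_pow(v$e1, 2), v$P2))
  eq1 <- S(P(2, v$dc, v$c2, v$e1), P(-2, v$e1, v$P3),
           P(-6, mvp_pow(v$e0, 2), v$e1, v$P1), P(-4, v$e0, v$e1, v$P2))
  eq0 <- S(P(1, v$dc, v$c1, v$e1), P(-2, mvp_pow(v$e0, 3), v$P1),
           P(-2, mvp_pow(v$e0, 2), v$P2), P(-2, v$e0, v$P3))
  structure(list(eq0 = eq0, eq1 = eq1, eq2 = eq2, eq3 = eq3),
            class = "power_system")
}

#' @export
format.power_system <- function(x, ...) {
  paste0("(chi)^3: ", format(x$eq3), " = 0\n",
         "(chi)^2: ", format(x$eq2), " = 0\n",
         "(chi)^1: ", format(x$eq1), " = 0\n",
         "(chi)^0: ", format(x$eq0), " = 0")
}

#' @export
print.power_system <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Render the chi-power system to text
#'
#' Deterministic textual rendering (sorted monomials) for golden-file
#' comparison.
#'
#' @param sys a `power_system`.
#' @return character scalar.
#' @export
power_system_text <- function(sys = build_power_system()) format(sys)

#' Evaluate the chi-power system numerically
#'
#' @param sys a `power_system`.
#' @param frame a [wave_frame()].
#' @param phis a `reduced_coefficients` object (with `Phi3` resolved, or `NA`
#'   treated as 0 in `eq1`/`eq0`).
#' @param coeffs a `gee_coefficients` vector.
#' @param eta0,eta1 series coefficients.
#' @return named numeric/complex vector `c(eq3, eq2, eq1, eq0)`.
#' @export
power_system_eval <- function(sys, frame, phis, coeffs, eta0, eta1) {
  cs <- unclass(coeffs)
  Phi3 <- if (is.na(phis$Phi3)) 0 else phis$Phi3
  vals <- list(dc = frame$delta_c, c1 = cs[["c1"]], c2 = cs[["c2"]],
               c3 = cs[["c3"]], c4 = cs[["c4"]], eta0 = eta0, eta1 = eta1,
               Phi1 = phis$Phi1, Phi2 = phis$Phi2, Phi3 = Phi3)
  c(eq3 = mvp_eval(sys$eq3, vals), eq2 = mvp_eval(sys$eq2, vals),
    eq1 = mvp_eval(sys$eq1, vals), eq0 = mvp_eval(sys$eq0, vals))
}

#' Closed-form series coefficients
#'
#' Solves the cubic- and quadratic-power equations of the chi-power system:
#' `eta1 = branch * sqrt(2*delta_c*c4/Phi1)` and
#' `eta0 = (3*delta_c*c3 - 2*eta1*Phi2) / (6*eta1*Phi1)`. A negative radicand
#' yields a complex amplitude, which is returned flagged rather than
#' rejected (the catalogue contains explicitly complex solutions).
#'
#' @param frame a [wave_frame()].
#' @param phis a `reduced_coefficients` (only `Phi1`, `Phi2` enter).
#' @param coeffs a `gee_coefficients` vector with `c4 != 0`.
#' @return list of two `eta_pair` objects (branches -1 and +1 of the printed
#'   minus-plus), each with `eta0`, `eta1`, `branch`, `complex_amplitude`.
#' @examples
#' fr <- wave_frame(xi = 1, zeta = 4, Lambda1 = 1)
#' ph <- reduced_coefficients(Phi1 = 1, Phi2 = 1, Lambda1 = 1)
#' cf <- gee_from_riccati(1, 1, 0.01)
#' solve_eta(fr, ph, cf)[[1]]$eta1  # -sqrt(0.003)
#' @export
solve_eta <- function(frame, phis, coeffs) {
  stopifnot(inherits(frame, "wave_frame"),
            inherits(phis, "reduced_coefficients"))
  cs <- unclass(coeffs)
  if (cs[["c4"]] == 0)
    stop("c4 = 0: the order-1 ansatz amplitude vanishes (eta1 = 0)")
  if (phis$Phi1 == 0) stop("Phi1 = 0: eta1 undefined")
  rad <- 2 * frame$delta_c * cs[["c4"]] / phis$Phi1
  complex_amp <- rad < 0
  root <- if (complex_amp) sqrt(as.complex(rad)) else sqrt(rad)
  lapply(c(-1, 1), function(br) {
    eta1 <- br * root
    eta0 <- (3 * frame$delta_c * cs[["c3"]] - 2 * eta1 * phis$Phi2) /
      (6 * eta1 * phis$Phi1)
    structure(list(eta0 = eta0, eta1 = eta1, branch = br,
                   complex_amplitude = complex_amp),
              class = "eta_pair")
  })
}

#' @export
print.eta_pair <- function(x, ...) {
  cat(sprintf("eta_pair (branch %+d%s): eta0 = %s, eta1 = %s\n", x$branch,
              if (x$complex_amplitude) ", complex amplitude" else "",
              format(x$eta0), format(x$eta1)))
  invisible(x)
}

#' Constraints left implicit by the closed-form solution
#'
#' The closed form annihilates the cubic and quadratic equations only. The
#' linear equation determines the linear coefficient of the reduced equation
#' uniquely: `implied_Phi3 = delta_c*c2 - 3*eta0^2*Phi1 - 2*eta0*Phi2`. The
#' constant equation is then an honest residual: it is evaluated with that
#' value and reported, never assumed zero.
#'
#' @param eta an `eta_pair` from [solve_eta()].
#' @param frame a [wave_frame()].
#' @param phis a `reduced_coefficients`.
#' @param coeffs a `gee_coefficients`.
#' @return list with `implied_Phi3` and `constant_term_residual`.
#' @export
implied_constraints <- function(eta, frame, phis, coeffs) {
  cs <- unclass(coeffs)
  implied_Phi3 <- frame$delta_c * cs[["c2"]] - 3 * eta$eta0^2 * phis$Phi1 -
    2 * eta$eta0 * phis$Phi2
  res0 <- frame$delta_c * cs[["c1"]] * eta$eta1 -
    2 * eta$eta0^3 * phis$Phi1 - 2 * eta$eta0^2 * phis$Phi2 -
    2 * eta$eta0 * implied_Phi3
  list(implied_Phi3 = implied_Phi3, constant_term_residual = res0)
}

#' Exact annihilation check of the closed-form coefficients
#'
#' Verifies, in the polynomial ring (no numerics), that the closed-form pair
#' annihilates the cubic and quadratic equations for fully symbolic inputs:
#' `eta0` is eliminated via its defining ratio (clearing the `6*eta1*Phi1`
#' denominator) and `eta1^2` is reduced modulo the defining relation
#' `Phi1*eta1^2 = 2*dc*c4`. Returns `TRUE` iff both reductions are the zero
#' polynomial.
#'
#' @param sys a `power_system` (defaults to the freshly built one).
#' @return logical scalar.
#' @export
eta_annihilation_check <- function(sys = build_power_system()) {
  v <- .sys_vars()
  num0 <- mvp_sub(mvp_scale(mvp_mul(v$dc, v$c3), 3),
                  mvp_scale(mvp_mul(v$e1, v$P2), 2))          # 3*dc*c3 - 2*eta1*Phi2
  den0 <- mvp_scale(mvp_mul(v$e1, v$P1), 6)                   # 6*eta1*Phi1
  rel_num <- mvp_scale(mvp_mul(v$dc, v$c4), 2)                # eta1^2 = 2*dc*c4 / Phi1
  rel_den <- v$P1
  check_one <- function(eq) {
    p <- mvp_subst_ratio(eq, "eta0", num0, den0)
    p <- mvp_reduce_square(p, "eta1", rel_num, rel_den)
    mvp_is_zero(p)
  }
  check_one(sys$eq3) && check_one(sys$eq2)
}
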