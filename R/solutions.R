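# Assembly and evaluation of the traveling-wave solution families
# Theta_{case,type,k}(s, t) = eta0 + eta1 * chi(xi*s + zeta*t).
#
# Families 1..62 compose a catalogued auxiliary function with the closed-form
# series coefficients; families 63..94 are the printed modulus-limit
# degenerations of the Jacobi families (63..78: q -> 1 hyperbolic, 79..94:
# q -> 0 trigonometric), implemented as printed with flags where the printed
# form is internally inconsistent.

#' Registry of traveling-wave solution families
#'
#' One row per printed family index 1..94 with its case/type/chi wiring,
#' degeneration status and audit flags.
#'
#' @return a data frame.
#' @export
solution_registry <- function() {
  rows <- list()
  add <- function(family, case_id, type_id, chi_index, degenerate = FALSE,
                  limit = "", form = "", flagged = FALSE, note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      family_index = family, case_id = case_id, type_id = type_id,
      chi_index = chi_index, degenerate = degenerate, limit = limit,
      form = form, flagged = flagged, note = note, stringsAsFactors = FALSE)
  }
  for (k in 1:12) add(k, 1, 1, k,
                      flagged = k == 1,
                      note = if (k == 1) "printed form duplicates family 3; wired to the kink (tanh) auxiliary form per the figure" else "")
  for (k in 13:24) add(k, 1, 2, k)
  for (k in 25:36) add(k, 2, 1, k - 24)
  c3map <- list(c(1, 1), c(2, 2), c(3, 3), c(4, 4), c(5, 5), c(5, 6),
                c(6, 7), c(6, 8), c(7, 9), c(7, 10))
  for (j in seq_along(c3map)) {
    fam <- 36 + j
    add(fam, 3, c3map[[j]][1], c3map[[j]][2],
        flagged = fam == 45,
        note = if (fam == 45) "printed chi factor duplicated (squared in print); single factor implemented" else "")
  }
  c4types <- c(1, 1, 2, 3, 4, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14)
  for (j in 1:16) add(46 + j, 4, c4types[j], j)
  # q -> 1 hyperbolic degenerations (printed Eqs. of families 63..78)
  q1 <- list(
    list("sech", FALSE, ""),
    list("1", TRUE, "printed sech; structural q->1 limit of cd is 1 (an exact auxiliary solution of its triple)"),
    list("sech", FALSE, ""),
    list("sech", FALSE, ""), list("coth", FALSE, ""),
    list("1", FALSE, "printed sech/sech == 1"),
    list("cosh", FALSE, ""), list("cosh", FALSE, ""),
    list("sinh", FALSE, "printed tanh/sech == sinh"),
    list("sinh", TRUE, "printed sinh/sech (= sinh*cosh); structural limit of sd is sinh"),
    list("csch", FALSE, "printed sech/tanh == csch"),
    list("csch", FALSE, "printed sech/tanh == csch"),
    list("coth + csch", FALSE, ""), list("cosh + sinh", FALSE, ""),
    list("coth + csch", FALSE, ""),
    list("tanh + i*sech", TRUE, "printed tanh +- i*csch; limit of the coefficient-consistent row function sn +- i*cn is tanh +- i*sech")
  )
  for (j in 1:16)
    add(62 + j, 4, c4types[j], j, degenerate = TRUE, limit = "q1",
        form = q1[[j]][[1]], flagged = q1[[j]][[2]], note = q1[[j]][[3]])
  # q -> 0 trigonometric degenerations (families 79..94)
  q0 <- list(
    list("cos", FALSE, ""),
    list("cos", TRUE, "printed with the chi factor omitted; cd -> cos"),
    list("cos", FALSE, ""),
    list("1", FALSE, "dn -> 1"),
    list("csc", FALSE, ""),
    list("sec", FALSE, "printed dn/cos with dn == 1 at q = 0"),
    list("sec", FALSE, ""),
    list("1", FALSE, "nd -> 1"),
    list("tan", FALSE, "printed sin/cos"),
    list("sin", FALSE, ""),
    list("cot", FALSE, "printed cos/sin"),
    list("csc", FALSE, ""),
    list("csc + cot", FALSE, ""), list("sec + tan", FALSE, ""),
    list("csc + csc", TRUE, "printed csc +- csc: the minus branch is identically zero (ds -> csc duplicates ns)"),
    list("sin + i*cos", TRUE, "printed sin +- i*cot; limit of the coefficient-consistent row function sn +- i*cn is sin +- i*cos")
  )
  for (j in 1:16)
    add(78 + j, 4, c4types[j], j, degenerate = TRUE, limit = "q0",
        form = q0[[j]][[1]], flagged = q0[[j]][[2]], note = q0[[j]][[3]])
  do.call(rbind, rows)
}

# Evaluate a degenerate-form label like "coth + csch" or "sin + i*cos".
.degenerate_eval <- function(form, x, branch = 1) {
  parts <- strsplit(form, " + ", fixed = TRUE)[[1]]
  f1 <- .elementary_fn(parts[1])
  v <- f1(x)
  d <- .elementary_den(parts[1], x)
  if (length(parts) == 2L) {
    nm <- parts[2]
    fac <- 1
    if (startsWith(nm, "i*")) { fac <- 1i; nm <- substring(nm, 3) }
    f2 <- .elementary_fn(nm)
    v <- v + branch * fac * f2(x)
    d <- pmin(d, .elementary_den(nm, x))
  }
  list(v = v, d = d)
}

.elementary_den <- function(name, x) {
  switch(name,
    coth = , csch = abs(sinh(x)),
    tan = , sec = abs(cos(x)),
    cot = , csc = abs(sin(x)),
    rep(Inf, length(x))
  )
}

#' Specification of one traveling-wave solution
#'
#' @param family_index printed family index (1..94).
#' @param aux an [aux_params()] object (ignored for the fixed degenerate
#'   forms except for branch signs).
#' @param frame a [wave_frame()].
#' @param phis a `reduced_coefficients` object. `Phi3`, if `NA`, is resolved
#'   to the value implied by the linear chi-power equation.
#' @param branch +1 or -1: branch of the series amplitude (the printed
#'   minus-plus; -1 selects the top sign).
#' @return object of class `solution_spec`.
#' @export
solution_spec <- function(family_index, aux, frame, phis, branch = -1) {
  reg <- solution_registry()
  if (!family_index %in% reg$family_index)
    stop("unknown family index ", family_index)
  if (!branch %in% c(-1, 1)) stop("branch must be +1 or -1")
  structure(list(family_index = family_index,
                 row = reg[reg$family_index == family_index, , drop = FALSE],
                 aux = aux, frame = frame, phis = phis, branch = branch),
            class = "solution_spec")
}

#' Validate the parameter regime of a solution specification
#'
#' @param spec a [solution_spec()].
#' @return character vector of violated printed constraints (empty if valid).
#' @export
validate_regime <- function(spec) {
  stopifnot(inherits(spec, "solution_spec"))
  row <- spec$row
  v <- character(0)
  if (spec$frame$delta_c == 0) v <- c(v, "zeta^2 - xi^2*Lambda1^2 != 0")
  if (spec$phis$Phi1 == 0) v <- c(v, "Phi1 != 0")
  if (!row$degenerate) {
    sel <- chi_selector(row$case_id, row$type_id, row$chi_index)
    v <- c(v, validate_chi_regime(sel, spec$aux))
  }
  v
}

# Auxiliary coefficients and chi evaluator for a solution spec; for Case 2
# the Riccati mu-sign is fixed by matching the auxiliary ODE residual.
.solution_chi <- function(spec) {
  row <- spec$row
  if (row$degenerate) {
    sel <- chi_selector(row$case_id, row$type_id, row$chi_index)
    qlim <- if (row$limit == "q1") 1 else 0
    cs <- .case4_c(row$chi_index, qlim)
    br <- .branch(spec$aux, 1, 1)
    form <- row$form
    fn <- function(rho) .degenerate_eval(form, rho, branch = br)
    return(list(coeffs = cs, fn = fn, mu_sign = NA_integer_))
  }
  sel <- chi_selector(row$case_id, row$type_id, row$chi_index)
  mu_sign <- NA_integer_
  if (row$case_id == 2L) {
    res <- tryCatch(
      aux_ode_residual(sel, spec$aux),
      error = function(e) NULL)
    if (is.null(res)) {   # outside the printed regime (non-strict use)
      cs <- gee_candidates(sel, spec$aux)[[1]]$coeffs
    } else {
      mu_sign <- res$mu_sign
      cs <- res$coeffs
    }
  } else {
    cs <- gee_for_selector(sel, spec$aux)
  }
  fn <- function(rho) .chi_core(sel$case_id, sel$type_id, sel$index, spec$aux, rho)
  list(coeffs = cs, fn = fn, mu_sign = mu_sign)
}

#' Assemble a traveling-wave solution
#'
#' Resolves the selected family into a callable `Theta(s, t)`: the auxiliary
#' coefficients of the family fix the series pair via [solve_eta()], the
#' linear coefficient implied by the chi-power system is attached, and the
#' constant-term residual (the consistency metric the closed form leaves
#' open) is carried as metadata.
#'
#' @param spec a [solution_spec()].
#' @param strict error on violated regime constraints (default). With
#'   `strict = FALSE` the violations are recorded on the result and the
#'   formula is evaluated by analytic continuation — used for the published
#'   figure captions, two of which sit outside their family's printed regime.
#' @return object of class `dna_solution`: callable pieces `theta(s, t)` and
#'   `profile(rho)` plus metadata (`eta`, `implied_Phi3`, `chi0_residual`,
#'   `coeffs`, `amplitude_degenerate`, `regime_violations`).
#' @export
make_solution <- function(spec, strict = TRUE) {
  stopifnot(inherits(spec, "solution_spec"))
  viol <- validate_regime(spec)
  if (strict && length(viol))
    stop("regime constraint(s) violated: ", paste(viol, collapse = "; "))
  ch <- .solution_chi(spec)
  cs <- unclass(ch$coeffs)
  frame <- spec$frame; phis <- spec$phis
  amplitude_degenerate <- cs[["c4"]] == 0
  if (amplitude_degenerate) {
    # eta1 -> 0; eta0 has the finite limit -Phi2/(3*Phi1) when c3 = 0
    if (cs[["c3"]] != 0)
      stop("c4 = 0 with c3 != 0: series coefficients diverge in this limit")
    eta <- structure(list(eta0 = -phis$Phi2 / (3 * phis$Phi1), eta1 = 0,
                          branch = spec$branch, complex_amplitude = FALSE),
                     class = "eta_pair")
  } else {
    pair <- solve_eta(frame, phis, ch$coeffs)
    eta <- if (spec$branch == -1) pair[[1]] else pair[[2]]
  }
  ic <- implied_constraints(eta, frame, phis, ch$coeffs)
  Phi3 <- if (is.na(phis$Phi3)) ic$implied_Phi3 else phis$Phi3

  chi_fn <- ch$fn
  profile <- function(rho) {
    r <- chi_fn(rho)
    v <- eta$eta0 + eta$eta1 * as.complex(r$v)
    sing <- !is.finite(Re(v)) | !is.finite(Im(v)) | r$d < .SING_DEN_TOL
    v[sing] <- NA_complex_
    attr(v, "singular") <- sing
    v
  }
  theta <- function(s, t) profile(frame$xi * s + frame$zeta * t)

  structure(list(theta = theta, profile = profile, chi = chi_fn,
                 spec = spec, eta = eta, coeffs = ch$coeffs,
                 mu_sign = ch$mu_sign, implied_Phi3 = ic$implied_Phi3,
                 Phi3 = Phi3, chi0_residual = ic$constant_term_residual,
                 amplitude_degenerate = amplitude_degenerate,
                 regime_violations = viol),
            class = "dna_solution")
}

#' @export
print.dna_solution <- function(x, ...) {
  row <- x$spec$row
  cat(sprintf("Traveling-wave family %d (case %d, type %d, chi %d%s)\n",
              row$family_index, row$case_id, row$type_id, row$chi_index,
              if (row$degenerate) paste0(", ", row$limit, " limit ", row$form) else ""))
  cat(sprintf("  eta0 = %s, eta1 = %s (branch %+d)\n",
              format(x$eta$eta0), format(x$eta$eta1), x$eta$branch))
  cat(sprintf("  implied Phi3 = %s, constant-term residual = %s\n",
              format(x$implied_Phi3), format(x$chi0_residual)))
  invisible(x)
}

#' Evaluate a solution on a space-time grid
#'
#' @param sol a [make_solution()] result (or a [solution_spec()], resolved
#'   on the fly).
#' @param s_range,t_range numeric length-2 ranges.
#' @param ns,nt grid sizes (>= 2).
#' @return object of class `solution_field`: `s_axis`, `t_axis`, complex
#'   matrix `values` (`ns` x `nt`), logical `singular` mask, and the
#'   generating specification.
#' @export
eval_grid <- function(sol, s_range = c(-10, 10), t_range = c(0, 10),
                      ns = 201, nt = 101) {
  if (inherits(sol, "solution_spec")) sol <- make_solution(sol)
  stopifnot(inherits(sol, "dna_solution"), ns >= 2, nt >= 2)
  s_axis <- seq(s_range[1], s_range[2], length.out = ns)
  t_axis <- seq(t_range[1], t_range[2], length.out = nt)
  rho <- outer(s_axis * sol$spec$frame$xi, t_axis * sol$spec$frame$zeta, `+`)
  v <- sol$profile(as.numeric(rho))
  sing <- attr(v, "singular")
  values <- matrix(as.complex(v), ns, nt)
  singular <- matrix(sing, ns, nt)
  if (all(singular)) stop("the requested grid is entirely singular")
  structure(list(s_axis = s_axis, t_axis = t_axis, values = values,
                 singular = singular, solution = sol),
            class = "solution_field")
}

#' Extract a displayable component of a solution field
#'
#' @param field a `solution_field`.
#' @param component `"re"`, `"im"` or `"abs"`.
#' @return numeric matrix with `NA` at masked cells.
#' @export
field_component <- function(field, component = c("re", "im", "abs")) {
  component <- match.arg(component)
  m <- switch(component, re = Re(field$values), im = Im(field$values),
              abs = Mod(field$values))
  m[field$singular] <- NA_real_
  m
}

#' @export
print.solution_field <- function(x, ...) {
  cat(sprintf("solution_field: %d x %d grid, s in [%g, %g], t in [%g, %g], %.1f%% masked\n",
              length(x$s_axis), length(x$t_axis),
              min(x$s_axis), max(x$s_axis), min(x$t_axis), max(x$t_axis),
              100 * mean(x$singular)))
  invisible(x)
}

#' Export a solution field as delimited text with a JSON sidecar
#'
#' Writes a TSV (`s, t, re, im, abs, singular`) and `<path>.json` describing
#' the generating specification for reproducibility.
#'
#' @param field a `solution_field`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_grid <- function(field, path) {
  ns <- length(field$s_axis); nt <- length(field$t_axis)
  df <- data.frame(
    s = rep(field$s_axis, times = nt),
    t = rep(field$t_axis, each = ns),
    re = as.numeric(Re(field$values)),
    im = as.numeric(Im(field$values)),
    abs = as.numeric(Mod(field$values)),
    singular = as.logical(field$singular)
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  sol <- field$solution
  spec <- sol$spec
  sidecar <- list(
    family_index = spec$family_index,
    case_id = spec$row$case_id, type_id = spec$row$type_id,
    chi_index = spec$row$chi_index, degenerate = spec$row$degenerate,
    branch = spec$branch,
    frame = spec$frame[c("xi", "zeta", "Lambda1", "delta_c")],
    phis = spec$phis[c("Phi1", "Phi2", "Phi3")],
    aux = spec$aux[c("sigma", "mu", "rho", "E", "F", "alpha", "q",
                     "c0", "c1", "c3", "branch_signs")],
    eta = list(eta0 = format(sol$eta$eta0), eta1 = format(sol$eta$eta1),
               branch = sol$eta$branch),
    implied_Phi3 = if (is.complex(sol$implied_Phi3)) format(sol$implied_Phi3)
                   else sol$implied_Phi3,
    chi0_residual = format(sol$chi0_residual),
    grid = list(s_range = range(field$s_axis), t_range = range(field$t_axis),
                ns = ns, nt = nt)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
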