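# Catalogue of auxiliary functions chi(rho) solving the general elliptic
# equation chi'^2 = c0 + c1*chi + c2*chi^2 + c3*chi^3 + c4*chi^4.
#
# Case 1: generalized Riccati forms (hyperbolic for mu^2 - 4*rho*sigma > 0,
#         trigonometric for < 0), indices 1..24.
# Case 2: the c2 = 0 specialization (mu^2 = -2*sigma*rho, sigma*rho < 0),
#         indices 1..12.
# Case 3: rational hyperbolic/trigonometric forms for c0 = c1 = 0, in terms
#         of four free constants alpha1..alpha4, indices 1..10 over 7 types.
# Case 4: Jacobi elliptic rows (c1 = c3 = 0), indices 1..16.
# Case 5: Weierstrass form for c2 = c4 = 0.
#
# Printed typos found by auditing every form against the quartic are
# corrected here and flagged in the registry (`corrected`); the audit report
# surfaces them. See the methods vignette for the full list.

.SING_DEN_TOL <- 1e-10

# complex-safe square root: analytic continuation outside the printed regime
.csqrt <- function(x) if (is.complex(x) || all(x >= 0)) sqrt(x) else sqrt(as.complex(x))

sech <- function(z) 1 / cosh(z)
csch <- function(z) 1 / sinh(z)

#' Selector for one auxiliary-function family
#'
#' @param case_id catalogue case (1..5).
#' @param type_id parameter-regime type within the case.
#' @param index the printed chi subscript.
#' @return object of class `chi_selector`.
#' @export
chi_selector <- function(case_id, type_id, index) {
  reg <- chi_registry()
  hit <- reg$case_id == case_id & reg$type_id == type_id & reg$index == index
  if (!any(hit))
    stop(sprintf("no catalogue entry for case %d, type %d, index %d",
                 case_id, type_id, index))
  structure(list(case_id = case_id, type_id = type_id, index = index,
                 row = reg[hit, , drop = FALSE]),
            class = "chi_selector")
}

#' Auxiliary-equation parameters
#'
#' @param sigma,mu,rho generalized Riccati parameters (Cases 1-2).
#' @param E,F nonzero constants of the mixed hyperbolic/trigonometric forms.
#' @param alpha numeric vector `alpha1..alpha4` (Case 3).
#' @param q elliptic modulus in `[0, 1]` (Case 4).
#' @param c0,c1,c3 cubic auxiliary-equation constants (Case 5; `c3 > 0`).
#' @param branch_signs vector of +1/-1, one entry per plus-minus slot of the
#'   selected formula (recycled from +1).
#' @return object of class `aux_params`.
#' @export
aux_params <- function(sigma = NA_real_, mu = NA_real_, rho = NA_real_,
                       E = NA_real_, F = NA_real_,
                       alpha = rep(NA_real_, 4), q = NA_real_,
                       c0 = NA_real_, c1 = NA_real_, c3 = NA_real_,
                       branch_signs = integer(0)) {
  if (!is.na(q) && (q < 0 || q > 1)) stop("modulus q must lie in [0, 1]")
  if (length(alpha) != 4L) stop("alpha must have length 4")
  if (length(branch_signs) && !all(branch_signs %in% c(-1, 1)))
    stop("branch_signs entries must be +1 or -1")
  structure(list(sigma = sigma, mu = mu, rho = rho, E = E, F = F,
                 alpha = alpha, q = q, c0 = c0, c1 = c1, c3 = c3,
                 branch_signs = as.integer(branch_signs)),
            class = "aux_params")
}

.branch <- function(params, slot, n_slots) {
  bs <- params$branch_signs
  if (length(bs) == 0L) bs <- rep(1L, n_slots)
  if (length(bs) < n_slots) bs <- rep(bs, length.out = n_slots)
  bs[slot]
}

#' Registry of all catalogued auxiliary functions
#'
#' One row per chi entry: case, type, printed index, a short formula label,
#' the number of independent plus-minus branch slots, the parameter-regime
#' constraints, and whether the implemented form corrects a printed typo.
#'
#' @return a data frame.
#' @export
chi_registry <- function() {
  r <- function(case_id, type_id, index, fun, n_branch, constraint,
                corrected = FALSE, note = "") {
    data.frame(case_id = case_id, type_id = type_id, index = index,
               fun = fun, n_branch = n_branch, constraint = constraint,
               corrected = corrected, note = note,
               stringsAsFactors = FALSE)
  }
  c1t1 <- "mu^2-4*rho*sigma>0, mu*rho!=0, rho*sigma!=0"
  c1t2 <- "mu^2-4*rho*sigma<0, mu*rho!=0, rho*sigma!=0"
  c2t1 <- "rho*sigma<0"
  rows <- list(
    r(1, 1, 1,  "tanh", 0, c1t1),
    r(1, 1, 2,  "coth", 0, c1t1),
    r(1, 1, 3,  "tanh + i*sech", 1, c1t1),
    r(1, 1, 4,  "coth + csch", 1, c1t1),
    r(1, 1, 5,  "tanh + coth (half-argument)", 0, c1t1),
    r(1, 1, 6,  "mixed cosh/sinh with E,F", 0, paste(c1t1, "E!=0, F!=0", sep = ", ")),
    r(1, 1, 7,  "mixed sinh/cosh with E,F", 0, paste(c1t1, "E!=0, F!=0, F^2-E^2>0", sep = ", ")),
    r(1, 1, 8,  "cosh/(sinh,cosh)", 0, c1t1),
    r(1, 1, 9,  "sinh/(sinh,cosh)", 0, c1t1),
    r(1, 1, 10, "cosh/(sinh,cosh,i)", 1, c1t1),
    r(1, 1, 11, "sinh/(cosh,const)", 1, c1t1),
    r(1, 1, 12, "cosh*sinh rational (quarter-argument)", 0, c1t1),
    r(1, 2, 13, "tan", 0, c1t2),
    r(1, 2, 14, "cot", 0, c1t2),
    r(1, 2, 15, "tan + sec", 1, c1t2),
    r(1, 2, 16, "cot + csc", 1, c1t2),
    r(1, 2, 17, "tan - cot (quarter-argument)", 0, c1t2),
    r(1, 2, 18, "mixed cos/sin with E,F", 1, paste(c1t2, "E!=0, F!=0, E^2-F^2>0", sep = ", ")),
    r(1, 2, 19, "mixed sin/cos with E,F", 1, paste(c1t2, "E!=0, F!=0, E^2-F^2>0", sep = ", ")),
    r(1, 2, 20, "cos/(sin,cos)", 0, c1t2, corrected = TRUE,
      note = "denominator sign: sqrt()*sin - mu*cos (printed +mu*cos fails the quartic)"),
    r(1, 2, 21, "sin/(sin,cos)", 0, c1t2),
    r(1, 2, 22, "cos/(sin,cos,const)", 1, c1t2, corrected = TRUE,
      note = "unbalanced parenthesis in print; neighbour-pattern form verified"),
    r(1, 2, 23, "sin/(cos,const)", 1, c1t2),
    r(1, 2, 24, "cos*sin rational (quarter-argument)", 0, c1t2, corrected = TRUE,
      note = "inner radical normalized to sqrt(4*rho*sigma-mu^2)"),
    r(2, 1, 1,  "tanh", 1, c2t1),
    r(2, 1, 2,  "coth", 1, c2t1),
    r(2, 1, 3,  "tanh + i*sech", 2, c2t1),
    r(2, 1, 4,  "coth + csch", 2, c2t1, corrected = TRUE,
      note = "spurious iota on csch dropped (hyperbolic analogue has none)"),
    r(2, 1, 5,  "tanh + coth (half-argument)", 1, c2t1, corrected = TRUE,
      note = "leading term needs factor 2 (pattern of the Case-1 analogue)"),
    r(2, 1, 6,  "mixed cosh/sinh with E,F", 1, paste(c2t1, "E!=0, F!=0", sep = ", ")),
    r(2, 1, 7,  "mixed sinh/cosh with E,F", 1, paste(c2t1, "E!=0, F!=0, F^2-E^2>0", sep = ", ")),
    r(2, 1, 8,  "cosh/(sinh,cosh)", 1, c2t1),
    r(2, 1, 9,  "sinh/(sinh,cosh)", 1, c2t1),
    r(2, 1, 10, "cosh/(sinh,cosh,i)", 2, c2t1, corrected = TRUE,
      note = "unbalanced parenthesis in print; neighbour-pattern form verified"),
    r(2, 1, 11, "sinh/(sinh,cosh,const)", 2, c2t1, corrected = TRUE,
      note = "spurious iota dropped (Case-1 analogue is real)"),
    r(2, 1, 12, "cosh*sinh rational (quarter-argument)", 1, c2t1),
    r(3, 1, 1,  "1/(a2*cosh+a3)", 0, "alpha1!=0"),
    r(3, 2, 2,  "1/(a2*sinh+a3)", 0, "alpha1!=0"),
    r(3, 3, 3,  "sech^2 rational", 0, "alpha1!=0"),
    r(3, 4, 4,  "csch^2 rational", 0, "alpha1!=0", corrected = TRUE,
      note = "denominator a2*csch^2+a3*coth+a4 and c3 = +4*(a4-2*a2)/a1 (printed tanh-form fails the quartic)"),
    r(3, 5, 5,  "exp decay rational", 0, "alpha1!=0, alpha2!=0"),
    r(3, 5, 6,  "exp growth rational", 0, "alpha1!=0, alpha2!=0"),
    r(3, 6, 7,  "1/(a2*cos+a3)", 0, "alpha1!=0"),
    r(3, 6, 8,  "1/(a2*sin+a3)", 0, "alpha1!=0"),
    r(3, 7, 9,  "sec^2 rational", 0, "alpha1!=0"),
    r(3, 7, 10, "csc^2 rational", 0, "alpha1!=0"),
    r(4, 1, 1,  "cn", 0, "0<=q<=1", corrected = TRUE,
      note = "row-1 printed triple (1,-(1-q^2),q^2) fits neither printed function; cn uses (1-q^2,2q^2-1,-q^2)"),
    r(4, 1, 2,  "cd", 0, "0<=q<=1", corrected = TRUE,
      note = "printed 'cn/cd' implemented as cd = cn/dn; coefficients (1,-(1+q^2),q^2)"),
    r(4, 2, 3,  "cn", 0, "0<=q<=1"),
    r(4, 3, 4,  "dn", 0, "0<=q<=1"),
    r(4, 4, 5,  "ns", 0, "0<=q<=1"),
    r(4, 4, 6,  "dc", 0, "0<=q<=1"),
    r(4, 5, 7,  "nc", 0, "0<=q<=1"),
    r(4, 6, 8,  "nd", 0, "0<=q<=1"),
    r(4, 7, 9,  "sc", 0, "0<=q<=1"),
    r(4, 8, 10, "sd", 0, "0<=q<=1"),
    r(4, 9, 11, "cs", 0, "0<=q<=1"),
    r(4, 10, 12, "ds", 0, "0<=q<=1"),
    r(4, 11, 13, "ns + cs", 1, "0<=q<=1", corrected = TRUE,
      note = "malformed printed c4 read as 1/4 (symmetry with c0)"),
    r(4, 12, 14, "nc + sc", 1, "0<=q<=1"),
    r(4, 13, 15, "ns + ds", 1, "0<=q<=1", corrected = TRUE,
      note = "c0 = q^4/4 (printed q^2/4 fails the quartic)"),
    r(4, 14, 16, "sn + i*cn", 1, "0<=q<=1", corrected = TRUE,
      note = "printed 'rn +- i cr' (= sn +- i*cs) fails the row triple; sn +- i*cn satisfies it and matches the printed q-limits"),
    r(5, 1, 1,  "weierstrass", 0, "c3>0")
  )
  do.call(rbind, rows)
}

#' Serialize the catalogue registry as a JSON manifest
#'
#' @param path output path.
#' @return `path` invisibly.
#' @export
chi_manifest_json <- function(path) {
  jsonlite::write_json(chi_registry(), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' General-elliptic-equation coefficients from Riccati parameters
#'
#' Expands `(sigma + mu*chi + rho*chi^2)^2` and reads off the quartic's
#' coefficients: `c0 = sigma^2, c1 = 2*sigma*mu, c2 = mu^2 + 2*rho*sigma,
#' c3 = 2*mu*rho, c4 = rho^2`. The printed constant term `sigma^3` does not
#' match the expansion and is available behind `paper_literal = TRUE` for
#' audit only.
#'
#' @param sigma,mu,rho Riccati parameters.
#' @param paper_literal use the printed `c0 = sigma^3` instead of the
#'   expansion's `sigma^2` (audit mode).
#' @return named numeric vector `c(c0, c1, c2, c3, c4)` of class
#'   `gee_coefficients`.
#' @examples
#' gee_from_riccati(1, 1, 0.01)  # c(1, 2, 1.02, 0.02, 1e-4)
#' @export
gee_from_riccati <- function(sigma, mu, rho, paper_literal = FALSE) {
  c0 <- if (paper_literal) sigma^3 else sigma^2
  structure(c(c0 = c0, c1 = 2 * sigma * mu, c2 = mu^2 + 2 * rho * sigma,
              c3 = 2 * mu * rho, c4 = rho^2),
            class = "gee_coefficients")
}

# Coefficient triples of the Jacobi rows, per chi index (corrected where the
# printed row fails the quartic; see registry notes).
.case4_c <- function(index, q) {
  q2 <- q^2
  trip <- switch(as.character(index),
    `1` = c(1 - q2, 2 * q2 - 1, -q2),
    `2` = c(1, -(1 + q2), q2),
    `3` = c(1 - q2, 2 * q2 - 1, -q2),
    `4` = c(q2 - 1, 2 - q2, -1),
    `5` = c(q2, -(1 + q2), 1),
    `6` = c(q2, -(1 + q2), 1),
    `7` = c(-q2, 2 * q2 - 1, 1 - q2),
    `8` = c(-1, 2 - q2, q2 - 1),
    `9` = c(1, 2 - q2, 1 - q2),
    `10` = c(1, 2 * q2 - 1, -q2 * (1 - q2)),
    `11` = c(1 - q2, 2 - q2, 1),
    `12` = c(-q2 * (1 - q2), 2 * q2 - 1, 1),
    `13` = c(1 / 4, (1 - 2 * q2) / 2, 1 / 4),
    `14` = c((1 - q2) / 4, (1 + q2) / 2, (1 - q2) / 4),
    `15` = c(q2^2 / 4, (q2 - 2) / 2, 1 / 4),
    `16` = c(q2 / 4, (q2 - 2) / 2, q2 / 4),
    stop("unknown Case-4 index ", index)
  )
  structure(c(c0 = trip[1], c1 = 0, c2 = trip[2], c3 = 0, c4 = trip[3]),
            class = "gee_coefficients")
}

.case4_fun <- function(index) {
  switch(as.character(index),
    `1` = list(base = "cn"), `2` = list(base = "cd"), `3` = list(base = "cn"),
    `4` = list(base = "dn"), `5` = list(base = "ns"), `6` = list(base = "dc"),
    `7` = list(base = "nc"), `8` = list(base = "nd"), `9` = list(base = "sc"),
    `10` = list(base = "sd"), `11` = list(base = "cs"), `12` = list(base = "ds"),
    `13` = list(base = "ns", second = "cs", fac = 1),
    `14` = list(base = "nc", second = "sc", fac = 1),
    `15` = list(base = "ns", second = "ds", fac = 1),
    `16` = list(base = "sn", second = "cn", fac = 1i),
    stop("unknown Case-4 index ", index)
  )
}

.case3_c <- function(type_id, alpha) {
  a1 <- alpha[1]; a2 <- alpha[2]; a3 <- alpha[3]; a4 <- alpha[4]
  trip <- switch(as.character(type_id),
    `1` = c(1, -2 * a3 / a1, (a3^2 - a2^2) / a1^2),
    `2` = c(1, -2 * a3 / a1, (a3^2 + a2^2) / a1^2),
    `3` = c(4, -4 * (2 * a2 + a4) / a1, (a3^2 + 4 * a2^2 + 4 * a2 * a4) / a1^2),
    `4` = c(4, 4 * (a4 - 2 * a2) / a1, (a3^2 + 4 * a2^2 - 4 * a2 * a4) / a1^2),
    `5` = c(a1^2, 2 * a1 * a2, a2^2),
    `6` = c(-1, 2 * a3 / a1, -(a3^2 - a2^2) / a1^2),
    `7` = c(-4, 4 * (2 * a2 + a4) / a1, (a3^2 - 4 * a2^2 - 4 * a2 * a4) / a1^2),
    stop("unknown Case-3 type ", type_id)
  )
  structure(c(c0 = 0, c1 = 0, c2 = trip[1], c3 = trip[2], c4 = trip[3]),
            class = "gee_coefficients")
}

#' Regime constraints for a catalogue entry
#'
#' @param sel a [chi_selector()].
#' @param params an [aux_params()] object.
#' @return character vector of violated constraints (empty if valid).
#' @export
validate_chi_regime <- function(sel, params) {
  v <- character(0)
  p <- params
  if (sel$case_id == 1L) {
    disc <- p$mu^2 - 4 * p$rho * p$sigma
    if (sel$type_id == 1L && !(disc > 0)) v <- c(v, "mu^2 - 4*rho*sigma > 0")
    if (sel$type_id == 2L && !(disc < 0)) v <- c(v, "mu^2 - 4*rho*sigma < 0")
    if (p$mu * p$rho == 0) v <- c(v, "mu*rho != 0")
    if (p$rho * p$sigma == 0) v <- c(v, "rho*sigma != 0")
    if (sel$index %in% c(6, 7, 18, 19)) {
      if (is.na(p$E) || p$E == 0) v <- c(v, "E != 0")
      if (is.na(p$F) || p$F == 0) v <- c(v, "F != 0")
      if (sel$index == 7 && !isTRUE(p$F^2 - p$E^2 > 0)) v <- c(v, "F^2 - E^2 > 0")
      if (sel$index %in% c(18, 19) && !isTRUE(p$E^2 - p$F^2 > 0))
        v <- c(v, "E^2 - F^2 > 0")
    }
  } else if (sel$case_id == 2L) {
    if (!(p$rho * p$sigma < 0)) v <- c(v, "rho*sigma < 0")
    if (sel$index %in% c(6, 7)) {
      if (is.na(p$E) || p$E == 0) v <- c(v, "E != 0")
      if (is.na(p$F) || p$F == 0) v <- c(v, "F != 0")
      if (sel$index == 7 && !isTRUE(p$F^2 - p$E^2 > 0)) v <- c(v, "F^2 - E^2 > 0")
    }
  } else if (sel$case_id == 3L) {
    if (is.na(p$alpha[1]) || p$alpha[1] == 0) v <- c(v, "alpha1 != 0")
    if (sel$type_id == 5L && (is.na(p$alpha[2]) || p$alpha[2] == 0))
      v <- c(v, "alpha2 != 0")
  } else if (sel$case_id == 4L) {
    if (is.na(p$q) || p$q < 0 || p$q > 1) v <- c(v, "0 <= q <= 1")
  } else if (sel$case_id == 5L) {
    if (is.na(p$c3) || !(p$c3 > 0)) v <- c(v, "c3 > 0")
  }
  v
}

# Core dispatcher: value and minimum encountered denominator magnitude.
.chi_core <- function(case_id, type_id, index, params, rho_val) {
  p <- params; x <- rho_val
  n <- length(x)
  dInf <- rep(Inf, n)
  if (case_id == 1L) {
    sg <- p$sigma; mu <- p$mu; rh <- p$rho
    if (type_id == 1L) {
      D <- .csqrt(mu^2 - 4 * rh * sg)
      switch(as.character(index),
        "1" = list(v = -(mu + D * tanh(D * x / 2)) / (2 * rh), d = dInf),
        "2" = list(v = -(mu + D / tanh(D * x / 2)) / (2 * rh),
                   d = abs(sinh(D * x / 2))),
        "3" = {
          b <- .branch(p, 1, 1)
          list(v = -(mu + D * (tanh(D * x) + b * 1i * sech(D * x))) / (2 * rh),
               d = dInf)
        },
        "4" = {
          b <- .branch(p, 1, 1)
          list(v = -(mu + D * (1 / tanh(D * x) + b * csch(D * x))) / (2 * rh),
               d = abs(sinh(D * x)))
        },
        "5" = list(v = -(2 * mu + D * (tanh(D * x / 4) + 1 / tanh(D * x / 4))) / (4 * rh),
                   d = abs(sinh(D * x / 4))),
        "6" = {
          den <- p$E * sinh(D * x) + p$F
          list(v = (-mu + (.csqrt((p$E^2 + p$F^2) * (mu^2 - 4 * rh * sg)) -
                             p$E * D * cosh(D * x)) / den) / (2 * rh),
               d = abs(den))
        },
        "7" = {
          den <- p$E * cosh(D * x) + p$F
          list(v = (-mu - (.csqrt((p$F^2 - p$E^2) * (mu^2 - 4 * rh * sg)) +
                             p$E * D * sinh(D * x)) / den) / (2 * rh),
               d = abs(den))
        },
        "8" = {
          den <- D * sinh(D * x / 2) - mu * cosh(D * x / 2)
          list(v = 2 * sg * cosh(D * x / 2) / den, d = abs(den))
        },
        "9" = {
          den <- mu * sinh(D * x / 2) - D * cosh(D * x / 2)
          list(v = -2 * sg * sinh(D * x / 2) / den, d = abs(den))
        },
        "10" = {
          b <- .branch(p, 1, 1)
          den <- D * sinh(D * x) - (mu * cosh(D * x) + b * 1i * D)
          list(v = 2 * sg * cosh(D * x) / den, d = Mod(den))
        },
        "11" = {
          b <- .branch(p, 1, 1)
          den <- (D * cosh(D * x) + b * D) - mu * sinh(D * x)
          list(v = 2 * sg * sinh(D * x) / den, d = abs(den))
        },
        "12" = {
          ch <- cosh(D * x / 4); sh <- sinh(D * x / 4)
          den <- -2 * mu * ch * sh + 2 * D * ch^2 - D
          list(v = 4 * sg * ch * sh / den, d = abs(den))
        },
        stop("unknown Case-1 Type-1 index ", index)
      )
    } else {
      P <- .csqrt(4 * rh * sg - mu^2)
      switch(as.character(index),
        "13" = list(v = (-mu + P * tan(P * x / 2)) / (2 * rh),
                    d = abs(cos(P * x / 2))),
        "14" = list(v = (-mu - P / tan(P * x / 2)) / (2 * rh),
                    d = abs(sin(P * x / 2))),
        "15" = {
          b <- .branch(p, 1, 1)
          list(v = (-mu + P * (tan(P * x) + b / cos(P * x))) / (2 * rh),
               d = abs(cos(P * x)))
        },
        "16" = {
          b <- .branch(p, 1, 1)
          list(v = (-mu - P * (1 / tan(P * x) + b / sin(P * x))) / (2 * rh),
               d = abs(sin(P * x)))
        },
        "17" = list(v = (-2 * mu + P * (tan(P * x / 4) - 1 / tan(P * x / 4))) / (4 * rh),
                    d = pmin(abs(cos(P * x / 4)), abs(sin(P * x / 4)))),
        "18" = {
          b <- .branch(p, 1, 1)
          den <- p$E * sin(P * x) + p$F
          list(v = (-mu + (b * .csqrt((p$E^2 - p$F^2) * (4 * rh * sg - mu^2)) -
                             p$E * P * cos(P * x)) / den) / (2 * rh),
               d = abs(den))
        },
        "19" = {
          b <- .branch(p, 1, 1)
          den <- p$E * cos(P * x) + p$F
          list(v = (-mu - (b * .csqrt((p$E^2 - p$F^2) * (4 * rh * sg - mu^2)) -
                             p$E * P * sin(P * x)) / den) / (2 * rh),
               d = abs(den))
        },
        "20" = {
          den <- P * sin(P * x / 2) - mu * cos(P * x / 2)  # corrected sign
          list(v = 2 * sg * cos(P * x / 2) / den, d = abs(den))
        },
        "21" = {
          den <- -mu * sin(P * x / 2) + P * cos(P * x / 2)
          list(v = 2 * sg * sin(P * x / 2) / den, d = abs(den))
        },
        "22" = {
          b <- .branch(p, 1, 1)
          den <- P * sin(P * x) + mu * cos(P * x) + b * P
          list(v = -2 * sg * cos(P * x) / den, d = abs(den))
        },
        "23" = {
          b <- .branch(p, 1, 1)
          den <- (P * cos(P * x) + b * P) - mu * sin(P * x)
          list(v = 2 * sg * sin(P * x) / den, d = abs(den))
        },
        "24" = {
          cs <- cos(P * x / 4); sn <- sin(P * x / 4)
          den <- -2 * mu * cs * sn + 2 * P * cs^2 - P
          list(v = 4 * sg * cs * sn / den, d = abs(den))
        },
        stop("unknown Case-1 Type-2 index ", index)
      )
    }
  } else if (case_id == 2L) {
    sg <- p$sigma; rh <- p$rho
    m6 <- .csqrt(-6 * rh * sg); m2 <- .csqrt(-2 * rh * sg)
    s1 <- .branch(p, 1, 2); s2 <- .branch(p, 2, 2)
    switch(as.character(index),
      "1" = list(v = -(s1 * m2 + m6 * tanh(m6 * x / 2)) / (2 * rh), d = dInf),
      "2" = list(v = -(s1 * m2 + m6 / tanh(m6 * x / 2)) / (2 * rh),
                 d = abs(sinh(m6 * x / 2))),
      "3" = list(v = -(s1 * m2 + m6 * (tanh(m6 * x) + s2 * 1i * sech(m6 * x))) / (2 * rh),
                 d = dInf),
      "4" = list(v = -(s1 * m2 + m6 * (1 / tanh(m6 * x) + s2 * csch(m6 * x))) / (2 * rh),
                 d = abs(sinh(m6 * x))),
      "5" = list(v = -(2 * s1 * m2 + m6 * (tanh(m6 * x / 4) + 1 / tanh(m6 * x / 4))) / (4 * rh),
                 d = abs(sinh(m6 * x / 4))),
      "6" = {
        den <- p$E * sinh(m6 * x) + p$F
        list(v = (s1 * m2 + (.csqrt((p$E^2 + p$F^2) * (-6 * rh * sg)) -
                               p$E * m6 * cosh(m6 * x)) / den) / (2 * rh),
             d = abs(den))
      },
      "7" = {
        den <- p$E * cosh(m6 * x) + p$F
        list(v = (s1 * m2 - (.csqrt((p$F^2 - p$E^2) * (-6 * rh * sg)) +
                               p$E * m6 * sinh(m6 * x)) / den) / (2 * rh),
             d = abs(den))
      },
      "8" = {
        den <- m6 * sinh(m6 * x / 2) + s1 * m2 * cosh(m6 * x / 2)
        list(v = 2 * sg * cosh(m6 * x / 2) / den, d = abs(den))
      },
      "9" = {
        den <- s1 * m2 * sinh(m6 * x / 2) - m6 * cosh(m6 * x / 2)
        list(v = -2 * sg * sinh(m6 * x / 2) / den, d = abs(den))
      },
      "10" = {
        den <- m6 * sinh(m6 * x) + s1 * m2 * cosh(m6 * x) + s2 * 1i * m6
        list(v = 2 * sg * cosh(m6 * x) / den, d = Mod(den))
      },
      "11" = {
        den <- s1 * m2 * sinh(m6 * x) + m6 * cosh(m6 * x) + s2 * m6
        list(v = 2 * sg * sinh(m6 * x) / den, d = abs(den))
      },
      "12" = {
        ch <- cosh(m6 * x / 4); sh <- sinh(m6 * x / 4)
        den <- 2 * s1 * m2 * ch * sh + 2 * m6 * ch^2 - m6
        list(v = 4 * sg * ch * sh / den, d = abs(den))
      },
      stop("unknown Case-2 index ", index)
    )
  } else if (case_id == 3L) {
    a <- p$alpha
    switch(as.character(index),
      "1" = { den <- a[2] * cosh(x) + a[3]; list(v = a[1] / den, d = abs(den)) },
      "2" = { den <- a[2] * sinh(x) + a[3]; list(v = a[1] / den, d = abs(den)) },
      "3" = {
        den <- a[2] + a[3] * sinh(x) * cosh(x) + a[4] * cosh(x)^2
        list(v = a[1] / den, d = abs(den))
      },
      "4" = {
        den <- a[2] + a[3] * sinh(x) * cosh(x) + a[4] * sinh(x)^2
        list(v = a[1] / den, d = abs(den))
      },
      "5" = {
        den <- a[2] * (exp(-a[1] * x) + a[3])
        list(v = -a[1] * a[3] / den, d = abs(den))
      },
      "6" = {
        den <- a[2] * (exp(a[1] * x) + a[3])
        list(v = -a[1] * exp(a[1] * x) / den, d = abs(den))
      },
      "7" = { den <- a[2] * cos(x) + a[3]; list(v = a[1] / den, d = abs(den)) },
      "8" = { den <- a[2] * sin(x) + a[3]; list(v = a[1] / den, d = abs(den)) },
      "9" = {
        den <- a[2] + a[3] * sin(x) * cos(x) + a[4] * cos(x)^2
        list(v = a[1] / den, d = abs(den))
      },
      "10" = {
        den <- a[2] + a[3] * sin(x) * cos(x) + a[4] * sin(x)^2
        list(v = a[1] / den, d = abs(den))
      },
      stop("unknown Case-3 index ", index)
    )
  } else if (case_id == 4L) {
    f <- .case4_fun(index)
    v <- jef_eval(f$base, x, p$q)
    d <- jef_pole_distance(f$base, x, p$q)
    if (!is.null(f$second)) {
      b <- .branch(p, 1, 1)
      v <- v + b * f$fac * jef_eval(f$second, x, p$q)
      d <- pmin(d, jef_pole_distance(f$second, x, p$q))
    }
    list(v = v, d = d)
  } else if (case_id == 5L) {
    v <- weierstrass_p(sqrt(p$c3) / 2 * x, -4 * p$c1 / p$c3, -4 * p$c0 / p$c3)
    # double pole at lattice points: P ~ z^-2, so 1/sqrt(|P|) tracks the
    # pole distance
    list(v = v, d = ifelse(is.finite(v), pmin(1, 1 / sqrt(abs(v))), 0))
  } else stop("unknown case ", case_id)
}

#' Evaluate a catalogued auxiliary function
#'
#' @param sel a [chi_selector()].
#' @param params an [aux_params()] object satisfying the entry's regime
#'   constraints.
#' @param rho_val traveling-wave coordinate values.
#' @return complex vector with a logical attribute `singular` marking points
#'   where a composing denominator magnitude falls below `1e-10` (or the
#'   value is non-finite); singular entries are `NA`.
#' @examples
#' sel <- chi_selector(1, 1, 1)
#' p <- aux_params(sigma = 1, mu = 1, rho = 0.01)
#' eval_chi(sel, p, 0)  # -mu/(2*rho) = -50
#' @export
eval_chi <- function(sel, params, rho_val) {
  stopifnot(inherits(sel, "chi_selector"), inherits(params, "aux_params"))
  viol <- validate_chi_regime(sel, params)
  if (length(viol))
    stop("regime constraint(s) violated: ", paste(viol, collapse = "; "))
  res <- .chi_core(sel$case_id, sel$type_id, sel$index, params, rho_val)
  v <- as.complex(res$v)
  sing <- !is.finite(Re(v)) | !is.finite(Im(v)) | res$d < .SING_DEN_TOL
  v[sing] <- NA_complex_
  attr(v, "singular") <- sing
  v
}

# Characteristic frequency of the entry: argument multiplier of the composing
# functions, used to scale differentiation steps.
.chi_freq <- function(sel, params) {
  p <- params
  f <- switch(sel$case_id,
    `1` = sqrt(abs(p$mu^2 - 4 * p$rho * p$sigma)),
    `2` = sqrt(abs(6 * p$rho * p$sigma)),
    `3` = if (sel$type_id == 5L) abs(p$alpha[1]) else 1,
    `4` = 1,
    `5` = sqrt(p$c3) / 2 * max(1, abs(-4 * p$c1 / p$c3), abs(-4 * p$c0 / p$c3))^(1 / 2)
  )
  # the mixed E,F forms develop a sharp feature where E*cosh + F (etc.)
  # crosses zero; its width shrinks with the amplitude ratio
  ef <- sel$index %in% if (sel$case_id == 1L) c(6, 7, 18, 19) else
    if (sel$case_id == 2L) c(6, 7) else integer(0)
  if (ef && is.finite(p$E) && is.finite(p$F) && p$E != 0 && p$F != 0)
    f <- f * min(6, (abs(p$E) + abs(p$F)) / min(abs(p$E), abs(p$F)))
  max(f, 0.25)
}

# Richardson-extrapolated central first derivative of a complex-valued
# function of a real variable: the 6th-order 7-point stencil evaluated at h
# and h/2 and combined to 8th order. Complex-step differentiation is not
# applicable to the complex-valued branches (the step would mix real and
# imaginary parts), so a high-order real-step stencil with a
# frequency-scaled step is used.
.num_deriv6 <- function(fn, x, h) {
  w <- c(-1, 9, -45, 45, -9, 1) / 60
  off <- c(-3, -2, -1, 1, 2, 3)
  acc <- 0
  for (i in seq_along(off)) acc <- acc + w[i] * fn(x + off[i] * h)
  acc / h
}

.num_deriv <- function(fn, x, h) {
  d1 <- .num_deriv6(fn, x, h)
  d2 <- .num_deriv6(fn, x, h / 2)
  (64 * d2 - d1) / 63
}

#' Residual of an auxiliary function against the quartic first-order ODE
#'
#' Checks `chi'^2 = c0 + c1*chi + ... + c4*chi^4` numerically: the derivative
#' comes from a 6th-order central difference with a frequency-scaled step,
#' and the residual is normalized by `1 + |quartic|`. For Case-2 entries the
#' Riccati parameter `mu = s*sqrt(-2*rho*sigma)` is sign-ambiguous in the
#' printed forms; both signs are tried and the matching one reported.
#'
#' @param sel a [chi_selector()].
#' @param params an [aux_params()].
#' @param coeffs optional `gee_coefficients`; defaults to the entry's own
#'   coefficients ([gee_for_selector()]).
#' @param sample_points evaluation points (default: 50 points in `[-5, 5]`,
#'   widened by the reciprocal frequency for slowly varying entries);
#'   singular and pole-adjacent points are dropped.
#' @param check_regime error on violated regime constraints (disable for
#'   boundary parameter sets evaluated by continuity).
#' @return list with `max`, `mean`, `n_used`, `mu_sign` (Case 2; `NA`
#'   otherwise) and the `coeffs` actually used.
#' @export
aux_ode_residual <- function(sel, params, coeffs = NULL,
                             sample_points = NULL,
                             check_regime = TRUE) {
  stopifnot(inherits(sel, "chi_selector"), inherits(params, "aux_params"))
  viol <- validate_chi_regime(sel, params)
  if (check_regime && length(viol))
    stop("regime constraint(s) violated: ", paste(viol, collapse = "; "))

  cand <- if (!is.null(coeffs)) list(list(coeffs = coeffs, mu_sign = NA_integer_))
          else gee_candidates(sel, params)

  freq <- .chi_freq(sel, params)
  if (is.null(sample_points))  # widen the window for slowly varying entries
    sample_points <- seq(-5, 5, length.out = 50) / min(1, freq)
  h <- 2e-3 / freq
  core <- function(x) .chi_core(sel$case_id, sel$type_id, sel$index, params, x)
  fn <- function(x) {
    r <- core(x)
    v <- as.complex(r$v)
    v[r$d < .SING_DEN_TOL] <- NA_complex_
    v
  }
  # guard the whole stencil against poles: points whose composing
  # denominators dip below 0.3 anywhere on the stencil are excluded (the
  # truncation error of the difference stencil blows up as the 7th inverse
  # power of the pole distance)
  dmin <- core(sample_points)$d
  ok <- !is.na(fn(sample_points))
  for (o in c(-3, -2, -1, 1, 2, 3)) {
    r <- core(sample_points + o * h)
    dmin <- pmin(dmin, r$d)
    ok <- ok & !is.na(as.complex(r$v))
  }
  ok <- ok & dmin > 0.3
  pts <- sample_points[ok]
  if (length(pts) == 0L) stop("all sample points are singular or pole-adjacent")
  chi <- fn(pts)
  dchi <- .num_deriv(fn, pts, h)

  best <- NULL
  for (cc in cand) {
    cs <- unclass(cc$coeffs)
    quart <- cs[1] + cs[2] * chi + cs[3] * chi^2 + cs[4] * chi^3 + cs[5] * chi^4
    res <- Mod(dchi^2 - quart) / (1 + Mod(quart))
    summ <- list(max = max(res), mean = mean(res), n_used = length(pts),
                 mu_sign = cc$mu_sign, coeffs = cc$coeffs)
    if (is.null(best) || summ$max < best$max) best <- summ
  }
  best
}

#' Auxiliary-equation coefficients for a catalogue entry
#'
#' @param sel a [chi_selector()].
#' @param params an [aux_params()].
#' @param mu_sign for Case-2 entries, the sign `s` in
#'   `mu = s*sqrt(-2*rho*sigma)`; `NULL` returns the first candidate.
#' @return a `gee_coefficients` vector.
#' @export
gee_for_selector <- function(sel, params, mu_sign = NULL) {
  cand <- gee_candidates(sel, params)
  if (sel$case_id == 2L && !is.null(mu_sign)) {
    for (cc in cand) if (identical(cc$mu_sign, as.integer(mu_sign))) return(cc$coeffs)
    stop("mu_sign must be +1 or -1")
  }
  cand[[1]]$coeffs
}

# All candidate coefficient sets for an entry (two for Case 2: the printed
# plus-minus slots leave the sign of mu ambiguous).
gee_candidates <- function(sel, params) {
  p <- params
  switch(sel$case_id,
    `1` = list(list(coeffs = gee_from_riccati(p$sigma, p$mu, p$rho),
                    mu_sign = NA_integer_)),
    `2` = {
      m2 <- sqrt(-2 * p$rho * p$sigma)
      lapply(c(1L, -1L), function(s)
        list(coeffs = gee_from_riccati(p$sigma, s * m2, p$rho), mu_sign = s))
    },
    `3` = list(list(coeffs = .case3_c(sel$type_id, p$alpha),
                    mu_sign = NA_integer_)),
    `4` = list(list(coeffs = .case4_c(sel$index, p$q), mu_sign = NA_integer_)),
    `5` = list(list(coeffs = structure(
      c(c0 = p$c0, c1 = p$c1, c2 = 0, c3 = p$c3, c4 = 0),
      class = "gee_coefficients"), mu_sign = NA_integer_))
  )
}

#' Degeneration of a Jacobi-elliptic entry at modulus 0 or 1
#'
#' Maps a Case-4 entry to its elementary limit: hyperbolic functions at
#' `q = 1`, trigonometric at `q = 0` (constants where the function tends to
#' 1). The source notation's "r" Glaisher letter is the standard "s" (`rn = sn`, `cr =
#' cs`, ...).
#'
#' @param sel a Case-4 [chi_selector()].
#' @param q exactly 0 or 1.
#' @return list with `label` (human-readable limit expression) and
#'   `fn(rho_val, branch)` evaluating the limit form.
#' @export
jef_degenerate <- function(sel, q) {
  stopifnot(inherits(sel, "chi_selector"))
  if (sel$case_id != 4L) stop("degeneration applies to Case-4 entries only")
  if (!q %in% c(0, 1)) stop("q must be exactly 0 or 1")
  map1 <- c(sn = "tanh", cn = "sech", dn = "sech", ns = "coth", nc = "cosh",
            nd = "cosh", sc = "sinh", sd = "sinh", cs = "csch", ds = "csch",
            cd = "1", dc = "1")
  map0 <- c(sn = "sin", cn = "cos", dn = "1", ns = "csc", nc = "sec",
            nd = "1", sc = "tan", sd = "sin", cs = "cot", ds = "csc",
            cd = "cos", dc = "sec")
  map <- if (q == 1) map1 else map0
  f <- .case4_fun(sel$index)
  lab <- map[[f$base]]
  ev1 <- .elementary_fn(map[[f$base]])
  if (is.null(f$second)) {
    return(list(label = lab, fn = function(rho_val, branch = 1) ev1(rho_val)))
  }
  lab2 <- map[[f$second]]
  ev2 <- .elementary_fn(lab2)
  fac <- f$fac
  list(label = paste0(lab, " +- ", if (!identical(fac, 1)) "i*" else "", lab2),
       fn = function(rho_val, branch = 1) ev1(rho_val) + branch * fac * ev2(rho_val))
}

.elementary_fn <- function(name) {
  switch(name,
    "1" = function(x) rep(1, length(x)),
    tanh = tanh, sinh = sinh, cosh = cosh,
    coth = function(x) 1 / tanh(x),
    sech = function(x) 1 / cosh(x),
    csch = function(x) 1 / sinh(x),
    sin = sin, cos = cos,
    tan = tan, cot = function(x) 1 / tan(x),
    sec = function(x) 1 / cos(x),
    csc = function(x) 1 / sin(x),
    stop("unknown elementary function '", name, "'")
  )
}

#' Draw valid random auxiliary parameters for a catalogue entry
#'
#' Used by the property-based audit: parameters are drawn on O(1) scales
#' (Riccati parameters and the mixed-form constants in `[0.3, 2.5]` in
#' magnitude, moduli away from the degenerate endpoints) subject to the
#' entry's regime inequalities, with branch signs drawn uniformly.
#'
#' @param sel a [chi_selector()].
#' @param n number of draws.
#' @param seed RNG seed (local to this call).
#' @return list of [aux_params()] objects.
#' @export
draw_aux_params <- function(sel, n = 20, seed = 1) {
  stopifnot(inherits(sel, "chi_selector"))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  runif_s <- function(lo, hi) runif(1, lo, hi) * sample(c(-1, 1), 1)
  nb <- sel$row$n_branch
  out <- vector("list", n)
  i <- 0L
  while (i < n) {
    p <- switch(sel$case_id,
      `1` = {
        mu <- runif_s(0.5, 2); rho <- runif_s(0.1, 0.6)
        disc_sign <- if (sel$type_id == 1L) 1 else -1
        # choose sigma so that sign(mu^2 - 4*rho*sigma) is as required
        sg <- if (disc_sign > 0) (mu^2 - runif(1, 0.5, 3)) / (4 * rho)
              else (mu^2 + runif(1, 0.5, 3)) / (4 * rho)
        if (abs(sg) < 0.05) NULL else {
          EF <- if (sel$index %in% c(6, 7)) c(E = runif_s(0.3, 1), F = runif(1, 1.2, 2.5))
                else if (sel$index %in% c(18, 19)) c(E = runif_s(1.2, 2.5), F = runif(1, 0.3, 1))
                else c(E = NA_real_, F = NA_real_)
          aux_params(sigma = sg, mu = mu, rho = rho, E = EF[["E"]], F = EF[["F"]],
                     branch_signs = sample(c(-1L, 1L), max(nb, 1), replace = TRUE)[seq_len(nb)])
        }
      },
      `2` = {
        sg <- runif_s(0.3, 2); rho <- -sign(sg) * runif(1, 0.1, 1)
        EF <- if (sel$index %in% c(6, 7)) c(E = runif_s(0.3, 1), F = runif(1, 1.2, 2.5))
              else c(E = NA_real_, F = NA_real_)
        aux_params(sigma = sg, rho = rho, E = EF[["E"]], F = EF[["F"]],
                   branch_signs = sample(c(-1L, 1L), max(nb, 1), replace = TRUE)[seq_len(nb)])
      },
      `3` = {
        al <- c(runif_s(0.5, 2), runif_s(0.5, 2), runif_s(0.3, 1.5), runif_s(0.5, 2))
        # keep the quartic non-degenerate and the denominator away from zero
        cs <- .case3_c(sel$type_id, al)
        if (abs(cs[["c4"]]) < 0.05 || abs(abs(al[2]) - abs(al[3])) < 0.3) NULL
        else aux_params(alpha = al)
      },
      `4` = aux_params(q = runif(1, 0.15, 0.9),
                       branch_signs = sample(c(-1L, 1L), max(nb, 1), replace = TRUE)[seq_len(nb)]),
      `5` = aux_params(c0 = runif_s(0.2, 1.5), c1 = runif_s(0.2, 1.5),
                       c3 = runif(1, 0.5, 2))
    )
    if (is.null(p)) next
    if (length(validate_chi_regime(sel, p))) next
    i <- i + 1L
    out[[i]] <- p
  }
  out
}
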