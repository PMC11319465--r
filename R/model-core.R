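# Physical parameter -> PDE coefficient maps for the double-chain DNA model.
#
# The model couples the difference of longitudinal displacements (Theta) and
# of transverse displacements (Xi) of the two strands, treated as elastic
# filaments joined by hydrogen-bond "membranes". The linear relation
# Xi = b0*Theta + b1 collapses the pair to a single cubic-quadratic wave
# equation
#   Theta_tt - Lambda1^2 Theta_ss = Phi1 Theta^3 + Phi2 Theta^2 + Phi3 Theta
# whose consistency fixes b1 = h/sqrt(2) and Z = g.

#' Physical parameters of the double-chain DNA lattice
#'
#' Bundles the lattice constants of the double-strand model together with the
#' slope and intercept of the linear map from the longitudinal to the
#' transverse displacement difference.
#'
#' @param a0 membrane height (length), positive.
#' @param h separation of the two strands (length), positive.
#' @param omega elastic rigidity of the hydrogen-bond membrane.
#' @param g stress density per thread.
#' @param Z Young modulus. The single-equation reduction requires `Z == g`;
#'   [compute_phi()] enforces this.
#' @param Gamma cross-sectional area, positive.
#' @param Delta mass density, positive.
#' @param b0 slope of the transverse map (dimensionless).
#' @param b1 intercept of the transverse map. Defaults to `h/sqrt(2)`, the
#'   value forced by consistency of the reduction; supplying anything else is
#'   allowed for exploratory work but [compute_phi()] will refuse it.
#' @return an object of class `physical_params`.
#' @examples
#' p <- physical_params(a0 = 1, h = 1, omega = 1, g = 1, Z = 1,
#'                      Gamma = 1, Delta = 1, b0 = 1)
#' compute_lambda(p)$kappa
#' @export
physical_params <- function(a0, h, omega, g, Z = g, Gamma, Delta,
                            b0 = 1, b1 = h / sqrt(2)) {
  vals <- list(a0 = a0, h = h, omega = omega, g = g, Z = Z,
               Gamma = Gamma, Delta = Delta, b0 = b0, b1 = b1)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite numeric value", nm))
  }
  for (nm in c("a0", "h", "Gamma", "Delta")) {
    if (vals[[nm]] <= 0)
      stop(sprintf("'%s' must be positive (got %g)", nm, vals[[nm]]))
  }
  structure(vals, class = "physical_params")
}

#' @export
print.physical_params <- function(x, ...) {
  cat("Double-chain DNA physical parameters\n")
  cat(sprintf("  a0=%g h=%g omega=%g g=%g Z=%g Gamma=%g Delta=%g\n",
              x$a0, x$h, x$omega, x$g, x$Z, x$Gamma, x$Delta))
  cat(sprintf("  transverse map: b0=%g b1=%g\n", x$b0, x$b1))
  invisible(x)
}

#' Coupled-system coefficients from physical parameters
#'
#' Computes the eleven coefficients of the coupled displacement equations and
#' the combination `kappa = omega*a0/(Delta*Gamma)` that every nonlinear
#' coefficient carries. Two corrections to the printed source formulas are
#' applied and recorded: the undeclared denominator symbol in the first two
#' coefficients is identified with the mass density `Delta` (no second
#' density exists in the model), and the undefined symbol in the linear
#' coefficient is identified with the strand separation `h` (the unique
#' choice that reproduces the closed form of the reduced linear coefficient).
#' The seventh coefficient, absent from the printed list, is derived as
#' `-2*kappa/a0` from consistency of the two reduced scalar equations.
#'
#' @param params a [physical_params()] object.
#' @param sign1,sign6 sign branches (+1 or -1) of the two wave-speed
#'   coefficients `Lambda1 = sign1*Z/Delta`, `Lambda6 = sign6*g/Delta`. Only
#'   their squares enter the reduced equation.
#' @return an object of class `model_coefficients`: a list with `Lambda1` ..
#'   `Lambda11`, `kappa`, and a `corrections` character vector naming the
#'   substitutions applied.
#' @examples
#' p <- physical_params(a0 = 1, h = 1, omega = 1, g = 1, Z = 1,
#'                      Gamma = 1, Delta = 1)
#' cf <- compute_lambda(p)
#' cf$Lambda5  # 4*kappa/h^3 = 4
#' @export
compute_lambda <- function(params, sign1 = 1, sign6 = 1) {
  stopifnot(inherits(params, "physical_params"))
  if (!sign1 %in% c(-1, 1) || !sign6 %in% c(-1, 1))
    stop("sign1 and sign6 must be +1 or -1")
  a0 <- params$a0; h <- params$h; omega <- params$omega
  Gamma <- params$Gamma; Delta <- params$Delta
  kappa <- omega * a0 / (Delta * Gamma)
  out <- list(
    Lambda1  = sign1 * params$Z / Delta,
    # delta -> Delta and y -> h substitutions; + branch reproduces the
    # printed reduced linear coefficient -2k/a0 + 6k/h.
    Lambda2  = -2 * omega * (h - a0) / (Delta * Gamma * h),
    Lambda3  = 2 * sqrt(2) * omega * a0 / (Delta * Gamma * h^2),
    Lambda4  = -2 * omega * a0 / (Delta * Gamma * h^2),
    Lambda5  = 4 * omega * a0 / (Delta * Gamma * h^3),
    Lambda6  = sign6 * params$g / Delta,
    Lambda7  = -2 * kappa / a0,
    Lambda8  = sqrt(2) * omega * a0 / (Delta * Gamma * h^2),
    Lambda9  = -2 * omega * a0 / (Delta * Gamma * h^2),
    Lambda10 = 4 * omega * a0 / (Delta * Gamma * h^3),
    Lambda11 = sqrt(2) * omega * (h - a0) / (Delta * Gamma),
    kappa    = kappa,
    sign1 = sign1, sign6 = sign6,
    corrections = c("delta = Delta (undeclared denominator symbol)",
                    "y = h in Lambda2 (undefined symbol)",
                    "Lambda7 = -2*kappa/a0 (omitted from the printed list; derived from reduction consistency)")
  )
  class(out) <- "model_coefficients"
  out
}

#' @export
print.model_coefficients <- function(x, ...) {
  cat("Coupled-system coefficients (kappa =", format(x$kappa), ")\n")
  lam <- unlist(x[sprintf("Lambda%d", 1:11)])
  print(stats::setNames(as.numeric(lam), sprintf("Lambda%d", 1:11)))
  invisible(x)
}

#' Reduced single-equation coefficients
#'
#' Collapses the coupled system to the cubic-quadratic wave equation via
#' `Xi = b0*Theta + b1` and returns its three coefficients. The composition
#' route `Phi1 = Lambda4 + Lambda5*b0^2`, `Phi2 = 2*Lambda5*b0*b1 +
#' Lambda3*b0`, `Phi3 = Lambda2 + b1*Lambda3 + Lambda5*b1^2` is authoritative.
#' The printed closed form for `Phi1`, `kappa*(-2+4*b0^2)/h^3`, is
#' dimensionally inconsistent with the composition (its first term needs
#' `1/h^2`); it is evaluated and the discrepancy reported, never silently
#' used. The closed forms for `Phi2` and `Phi3` agree exactly and are checked.
#'
#' @param coeffs a [compute_lambda()] result.
#' @param params the [physical_params()] the coefficients came from; `b1` must
#'   equal `h/sqrt(2)` and `Z` must equal `g` (the reduction's consistency
#'   conditions).
#' @param tol relative tolerance for the closed-form cross-checks.
#' @return an object of class `reduced_coefficients`: `Phi1`, `Phi2`, `Phi3`,
#'   `Lambda1`, plus a `checks` data frame comparing composition and printed
#'   closed forms.
#' @examples
#' p <- physical_params(a0 = 1, h = 1, omega = 1, g = 1, Z = 1,
#'                      Gamma = 1, Delta = 1, b0 = 1)
#' ph <- compute_phi(compute_lambda(p), p)
#' ph$Phi2  # 6*sqrt(2)
#' @export
compute_phi <- function(coeffs, params, tol = 1e-12) {
  stopifnot(inherits(coeffs, "model_coefficients"),
            inherits(params, "physical_params"))
  h <- params$h; a0 <- params$a0; b0 <- params$b0
  if (abs(params$b1 - h / sqrt(2)) > tol * max(1, abs(params$b1)))
    stop("reduction requires b1 = h/sqrt(2); got b1 = ", params$b1)
  if (abs(params$Z - params$g) > tol * max(1, abs(params$Z)))
    stop("reduction requires Z = g; got Z = ", params$Z, ", g = ", params$g)
  b1 <- h / sqrt(2)
  kappa <- coeffs$kappa

  Phi1 <- coeffs$Lambda4 + coeffs$Lambda5 * b0^2
  Phi2 <- 2 * coeffs$Lambda5 * b0 * b1 + coeffs$Lambda3 * b0
  Phi3 <- coeffs$Lambda2 + b1 * coeffs$Lambda3 + coeffs$Lambda5 * b1^2

  printed <- c(Phi1 = kappa * (-2 + 4 * b0^2) / h^3,
               Phi2 = 6 * sqrt(2) * b0 * kappa / h^2,
               Phi3 = -2 * kappa / a0 + 6 * kappa / h)
  comp <- c(Phi1 = Phi1, Phi2 = Phi2, Phi3 = Phi3)
  checks <- data.frame(
    coefficient = names(comp),
    composition = as.numeric(comp),
    closed_form = as.numeric(printed),
    agree = abs(comp - printed) <= tol * pmax(1, abs(comp)),
    row.names = NULL
  )

  out <- list(Phi1 = Phi1, Phi2 = Phi2, Phi3 = Phi3,
              Lambda1 = coeffs$Lambda1, checks = checks,
              Phi1_degenerate = abs(Phi1) < .Machine$double.eps * 100)
  if (out$Phi1_degenerate)
    warning("Phi1 = 0: the series amplitude eta1 is undefined downstream")
  class(out) <- "reduced_coefficients"
  out
}

#' Assemble reduced coefficients directly
#'
#' Constructor used when the reduced cubic, quadratic and linear coefficients
#' are given directly (as in the published figure captions) rather than
#' derived from lattice constants.
#'
#' @param Phi1,Phi2,Phi3 cubic, quadratic and linear coefficients of the
#'   reduced wave equation. `Phi3` may be `NA` to be filled in later by
#'   [implied_constraints()].
#' @param Lambda1 wave-speed coefficient of the reduced equation.
#' @return an object of class `reduced_coefficients`.
#' @export
reduced_coefficients <- function(Phi1, Phi2, Phi3 = NA_real_, Lambda1) {
  stopifnot(is.numeric(Phi1), is.numeric(Phi2), length(Phi1) == 1L)
  if (Phi1 == 0) stop("Phi1 must be nonzero (eta1 undefined otherwise)")
  structure(list(Phi1 = Phi1, Phi2 = Phi2, Phi3 = Phi3, Lambda1 = Lambda1,
                 checks = NULL, Phi1_degenerate = FALSE),
            class = "reduced_coefficients")
}

#' @export
print.reduced_coefficients <- function(x, ...) {
  cat(sprintf("Reduced wave-equation coefficients: Phi1=%g Phi2=%g Phi3=%s Lambda1=%g\n",
              x$Phi1, x$Phi2,
              if (is.na(x$Phi3)) "<implied downstream>" else format(x$Phi3),
              x$Lambda1))
  if (!is.null(x$checks)) {
    cat("closed-form cross-checks:\n")
    print(x$checks)
  }
  invisible(x)
}

#' Reconstruct the transverse displacement field
#'
#' Applies the affine map `Xi = b0*Theta + b1` elementwise, preserving any
#' singularity mask attribute carried by the input.
#'
#' @param theta numeric or complex vector/matrix of longitudinal-difference
#'   values (possibly with a `singular` attribute as produced by grid
#'   evaluation).
#' @param b0,b1 slope and intercept of the transverse map.
#' @return object of the same shape with the map applied.
#' @export
reconstruct_transverse <- function(theta, b0, b1) {
  out <- b0 * theta + b1
  sing <- attr(theta, "singular", exact = TRUE)
  if (!is.null(sing)) attr(out, "singular") <- sing
  out
}

#' Read physical parameters from a flat key-value file
#'
#' Parses `key = value` lines (`#` comments allowed) with keys matching the
#' [physical_params()] argument names.
#'
#' @param path file path.
#' @return a [physical_params()] object.
#' @export
read_params_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) stop("malformed line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, character(1), 2L))))
  if (anyNA(vals)) stop("non-numeric value for key(s): ",
                        paste(keys[is.na(vals)], collapse = ", "))
  args <- as.list(vals)
  names(args) <- keys
  known <- c("a0", "h", "omega", "g", "Z", "Gamma", "Delta", "b0", "b1")
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown key(s): ", paste(unknown, collapse = ", "))
  do.call(physical_params, args)
}

#' Write a coefficient report as JSON
#'
#' Serializes the physical parameters, coupled-system coefficients, reduced
#' coefficients and the closed-form cross-checks (including corrections
#' applied) to a JSON file.
#'
#' @param params [physical_params()] object.
#' @param coeffs [compute_lambda()] result.
#' @param phis [compute_phi()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_coefficient_report <- function(params, coeffs, phis, path) {
  rep <- list(
    physical_params = unclass(params),
    lambda = coeffs[c(sprintf("Lambda%d", 1:11), "kappa")],
    corrections = coeffs$corrections,
    phi = phis[c("Phi1", "Phi2", "Phi3", "Lambda1")],
    closed_form_checks = phis$checks
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
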