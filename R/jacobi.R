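# Jacobi elliptic functions and the Weierstrass P function.
#
# The modulus convention follows the catalogue: q in [0, 1] is the elliptic
# modulus, and the underlying evaluator uses the parameter m = q^2 (the
# MATLAB/pracma `ellipj` convention). q -> 1 degenerates to hyperbolic
# functions, q -> 0 to trigonometric ones.

.jef_base <- function(u, q) {
  stopifnot(is.numeric(q), length(q) == 1L, q >= 0, q <= 1)
  if (q == 0) return(list(sn = sin(u), cn = cos(u), dn = rep(1, length(u))))
  if (q == 1) return(list(sn = tanh(u), cn = 1 / cosh(u), dn = 1 / cosh(u)))
  ej <- pracma::ellipj(u, q^2)
  list(sn = ej$sn, cn = ej$cn, dn = ej$dn)
}

#' Evaluate a Jacobi elliptic function
#'
#' @param name one of the twelve Glaisher functions `sn, cn, dn, ns, nc, nd,
#'   sc, sd, cs, ds, cd, dc`.
#' @param u real argument vector.
#' @param q elliptic modulus in `[0, 1]` (parameter `m = q^2`).
#' @return numeric vector; poles evaluate to `Inf`/`NaN` and should be masked
#'   via [jef_pole_distance()].
#' @export
jef_eval <- function(name, u, q) {
  b <- .jef_base(u, q)
  switch(name,
    sn = b$sn, cn = b$cn, dn = b$dn,
    ns = 1 / b$sn, nc = 1 / b$cn, nd = 1 / b$dn,
    sc = b$sn / b$cn, sd = b$sn / b$dn,
    cs = b$cn / b$sn, ds = b$dn / b$sn,
    cd = b$cn / b$dn, dc = b$dn / b$cn,
    stop("unknown Jacobi function '", name, "'")
  )
}

#' Magnitude of the denominator controlling a Jacobi function's poles
#'
#' Returns `|sn|`, `|cn|` or `|dn|` where `name` has poles at the zeros of
#' that base function, and `Inf` for the pole-free functions.
#'
#' @inheritParams jef_eval
#' @export
jef_pole_distance <- function(name, u, q) {
  b <- .jef_base(u, q)
  switch(name,
    sn = , cn = , dn = rep(Inf, length(u)),
    ns = , cs = , ds = abs(b$sn),
    nc = , sc = , dc = abs(b$cn),
    nd = , sd = , cd = abs(b$dn),
    stop("unknown Jacobi function '", name, "'")
  )
}

#' Weierstrass P function (real argument, real invariants)
#'
#' Evaluates the Weierstrass elliptic function via its reduction to Jacobi
#' functions on the roots of the cubic `4 t^3 - g2 t - g3`. Both root
#' configurations (three real roots; one real root and a conjugate pair) are
#' handled. Written in-package because no installed R package provides it.
#'
#' @param z real argument vector.
#' @param g2,g3 invariants.
#' @return numeric vector; near lattice points the double pole produces large
#'   values which callers mask.
#' @export
weierstrass_p <- function(z, g2, g3) {
  r <- polyroot(c(-g3, -g2, 0, 4))
  is_real <- abs(Im(r)) < 1e-10 * pmax(1, Mod(r))
  if (sum(is_real) >= 3L) {
    e <- sort(Re(r), decreasing = TRUE)   # e1 >= e2 >= e3
    e1 <- e[1]; e2 <- e[2]; e3 <- e[3]
    if (e1 - e3 < .Machine$double.eps) return(rep(e1, length(z)))
    m <- (e2 - e3) / (e1 - e3)
    s <- .jef_base(sqrt(e1 - e3) * z, sqrt(max(0, min(1, m))))$sn
    e3 + (e1 - e3) / s^2
  } else {
    a <- Re(r[which(is_real)[1]])         # the single real root
    H2 <- sqrt(max(0, 3 * a^2 - g2 / 4))
    if (H2 == 0) return(a + 1 / z^2)
    m <- 0.5 - 3 * a / (8 * H2) * 2      # m = 1/2 - 3a/(4 H2)
    m <- max(0, min(1, m))
    cnv <- .jef_base(2 * sqrt(H2) * z, sqrt(m))$cn
    a + H2 * (1 + cnv) / (1 - cnv)
  }
}
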