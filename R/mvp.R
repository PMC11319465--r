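# Exact sparse multivariate polynomial arithmetic.
#
# Used for the identity checks of the expansion machinery: the chi-power
# system, its derivation from the ansatz, and the annihilation of the cubic
# and quadratic equations by the closed-form series coefficients. All
# coefficients arising there are dyadic rationals, which double precision
# represents exactly, so zero-testing with `== 0` is exact.
#
# A polynomial is a named numeric vector: names are canonical monomial keys
# ("1" for the constant; otherwise "a^2*b^1" with variables sorted), values
# are coefficients.

.mono_parse <- function(key) {
  if (key == "1") return(integer(0))
  parts <- strsplit(key, "*", fixed = TRUE)[[1]]
  ex <- vapply(parts, function(p) {
    kv <- strsplit(p, "^", fixed = TRUE)[[1]]
    as.integer(kv[2])
  }, integer(1))
  names(ex) <- vapply(parts, function(p) strsplit(p, "^", fixed = TRUE)[[1]][1],
                      character(1))
  ex
}

.mono_key <- function(ex) {
  ex <- ex[ex != 0L]
  if (length(ex) == 0L) return("1")
  ex <- ex[order(names(ex), method = "radix")]
  paste(sprintf("%s^%d", names(ex), ex), collapse = "*")
}

.mono_mul <- function(k1, k2) {
  e1 <- .mono_parse(k1); e2 <- .mono_parse(k2)
  vars <- union(names(e1), names(e2))
  ex <- integer(length(vars)); names(ex) <- vars
  ex[names(e1)] <- e1
  ex[names(e2)] <- ex[names(e2)] + e2
  .mono_key(ex)
}

.mvp_canon <- function(p) {
  if (length(p) == 0L) return(structure(numeric(0), class = "mvp"))
  s <- vapply(split(unclass(p), names(p)), sum, numeric(1))
  s <- s[s != 0]
  structure(s[order(names(s), method = "radix")], class = "mvp")
}

#' Construct a polynomial variable or constant
#'
#' Minimal constructors for the package's exact sparse polynomial type, which
#' backs the algebraic identity checks of the expansion engine.
#'
#' @param name variable name (a syntactic symbol string).
#' @param x numeric constant.
#' @return an object of class `mvp`.
#' @keywords internal
#' @name mvp
NULL

#' @rdname mvp
#' @export
mvp_var <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  .mvp_canon(structure(stats::setNames(1, sprintf("%s^1", name)), class = "mvp"))
}

#' @rdname mvp
#' @export
mvp_const <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L)
  .mvp_canon(structure(stats::setNames(x, "1"), class = "mvp"))
}

.as_mvp <- function(x) {
  if (inherits(x, "mvp")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(mvp_const(x))
  stop("cannot coerce to mvp")
}

#' @rdname mvp
#' @export
mvp_add <- function(p, q) {
  p <- .as_mvp(p); q <- .as_mvp(q)
  .mvp_canon(structure(c(unclass(p), unclass(q)), class = "mvp"))
}

#' @rdname mvp
#' @export
mvp_neg <- function(p) {
  p <- .as_mvp(p)
  structure(-unclass(p), class = "mvp")
}

#' @rdname mvp
#' @export
mvp_sub <- function(p, q) mvp_add(p, mvp_neg(q))

#' @rdname mvp
#' @export
mvp_mul <- function(p, q) {
  p <- .as_mvp(p); q <- .as_mvp(q)
  if (length(p) == 0L || length(q) == 0L)
    return(structure(numeric(0), class = "mvp"))
  keys <- character(length(p) * length(q))
  vals <- numeric(length(p) * length(q))
  i <- 0L
  for (a in seq_along(p)) {
    for (b in seq_along(q)) {
      i <- i + 1L
      keys[i] <- .mono_mul(names(p)[a], names(q)[b])
      vals[i] <- unclass(p)[a] * unclass(q)[b]
    }
  }
  .mvp_canon(structure(stats::setNames(vals, keys), class = "mvp"))
}

#' @rdname mvp
#' @export
mvp_pow <- function(p, n) {
  stopifnot(n >= 0L, n == round(n))
  out <- mvp_const(1)
  for (i in seq_len(n)) out <- mvp_mul(out, p)
  out
}

#' @rdname mvp
#' @export
mvp_scale <- function(p, s) mvp_mul(p, mvp_const(s))

#' @rdname mvp
#' @export
mvp_is_zero <- function(p) length(.mvp_canon(.as_mvp(p))) == 0L

#' @rdname mvp
#' @export
mvp_equal <- function(p, q) mvp_is_zero(mvp_sub(p, q))

#' @rdname mvp
#' @param p an `mvp` polynomial.
#' @export
mvp_vars <- function(p) {
  p <- .as_mvp(p)
  sort(unique(unlist(lapply(names(p), function(k) names(.mono_parse(k))))), method = "radix")
}

#' @rdname mvp
#' @export
mvp_degree <- function(p, var) {
  p <- .as_mvp(p)
  if (length(p) == 0L) return(0L)
  max(vapply(names(p), function(k) {
    ex <- .mono_parse(k)
    if (var %in% names(ex)) ex[[var]] else 0L
  }, integer(1)))
}

# Evaluate at a named list/vector of (possibly complex) values.
#' @rdname mvp
#' @export
mvp_eval <- function(p, values) {
  p <- .as_mvp(p)
  if (length(p) == 0L) return(0)
  tot <- 0
  for (i in seq_along(p)) {
    ex <- .mono_parse(names(p)[i])
    term <- unclass(p)[[i]]
    for (v in names(ex)) {
      if (is.null(values[[v]])) stop(sprintf("no value for variable '%s'", v))
      term <- term * values[[v]]^ex[[v]]
    }
    tot <- tot + term
  }
  tot
}

# Substitute a polynomial for a variable.
#' @rdname mvp
#' @export
mvp_subst <- function(p, var, q) {
  p <- .as_mvp(p); q <- .as_mvp(q)
  out <- mvp_const(0)
  for (i in seq_along(p)) {
    ex <- .mono_parse(names(p)[i])
    k <- if (var %in% names(ex)) ex[[var]] else 0L
    rest <- .mono_key(ex[names(ex) != var])
    term <- structure(stats::setNames(unclass(p)[[i]], rest), class = "mvp")
    out <- mvp_add(out, mvp_mul(term, mvp_pow(q, k)))
  }
  out
}

# Substitute var -> num/den after clearing denominators: the return value is
# p * den^deg_var(p), exact in the polynomial ring.
#' @rdname mvp
#' @export
mvp_subst_ratio <- function(p, var, num, den) {
  p <- .as_mvp(p); num <- .as_mvp(num); den <- .as_mvp(den)
  d <- mvp_degree(p, var)
  out <- mvp_const(0)
  for (i in seq_along(p)) {
    ex <- .mono_parse(names(p)[i])
    k <- if (var %in% names(ex)) ex[[var]] else 0L
    rest <- .mono_key(ex[names(ex) != var])
    term <- structure(stats::setNames(unclass(p)[[i]], rest), class = "mvp")
    out <- mvp_add(out, mvp_mul(term, mvp_mul(mvp_pow(num, k), mvp_pow(den, d - k))))
  }
  out
}

# Reduce modulo the relation var^2 = num/den, clearing denominators: returns
# p * den^M where M = max_i floor(deg_var(term_i)/2). Zero iff p lies in the
# ideal generated by (den*var^2 - num) over the localisation at den.
#' @rdname mvp
#' @export
mvp_reduce_square <- function(p, var, num, den) {
  p <- .as_mvp(p); num <- .as_mvp(num); den <- .as_mvp(den)
  M <- 0L
  for (k in names(p)) {
    ex <- .mono_parse(k)
    a <- if (var %in% names(ex)) ex[[var]] else 0L
    M <- max(M, a %/% 2L)
  }
  out <- mvp_const(0)
  for (i in seq_along(p)) {
    ex <- .mono_parse(names(p)[i])
    a <- if (var %in% names(ex)) ex[[var]] else 0L
    m <- a %/% 2L; r <- a - 2L * m
    ex2 <- ex[names(ex) != var]
    if (r > 0L) ex2 <- c(ex2, stats::setNames(r, var))
    term <- structure(stats::setNames(unclass(p)[[i]], .mono_key(ex2)),
                      class = "mvp")
    out <- mvp_add(out, mvp_mul(term, mvp_mul(mvp_pow(num, m), mvp_pow(den, M - m))))
  }
  out
}

#' @export
format.mvp <- function(x, ...) {
  if (length(x) == 0L) return("0")
  pieces <- vapply(seq_along(x), function(i) {
    co <- unclass(x)[[i]]
    key <- names(x)[i]
    lead <- if (i == 1L) {
      if (co < 0) "-" else ""
    } else {
      if (co < 0) " - " else " + "
    }
    aco <- abs(co)
    if (key == "1") {
      paste0(lead, format(aco, digits = 15))
    } else {
      mono <- gsub("\\^1(\\*|$)", "\\1", key)
      if (aco == 1) paste0(lead, mono) else
        paste0(lead, format(aco, digits = 15), "*", mono)
    }
  }, character(1))
  paste(pieces, collapse = "")
}

#' @export
print.mvp <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
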