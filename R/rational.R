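#' Exact rational numbers
#'
#' A small vectorised exact-rational type used throughout the package so that
#' stationary distributions, payoff series and critical cost thresholds are
#' computed without floating-point round-off. Numerators and denominators are
#' stored as doubles holding exact integers; every operation reduces by the
#' greatest common divisor and asserts that no intermediate exceeds 2^53,
#' the largest integer a double represents exactly.
#'
#' @param n integer numerator(s).
#' @param d integer denominator(s), non-zero; recycled against `n`.
#' @return A `rat` vector.
#' @examples
#' rat(16, 33) + rat(1, 3)
#' as_rational("2/9") < as_rational(0.25)
#' @export
rat <- function(n, d = 1) {
  stopifnot(is.numeric(n), is.numeric(d), all(d != 0))
  if (length(d) == 1L) d <- rep(d, length(n))
  if (length(n) == 1L) n <- rep(n, length(d))
  stopifnot(length(n) == length(d))
  rat_reduce(structure(list(n = as.numeric(n), d = as.numeric(d)), class = "rat"))
}

.INT_MAX_EXACT <- 2^53

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b > 0)) {
    t <- b
    b <- ifelse(b > 0, a %% b, 0)
    a <- ifelse(t > 0, t, a)
  }
  a
}

rat_reduce <- function(x) {
  n <- x$n; d <- x$d
  if (any(abs(n) >= .INT_MAX_EXACT) || any(abs(d) >= .INT_MAX_EXACT)) {
    stop("exact rational arithmetic overflow beyond 2^53", call. = FALSE)
  }
  if (any(n != round(n)) || any(d != round(d))) {
    stop("rational components must be integers", call. = FALSE)
  }
  s <- sign(d)
  n <- n * s; d <- d * s
  g <- gcd2(n, d)
  g[g == 0] <- 1
  structure(list(n = n / g, d = d / g), class = "rat")
}

#' @export
is_rat <- function(x) inherits(x, "rat")

#' Coerce to an exact rational
#'
#' Accepts `rat` vectors, `"p/q"` strings, integers, and numerics that are
#' recognisably close to a small-denominator fraction (continued-fraction
#' reconstruction with denominators up to `max_den`; the reconstruction must
#' agree with the input essentially to double precision, otherwise the value
#' is rejected so a silent loss of exactness cannot occur — irrational or
#' generic floating-point inputs raise an error).
#'
#' @param x value(s) to coerce.
#' @param max_den largest denominator tried for numeric input.
#' @return A `rat` vector.
#' @export
as_rational <- function(x, max_den = 1e6) {
  if (is_rat(x)) return(x)
  if (is.character(x)) {
    parts <- strsplit(x, "/", fixed = TRUE)
    n <- vapply(parts, function(p) as.numeric(p[[1]]), 0)
    d <- vapply(parts, function(p) if (length(p) > 1L) as.numeric(p[[2]]) else 1, 0)
    return(rat(n, d))
  }
  stopifnot(is.numeric(x))
  if (all(x == round(x))) return(rat(x, 1))
  approx1 <- function(v) {
    # continued-fraction convergents
    h0 <- 0; h1 <- 1; k0 <- 1; k1 <- 0; r <- v
    for (i in 1:40) {
      a <- floor(r)
      h <- a * h1 + h0; k <- a * k1 + k0
      if (k > max_den) break
      h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
      if (abs(v - h / k) < 1e-15 * max(1, abs(v))) break
      if (r == a) break
      r <- 1 / (r - a)
    }
    if (abs(v - h1 / k1) > 4e-15 * max(1, abs(v))) {
      stop("numeric value ", v, " is not recognisably rational; pass a \"p/q\" string",
           call. = FALSE)
    }
    c(h1, k1)
  }
  pq <- vapply(x, approx1, numeric(2))
  rat(pq[1, ], pq[2, ])
}

#' @export
length.rat <- function(x) length(x$n)

#' @export
`[.rat` <- function(x, i) structure(list(n = x$n[i], d = x$d[i]), class = "rat")

#' @export
`[<-.rat` <- function(x, i, value) {
  value <- as_rational(value)
  x$n[i] <- value$n; x$d[i] <- value$d
  x
}

#' @export
c.rat <- function(...) {
  parts <- lapply(list(...), as_rational)
  structure(list(n = unlist(lapply(parts, `[[`, "n")),
                 d = unlist(lapply(parts, `[[`, "d"))), class = "rat")
}

#' @export
as.double.rat <- function(x, ...) x$n / x$d

#' @export
format.rat <- function(x, ...) {
  ifelse(x$d == 1, formatC(x$n, format = "fg"),
         paste0(formatC(x$n, format = "fg"), "/", formatC(x$d, format = "fg")))
}

#' @export
print.rat <- function(x, ...) {
  cat("<rat> ", paste(format(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
rep.rat <- function(x, ...) structure(list(n = rep(x$n, ...), d = rep(x$d, ...)), class = "rat")

#' Arithmetic and comparison for exact rationals
#'
#' @param e1,e2 `rat` vectors (or whole numbers / "p/q" strings, coerced).
#' @export
Ops.rat <- function(e1, e2) {
  if (missing(e2)) {
    x <- as_rational(e1)
    return(switch(.Generic,
      "-" = rat(-x$n, x$d),
      "+" = x,
      stop("unsupported unary op for rat: ", .Generic, call. = FALSE)))
  }
  x <- as_rational(e1); y <- as_rational(e2)
  switch(.Generic,
    "+" = rat(x$n * y$d + y$n * x$d, x$d * y$d),
    "-" = rat(x$n * y$d - y$n * x$d, x$d * y$d),
    "*" = rat(x$n * y$n, x$d * y$d),
    "/" = {
      if (any(y$n == 0)) stop("division by zero rational", call. = FALSE)
      rat(x$n * y$d, x$d * y$n)
    },
    "==" = x$n * y$d == y$n * x$d,
    "!=" = x$n * y$d != y$n * x$d,
    "<"  = x$n * y$d <  y$n * x$d,
    "<=" = x$n * y$d <= y$n * x$d,
    ">"  = x$n * y$d >  y$n * x$d,
    ">=" = x$n * y$d >= y$n * x$d,
    stop("unsupported op for rat: ", .Generic, call. = FALSE))
}

#' Sum an exact rational vector
#' @param x a `rat` vector.
#' @return A length-one `rat`.
#' @export
rat_sum <- function(x) {
  out <- rat(0)
  for (i in seq_along(x$n)) out <- out + x[i]
  out
}

rat_zero <- function(k) rat(rep(0, k))

# ---- integer-coefficient polynomials in eps -------------------------------
# Represented as plain numeric vectors p, with p[k] the coefficient of
# eps^(k-1). All coefficients are exact integers; products/sums stay exact
# well below 2^53 for the degree-<=8 polynomials arising from 4x4 chains.

ip_trim <- function(p) {
  nz <- which(p != 0)
  if (length(nz) == 0L) return(0)
  p[seq_len(max(nz))]
}

ip_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  ip_trim(a + b)
}

ip_sub <- function(a, b) ip_add(a, -b)

ip_mul <- function(a, b) {
  res <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    if (a[i] != 0) {
      idx <- i:(i + length(b) - 1L)
      res[idx] <- res[idx] + a[i] * b
    }
  }
  if (any(abs(res) >= .INT_MAX_EXACT)) stop("polynomial coefficient overflow", call. = FALSE)
  ip_trim(res)
}

ip_scale <- function(a, k) ip_trim(a * k)

ip_equal <- function(a, b) {
  d <- ip_sub(a, b)
  all(d == 0)
}

# order of the lowest nonzero term (0-based); Inf for the zero polynomial
ip_order <- function(p) {
  nz <- which(p != 0)
  if (length(nz) == 0L) return(Inf)
  nz[1] - 1L
}

# drop a factor eps^k
ip_shift <- function(p, k) {
  if (k == 0) return(p)
  stopifnot(length(p) > k, all(p[seq_len(k)] == 0))
  p[-seq_len(k)]
}

# evaluate integer polynomial at an exact rational (Horner)
ip_eval_rat <- function(p, x) {
  acc <- rat(0)
  for (k in rev(seq_along(p))) acc <- acc * x + rat(p[k])
  acc
}

# determinant of an n x n matrix of integer polynomials (list-matrix,
# column-major list of length n^2); Laplace expansion along the first row
ipm_det <- function(m, n) {
  if (n == 1L) return(m[[1]])
  det <- 0
  for (j in seq_len(n)) {
    a1j <- m[[(j - 1L) * n + 1L]]
    if (length(a1j) == 1L && a1j[1] == 0) next
    minor <- vector("list", (n - 1L)^2)
    mi <- 1L
    for (jj in seq_len(n)) {
      if (jj == j) next
      for (ii in 2:n) {
        minor[[mi]] <- m[[(jj - 1L) * n + ii]]
        mi <- mi + 1L
      }
    }
    # note: column-major fill keeps row/col structure of the minor
    term <- ip_mul(a1j, ipm_det_cm(minor, n - 1L))
    det <- if (j %% 2L == 1L) ip_add(det, term) else ip_sub(det, term)
  }
  det
}

# helper alias so the recursion reads clearly (minor built column-major)
ipm_det_cm <- function(m, n) ipm_det(m, n)

# ---- truncated power series with exact rational coefficients --------------

# N / D as a power series in eps up to `order`, where N, D are integer
# polynomials and D's lowest-order coefficient (after stripping the common
# eps^k factor) is nonzero. Returns a rat vector of length order + 1.
series_div <- function(N, D, order) {
  k <- ip_order(D)
  stopifnot(is.finite(k))
  nN <- ip_order(N)
  if (!is.finite(nN)) return(rat_zero(order + 1L))
  stopifnot(nN >= k)
  N <- ip_shift(N, k); D <- ip_shift(D, k)
  d0 <- rat(D[1])
  b <- rat_zero(order + 1L)
  for (j in 0:order) {
    aj <- if (j + 1L <= length(N)) rat(N[j + 1L]) else rat(0)
    acc <- aj
    if (j > 0) {
      for (i in 1:j) {
        di <- if (i + 1L <= length(D)) rat(D[i + 1L]) else rat(0)
        if (di$n != 0) acc <- acc - di * b[j - i + 1L]
      }
    }
    b[j + 1L] <- acc / d0
  }
  b
}
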