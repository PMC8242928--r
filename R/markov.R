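# Two-player Markov chain over joint states (CC, CD, DC, DD) and its exact
# stationary analysis. The error rate eps makes every transition probability a
# degree-2 integer polynomial in eps, so stationary probabilities are ratios
# of integer polynomials (Cramer's rule on the balance equations) and payoffs
# admit exact small-eps Taylor expansions with rational coefficients.

.engine_cache <- new.env(parent = emptyenv())

.cooperation_polys <- function(index) {
  d <- strategy_digits(index)
  lapply(d, function(b) if (b == 1) c(1, -1) else c(0, 1))  # 1-eps or eps
}

# next-state index from the two realised moves (1 = cooperate)
.next_state <- function(a, b) 1L + 2L * (1L - a) + (1L - b)

#' Transition matrix of a match between two strategies
#'
#' From state XY the focal player cooperates with probability given by their
#' perturbed prescription at XY, the co-player with their perturbed
#' prescription at YX, independently. Every entry is at least `epsilon^2`, so
#' for `epsilon > 0` the chain is irreducible and aperiodic and the stationary
#' distribution is unique.
#'
#' @param a,b strategy literals (index, bit-string or alias) for the focal
#'   player and co-player.
#' @param epsilon error rate in \[0, 1/2\].
#' @return A 4x4 row-stochastic matrix with rows/columns (CC, CD, DC, DD),
#'   state labels from the focal player's perspective.
#' @examples
#' transition_matrix("TFT", "TFT", 0.01)
#' @export
transition_matrix <- function(a, b, epsilon) {
  sA <- perturb_strategy(a, epsilon)
  sB <- perturb_strategy(b, epsilon)
  T <- matrix(0, 4, 4, dimnames = list(STATES, STATES))
  for (s in 1:4) {
    pA <- sA[s]; pB <- sB[.SWAP_IDX[s]]
    T[s, ] <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  }
  T
}

# column-major list of 16 integer polynomials in eps: T[row, col]
.transition_polys <- function(iA, iB) {
  pA <- .cooperation_polys(iA)
  pB <- .cooperation_polys(iB)
  one <- 1
  entries <- vector("list", 16L)
  for (s in 1:4) {
    qA <- pA[[s]]; qB <- pB[[.SWAP_IDX[s]]]
    nA <- ip_sub(one, qA); nB <- ip_sub(one, qB)
    row <- list(ip_mul(qA, qB), ip_mul(qA, nB), ip_mul(nA, qB), ip_mul(nA, nB))
    for (t in 1:4) entries[[(t - 1L) * 4L + s]] <- row[[t]]
  }
  entries
}

# numerators N_1..N_4 and common denominator D of the stationary distribution
# as integer polynomials in eps (Cramer's rule; sum(N_i) == D identically)
.stationary_polys <- function(iA, iB) {
  key <- paste0("sp_", iA, "_", iB)
  if (!is.null(.engine_cache[[key]])) return(.engine_cache[[key]])
  T <- .transition_polys(iA, iB)
  # M = t(T) - I, column-major: M[r, c] = T[c, r] - delta_rc
  M <- vector("list", 16L)
  for (r in 1:4) for (cc in 1:4) {
    e <- T[[(r - 1L) * 4L + cc]]  # T[cc, r]
    if (r == cc) e <- ip_sub(e, 1)
    M[[(cc - 1L) * 4L + r]] <- e
  }
  # A = rows 1..3 of M plus a row of ones; D = det(A)
  A <- vector("list", 16L)
  for (cc in 1:4) {
    for (r in 1:3) A[[(cc - 1L) * 4L + r]] <- M[[(cc - 1L) * 4L + r]]
    A[[(cc - 1L) * 4L + 4L]] <- 1
  }
  D <- ipm_det(A, 4L)
  N <- vector("list", 4L)
  for (i in 1:4) {
    B <- vector("list", 9L)
    bi <- 1L
    for (cc in 1:4) {
      if (cc == i) next
      for (r in 1:3) {
        B[[bi]] <- M[[(cc - 1L) * 4L + r]]
        bi <- bi + 1L
      }
    }
    s <- if (i %% 2L == 1L) -1 else 1
    N[[i]] <- ip_scale(ipm_det(B, 3L), s)
  }
  tot <- Reduce(ip_add, N)
  if (!ip_equal(tot, D)) stop("internal error: stationary numerators do not sum to denominator")
  out <- list(N = N, D = D)
  .engine_cache[[key]] <- out
  out
}

# exact small-eps series of v as a list of 4 rat vectors (length order + 1)
.stationary_series_rat <- function(iA, iB, order = 4L) {
  key <- paste0("ss_", iA, "_", iB, "_", order)
  if (!is.null(.engine_cache[[key]])) return(.engine_cache[[key]])
  sp <- .stationary_polys(iA, iB)
  out <- lapply(sp$N, series_div, D = sp$D, order = order)
  .engine_cache[[key]] <- out
  out
}

.stationary_num <- function(iA, iB, epsilon) {
  T <- transition_matrix(iA, iB, epsilon)
  A <- rbind((t(T) - diag(4))[1:3, ], rep(1, 4))
  v <- solve(A, c(0, 0, 0, 1))
  stats::setNames(v, STATES)
}

#' Stationary distribution of a match
#'
#' Long-run frequencies of the joint states (CC, CD, DC, DD) for two
#' memory-one strategies under implementation error. The default path solves
#' the balance equations numerically; `exact = TRUE` evaluates the exact
#' rational-function solution at a rational `epsilon` and reports the entries
#' as `"p/q"` strings alongside their numeric values.
#'
#' @inheritParams transition_matrix
#' @param epsilon error rate, strictly positive (at `epsilon = 0` the chain
#'   can be reducible; use [limit_stationary()] for the small-error limit).
#' @param exact evaluate the exact rational solution (requires a rational
#'   `epsilon`, e.g. `"1/100"`).
#' @return A tibble with columns `state`, `probability`, and (when
#'   `exact = TRUE`) `exact`.
#' @examples
#' stationary_dist("WSLS", "WSLS", 0.01)
#' stationary_dist(0, 0, "1/100", exact = TRUE)
#' @export
stationary_dist <- function(a, b, epsilon, exact = FALSE) {
  iA <- as_strategy(a); iB <- as_strategy(b)
  if (!exact) {
    eps <- if (is.character(epsilon)) as.double(as_rational(epsilon)) else epsilon
    stopifnot(eps > 0, eps <= 0.5)
    v <- .stationary_num(iA, iB, eps)
    if (any(v < -1e-12)) stop("internal error: negative stationary entry")
    return(tibble::tibble(state = STATES, probability = as.numeric(v)))
  }
  er <- as_rational(epsilon)
  stopifnot(as.double(er) > 0, as.double(er) <= 0.5)
  sp <- .stationary_polys(iA, iB)
  Dv <- ip_eval_rat(sp$D, er)
  vr <- rat_zero(4)
  for (i in 1:4) vr[i] <- ip_eval_rat(sp$N[[i]], er) / Dv
  tibble::tibble(state = STATES, probability = as.double(vr), exact = format(vr))
}

#' Small-error expansion of the stationary distribution
#'
#' Exact Taylor coefficients of each stationary probability around
#' `epsilon = 0`, computed from the rational-function solution.
#'
#' @inheritParams transition_matrix
#' @param order highest power of `epsilon` retained.
#' @return A tibble with columns `state`, `power`, `coef` (exact `"p/q"`
#'   string) and `coef_num`.
#' @export
stationary_series <- function(a, b, order = 4) {
  iA <- as_strategy(a); iB <- as_strategy(b)
  ser <- .stationary_series_rat(iA, iB, as.integer(order))
  purrr::map_dfr(1:4, function(i) {
    tibble::tibble(state = STATES[i], power = 0:order,
                   coef = format(ser[[i]]), coef_num = as.double(ser[[i]]))
  })
}

#' Small-error limit of the stationary distribution
#'
#' The entrywise `epsilon -> 0+` limit of the exact stationary solution,
#' together with each entry's leading-order term (e.g. `2 eps` or `eps^2` for
#' entries that vanish in the limit) and whether the state remains observable
#' (positive limit frequency) to an onlooker making finitely many
#' observations.
#'
#' @inheritParams transition_matrix
#' @param order series order used to locate leading terms of vanishing
#'   entries.
#' @return A tibble with columns `state`, `limit`, `limit_exact`,
#'   `leading_coef`, `leading_power`, `observable`.
#' @examples
#' limit_stationary("TFT", "TFT")   # uniform over the four states
#' limit_stationary(0, 0)           # AllD self-play: all mass on DD
#' @export
limit_stationary <- function(a, b, order = 6) {
  iA <- as_strategy(a); iB <- as_strategy(b)
  ser <- .stationary_series_rat(iA, iB, as.integer(order))
  rows <- purrr::map_dfr(1:4, function(i) {
    s <- ser[[i]]
    nz <- which(s$n != 0)
    if (length(nz) == 0L) stop("stationary entry vanished to tested order; raise `order`")
    lead <- s[nz[1]]
    tibble::tibble(
      state = STATES[i],
      limit = as.double(s[1]),
      limit_exact = format(s[1]),
      leading_coef = format(lead),
      leading_power = nz[1] - 1L,
      observable = s[1]$n != 0
    )
  })
  tot <- rat_sum(c(ser[[1]][1], ser[[2]][1], ser[[3]][1], ser[[4]][1]))
  if (!(tot == rat(1))) stop("internal error: stationary limits do not sum to 1")
  rows
}

#' Long-run payoff of one strategy against another
#'
#' The stationary distribution dotted with the payoff vector
#' `P = (1 - c, -c, 1, 0)`.
#'
#' @inheritParams stationary_dist
#' @param game an [game_params()] object.
#' @param exact use the exact rational path (rational `epsilon` required).
#' @return A single numeric payoff (per round, long-run average).
#' @examples
#' payoff("WSLS", "WSLS", 1e-4, game_params(0.2))
#' @export
payoff <- function(a, b, epsilon, game, exact = FALSE) {
  stopifnot(inherits(game, "ipd_game"))
  if (!exact) {
    v <- stationary_dist(a, b, epsilon)$probability
    return(sum(v * game$payoff))
  }
  pr <- payoff_exact(a, b, epsilon, game)
  as.double(pr)
}

#' Exact rational payoff at a rational error rate
#' @inheritParams payoff
#' @return A length-one `rat`.
#' @export
payoff_exact <- function(a, b, epsilon, game) {
  stopifnot(inherits(game, "ipd_game"))
  iA <- as_strategy(a); iB <- as_strategy(b)
  er <- as_rational(epsilon)
  sp <- .stationary_polys(iA, iB)
  Dv <- ip_eval_rat(sp$D, er)
  cr <- game$cost_rat
  P <- list(rat(1) - cr, -cr, rat(1), rat(0))
  acc <- rat(0)
  for (i in 1:4) acc <- acc + (ip_eval_rat(sp$N[[i]], er) / Dv) * P[[i]]
  acc
}

#' Exact small-error payoff series
#'
#' Taylor expansion at `epsilon = 0` of the long-run payoff of `a` against
#' `b`. Because the payoff vector is linear in the cooperation cost `c` and
#' the stationary distribution does not depend on it, each coefficient has the
#' exact form `const + cost_coef * c`. With `game = NULL` the series is kept
#' symbolic in `c`; with a game supplied the coefficients are evaluated at its
#' exact rational cost.
#'
#' @inheritParams transition_matrix
#' @param game optional [game_params()]; `NULL` keeps `c` symbolic.
#' @param order highest power of `epsilon` retained (default 2).
#' @return A `payoff_series` object; see [tidy.payoff_series()].
#' @examples
#' payoff_series("AllC", "TFT")        # (1 - c) - (2 - c) eps + O(eps^2)
#' payoff_series(0, 0, game_params(0.4))
#' @export
payoff_series <- function(a, b, game = NULL, order = 2) {
  iA <- as_strategy(a); iB <- as_strategy(b)
  order <- as.integer(order)
  ser <- .stationary_series_rat(iA, iB, order)
  const <- rat_zero(order + 1L); ccoef <- rat_zero(order + 1L)
  for (k in seq_len(order + 1L)) {
    const[k] <- ser[[1]][k] + ser[[3]][k]            # v_CC + v_DC
    ccoef[k] <- -(ser[[1]][k] + ser[[2]][k])         # -(v_CC + v_CD)
  }
  ps <- structure(list(const = const, ccoef = ccoef, order = order,
                       a = iA, b = iB, cost_rat = NULL), class = "payoff_series")
  if (!is.null(game)) ps <- ps_at_cost(ps, game)
  ps
}

# evaluate the linear-in-c coefficients at an exact rational cost;
# result is still a payoff_series but with ccoef folded in
ps_at_cost <- function(ps, game) {
  stopifnot(inherits(ps, "payoff_series"))
  cr <- if (inherits(game, "ipd_game")) game$cost_rat else as_rational(game)
  const <- ps$const + ps$ccoef * cr
  structure(list(const = const, ccoef = rat_zero(ps$order + 1L), order = ps$order,
                 a = ps$a, b = ps$b, cost_rat = cr), class = "payoff_series")
}

# exact rational coefficient vector of a cost-evaluated series
ps_coeffs <- function(ps) {
  stopifnot(!is.null(ps$cost_rat) || all(ps$ccoef$n == 0))
  ps$const
}

# numeric evaluation of the series at given eps (cost must be folded in)
ps_eval <- function(ps, epsilon) {
  co <- as.double(ps_coeffs(ps))
  sum(co * epsilon^(0:ps$order))
}

.fmt_lin <- function(a, b) {
  # pretty "a + b c" with exact rational a, b
  if (b$n == 0) return(format(a))
  bs <- if (b == rat(1)) "c" else if (b == rat(-1)) "-c" else paste0(format(b), " c")
  if (a$n == 0) return(bs)
  if (b$n > 0) paste0(format(a), " + ", bs) else
    paste0(format(a), " - ", sub("^-", "", bs))
}

#' @export
format.payoff_series <- function(x, ...) {
  terms <- character(0)
  for (k in 0:x$order) {
    a <- x$const[k + 1L]; b <- x$ccoef[k + 1L]
    if (a$n == 0 && b$n == 0) next
    lin <- .fmt_lin(a, b)
    if (grepl("[+-]", substr(lin, 2, nchar(lin)))) lin <- paste0("(", lin, ")")
    term <- if (k == 0) lin else if (k == 1) paste0(lin, " eps") else paste0(lin, " eps^", k)
    terms <- c(terms, term)
  }
  if (length(terms) == 0L) terms <- "0"
  paste0(paste(terms, collapse = " + "), " + O(eps^", x$order + 1L, ")")
}

#' @export
print.payoff_series <- function(x, ...) {
  cat("Payoff series d", x$a, " vs d", x$b,
      if (!is.null(x$cost_rat)) paste0(" at c = ", format(x$cost_rat)) else " (symbolic c)",
      ":\n  ", format(x), "\n", sep = "")
  invisible(x)
}

#' Tidy a payoff series
#'
#' @param x a `payoff_series` object.
#' @param ... unused.
#' @return A tibble with one row per power of `epsilon`: `power`, `constant`
#'   and `cost_coef` (exact strings), `constant_num`, `cost_coef_num`.
#' @export
tidy.payoff_series <- function(x, ...) {
  tibble::tibble(
    power = 0:x$order,
    constant = format(x$const),
    cost_coef = format(x$ccoef),
    constant_num = as.double(x$const),
    cost_coef_num = as.double(x$ccoef)
  )
}

# 16 x 16 tables of exact limit and eps^1 payoff coefficients, linear in c:
# component matrices (const, ccoef) for focal strategy (row) vs resident (col)
.payoff_tables <- function(order = 2L) {
  key <- paste0("pt_", order)
  if (!is.null(.engine_cache[[key]])) return(.engine_cache[[key]])
  tabs <- list()
  for (k in 0:order) {
    tabs[[k + 1L]] <- list(an = matrix(0, 16, 16), ad = matrix(1, 16, 16),
                           bn = matrix(0, 16, 16), bd = matrix(1, 16, 16))
  }
  for (ia in 0:15) for (ib in 0:15) {
    ps <- payoff_series(ia, ib, order = order)
    for (k in 0:order) {
      tabs[[k + 1L]]$an[ia + 1L, ib + 1L] <- ps$const[k + 1L]$n
      tabs[[k + 1L]]$ad[ia + 1L, ib + 1L] <- ps$const[k + 1L]$d
      tabs[[k + 1L]]$bn[ia + 1L, ib + 1L] <- ps$ccoef[k + 1L]$n
      tabs[[k + 1L]]$bd[ia + 1L, ib + 1L] <- ps$ccoef[k + 1L]$d
    }
  }
  .engine_cache[[key]] <- tabs
  tabs
}

# numeric 16 x 16 payoff-coefficient matrices at a given numeric cost;
# element [a+1, b+1] = coefficient of eps^k in payoff of focal a vs resident b
.payoff_coef_matrices <- function(cost, order = 2L) {
  tabs <- .payoff_tables(order)
  lapply(tabs, function(tt) tt$an / tt$ad + cost * tt$bn / tt$bd)
}
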