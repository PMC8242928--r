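# Best responses within the sixteen memory-one pure strategies, in the
# small-error sense: strategy a beats strategy b against a resident when its
# payoff is larger for every sufficiently small error rate, decided
# lexicographically on the exact series coefficients (limit first, then the
# eps^1 coefficient, and so on).

# lexicographic comparison of two exact rational coefficient vectors
# returns -1, 0, 1; 0 only when all compared coefficients are equal
.lex_cmp <- function(x, y) {
  stopifnot(length(x) == length(y))
  for (k in seq_along(x$n)) {
    if (x[k] < y[k]) return(-1L)
    if (x[k] > y[k]) return(1L)
  }
  0L
}

#' Compare two payoff series in the small-error order
#'
#' Lexicographic comparison: the `epsilon -> 0` limit decides first, then the
#' `epsilon^1` coefficient, and so on up to the common expansion order. Both
#' series must have their cost folded in (built with a `game`, or via an
#' exactly rational shared cost).
#'
#' @param a,b `payoff_series` objects expanded to the same order with the same
#'   cost.
#' @return `"a<b"`, `"a=b"` or `"a>b"`. Equality means every compared
#'   coefficient is exactly equal; for series produced by this package's exact
#'   engine that implies equality of the underlying rational functions to the
#'   expansion order.
#' @export
small_eps_compare <- function(a, b) {
  stopifnot(inherits(a, "payoff_series"), inherits(b, "payoff_series"),
            a$order == b$order)
  cmp <- .lex_cmp(ps_coeffs(a), ps_coeffs(b))
  c("a<b", "a=b", "a>b")[cmp + 2L]
}

# exact coefficient vectors (rat, length order+1) of all 16 candidate payoffs
# against `resident` at exact rational cost
.candidate_coeffs <- function(resident, cost_rat, order = 2L) {
  lapply(0:15, function(ia) {
    ps <- ps_at_cost(payoff_series(ia, resident, order = order), cost_rat)
    ps_coeffs(ps)
  })
}

# argmax under lexicographic order; returns indices (0-based strategies) of
# all exact co-maximisers plus the set tied with the max at the limit order
.lex_argmax <- function(coeffs) {
  best <- 1L
  for (i in 2:length(coeffs)) {
    if (.lex_cmp(coeffs[[i]], coeffs[[best]]) > 0L) best <- i
  }
  full_ties <- which(vapply(coeffs, function(x) .lex_cmp(x, coeffs[[best]]) == 0L, TRUE))
  limit_ties <- which(vapply(coeffs, function(x) x[1] == coeffs[[best]][1], TRUE))
  list(max = best - 1L, ties = full_ties - 1L, limit_ties = limit_ties - 1L)
}

#' Best response to a resident strategy in the small-error limit
#'
#' Enumerates all sixteen memory-one pure strategies against the resident and
#' returns the maximiser(s) of the exact payoff series under the lexicographic
#' small-error order. At a critical cost the limit payoffs of two candidates
#' tie; the tie is reported (`at_threshold`, `limit_ties`) rather than
#' silently resolved, and if candidates are exactly equal to the expansion
#' order all of them are returned.
#'
#' @param resident strategy literal for the monomorphic resident.
#' @param game a [game_params()] object.
#' @param order series order used for the comparison (default 2).
#' @return A list of class `br_record`: `resident`, `responders` (indices),
#'   `payoff` (`payoff_series` of the maximiser), `is_self`, `at_threshold`,
#'   `limit_ties`.
#' @examples
#' best_response("TFT", game_params(0.3))   # AllC
#' best_response(8, game_params(0.4))$is_self
#' @export
best_response <- function(resident, game, order = 2) {
  stopifnot(inherits(game, "ipd_game"))
  ir <- as_strategy(resident)
  coeffs <- .candidate_coeffs(ir, game$cost_rat, as.integer(order))
  am <- .lex_argmax(coeffs)
  sym <- lapply(am$limit_ties, function(i) payoff_series(i, ir, order = 0))
  structure(list(
    resident = ir,
    responders = am$ties,
    payoff = ps_at_cost(payoff_series(am$max, ir, order = order), game$cost_rat),
    is_self = ir %in% am$ties,
    at_threshold = .limit_tie_is_critical(sym),
    limit_ties = am$limit_ties
  ), class = "br_record")
}

#' @export
print.br_record <- function(x, ...) {
  if (is.na(x$resident)) {
    cat("Best-looking response: ", paste0("d", x$responders, collapse = ", "), "\n", sep = "")
    if (!is.null(x$payoff)) cat("  expected payoff: ", format(x$payoff), "\n", sep = "")
    if (x$at_threshold) {
      cat("  note: limit-payoff tie among d", paste(x$limit_ties, collapse = ", d"), "\n", sep = "")
    }
    return(invisible(x))
  }
  cat("Best response to d", x$resident, ": ",
      paste0("d", x$responders, collapse = ", "),
      if (isTRUE(x$is_self)) " (self)" else "", "\n", sep = "")
  if (!is.null(x$payoff)) cat("  payoff: ", format(x$payoff), "\n", sep = "")
  if (x$at_threshold) {
    cat("  note: limit-payoff tie among d", paste(x$limit_ties, collapse = ", d"),
        " (cost at or near a critical value)\n", sep = "")
  }
  invisible(x)
}

#' Best-response table over all sixteen residents
#'
#' One row per resident strategy: its best response(s), the payoff series of
#' the best response, and whether the resident is a best response to itself
#' (i.e. a symmetric Nash equilibrium within the memory-one pure strategies).
#'
#' @param game a [game_params()] object.
#' @param order series order for the comparison.
#' @return A tibble with columns `resident`, `resident_name`, `responders`
#'   (list of indices), `responder` (first maximiser), `responder_name`,
#'   `payoff_limit`, `payoff_eps1` (exact strings), `payoff_limit_num`,
#'   `payoff_eps1_num`, `is_self`, `at_threshold`, and `series` (pretty form).
#' @examples
#' response_table(game_params(0.4))
#' @export
response_table <- function(game, order = 2) {
  recs <- lapply(0:15, best_response, game = game, order = order)
  purrr::map_dfr(recs, function(r) {
    co <- ps_coeffs(r$payoff)
    tibble::tibble(
      resident = r$resident,
      resident_name = strategy_name(r$resident),
      responders = list(r$responders),
      responder = r$responders[1],
      responder_name = strategy_name(r$responders[1]),
      payoff_limit = format(co[1]),
      payoff_eps1 = format(co[2]),
      payoff_limit_num = as.double(co[1]),
      payoff_eps1_num = as.double(co[2]),
      is_self = r$is_self,
      at_threshold = r$at_threshold,
      series = format(r$payoff)
    )
  })
}

#' Directed best-response graph
#'
#' Edges resident -> best responder over all sixteen strategies; following
#' the edges traces the best-response dynamics, whose fixed points are the
#' symmetric Nash equilibria.
#'
#' @inheritParams response_table
#' @return A tibble of edges with columns `from`, `to`, `from_name`,
#'   `to_name`, `self_loop`.
#' @seealso [graph_dot()] for a DOT-format export.
#' @export
response_graph <- function(game, order = 2) {
  tb <- response_table(game, order = order)
  tidyr::unnest(
    dplyr::transmute(tb, from = .data$resident, to = .data$responders),
    "to"
  ) |>
    dplyr::mutate(
      from_name = strategy_name(.data$from),
      to_name = strategy_name(.data$to),
      self_loop = .data$from == .data$to
    )
}

#' DOT export of a best-response graph
#' @param edges an edge tibble from [response_graph()].
#' @return A single string in Graphviz DOT format.
#' @export
graph_dot <- function(edges) {
  lab <- function(i, nm) ifelse(is.na(nm), paste0("d", i), paste0("d", i, " (", nm, ")"))
  lines <- sprintf("  \"%s\" -> \"%s\";", lab(edges$from, edges$from_name),
                   lab(edges$to, edges$to_name))
  paste0("digraph best_response {\n", paste(lines, collapse = "\n"), "\n}\n")
}

# a tie of limit payoffs at a fixed cost is only a *critical-cost* tie when
# the tied strategies' limit payoffs differ as linear functions of c — if the
# functions are identical the tie is structural and holds at every cost
.limit_tie_is_critical <- function(sym_list) {
  if (length(sym_list) < 2L) return(FALSE)
  a0 <- sym_list[[1]]$const[1]; b0 <- sym_list[[1]]$ccoef[1]
  for (s in sym_list[-1]) {
    if (!(s$const[1] == a0) || !(s$ccoef[1] == b0)) return(TRUE)
  }
  FALSE
}

# solve a + b*c == a2 + b2*c exactly in c; NULL when the two linear functions
# are parallel or identical
.lin_cross <- function(a, b, a2, b2) {
  if (b == b2) return(NULL)
  (a - a2) / (b2 - b)
}

# generic exact crossing finder: `coef_fun(cost_rat)` must return the list of
# 16 exact coefficient vectors; finds the cost in (lo, hi) where the argmax
# switches, by solving the first-order coefficient equality of the two
# competitors as symbolic linear functions of c
.critical_cost_generic <- function(sym_coeffs, lo, hi, order = 2L) {
  # sym_coeffs: list of 16 entries, each list(const = rat vec, ccoef = rat vec)
  at_cost <- function(cr) lapply(sym_coeffs, function(s) s$const + s$ccoef * cr)
  lo_r <- as_rational(lo); hi_r <- as_rational(hi)
  w_lo <- .lex_argmax(at_cost(lo_r))$max
  w_hi <- .lex_argmax(at_cost(hi_r))$max
  if (w_lo == w_hi) stop("argmax does not differ between lo and hi", call. = FALSE)
  s1 <- sym_coeffs[[w_lo + 1L]]; s2 <- sym_coeffs[[w_hi + 1L]]
  for (k in seq_len(order + 1L)) {
    identical_fun <- s1$const[k] == s2$const[k] && s1$ccoef[k] == s2$ccoef[k]
    if (identical_fun) next
    cr <- .lin_cross(s1$const[k], s1$ccoef[k], s2$const[k], s2$ccoef[k])
    if (is.null(cr)) next  # parallel at this order: ordering never flips here
    if (cr > lo_r && cr < hi_r) {
      # confirm: on each side of cr the respective competitor wins
      mid_lo <- (lo_r + cr) / rat(2); mid_hi <- (cr + hi_r) / rat(2)
      ok <- .lex_argmax(at_cost(mid_lo))$max == w_lo &&
            .lex_argmax(at_cost(mid_hi))$max == w_hi
      if (!ok) {
        stop("more than one argmax switch in the bracket; narrow it", call. = FALSE)
      }
      return(list(critical = cr, low_side = w_lo, high_side = w_hi, order = k - 1L))
    }
  }
  stop("no crossing of the two competitors found inside the bracket", call. = FALSE)
}

.sym_candidate_coeffs <- function(resident, order = 2L) {
  lapply(0:15, function(ia) {
    ps <- payoff_series(ia, resident, order = order)
    list(const = ps$const, ccoef = ps$ccoef)
  })
}

#' Critical cooperation cost where a best response switches
#'
#' Finds the exact rational cost at which the best response to a resident
#' flips between two strategies, by solving the equality of the competitors'
#' payoff coefficients (which are linear functions of the cost) at the first
#' series order where they differ.
#'
#' @param resident strategy literal.
#' @param lo,hi bracket costs with different best responses.
#' @param order series order used.
#' @return A list of class `cost_threshold`: `critical` (exact `rat`),
#'   `critical_num`, `low_side` and `high_side` (the competing responders),
#'   `order` (series order deciding the flip).
#' @examples
#' critical_cost(8, 0.1, 0.9)   # 1/3: Grim-Trigger-1 gains its self-response
#' critical_cost(9, 0.1, 0.9)   # 1/2: WSLS loses its self-response
#' @export
critical_cost <- function(resident, lo = 0.05, hi = 0.95, order = 2) {
  ir <- as_strategy(resident)
  res <- .critical_cost_generic(.sym_candidate_coeffs(ir, as.integer(order)),
                                lo, hi, as.integer(order))
  structure(c(list(resident = ir, critical_num = as.double(res$critical)), res),
            class = "cost_threshold")
}

#' @export
print.cost_threshold <- function(x, ...) {
  cat("Critical cost c* = ", format(x$critical),
      "  (d", x$low_side, " below, d", x$high_side, " above; decided at eps^",
      x$order, ")\n", sep = "")
  invisible(x)
}

#' Best response to a fixed mixed (behaviour) strategy
#'
#' The resident plays a point `q` of the behaviour-strategy hypercube: a
#' cooperation probability per state, used as-is (error, if any, is already
#' folded into `q`). Each pure candidate is perturbed by `epsilon` and its
#' long-run payoff against `q` computed numerically; the argmax is returned.
#' Near-ties within `tol` are all reported, so genuinely non-generic residents
#' are flagged rather than silently resolved.
#'
#' @param q numeric vector of 4 cooperation probabilities over
#'   (CC, CD, DC, DD).
#' @param game a [game_params()] object.
#' @param epsilon error rate applied to the pure candidates.
#' @param tol absolute payoff tolerance for reporting ties.
#' @return A list: `responders` (indices of maximisers within `tol`),
#'   `payoffs` (all 16 payoffs), `unique` (single maximiser flag).
#' @export
best_response_mixed <- function(q, game, epsilon, tol = 1e-10) {
  stopifnot(inherits(game, "ipd_game"), length(q) == 4L, all(q >= 0), all(q <= 1),
            epsilon > 0, epsilon <= 0.5)
  pay <- vapply(0:15, function(ia) {
    sA <- perturb_strategy(ia, epsilon)
    T <- matrix(0, 4, 4)
    for (s in 1:4) {
      pA <- sA[s]; pB <- q[.SWAP_IDX[s]]
      T[s, ] <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
    }
    A <- rbind((t(T) - diag(4))[1:3, ], rep(1, 4))
    v <- solve(A, c(0, 0, 0, 1))
    sum(v * game$payoff)
  }, 0)
  top <- max(pay)
  responders <- which(pay >= top - tol) - 1L
  list(responders = responders, payoffs = stats::setNames(pay, paste0("d", 0:15)),
       unique = length(responders) == 1L)
}
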