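# The Bayesian observer: what a monomorphic population's stationary behaviour
# reveals about its strategy, how a prior over candidate strategies updates
# with observed (state, move) records, and which strategy looks best under
# the resulting belief. Self-confirming equilibria (SCE) are residents whose
# best-looking response is themselves; SCENEs are SCE and Nash at once.

#' Beliefs over the sixteen strategies
#'
#' A belief is a tibble with columns `strategy` (index 0-15) and `weight`
#' (non-negative, summing to 1). `belief_uniform()` spreads mass uniformly
#' over a support set; `belief_point()` is a point mass.
#'
#' @param support strategy literals to carry positive mass.
#' @return A belief tibble.
#' @examples
#' belief_uniform(c(0, 6, 8))
#' @export
belief_uniform <- function(support) {
  idx <- vapply(support, as_strategy, 0L)
  stopifnot(!anyDuplicated(idx))
  tibble::tibble(strategy = idx, weight = rep(1 / length(idx), length(idx)))
}

#' @rdname belief_uniform
#' @param strategy a single strategy literal.
#' @export
belief_point <- function(strategy) {
  tibble::tibble(strategy = as_strategy(strategy), weight = 1)
}

.check_belief <- function(belief) {
  stopifnot(is.data.frame(belief), all(c("strategy", "weight") %in% names(belief)),
            all(belief$weight >= 0), abs(sum(belief$weight) - 1) < 1e-9)
  belief
}

#' Classify a strategy's self-play signature
#'
#' In a monomorphic population the observable footprint of the resident
#' strategy is the small-error limit of its self-play stationary
#' distribution. States with positive limit frequency are observable after
#' `M >> 1` observations, and the prescriptions at those states are
#' identifiable. Categories: I — three or four observable states, so the
#' strategy can be singled out; II — two observable states, several
#' candidates remain but they share one best response; III — a single
#' observable state (all-defect- or all-cooperate-looking populations), where
#' real uncertainty persists unless `M >> 1/eps`.
#'
#' @param strategy a strategy literal.
#' @return A list of class `signature_report`: `strategy`, `limit` (numeric
#'   4-vector), `limit_exact`, `observable_states`, `identifiable_digits`
#'   (named 0/1 vector at observable states), `category`.
#' @examples
#' classify_signature("WSLS")$category   # "III"
#' @export
classify_signature <- function(strategy) {
  i <- as_strategy(strategy)
  ls <- limit_stationary(i, i)
  obs <- ls$state[ls$observable]
  digits <- strategy_digits(i)
  n_obs <- length(obs)
  category <- if (n_obs >= 3L) "I" else if (n_obs == 2L) "II" else "III"
  structure(list(
    strategy = i,
    limit = stats::setNames(ls$limit, ls$state),
    limit_exact = stats::setNames(ls$limit_exact, ls$state),
    observable_states = obs,
    identifiable_digits = stats::setNames(digits[match(obs, STATES)], obs),
    category = category
  ), class = "signature_report")
}

#' @export
print.signature_report <- function(x, ...) {
  cat("d", x$strategy, " self-play signature: v = (",
      paste(x$limit_exact, collapse = ", "), ")\n  observable states: ",
      paste(x$observable_states, collapse = ", "), "  -> Category ", x$category,
      "\n", sep = "")
  invisible(x)
}

#' Signature table over all strategies
#'
#' @return A tibble with one row per strategy: limit stationary entries,
#'   number of observable states, and category.
#' @export
signature_table <- function() {
  purrr::map_dfr(0:15, function(i) {
    s <- classify_signature(i)
    tibble::tibble(
      strategy = i, name = strategy_name(i),
      v_cc = s$limit[["CC"]], v_cd = s$limit[["CD"]],
      v_dc = s$limit[["DC"]], v_dd = s$limit[["DD"]],
      n_observable = length(s$observable_states),
      category = s$category
    )
  })
}

#' Candidate strategies consistent with an observed signature
#'
#' All strategies whose self-play limit signature equals the observed limit
#' distribution and whose prescriptions agree with any observed moves at
#' observable states. Prescriptions at states never observed are
#' unconstrained.
#'
#' @param observed_limit numeric 4-vector over (CC, CD, DC, DD) — the
#'   observed limiting state frequencies (must match some strategy's
#'   signature exactly, up to rational reconstruction), or a tibble from
#'   [limit_stationary()].
#' @param observed_moves optional named vector of observed prescriptions at
#'   states, e.g. `c(DD = 0)` or `c(CD = "D")` (1/"C" cooperate, 0/"D"
#'   defect).
#' @return Integer vector of candidate strategy indices.
#' @examples
#' candidate_set(c(0, 0, 0, 1))            # d0, d6, d8
#' candidate_set(c(0, 1/4, 1/4, 1/2))      # d2, d4
#' @export
candidate_set <- function(observed_limit, observed_moves = NULL) {
  if (is.data.frame(observed_limit)) observed_limit <- observed_limit$limit
  stopifnot(length(observed_limit) == 4L)
  obs_r <- as_rational(observed_limit)
  if (!(rat_sum(obs_r) == rat(1))) stop("observed limit frequencies must sum to 1")
  moves <- NULL
  if (!is.null(observed_moves)) {
    mv <- observed_moves
    if (is.character(mv)) mv <- ifelse(toupper(mv) == "C", 1L, 0L)
    moves <- stats::setNames(as.integer(mv), names(observed_moves))
    stopifnot(all(names(moves) %in% STATES))
  }
  hits <- integer(0)
  for (i in 0:15) {
    sig <- classify_signature(i)
    sig_r <- as_rational(unname(sig$limit_exact))
    if (!all(sig_r == obs_r)) next
    if (!is.null(moves)) {
      chk <- intersect(names(moves), sig$observable_states)
      d <- strategy_digits(i)
      if (length(chk) > 0L && !all(d[match(chk, STATES)] == moves[chk])) next
    }
    hits <- c(hits, i)
  }
  if (length(hits) == 0L) {
    stop("no strategy's self-play signature is consistent with the observation",
         call. = FALSE)
  }
  hits
}

#' Bayesian posterior over strategies from observed records
#'
#' Each observation record is a state (from the acting player's perspective)
#' and that player's realised next move. Under candidate strategy `d` with
#' error rate `epsilon`, the likelihood of a cooperative move at state XY is
#' the perturbed prescription there; records are conditionally independent,
#' so sequential single-record updates and one batch update coincide.
#'
#' @param observations a data frame with columns `state`
#'   (`"CC","CD","DC","DD"`) and `move` (`"C"`/`"D"`), e.g. from
#'   [sample_observations()].
#' @param prior a belief tibble (see [belief_uniform()]).
#' @param epsilon error rate in (0, 1/2).
#' @return A belief tibble with posterior weights; log-likelihoods per
#'   candidate are attached as attribute `log_lik`.
#' @export
posterior_update <- function(observations, prior, epsilon) {
  .check_belief(prior)
  stopifnot(is.data.frame(observations), epsilon > 0, epsilon < 0.5)
  if (nrow(observations) == 0L) return(prior)
  stopifnot(all(c("state", "move") %in% names(observations)),
            all(observations$state %in% STATES),
            all(observations$move %in% c("C", "D")))
  n_c <- n_d <- stats::setNames(numeric(4), STATES)
  tabC <- table(factor(observations$state[observations$move == "C"], levels = STATES))
  tabD <- table(factor(observations$state[observations$move == "D"], levels = STATES))
  n_c[] <- as.numeric(tabC); n_d[] <- as.numeric(tabD)
  ll <- vapply(prior$strategy, function(i) {
    p <- perturb_strategy(i, epsilon)
    sum(n_c * log(p) + n_d * log1p(-p))
  }, 0)
  lw <- log(prior$weight) + ll
  lw <- lw - max(lw)
  w <- exp(lw); w <- w / sum(w)
  out <- tibble::tibble(strategy = prior$strategy, weight = w)
  attr(out, "log_lik") <- stats::setNames(ll, paste0("d", prior$strategy))
  out
}

# exact symbolic expected-payoff coefficients for the 16 candidates under a
# belief with exactly rational weights: list of list(const, ccoef) rat vectors
.sym_expected_coeffs <- function(belief, order = 2L) {
  w <- as_rational(belief$weight)
  lapply(0:15, function(ia) {
    const <- rat_zero(order + 1L); ccoef <- rat_zero(order + 1L)
    for (j in seq_along(belief$strategy)) {
      ps <- payoff_series(ia, belief$strategy[j], order = order)
      const <- const + ps$const * w[j]
      ccoef <- ccoef + ps$ccoef * w[j]
    }
    list(const = const, ccoef = ccoef)
  })
}

#' Expected payoff of a candidate strategy under a belief
#'
#' The belief-weighted average of the candidate's exact payoff series against
#' each strategy in the belief's support; linear in the belief. Weights are
#' reconstructed as exact rationals when possible (e.g. uniform 1/3), so the
#' result is an exact series; otherwise the averaging is done in floating
#' point on the exact per-resident coefficients.
#'
#' @param candidate strategy literal.
#' @param belief a belief tibble.
#' @param game optional [game_params()]; `NULL` keeps the cost symbolic
#'   (exact weights required).
#' @param order series order.
#' @return A `payoff_series` object.
#' @examples
#' expected_payoff("WSLS", belief_uniform(c(0, 6, 8)), game_params(0.3))
#' @export
expected_payoff <- function(candidate, belief, game = NULL, order = 2) {
  .check_belief(belief)
  ia <- as_strategy(candidate)
  order <- as.integer(order)
  w <- as_rational(belief$weight)
  const <- rat_zero(order + 1L); ccoef <- rat_zero(order + 1L)
  for (j in seq_along(belief$strategy)) {
    ps <- payoff_series(ia, belief$strategy[j], order = order)
    const <- const + ps$const * w[j]
    ccoef <- ccoef + ps$ccoef * w[j]
  }
  ps <- structure(list(const = const, ccoef = ccoef, order = order,
                       a = ia, b = NA_integer_, cost_rat = NULL),
                  class = "payoff_series")
  if (!is.null(game)) ps <- ps_at_cost(ps, game)
  ps
}

#' Best-looking response under a belief
#'
#' The strategy that maximises the expected payoff under the observer's
#' belief, in the small-error limit: the `epsilon -> 0` limits decide first
#' and coefficient ties are broken by higher-order terms; an exact limit tie
#' at a critical cost is reported, not resolved.
#'
#' @param belief a belief tibble.
#' @param game a [game_params()] object.
#' @param order series order.
#' @return A list of class `br_record` (as [best_response()]), with
#'   `resident = NA`.
#' @examples
#' best_looking_response(belief_uniform(c(0, 6, 8)), game_params(0.3))  # WSLS
#' @export
best_looking_response <- function(belief, game, order = 2) {
  .check_belief(belief)
  stopifnot(inherits(game, "ipd_game"))
  order <- as.integer(order)
  # exact path only for beliefs with genuinely small-denominator weights
  # (uniform priors and the like); Monte-Carlo posteriors go numeric
  w_rat <- tryCatch(as_rational(belief$weight, max_den = 1e4), error = function(e) NULL)
  if (!is.null(w_rat) && max(abs(as.double(w_rat) - belief$weight)) > 1e-13) w_rat <- NULL
  if (is.null(w_rat)) {
    # generic numeric weights (e.g. a Monte-Carlo posterior): lexicographic
    # argmax on the exact per-resident coefficients, averaged in floating point
    coefs <- .payoff_coef_matrices(game$cost, order = order)
    sc <- vapply(coefs, function(M) as.numeric(M[, belief$strategy + 1L, drop = FALSE] %*%
                                                belief$weight), numeric(16))
    keep <- which(sc[, 1] >= max(sc[, 1]) - 1e-11)
    limit_ties <- keep - 1L
    for (k in 2:(order + 1L)) {
      if (length(keep) == 1L) break
      keep <- keep[sc[keep, k] >= max(sc[keep, k]) - 1e-11]
    }
    return(structure(list(
      resident = NA_integer_, responders = keep - 1L, payoff = NULL,
      is_self = NA, at_threshold = length(limit_ties) > 1L,
      limit_ties = limit_ties
    ), class = "br_record"))
  }
  sym <- .sym_expected_coeffs(belief, order)
  coeffs <- lapply(sym, function(s) s$const + s$ccoef * game$cost_rat)
  am <- .lex_argmax(coeffs)
  pay <- expected_payoff(am$max, belief, game = game, order = order)
  structure(list(
    resident = NA_integer_,
    responders = am$ties,
    payoff = pay,
    is_self = NA,
    at_threshold = .limit_tie_is_critical(sym[am$limit_ties + 1L]),
    limit_ties = am$limit_ties
  ), class = "br_record")
}

#' Critical cost at which the best-looking response switches
#'
#' Solves exactly for the cooperation cost where the belief-weighted limit
#' payoffs of the two competing responses cross. Under the uniform belief
#' over an all-defect-looking population's candidates `{d0, d6, d8}` the
#' switch (WSLS below, Grim-Trigger-1 above) sits at 16/33; under the uniform
#' belief over an all-cooperate-looking population's candidates
#' `{d9, d14, d15}` the switch (WSLS below, d1 above) sits at 2/9.
#'
#' @param belief a belief tibble with exactly rational weights.
#' @param lo,hi bracket costs with different best-looking responses.
#' @param order series order.
#' @return A `cost_threshold` list (see [critical_cost()]).
#' @examples
#' belief_switch_cost(belief_uniform(c(0, 6, 8)))     # 16/33
#' belief_switch_cost(belief_uniform(c(9, 14, 15)))   # 2/9
#' @export
belief_switch_cost <- function(belief, lo = 0.05, hi = 0.95, order = 2) {
  .check_belief(belief)
  res <- .critical_cost_generic(.sym_expected_coeffs(belief, as.integer(order)),
                                lo, hi, as.integer(order))
  structure(c(list(resident = NA_integer_, critical_num = as.double(res$critical)), res),
            class = "cost_threshold")
}

#' Cost above which the WSLS prior region disappears
#'
#' Over priors on an all-cooperate-looking population's candidates
#' `{d9, d14, d15}`, the WSLS-winning region (when non-empty) always reaches
#' priors arbitrarily close to the point mass on `d9`: the region's bounding
#' condition is loosest there. The region is therefore non-empty exactly
#' while WSLS beats every alternative against a point-mass-on-`d9` belief;
#' this function returns the exact cost at which the strongest alternative
#' catches up — the feasibility bound of the WSLS region. The region maps in
#' [simplex_region()] provide the independent check on either side of the
#' bound.
#'
#' @param support candidate support (default `c(9, 14, 15)`).
#' @param order series order.
#' @return A length-one `rat` (1/2 for the default support).
#' @export
wsls_feasibility_cost <- function(support = c(9, 14, 15), order = 2) {
  idx <- vapply(support, as_strategy, 0L)
  stopifnot(9 %in% idx)
  # point mass on d9: limit payoff of each alternative vs d9, linear in c
  ps9 <- payoff_series(9, 9, order = order)
  best <- NULL
  for (alt in setdiff(0:15, 9L)) {
    psa <- payoff_series(alt, 9, order = order)
    cr <- .lin_cross(ps9$const[1], ps9$ccoef[1], psa$const[1], psa$ccoef[1])
    if (is.null(cr) || cr <= rat(0) || cr >= rat(1)) next
    # keep crossings where the alternative overtakes above cr
    above <- (psa$const[1] + psa$ccoef[1] * ((cr + rat(1)) / rat(2))) >
             (ps9$const[1] + ps9$ccoef[1] * ((cr + rat(1)) / rat(2)))
    if (!above) next
    if (is.null(best) || cr < best) best <- cr
  }
  if (is.null(best)) stop("no alternative ever overtakes WSLS in (0,1)")
  best
}

#' Map the best-looking response across a prior simplex
#'
#' For a three-strategy candidate support, evaluates the best-looking
#' response on a barycentric grid of priors and locates the boundaries
#' between adjacent regions by bisection on the competitors' expected-payoff
#' difference.
#'
#' @param support three strategy literals spanning the prior simplex.
#' @param game a [game_params()] object.
#' @param step barycentric grid step (default 0.01).
#' @param boundary_tol bisection tolerance for boundary points.
#' @return An object of class `simplex_region`: `grid` (tibble `f1,f2,f3`,
#'   `winner`), `boundary` (tibble of located boundary points with the two
#'   adjacent winners), `support`, `cost`, `step`.
#' @examples
#' simplex_region(c(0, 6, 8), game_params(0.2), step = 0.05)
#' @export
simplex_region <- function(support, game, step = 0.01, boundary_tol = 1e-6) {
  idx <- vapply(support, as_strategy, 0L)
  stopifnot(length(idx) == 3L, !anyDuplicated(idx), inherits(game, "ipd_game"))
  coefs <- .payoff_coef_matrices(game$cost, order = 2L)
  L <- coefs[[1]][, idx + 1L, drop = FALSE]   # 16 x 3 limit payoffs
  E1 <- coefs[[2]][, idx + 1L, drop = FALSE]  # eps^1 coefficients
  E2 <- coefs[[3]][, idx + 1L, drop = FALSE]
  winner_of <- function(fm) {
    # fm: 3 x n matrix of priors; lexicographic argmax per column
    s0 <- L %*% fm; s1 <- E1 %*% fm; s2 <- E2 %*% fm
    apply(rbind(s0, s1, s2), 2, function(col) {
      m0 <- matrix(col, nrow = 16L)
      keep <- which(m0[, 1] >= max(m0[, 1]) - 1e-11)
      for (k in 2:3) {
        if (length(keep) == 1L) break
        keep <- keep[m0[keep, k] >= max(m0[keep, k]) - 1e-11]
      }
      keep[1] - 1L
    })
  }
  # open simplex only (0 < f_i < 1): on the closed edges the limit expected
  # payoffs of several candidates coincide identically and the choice is an
  # O(eps) tie-break outside the scope of the region picture
  gseq <- seq(step, 1 - step, by = step)
  grid <- expand.grid(f1 = gseq, f2 = gseq)
  grid <- grid[grid$f1 + grid$f2 <= 1 - step + 1e-12, ]
  grid$f3 <- pmax(0, 1 - grid$f1 - grid$f2)
  fm <- t(as.matrix(grid[, c("f1", "f2", "f3")]))
  grid$winner <- winner_of(fm)
  grid <- tibble::as_tibble(grid)

  # boundary location between adjacent cells with different winners, by
  # recursive subdivision: if a third region lies between the two cells the
  # segment is split so every reported point is a genuine two-region boundary
  key <- function(a, b) paste(round(a / step), round(b / step))
  wmap <- stats::setNames(grid$winner, key(grid$f1, grid$f2))
  bnd <- list()
  refine <- function(p, q, wp, wq, depth = 0L) {
    if (wp == wq) return()
    if (sqrt(sum((p - q)^2)) <= boundary_tol) {
      m <- (p + q) / 2
      bnd[[length(bnd) + 1L]] <<- tibble::tibble(
        f1 = m[1], f2 = m[2], f3 = m[3],
        winner_a = unname(wp), winner_b = unname(wq))
      return()
    }
    m <- (p + q) / 2
    wm <- winner_of(matrix(m, ncol = 1))
    if (wm != wp && wm != wq && depth < 4L) {
      refine(p, m, wp, wm, depth + 1L)
      refine(m, q, wm, wq, depth + 1L)
    } else if (wm == wp) {
      refine(m, q, wp, wq, depth)
    } else {
      refine(p, m, wp, wm, depth)
    }
  }
  for (r in seq_len(nrow(grid))) {
    f1 <- grid$f1[r]; f2 <- grid$f2[r]; w <- grid$winner[r]
    for (nb in list(c(f1 + step, f2), c(f1, f2 + step))) {
      wn <- wmap[key(nb[1], nb[2])]
      if (is.na(wn) || wn == w) next
      refine(c(f1, f2, 1 - f1 - f2), c(nb[1], nb[2], 1 - nb[1] - nb[2]), w, wn)
    }
  }
  boundary <- if (length(bnd)) dplyr::bind_rows(bnd) else
    tibble::tibble(f1 = double(), f2 = double(), f3 = double(),
                   winner_a = integer(), winner_b = integer())
  structure(list(grid = grid, boundary = boundary, support = idx,
                 cost = game$cost, step = step), class = "simplex_region")
}

#' @export
print.simplex_region <- function(x, ...) {
  shares <- sort(table(factor(paste0("d", x$grid$winner))), decreasing = TRUE)
  cat("Prior-simplex region map over {",
      paste0("d", x$support, collapse = ", "), "} at c = ", x$cost,
      " (step ", x$step, ")\n", sep = "")
  print(round(shares / nrow(x$grid), 3))
  invisible(x)
}

#' Closed-form WSLS-region conditions for the two canonical supports
#'
#' For the all-defect-looking support `{d0, d6, d8}` (prior `(f0, f6, f8)`)
#' WSLS wins exactly when both
#' `f6 > f8/3 - 5c/(4 + 3c)` and
#' `f6 > 3c/(2 + 3c) - (3/5) (2 - c)/(2 + 3c) f8` hold; for the
#' all-cooperate-looking support `{d9, d14, d15}` (prior `(f9, f14, f15)`)
#' when `f9 > (c/(1 - c)) (1 + f15/2)`. These are used as independent ground
#' truth to validate the argmax-based region maps.
#'
#' @param support either `c(0, 6, 8)` or `c(9, 14, 15)`.
#' @param game a [game_params()] object.
#' @return A list of functions: `holds(f)` (logical, `f` a barycentric
#'   3-vector in support order) and `residual(f)` (smallest absolute slack of
#'   the bounding equalities at `f`).
#' @export
wsls_prior_condition <- function(support, game) {
  idx <- vapply(support, as_strategy, 0L)
  cc <- game$cost
  if (identical(sort(idx), c(0L, 6L, 8L))) {
    # f = (f0, f6, f8)
    rhs1 <- function(f8) f8 / 3 - 5 * cc / (4 + 3 * cc)
    rhs2 <- function(f8) 3 * cc / (2 + 3 * cc) - (3 / 5) * (2 - cc) / (2 + 3 * cc) * f8
    list(
      holds = function(f) f[2] > rhs1(f[3]) && f[2] > rhs2(f[3]),
      residual = function(f) min(abs(f[2] - rhs1(f[3])), abs(f[2] - rhs2(f[3])))
    )
  } else if (identical(sort(idx), c(9L, 14L, 15L))) {
    # f = (f9, f14, f15)
    rhs <- function(f15) (cc / (1 - cc)) * (1 + f15 / 2)
    list(
      holds = function(f) f[1] > rhs(f[3]),
      residual = function(f) abs(f[1] - rhs(f[3]))
    )
  } else {
    stop("closed-form conditions are available for supports {0,6,8} and {9,14,15} only")
  }
}

#' Equilibrium classification: NE, SCE, SCENE
#'
#' A resident strategy is a Nash equilibrium (NE) within the memory-one pure
#' strategies when it is a best response to itself. It is a self-confirming
#' equilibrium (SCE) when the best-looking response under the observer's
#' limiting belief is the resident itself. In the exact-identification regime
#' (`M >> 1/eps`) the belief is a point mass and SCE coincides with NE; in
#' the uncertain regime (`1 << M << 1/eps`) the belief is uniform over the
#' candidate set consistent with the resident's observable signature, which
#' differs from a point mass only for the six Category-III strategies. SCENE
#' = SCE and NE simultaneously.
#'
#' @param strategy a strategy literal.
#' @param game a [game_params()] object.
#' @param regime `"uncertain"` (default) or `"exact"`.
#' @param order series order.
#' @return A list of class `equilibrium_report` with logical flags `NE`,
#'   `SCE`, `SCENE`, plus `candidates`, `best_looking`, `category` and any
#'   threshold-tie flag.
#' @examples
#' classify_equilibrium("WSLS", game_params(0.2))$SCENE   # TRUE
#' classify_equilibrium("AllD", game_params(0.3))$SCE     # FALSE
#' @export
classify_equilibrium <- function(strategy, game, regime = c("uncertain", "exact"),
                                 order = 2) {
  regime <- match.arg(regime)
  i <- as_strategy(strategy)
  br <- best_response(i, game, order = order)
  ne <- br$is_self
  sig <- classify_signature(i)
  if (regime == "exact") {
    cands <- i
  } else {
    cands <- candidate_set(unname(sig$limit_exact), sig$identifiable_digits)
  }
  blr <- best_looking_response(belief_uniform(cands), game, order = order)
  sce <- i %in% blr$responders
  structure(list(
    strategy = i, regime = regime, category = sig$category,
    candidates = cands, best_looking = blr$responders,
    NE = ne, SCE = sce, SCENE = ne && sce,
    at_threshold = br$at_threshold || blr$at_threshold
  ), class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat("d", x$strategy, " (", x$regime, " regime, Category ", x$category, "): ",
      "NE=", x$NE, "  SCE=", x$SCE, "  SCENE=", x$SCENE, "\n",
      "  candidates {", paste0("d", x$candidates, collapse = ", "),
      "}; best-looking response {", paste0("d", x$best_looking, collapse = ", "),
      "}\n", sep = "")
  invisible(x)
}

#' Classify all sixteen strategies
#'
#' @inheritParams classify_equilibrium
#' @return A tibble with one row per strategy: category, candidate set, best
#'   looking response(s), and the `NE`/`SCE`/`SCENE` flags.
#' @examples
#' classify_population(game_params(0.2))
#' @export
classify_population <- function(game, regime = c("uncertain", "exact"), order = 2) {
  regime <- match.arg(regime)
  purrr::map_dfr(0:15, function(i) {
    r <- classify_equilibrium(i, game, regime = regime, order = order)
    tibble::tibble(
      strategy = i, name = strategy_name(i), category = r$category,
      candidates = list(r$candidates), best_looking = list(r$best_looking),
      NE = r$NE, SCE = r$SCE, SCENE = r$SCENE, at_threshold = r$at_threshold
    )
  })
}
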