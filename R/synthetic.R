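# Seeded Monte-Carlo generators emulating the model's data-generating
# processes: full match trajectories between two strategies, and the
# observer's samples from a monomorphic resident population in its
# stationary state. Every analytic quantity in the package has one of these
# as a simulation oracle.

#' Simulate a repeated match between two strategies
#'
#' Runs the two-player joint-state Markov chain for `rounds` rounds after a
#' burn-in, starting from a uniformly random state. Moves are realised with
#' implementation error `epsilon`. The empirical mean payoff is an unbiased
#' long-run estimator of the analytic stationary payoff.
#'
#' @inheritParams transition_matrix
#' @param epsilon error rate in (0, 1/2].
#' @param rounds number of recorded rounds (after burn-in).
#' @param game optional [game_params()]; payoffs are reported when supplied.
#' @param seed optional RNG seed; identical seeds give identical
#'   trajectories.
#' @param burn_in rounds discarded before recording (initial-state effects
#'   are irrelevant to long-run averages; the burn-in just shortens the
#'   transient).
#' @return An object of class `match_sim`: state counts, empirical state
#'   frequencies, per-player mean payoffs with batch-means standard errors,
#'   and the trajectory (integer state codes 1-4 for CC, CD, DC, DD).
#' @examples
#' sim <- simulate_match("WSLS", "WSLS", 1e-3, rounds = 1e4,
#'                       game = game_params(0.2), seed = 1)
#' glance(sim)
#' @export
simulate_match <- function(a, b, epsilon, rounds, game = NULL, seed = NULL,
                           burn_in = 1000) {
  stopifnot(rounds >= 1, epsilon > 0, epsilon <= 0.5)
  iA <- as_strategy(a); iB <- as_strategy(b)
  if (!is.null(seed)) set.seed(seed)
  T <- transition_matrix(iA, iB, epsilon)
  cum <- t(apply(T, 1, cumsum))
  init <- sample.int(4L, 1L)
  states <- cpp_simulate_chain(cum, as.integer(rounds + burn_in), init)
  states <- states[(burn_in + 1L):(rounds + burn_in)]
  counts <- tabulate(states, nbins = 4L)
  freqs <- counts / rounds
  # batch-means standard errors: the chain decorrelates on a 1/epsilon
  # timescale, so naive multinomial errors would be optimistic
  nb <- max(2L, min(100L, rounds %/% 100L))
  bm <- function(x) {
    m <- matrix(x[seq_len((length(x) %/% nb) * nb)], ncol = nb)
    stats::sd(colMeans(m)) / sqrt(nb)
  }
  freq_se <- vapply(1:4, function(s) bm(as.numeric(states == s)), 0)
  out <- list(a = iA, b = iB, epsilon = epsilon, rounds = rounds,
              burn_in = burn_in, seed = seed, states = states,
              counts = stats::setNames(counts, STATES),
              freqs = stats::setNames(freqs, STATES),
              freq_se = stats::setNames(freq_se, STATES))
  if (!is.null(game)) {
    stopifnot(inherits(game, "ipd_game"))
    pay_a <- game$payoff[states]
    pay_b <- game$payoff[.SWAP_IDX[states]]
    out$payoff_a <- mean(pay_a); out$payoff_b <- mean(pay_b)
    out$se_a <- bm(pay_a); out$se_b <- bm(pay_b)
    out$cost <- game$cost
  }
  structure(out, class = "match_sim")
}

#' @export
print.match_sim <- function(x, ...) {
  cat("Simulated match d", x$a, " vs d", x$b, ": ", x$rounds,
      " rounds at eps = ", x$epsilon, "\n  state frequencies: ",
      paste(names(x$freqs), signif(x$freqs, 4), collapse = "  "), "\n", sep = "")
  if (!is.null(x$payoff_a)) {
    cat("  mean payoffs: focal ", signif(x$payoff_a, 5), " (se ",
        signif(x$se_a, 3), "), co-player ", signif(x$payoff_b, 5), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname simulate_match
#' @param x a `match_sim` object.
#' @param ... unused.
#' @export
tidy.match_sim <- function(x, ...) {
  tibble::tibble(round = seq_along(x$states), state = STATES[x$states])
}

#' @rdname simulate_match
#' @export
glance.match_sim <- function(x, ...) {
  tibble::tibble(
    a = x$a, b = x$b, epsilon = x$epsilon, rounds = x$rounds,
    v_cc = x$freqs[["CC"]], v_cd = x$freqs[["CD"]],
    v_dc = x$freqs[["DC"]], v_dd = x$freqs[["DD"]],
    payoff_a = x$payoff_a %||% NA_real_, se_a = x$se_a %||% NA_real_,
    payoff_b = x$payoff_b %||% NA_real_, se_b = x$se_b %||% NA_real_
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Sample the observer's records from a monomorphic population
#'
#' Emulates the observational-learning data stream: `M` pairs of resident
#' players are watched, each pair's joint state drawn independently from the
#' resident's self-play stationary distribution (the population is a large
#' stationary ensemble), and each of the two players contributes one record —
#' the state from their own perspective and their realised
#' (error-perturbed) next move. `2 M` records in total.
#'
#' @param resident strategy literal of the resident population.
#' @param epsilon error rate in (0, 1/2).
#' @param M number of observed pairs.
#' @param seed optional RNG seed.
#' @return A tibble with `2 M` rows: `pair`, `perspective` (1 or 2), `state`,
#'   `move` (`"C"`/`"D"`).
#' @examples
#' sample_observations(0, 1e-4, M = 50, seed = 1)
#' @export
sample_observations <- function(resident, epsilon, M, seed = NULL) {
  stopifnot(M >= 1, epsilon > 0, epsilon < 0.5)
  ir <- as_strategy(resident)
  if (!is.null(seed)) set.seed(seed)
  v <- .stationary_num(ir, ir, epsilon)
  p <- perturb_strategy(ir, epsilon)
  s1 <- sample.int(4L, M, replace = TRUE, prob = v)  # pair state, player 1 view
  s2 <- .SWAP_IDX[s1]                                # same state, player 2 view
  st <- c(s1, s2)
  mv <- ifelse(stats::runif(2L * M) < p[st], "C", "D")
  ord <- order(rep(seq_len(M), 2L))
  tibble::tibble(
    pair = rep(seq_len(M), 2L)[ord],
    perspective = rep(c(1L, 2L), each = M)[ord],
    state = STATES[st][ord],
    move = mv[ord]
  )
}

#' Posterior concentration across observation budgets
#'
#' Repeats the observe-then-update experiment over a grid of observation
#' counts `M`: for each replicate, draw `M` pairs from the resident
#' population, update the prior (uniform over the resident's candidate set by
#' default), and record how concentrated the posterior is and which strategy
#' then looks best. Demonstrates the crossover from persistent uncertainty
#' (`M << 1/eps`) to exact identification (`M >> 1/eps`).
#'
#' @inheritParams sample_observations
#' @param M_grid integer vector of observation counts.
#' @param replicates replicates per grid point.
#' @param game a [game_params()] object.
#' @param prior optional belief tibble; defaults to the uniform belief over
#'   the resident's signature-consistent candidate set.
#' @param seed optional RNG seed for the whole sweep.
#' @return A tibble with one row per (M, replicate): `M`, `replicate`,
#'   `max_weight`, `weight_on_resident`, `entropy`, `choice` (best-looking
#'   response under the posterior).
#' @export
regime_sweep <- function(resident, epsilon, M_grid, replicates, game,
                         prior = NULL, seed = NULL) {
  ir <- as_strategy(resident)
  stopifnot(inherits(game, "ipd_game"))
  if (is.null(prior)) {
    sig <- classify_signature(ir)
    prior <- belief_uniform(candidate_set(unname(sig$limit_exact),
                                          sig$identifiable_digits))
  }
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(M_grid, function(M) {
    purrr::map_dfr(seq_len(replicates), function(r) {
      obs <- sample_observations(ir, epsilon, M)
      post <- posterior_update(obs, prior, epsilon)
      w <- post$weight
      blr <- best_looking_response(post, game)
      tibble::tibble(
        M = M, replicate = r,
        max_weight = max(w),
        weight_on_resident = sum(w[post$strategy == ir]),
        entropy = -sum(ifelse(w > 0, w * log(w), 0)),
        choice = blr$responders[1]
      )
    })
  })
}
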