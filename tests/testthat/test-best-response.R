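# Best-response enumeration in the small-error order, the best-response
# table, exact switching costs, and responses to mixed residents.

test_that("series comparison is lexicographic with the limit dominating", {
  g_half <- game_params("1/2")
  # equal limits, different eps coefficients: larger eps^1 wins
  a <- payoff_series(9, 9, game = g_half)    # limit 1/2 at c = 1/2
  b <- payoff_series(0, 9, game = g_half)    # limit 1/2 as well
  cmp <- small_eps_compare(a, b)
  expect_true(cmp %in% c("a<b", "a>b"))      # broken at O(eps), not a tie
  # a strictly larger limit dominates any coefficients
  hi <- payoff_series(0, 5, game = game_params(0.3))   # limit 1
  lo <- payoff_series(0, 1, game = game_params(0.3))   # limit 1/2
  expect_identical(small_eps_compare(hi, lo), "a>b")
  expect_identical(small_eps_compare(hi, hi), "a=b")
})

test_that("best responses match the frozen table at generic costs", {
  fx <- table1_fixture()
  for (g in list(game_params("1/5"), game_params("3/5"))) {
    cond <- ifelse(g$cost < 1 / 3, "c<1/3", "c>1/3")
    cond2 <- ifelse(g$cost < 1 / 2, "c<1/2", "c>1/2")
    rows <- fx[fx$cost_cond %in% c("any", cond, cond2), ]
    for (r in seq_len(nrow(rows))) {
      br <- best_response(rows$resident[r], g)
      expect_identical(br$responders, rows$responder[r],
                       label = sprintf("resident %d at c=%s", rows$resident[r],
                                       format(g$cost)))
    }
  }
})

test_that("best-response payoff series match the frozen exact coefficients", {
  fx <- table1_fixture()
  for (r in seq_len(nrow(fx))) {
    ps <- payoff_series(fx$responder[r], fx$resident[r], order = 2)
    expect_series_row(ps, fx$limit_const[r], fx$limit_ccoef[r],
                      fx$eps1_const[r], fx$eps1_ccoef[r])
  }
})

test_that("the self-responder (dagger) set shifts with the cost as expected", {
  selfset <- function(cc) {
    tb <- response_table(game_params(cc))
    tb$resident[tb$is_self]
  }
  expect_identical(selfset("1/5"), c(0L, 9L))        # below 1/3
  expect_identical(selfset("2/5"), c(0L, 8L, 9L))    # between 1/3 and 1/2
  expect_identical(selfset("3/5"), c(0L, 8L))        # above 1/2
  # AllD responds to itself across the whole cost grid
  for (cc in seq(0.05, 0.95, by = 0.1)) {
    expect_true(0L %in% best_response(0, game_params(cc))$responders)
  }
})

test_that("best response to TFT is AllC at any cost", {
  for (cc in c(0.1, 0.5, 0.9)) {
    expect_identical(best_response("TFT", game_params(cc))$responders, 15L)
  }
})

test_that("switching costs are recovered as exact rationals", {
  t8 <- critical_cost(8, 0.1, 0.9)
  expect_true(t8$critical == as_rational("1/3"))
  expect_identical(c(t8$low_side, t8$high_side), c(15L, 8L))
  t9 <- critical_cost(9, 0.1, 0.9)
  expect_true(t9$critical == as_rational("1/2"))
  t11 <- critical_cost(11, 0.1, 0.9)
  expect_true(t11$critical == as_rational("1/2"))
  expect_identical(c(t11$low_side, t11$high_side), c(13L, 0L))
  # degenerate bracket is rejected
  expect_error(critical_cost(8, 0.4, 0.9), "does not differ")
})

test_that("threshold ties are flagged only at critical costs", {
  # structural limit ties (payoff functions identical in c) are not thresholds
  expect_false(best_response("TFT", game_params(0.2))$at_threshold)
  # exactly at a critical cost the competing limits tie and are flagged
  br_crit <- best_response(9, game_params("1/2"))
  expect_true(br_crit$at_threshold)
  expect_true(all(c(0L, 9L) %in% br_crit$limit_ties))
  expect_false(best_response(9, game_params("2/5"))$at_threshold)
  blr_crit <- best_looking_response(belief_uniform(c(0, 6, 8)), game_params("16/33"))
  expect_true(blr_crit$at_threshold)
  expect_true(all(c(8L, 9L) %in% blr_crit$limit_ties))
})

test_that("the best-response graph encodes residents, responders and loops", {
  edges <- response_graph(game_params(0.4))
  expect_identical(sort(unique(edges$from)), 0:15)
  expect_identical(edges$to[edges$from == 6], 9L)
  expect_identical(sort(edges$from[edges$self_loop]), c(0L, 8L, 9L))
  dot <- graph_dot(edges)
  expect_match(dot, "digraph", fixed = TRUE)
  expect_match(dot, "d10 (TFT)", fixed = TRUE)
})

test_that("mixed residents: perturbed pure residents reproduce the pure case", {
  g <- game_params(0.3)
  q <- perturb_strategy("TFT", 1e-4)
  br <- best_response_mixed(q, g, epsilon = 1e-4)
  expect_identical(br$responders, 15L)
  # uniformly random opponent: defection maximises, uniquely at eps > 0
  br_u <- best_response_mixed(rep(0.5, 4), g, epsilon = 1e-3)
  expect_identical(br_u$responders, 0L)
})

test_that("random mixed residents generically admit a unique best response", {
  set.seed(20240917)
  g <- game_params(0.37)
  n_unique <- 0L
  for (k in 1:200) {
    q <- stats::runif(4)
    br <- best_response_mixed(q, g, epsilon = 1e-3, tol = 1e-10)
    n_unique <- n_unique + as.integer(br$unique)
  }
  expect_identical(n_unique, 200L)
})
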