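# The observer: signature categories, candidate sets, Bayesian updating,
# expected payoffs under belief, best-looking responses and the
# NE / SCE / SCENE classification.

test_that("signature categories partition the strategy set 8/2/6", {
  st <- signature_table()
  expect_identical(as.integer(table(st$category)[c("I", "II", "III")]), c(8L, 2L, 6L))
  expect_identical(st$strategy[st$category == "II"], c(1L, 7L))
  expect_identical(st$strategy[st$category == "III"], c(0L, 6L, 8L, 9L, 14L, 15L))
  # the two Category-II members share best response AllD at any generic cost
  for (cc in c(0.2, 0.45, 0.8)) {
    expect_identical(best_response(1, game_params(cc))$responders, 0L)
    expect_identical(best_response(7, game_params(cc))$responders, 0L)
  }
})

test_that("example signatures classify as published", {
  expect_identical(classify_signature(3)$category, "I")
  s1 <- classify_signature(1)
  expect_identical(s1$category, "II")
  expect_identical(s1$observable_states, c("CC", "DD"))
  s9 <- classify_signature(9)
  expect_identical(s9$category, "III")
  expect_identical(s9$observable_states, "CC")
})

test_that("candidate sets follow the observed limit signature and moves", {
  expect_identical(candidate_set(c(0, 1 / 4, 1 / 4, 1 / 2)), c(2L, 4L))
  expect_identical(candidate_set(c(0, 0, 0, 1)), c(0L, 6L, 8L))
  expect_identical(candidate_set(c(0, 0, 0, 1), c(DD = "D")), c(0L, 6L, 8L))
  expect_identical(candidate_set(c(1, 0, 0, 0)), c(9L, 14L, 15L))
  expect_identical(candidate_set(c(1 / 2, 0, 0, 1 / 2)), c(1L, 7L))
  # move information at an observable state separates Category-I twins
  expect_identical(candidate_set(c(0, 1 / 4, 1 / 4, 1 / 2), c(CD = "D")), 2L)
  expect_identical(candidate_set(c(0, 1 / 4, 1 / 4, 1 / 2), c(CD = "C")), 4L)
  expect_error(candidate_set(c(0.3, 0.3, 0.3, 0.1)), "consistent")
})

test_that("posterior updating is exchangeable: sequential equals batch", {
  set.seed(101)
  obs <- sample_observations(0, 0.01, M = 200)
  prior <- belief_uniform(0:15)
  batch <- posterior_update(obs, prior, 0.01)
  # sequential over arbitrary chunks, and over a permutation
  seq1 <- prior
  for (chunk in split(seq_len(nrow(obs)), rep(1:8, length.out = nrow(obs)))) {
    seq1 <- posterior_update(obs[chunk, ], seq1, 0.01)
  }
  perm <- obs[sample(nrow(obs)), ]
  expect_equal(batch$weight, seq1$weight, tolerance = 1e-12)
  expect_equal(batch$weight, posterior_update(perm, prior, 0.01)$weight,
               tolerance = 1e-12)
  # no observations: the prior is returned unchanged
  expect_identical(posterior_update(obs[0, ], prior, 0.01), prior)
})

test_that("a single record reweights by the perturbed prescription ratio", {
  one <- tibble::tibble(state = "CD", move = "C")
  post <- posterior_update(one, belief_uniform(0:15), 0.01)
  w_coop <- post$weight[post$strategy == 15]   # p_CD = 1 -> likelihood 0.99
  w_def <- post$weight[post$strategy == 0]     # p_CD = 0 -> likelihood 0.01
  expect_equal(w_coop / w_def, 99, tolerance = 1e-12)
})

test_that("expected payoff is linear in the belief and exact at vertices", {
  g <- game_params("2/5")
  # degenerate belief reduces to the pairwise payoff series
  ps_point <- expected_payoff(5, belief_point("TFT"), game = g)
  ps_pair <- payoff_series(5, "TFT", game = g)
  expect_identical(format(ps_point), format(ps_pair))
  # mixture of two beliefs
  b1 <- belief_uniform(c(0, 6, 8))
  b2 <- belief_point(9)
  lam <- as_rational("1/4")
  mix <- tibble::tibble(
    strategy = c(0L, 6L, 8L, 9L),
    weight = c(rep(as.double(lam) / 3, 3), 1 - as.double(lam)))
  lhs <- scenepd:::ps_coeffs(expected_payoff(9, mix, game = g))
  r1 <- scenepd:::ps_coeffs(expected_payoff(9, b1, game = g))
  r2 <- scenepd:::ps_coeffs(expected_payoff(9, b2, game = g))
  expect_true(all(lhs == r1 * lam + r2 * (rat(1) - lam)))
  # WSLS against the cooperate-looking candidates: limits 1-c, 1-c/3, 1-c/2
  # (verified against the numeric solver at eps = 1e-6), averaging to
  # 1 - (11/18) c under the uniform belief
  ps <- expected_payoff(9, belief_uniform(c(9, 14, 15)), order = 2)
  expect_true(ps$const[1] == rat(1) && ps$ccoef[1] == rat(-11, 18))
})

test_that("best-looking responses switch at the published cost thresholds", {
  bd <- belief_uniform(c(0, 6, 8))
  expect_identical(best_looking_response(bd, game_params(0.3))$responders, 9L)
  expect_identical(best_looking_response(bd, game_params(0.6))$responders, 8L)
  bc <- belief_uniform(c(9, 14, 15))
  expect_identical(best_looking_response(bc, game_params(0.1))$responders, 9L)
  expect_identical(best_looking_response(bc, game_params(0.3))$responders, 1L)
  # point-mass beliefs reduce to plain best responses
  expect_identical(best_looking_response(belief_point("TFT"), game_params(0.4))$responders, 15L)
  t_d <- belief_switch_cost(bd)
  expect_true(t_d$critical == as_rational("16/33"))
  t_c <- belief_switch_cost(bc)
  expect_true(t_c$critical == as_rational("2/9"))
  expect_true(wsls_feasibility_cost() == as_rational("1/2"))
})

test_that("exact identification makes SCE coincide with NE for all residents", {
  g <- game_params("2/5")
  for (i in 0:15) {
    blr <- best_looking_response(belief_point(i), g)
    br <- best_response(i, g)
    expect_identical(blr$responders, br$responders)
    r <- classify_equilibrium(i, g, regime = "exact")
    expect_identical(r$SCE, r$NE)
  }
})

test_that("equilibrium verdicts under observational uncertainty", {
  # WSLS is a SCENE at low cost; AllD is Nash but never self-confirming below 16/33
  r9 <- classify_equilibrium("WSLS", game_params(0.2))
  expect_true(r9$NE && r9$SCE && r9$SCENE)
  r0 <- classify_equilibrium("AllD", game_params(0.3))
  expect_true(r0$NE)
  expect_false(r0$SCE)
  expect_identical(r0$best_looking, 9L)
  # GT1 at high cost is both Nash and self-confirming
  r8 <- classify_equilibrium(8, game_params(0.6))
  expect_true(r8$NE && r8$SCE)
  # Category I and II residents: uncertainty changes nothing
  tb_u <- classify_population(game_params(0.4), regime = "uncertain")
  tb_e <- classify_population(game_params(0.4), regime = "exact")
  idx <- tb_u$category != "III"
  expect_identical(tb_u$SCE[idx], tb_e$SCE[idx])
})

test_that("simplex region maps respect the closed-form WSLS conditions", {
  g <- game_params(0.2)
  sr <- simplex_region(c(0, 6, 8), g, step = 0.02)
  cond <- wsls_prior_condition(c(0, 6, 8), g)
  # interior grid agreement away from boundaries
  for (r in seq_len(nrow(sr$grid))) {
    f <- c(sr$grid$f1[r], sr$grid$f2[r], sr$grid$f3[r])
    if (cond$residual(f) < 0.02) next
    expect_identical(sr$grid$winner[r] == 9L, cond$holds(f))
  }
  # located boundaries adjacent to the WSLS region sit on a closed-form curve
  b <- sr$boundary[sr$boundary$winner_a == 9L | sr$boundary$winner_b == 9L, ]
  expect_gt(nrow(b), 0)
  res <- vapply(seq_len(nrow(b)), function(i) {
    cond$residual(c(b$f1[i], b$f2[i], b$f3[i]))
  }, 0)
  expect_lt(max(res), 1e-4)
})

test_that("region maps are stable under grid refinement", {
  g <- game_params(0.4)
  s1 <- glance(simplex_region(c(9, 14, 15), g, step = 0.04))
  s2 <- glance(simplex_region(c(9, 14, 15), g, step = 0.02))
  expect_lt(abs(s1$wsls_share - s2$wsls_share), 0.05)
})
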