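# The two-player chain: transition structure, exact stationary solutions,
# their small-error limits and payoff series.

test_that("transition matrices are stochastic with error-floored entries", {
  eps <- 0.01
  for (ia in 0:15) for (ib in c(0L, 5L, 9L, 10L, 15L)) {
    T <- transition_matrix(ia, ib, eps)
    expect_equal(unname(rowSums(T)), rep(1, 4))
    expect_true(all(T >= eps^2 - 1e-15))
  }
  # mutual-defectors row DD: cooperation only by independent errors
  T <- transition_matrix(0, 0, eps)
  expect_equal(unname(T["DD", ]), c(eps^2, eps * (1 - eps), (1 - eps) * eps, (1 - eps)^2))
  # TFT vs TFT without error: from CD each copies the other -> DC surely
  T0 <- transition_matrix("TFT", "TFT", 1e-9)
  expect_gt(T0["CD", "DC"], 1 - 1e-8)
})

test_that("stationary distributions are normalised, positive and unique", {
  for (ia in 0:15) for (ib in c(1L, 8L, 9L, 12L)) {
    v <- stationary_dist(ia, ib, 0.05)$probability
    expect_equal(sum(v), 1, tolerance = 1e-12)
    expect_true(all(v > 0))
    # fixed point of the transition matrix
    T <- transition_matrix(ia, ib, 0.05)
    expect_equal(as.numeric(v %*% T), v, tolerance = 1e-12)
  }
  expect_error(stationary_dist(0, 0, 0))
})

test_that("exact and numeric stationary solutions agree", {
  # exact rational evaluation needs moderate denominators (8-bit doubles for
  # integer arithmetic); 1/128 keeps every power exactly representable
  for (pair in list(c(0, 0), c(9, 9), c(8, 2), c(10, 15))) {
    ex <- stationary_dist(pair[1], pair[2], "1/128", exact = TRUE)$probability
    nu <- stationary_dist(pair[1], pair[2], 1 / 128)$probability
    expect_equal(ex, nu, tolerance = 1e-12)
  }
  # at truly tiny error rates the exact series stands in for the rational
  # evaluation; the (ill-conditioned) numeric solve still matches absolutely
  for (pair in list(c(0, 0), c(9, 9), c(13, 11))) {
    ser <- stationary_series(pair[1], pair[2], order = 4)
    eps <- 1e-6
    v_ser <- vapply(split(ser, ser$state), function(d) {
      sum(d$coef_num[order(d$power)] * eps^(0:4))
    }, 0)[c("CC", "CD", "DC", "DD")]
    nu <- stationary_dist(pair[1], pair[2], eps)$probability
    expect_equal(unname(v_ser), nu, tolerance = 1e-9)
  }
})

test_that("perspective symmetry holds exactly for every ordered pair", {
  # v(dA, dB)_XY == v(dB, dA)_YX, compared as exact rationals at eps = 1/10
  swap <- c(1L, 3L, 2L, 4L)
  for (ia in 0:15) for (ib in ia:15) {
    vab <- stationary_dist(ia, ib, "1/10", exact = TRUE)$exact
    vba <- stationary_dist(ib, ia, "1/10", exact = TRUE)$exact
    expect_identical(vab, vba[swap])
  }
})

test_that("payoff-sum identity links the two players' payoffs", {
  g <- game_params(0.35)
  tot <- c(2 * (1 - g$cost), 1 - g$cost, 1 - g$cost, 0)
  for (ia in 0:15) for (ib in 0:15) {
    v <- stationary_dist(ia, ib, 0.01)$probability
    lhs <- payoff(ia, ib, 0.01, g) + payoff(ib, ia, 0.01, g)
    expect_equal(lhs, sum(v * tot), tolerance = 1e-12)
  }
})

test_that("maximal error rate gives the uniform closed form exactly", {
  g <- game_params("2/5")
  for (ia in c(0, 3, 9, 14)) for (ib in c(0, 6, 10, 15)) {
    v <- stationary_dist(ia, ib, "1/2", exact = TRUE)
    expect_identical(v$exact, rep("1/4", 4))
    expect_true(payoff_exact(ia, ib, "1/2", g) == as_rational("3/10"))  # (1-c)/2
  }
})

test_that("small-error limits match the known self-play signatures", {
  expect_equal(limit_stationary("TFT", "TFT")$limit, rep(1 / 4, 4))
  expect_equal(limit_stationary(2, 2)$limit, c(0, 1 / 4, 1 / 4, 1 / 2))
  expect_equal(limit_stationary(1, 1)$limit, c(1 / 2, 0, 0, 1 / 2))
  # leading orders for vanishing entries
  ls0 <- limit_stationary(0, 0)
  expect_identical(ls0$leading_power, c(2L, 1L, 1L, 0L))
  ls9 <- limit_stationary(9, 9)
  expect_identical(ls9$leading_coef[4], "2")
  expect_identical(ls9$leading_power[4], 1L)
})

test_that("payoff series agree with the exact payoff as the error shrinks", {
  g <- game_params("2/5")
  for (pair in list(c(15, 10), c(0, 0), c(9, 6), c(13, 11))) {
    ps <- payoff_series(pair[1], pair[2], game = g, order = 2)
    err_ratio <- vapply(c(1e-3, 1e-4, 1e-5), function(eps) {
      exact <- payoff(pair[1], pair[2], eps, g)
      abs(exact - scenepd:::ps_eval(ps, eps)) / eps^3
    }, 0)
    expect_true(all(err_ratio < 50))
  }
})

test_that("payoff limits follow the stationary limits", {
  g <- game_params(0.25)
  ps <- payoff_series(9, 9, game = g)
  lim <- limit_stationary(9, 9)$limit
  expect_equal(as.double(scenepd:::ps_coeffs(ps)[1]), sum(lim * g$payoff))
})
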