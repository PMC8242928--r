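# Seeded generators: determinism, agreement with the analytic engine, and
# the identification crossover with the observation budget.

test_that("generators are deterministic under a fixed seed", {
  s1 <- simulate_match(9, 10, 0.05, rounds = 500, seed = 77)
  s2 <- simulate_match(9, 10, 0.05, rounds = 500, seed = 77)
  expect_identical(s1$states, s2$states)
  s3 <- simulate_match(9, 10, 0.05, rounds = 500, seed = 78)
  expect_false(identical(s1$states, s3$states))
  o1 <- sample_observations(0, 0.01, M = 100, seed = 5)
  o2 <- sample_observations(0, 0.01, M = 100, seed = 5)
  expect_identical(o1, o2)
})

test_that("empirical state frequencies and payoffs track the analytic chain", {
  g <- game_params(0.3)
  panel <- list(c(0, 0), c(9, 9), c(10, 10), c(8, 8), c(2, 4), c(10, 15),
                c(0, 15), c(9, 6), c(13, 11), c(5, 12))
  eps <- 0.01
  for (k in seq_along(panel)) {
    a <- panel[[k]][1]; b <- panel[[k]][2]
    sim <- simulate_match(a, b, eps, rounds = 1e5, game = g, seed = 1000 + k)
    v <- stationary_dist(a, b, eps)$probability
    expect_true(all(abs(sim$freqs - v) < 3 * pmax(sim$freq_se, 3e-4)),
                label = sprintf("state freqs, pair d%d vs d%d", a, b))
    expect_lt(abs(sim$payoff_a - payoff(a, b, eps, g)), 3 * max(sim$se_a, 3e-4))
  }
})

test_that("WSLS self-play earns nearly the full cooperation payoff", {
  g <- game_params(0.2)
  sim <- simulate_match(9, 9, 1e-3, rounds = 1e5, game = g, seed = 42)
  expect_lt(abs(sim$payoff_a - (1 - g$cost)), 0.02)
  expect_lt(abs(sim$payoff_a - payoff(9, 9, 1e-3, g)), 3 * sim$se_a)
})

test_that("observation samples mirror the resident's stationary ensemble", {
  obs <- sample_observations("TFT", 1e-3, M = 2e4, seed = 9)
  expect_identical(nrow(obs), 4e4L)
  freq <- as.numeric(table(factor(obs$state, levels = c("CC", "CD", "DC", "DD"))) / nrow(obs))
  se <- sqrt(0.25 * 0.75 / nrow(obs))
  expect_true(all(abs(freq - 0.25) < 4 * se))
  # an all-defect population yields almost exclusively DD records
  obs0 <- sample_observations(0, 1e-4, M = 100, seed = 2)
  expect_gt(mean(obs0$state == "DD"), 0.97)
})

test_that("both perspectives of one pair describe the same game", {
  obs <- sample_observations(2, 0.01, M = 500, seed = 31)
  by_pair <- split(obs$state, obs$pair)
  ok <- vapply(by_pair, function(st) {
    identical(unname(swap_perspective(st[1])), st[2])
  }, TRUE)
  expect_true(all(ok))
})

test_that("posterior mass on the resident grows with the observation budget", {
  g <- game_params(0.2)
  sw <- regime_sweep(9, 1e-3, M_grid = c(10, 1000, 30000), replicates = 4,
                     game = g, seed = 13)
  agg <- tapply(sw$weight_on_resident, sw$M, mean)
  expect_true(all(diff(agg[order(as.numeric(names(agg)))]) > -0.02))
  # deep-uncertainty end: belief still uniform over the three candidates
  expect_equal(min(sw$entropy[sw$M == 10]), log(3), tolerance = 0.2)
  # identification end: the resident dominates and is chosen
  expect_gt(mean(sw$weight_on_resident[sw$M == 30000]), 0.95)
  expect_true(all(sw$choice[sw$M == 30000] == 9L))
})
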