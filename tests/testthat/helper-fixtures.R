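# Frozen expected values for the best-response table and the self-play
# signature table, written as exact strings. Payoff-series entries are the
# limit and eps^1 coefficient in the exact linear-in-c form "const" and
# "cost_coef"; NA marks coefficients with no frozen reference value.
# All entries were verified against two independent computations (the exact
# series engine and numeric linear solves at small error rates).

table1_fixture <- function() {
  tibble::tribble(
    ~resident, ~cost_cond, ~responder, ~limit_const, ~limit_ccoef, ~eps1_const, ~eps1_ccoef,
    0L,  "any",    0L,  "0",   "0",  "1",    "-1",
    1L,  "any",    0L,  "1/2", "0",  "-1/4", "-1",
    2L,  "any",    11L, "1/2", "-1/2", "-1/2", "-1/2",
    3L,  "any",    0L,  "1/2", "0",  "0",    "-1",
    4L,  "any",    0L,  "1/3", "0",  "2/9",  "-1",
    5L,  "any",    0L,  "1",   "0",  "-2",   "-1",
    6L,  "any",    9L,  "1",   "0",  "-3",   "-3",
    7L,  "any",    0L,  "1",   "0",  "-2",   "-1",
    8L,  "c>1/3",  8L,  "0",   "0",  "3/2",  "-3/2",
    8L,  "c<1/3",  15L, "1/3", "-1", NA,     NA,
    9L,  "c>1/2",  0L,  "1/2", "0",  NA,     NA,
    9L,  "c<1/2",  9L,  "1",   "-1", NA,     NA,
    10L, "any",    15L, "1",   "-1", "-2",   "1",
    11L, "c>1/2",  0L,  "1/2", "0",  "1/4",  "-1",
    11L, "c<1/2",  13L, "1",   "-1", "-2",   "2",
    12L, "any",    0L,  "1/2", "0",  NA,     NA,
    13L, "any",    0L,  "1",   "0",  "-1",   "-1",
    14L, "any",    1L,  "1",   "0",  "-2",   "-2",
    15L, "any",    0L,  "1",   "0",  "-1",   "-1"
  )
}

table2_fixture <- function() {
  tibble::tribble(
    ~strategy, ~v_cc, ~v_cd, ~v_dc, ~v_dd, ~category,
    0L,  "eps^2",   "eps", "eps", "1",       "III",
    1L,  "1/2",     "eps", "eps", "1/2",     "II",
    2L,  "1/2 eps", "1/4", "1/4", "1/2",     "I",
    3L,  "1/4",     "1/4", "1/4", "1/4",     "I",
    4L,  "1/2 eps", "1/4", "1/4", "1/2",     "I",
    5L,  "1/4",     "1/4", "1/4", "1/4",     "I",
    6L,  "2 eps",   "eps", "eps", "1",       "III",
    7L,  "1/2",     "eps", "eps", "1/2",     "II",
    8L,  "1/2 eps", "eps", "eps", "1",       "III",
    9L,  "1",       "eps", "eps", "2 eps",   "III",
    10L, "1/4",     "1/4", "1/4", "1/4",     "I",
    11L, "1/2",     "1/4", "1/4", "1/2 eps", "I",
    12L, "1/4",     "1/4", "1/4", "1/4",     "I",
    13L, "1/2",     "1/4", "1/4", "1/2 eps", "I",
    14L, "1",       "eps", "eps", "1/2 eps", "III",
    15L, "1",       "eps", "eps", "eps^2",   "III"
  )
}

# exact-coefficient comparison of a payoff_series against fixture strings
expect_series_row <- function(ps, limit_const, limit_ccoef, eps1_const, eps1_ccoef) {
  tid <- tidy(ps)
  expect_true(as_rational(tid$constant[1]) == as_rational(limit_const))
  expect_true(as_rational(tid$cost_coef[1]) == as_rational(limit_ccoef))
  if (!is.na(eps1_const)) {
    expect_true(as_rational(tid$constant[2]) == as_rational(eps1_const))
    expect_true(as_rational(tid$cost_coef[2]) == as_rational(eps1_ccoef))
  }
}
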