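# scenepd

Exact analysis of the iterated Prisoner's Dilemma among the sixteen
memory-one pure strategies when moves are misimplemented with a small error
probability, and of the Bayesian observer who must infer a resident
population's strategy from finitely many observed interactions.

The package is for researchers in evolutionary game theory and cultural
transmission who want the full best-response and observational-learning
structure of this model reproducible to the last rational digit: which
strategies are Nash equilibria (NE), which are self-confirming equilibria
(SCE) once observation is limited, and why Win-Stay-Lose-Shift (WSLS) can
sustain cooperation through observational learning while Always-Defect
cannot.

## The model

A memory-one pure strategy is a rule `[p_CC, p_CD, p_DC, p_DD]` prescribing
cooperate (1) or defect (0) after each previous-round joint state (first
letter = own move); the sixteen rules are indexed `d0`-`d15` by big-endian
bit encoding (`d0` AllD, `d8` Grim-Trigger-1, `d9` WSLS, `d10` TFT, `d15`
AllC). Cooperation costs `c` (0 < `c` < 1) and benefits the co-player by 1,
so the focal payoff vector over states `(CC, CD, DC, DD)` is
`P = (1-c, -c, 1, 0)`. Intended moves flip with probability `eps`, making
the match an irreducible four-state Markov chain with stationary
distribution `v(dA, dB, eps)` and long-run payoff `Pi = v . P`.

Everything is computed exactly: stationary distributions as ratios of
integer polynomials in `eps` (Cramer's rule), payoffs as power series at
`eps = 0` with coefficients of the exact form `a + b c`, best responses by
lexicographic comparison of those series, and critical costs by solving the
linear coefficient equalities — yielding the thresholds 1/3, 1/2, 16/33,
2/9 and 1/2 as exact rationals. An observer of a monomorphic population
sees only states and moves; the package classifies each strategy's
self-play signature (Categories I/II/III by how many states remain
observable as `eps -> 0`), forms the candidate set and Bayesian posterior,
finds best-looking responses under a belief, maps them across prior
simplices, and issues NE / SCE / SCENE verdicts.

## Worked example

```r
library(scenepd)
g <- game_params(0.2)          # cooperation cost c = 1/5

best_response("TFT", g)
#> Best response to d10: d15
#>   payoff: 4/5 + -9/5 eps + 2 eps^2 + O(eps^3)

payoff_series("AllC", "TFT")   # symbolic in c
#> Payoff series d15 vs d10 (symbolic c):
#>   (1 - c) + (-2 + c) eps + 2 eps^2 + O(eps^3)
```

The best reply to Tit-for-Tat is Always-Cooperate: against TFT under rare
error, AllC earns `1 - c` per round (here 4/5) minus an order-`eps`
correction, and no other memory-one rule does better for small `eps`.

```r
report_thresholds()
#> # A tibble: 6 x 5
#>   context                                          threshold threshold_num below               above
#> 1 self-response switch of GT1 (d8)                 1/3               0.333 d15                 d8
#> 2 self-response switch of WSLS (d9)                1/2               0.5   d9                  d0
#> 3 best-response switch of d11                      1/2               0.5   d13                 d0
#> 4 best-looking switch, uniform prior {d0,d6,d8}    16/33             0.485 d9                  d8
#> 5 best-looking switch, uniform prior {d9,d14,d15}  2/9               0.222 d9                  d1
#> 6 WSLS prior-region feasibility bound {d9,d14,d15} 1/2               0.5   d9 region non-empty d9 region empty
```

Row 4 is the heart of the story: an observer who has only ever seen
defection cannot tell `d0`, `d6` and `d8` apart, and under the uniform
belief over those candidates the payoff-maximising reply is WSLS whenever
`c < 16/33` — defection fails to confirm itself. Conversely (row 5), a
WSLS population keeps looking best to its observers whenever `c < 2/9`:

```r
classify_equilibrium("WSLS", g)
#> d9 (uncertain regime, Category III): NE=TRUE  SCE=TRUE  SCENE=TRUE
#>   candidates {d9, d14, d15}; best-looking response {d9}

classify_equilibrium("AllD", g)
#> d0 (uncertain regime, Category III): NE=TRUE  SCE=FALSE  SCENE=FALSE
#>   candidates {d0, d6, d8}; best-looking response {d9}
```

Other entry points: `response_table()` / `report_table1()` (all sixteen
best responses with exact payoff series), `report_table2()` /
`signature_table()` (self-play signatures and observability categories),
`simplex_region()` with `autoplot()` (best-looking response across a prior
simplex), `posterior_update()` / `sample_observations()` /
`regime_sweep()` (the Bayesian pipeline and the `M ~ 1/eps`
identification crossover), and `simulate_match()` (seeded Monte-Carlo
oracle for every analytic payoff). See the vignette
`vignettes/memory-one-learning.Rmd` for the methods account.

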