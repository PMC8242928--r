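---
title: "Best responses and self-confirming equilibria among memory-one strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Best responses and self-confirming equilibria among memory-one strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scenepd)
```

## The model

Two players repeat a donation-game Prisoner's Dilemma indefinitely.
Cooperation delivers a benefit of 1 to the co-player at cost `c` (with
`0 < c < 1`) to the cooperator, so the focal player's per-round payoff by
joint state is `P = (1 - c, -c, 1, 0)` over the states `(CC, CD, DC, DD)`,
where the first letter is the focal player's own previous move. Strategies
are memory-one and pure: a rule `[p_CC, p_CD, p_DC, p_DD]` with each digit
prescribing cooperate (1) or defect (0) after the corresponding state. There
are sixteen such rules, indexed by the big-endian bit encoding
(`d0` = AllD, `d8` = memory-one Grim Trigger, `d9` = Win-Stay-Lose-Shift,
`d10` = Tit-for-Tat, `d15` = AllC).

Moves are *misimplemented* with probability `eps` (implementation error,
`0 < eps <= 1/2`). The error does three things at once: it makes the joint
process a single irreducible, aperiodic Markov chain over the four states,
so long-run payoffs are well defined and independent of initial moves; it
regularises the analysis, whose conclusions are taken in the limit
`eps -> 0`; and it is the sole source of the observational-learning problem
studied below, because reactions to never-visited states are never observed.

## Exact computation

All headline quantities of this analysis are rational numbers or rational
functions, and several of its verdicts hinge on exact coefficient
comparisons (e.g. a best response switching at cost exactly 16/33), so the
engine works in exact arithmetic end to end:

* Transition probabilities between joint states are degree-2 integer
  polynomials in `eps`.
* The stationary distribution solves the balance equations by Cramer's rule
  on integer-polynomial determinants, giving each state probability as a
  ratio of integer polynomials. The numerators provably sum to the
  denominator, which the engine asserts on every solve.
* Small-`eps` behaviour comes from truncated power-series division with
  exact rational coefficients (default order 2, matching the reported
  `O(eps^2)` remainders of the payoff tables).
* Because the payoff vector is linear in the cost and the stationary
  distribution does not involve it, every payoff-series coefficient has the
  exact form `a + b c`. Critical costs are found by solving these linear
  equalities, never by root-bracketing floats.

Rationals are stored as reduced integer pairs in doubles, exact below
`2^53`, with overflow raising an error rather than rounding. One practical
consequence: *evaluating* the exact rational solution pointwise is limited
to moderate denominators (powers of the evaluation point must stay below
`2^53`); for very small error rates the exact series (whose coefficients
are computed once, exactly) or the numeric linear solver is the right tool,
and the two are cross-checked against each other in the test suite.

A numeric path (dense linear solve of the transposed transition matrix with
a normalisation row) backs every exact computation as an independent
cross-check and serves fast Monte-Carlo-facing code.

## Best responses in the small-error limit

"Best response to `d` in the small-`eps` sense" means: better for every
sufficiently small positive error rate. The package decides this
lexicographically on exact series coefficients — limits first, then the
`eps^1` coefficient, then `eps^2`. Limit-only comparison would be too
coarse: several responses to a resident often share a limit payoff and are
separated only at `O(eps)`.

Ties are handled in two distinct ways, and the distinction matters. A
*structural* tie — tied strategies whose payoffs are identical linear
functions of the cost, as happens among several cooperative replies to
Tit-for-Tat — is not sensitive to the cost and is resolved by the
higher-order coefficients without comment. A *critical-cost* tie — tied
limits whose cost functions differ, so equality holds only at the specific
cost supplied — is reported via the `at_threshold` flag and the tied set,
because on either side of that cost the verdict differs and the analysis
never defines behaviour exactly at the boundary. `critical_cost()` and
`belief_switch_cost()` return those boundary costs as exact rationals:
1/3 (Grim-Trigger-1 becomes its own best response), 1/2 (WSLS stops being
its own best response), and the observer-side switches 16/33 and 2/9
derived below.

Enumeration is exhaustive over the sixteen strategies; there is nothing to
prune at this size and exhaustiveness makes every claim auditable. Mixed
(behaviour-strategy) residents are supported numerically via
`best_response_mixed()`; a sampling check in the test suite confirms the
genericity claim that a random mixed resident admits a unique pure best
response, so restricting the response search to pure strategies is not a
practical loss.

## What an observer can learn

A monomorphic resident population in its stationary state shows an observer
only (state, next-move) samples. In the small-error limit each strategy's
self-play stationary signature collapses to a distinctive limit
distribution, and the states that retain positive limit frequency are the
only ones whose prescriptions are identifiable with a realistic observation
budget. Counting observable states partitions the sixteen strategies:

* **Category I** (8 strategies): three or four observable states — the
  strategy is fully identifiable.
* **Category II** (2 strategies, `d1` and `d7`): two observable states,
  several consistent candidates — but all candidates share the same best
  response (AllD), so the ambiguity is harmless.
* **Category III** (6 strategies): a single observable state. An
  all-defect-looking population leaves `{d0, d6, d8}` as candidates; an
  all-cooperate-looking one leaves `{d9, d14, d15}`. This is where genuine
  uncertainty lives.

The observation budget `M` (pairs watched) sets the regime. Reactions at a
state with limit frequency of order `eps^k` are seen roughly `2 M eps^k`
times; with `1 << M << 1/eps` the observer gets excellent statistics at
observable states and essentially none at error-only states, so the
candidate ambiguity of Category III persists no matter how carefully she
watches. With `M >> 1/eps` the order-`eps` states are visited often enough
to discriminate, and inference reduces to exact identification. (Resolving
candidates that differ only at an `eps^2` state, such as `d0` versus `d8`
at mutual cooperation, requires the even larger budget `M >> 1/eps^2`; the
two regimes above are the ones the analysis contrasts.)

### Bayesian updating

Each observed pair contributes two records — the joint state from each
player's perspective together with that player's realised next move — which
uses all the stated information symmetrically. Conditional on the
candidate strategy, move records are independent Bernoulli draws with
success probability given by the error-perturbed prescription, so the
posterior is a product over records and sequential updating equals batch
updating exactly (exchangeability); the implementation works from
per-state move counts in log space. Observed *state frequencies* enter the
inference one level up, through the candidate set: the prior is uniform
over the strategies whose self-play signature matches what is seen, the
package's default reading of "assign equal probability to each candidate".
Sampling is i.i.d. across pairs from the stationary ensemble (pairs watched
for one round each, with replacement); watching fewer pairs for longer
would only change higher-order correlations that the likelihood above never
uses.

### Best-looking responses and equilibrium notions

Under a belief, the observer maximises the belief-weighted average payoff
series — the *best-looking response*. With the uniform belief over
`{d0, d6, d8}` the exact limit comparison gives WSLS below cost 16/33 and
Grim-Trigger-1 above; over `{d9, d14, d15}` it gives WSLS below 2/9 and
`d1` above. Three verdicts follow for each strategy:

* **NE**: best response to itself among the sixteen.
* **SCE** (self-confirming equilibrium): best-looking response to the
  belief its own monomorphic population induces. In the exact regime this
  coincides with NE; in the uncertain regime it differs exactly for the six
  Category-III strategies.
* **SCENE**: both at once.

The asymmetry the analysis turns on: AllD is always an NE but, for costs
below 16/33, an observer of a defecting population should play WSLS — so
full defection is *not* self-confirming, while WSLS at costs below 2/9 is
both. A cooperative convention can therefore survive observational
transmission where defection cannot.

## Priors beyond uniform: region maps

`simplex_region()` maps the best-looking response across all priors on a
three-candidate support, on a barycentric grid restricted to the *open*
simplex (`0 < f_i < 1`). The restriction is deliberate: on a closed edge
the limit expected payoffs of several candidates coincide identically and
the choice is decided at `O(eps)`, which is outside the region picture's
scope. Region boundaries are located by recursive subdivision between
adjacent grid cells with different winners, splitting any segment whose
midpoint belongs to a third region, so every reported boundary point
separates two genuinely adjacent regions — this matters at low cost, where
a thin `d13` strip separates the WSLS and AllC regions and naive pairwise
bisection would report spurious points.

The decision path is always the payoff argmax. The closed-form boundary
inequalities for the WSLS region (`wsls_prior_condition()`) are kept as
independent ground truth for validation only, which avoids hard-coding
transcribed fractions into the decision logic; the test suite checks that
located WSLS-region boundaries satisfy them pointwise to `1e-4` (they agree
to about `1e-6`, the bisection tolerance). Derivation note: on the
defect-looking support the two binding constraints are the comparisons of
WSLS against `d13` and against `d8`; on the cooperate-looking support the
binding alternative is `d1`. The WSLS region on the cooperate-looking
support is non-empty exactly up to cost 1/2 (`wsls_feasibility_cost()`):
its bounding condition is loosest at the point mass on `d9`, so the region
vanishes precisely when some alternative catches up against that belief —
the region maps on either side of 1/2 verify this independently.

## Synthetic data: what it emulates, and what it does not

`simulate_match()` runs the joint chain itself (compiled, using R's RNG so
`set.seed()` governs everything), from a uniform random initial state with
a 1000-round burn-in — initial moves are irrelevant to long-run averages,
the burn-in merely shortens the transient. Reported standard errors use
batch means (up to 100 batches), since the chain decorrelates on a
`1/eps` timescale and naive multinomial errors would be optimistic.
`sample_observations()` draws pair states i.i.d. from the exact stationary
distribution and realises both players' moves through the error channel;
`regime_sweep()` composes the two ends of the pipeline to show the
identification crossover around `M ~ 1/eps`.

These generators emulate the model's own data-generating process, not field
data: populations are perfectly monomorphic and exactly stationary, the
observer records states and moves without error of her own, and there is no
evolutionary (replicator or mutation) dynamics — the analysis is entirely
about best-response and belief structure. Passing simulation tests
therefore certify the analytic engine and the inference pipeline against
the model, and say nothing about behavioural data.

## Numerical choices

* Series order 2 by default (order 4-6 internally where leading orders of
  vanishing stationary entries are needed).
* Numeric lexicographic comparisons (only used for Monte-Carlo posteriors
  and grid scans) treat coefficients within `1e-11` as tied; exact paths
  have no tolerance at all.
* Beliefs with recognisably small-denominator weights (uniform priors and
  the like, denominators up to `1e4` reconstructed to double precision) are
  promoted to the exact path; Monte-Carlo posteriors stay numeric.
* Region grids default to step 0.01 (0.005 in the acceptance script);
  boundary subdivision tolerance `1e-6`.
* Problem sizes used by the tests and the acceptance script: match
  simulations of `1e5` rounds on a ten-pair panel; 200 replicates of
  `M = 100` observed pairs and one `M = 1e6` identification run at
  `eps = 1e-4`.

## Known limitations

* Exact arithmetic rests on integer-valued doubles: beyond `2^53` the
  engine stops with an overflow error instead of degrading. All quantities
  arising from the sixteen-strategy analysis fit comfortably; pointwise
  rational evaluation at tiny error rates does not (use the series).
* Best responses are enumerated within the memory-one pure space; mixed
  maximisers are only checked for non-genericity numerically.
* The observer model is the package's scope: no polymorphic populations, no
  observation of one's own play, no population dynamics.
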