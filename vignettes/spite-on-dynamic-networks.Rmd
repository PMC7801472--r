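---
title: "Spite on dynamic networks: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spite on dynamic networks: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spitenet)
```

## The scientific question

Spite — paying a cost to inflict a larger harm on someone else — is an
evolutionary puzzle: both parties end up worse off, so in a randomly
mixing population the harming strategy is strictly dominated and dies
out. Classical theory rescues costly harm only through *anti-correlated
interaction*: if, with probability $r$, individuals interact with
carriers of the other strategy, spite is favored once $r > c/b$, the
cost-to-harm ratio (a Hamilton-type rule with negative relatedness).
That account treats assortment as an exogenous global parameter.

`spitenet` implements an agent-based model in which assortment is
*endogenous*: agents on a weighted, directed network learn whom to
interact with (Roth–Erev reinforcement) at the same time as they learn
how to behave (payoff-biased imitation). The central result the package
reproduces is that spite can spread and fix even though the
population-average assortment stays near zero — social agents become
positively correlated and spiteful agents anti-correlated
*simultaneously*, something a single global $r$ cannot represent.

## The game

Two strategies, `social` and `spiteful`, play the Prisoner's Delight.
With the normalization $b + c = 1$:

|                | vs social | vs spiteful |
|----------------|-----------|-------------|
| **social**     | $1$       | $c$         |
| **spiteful**   | $b$       | $0$         |

Acting spitefully costs its actor $c$ (its payoff drops from 1 to $b$)
and removes $b$ from the partner. `social` strictly dominates
(`payoff(social, s) > payoff(spiteful, s)` for both `s`), so nothing
about the game itself favors harm; what matters is who meets whom.
`payoff_params()` enforces the normalization and warns when $b \le c$
(harm not exceeding cost), a boundary regime we permit but do not study.

## The simulation model

Each round, in this fixed order:

1. **Partner choice.** Every agent $i$ visits one host $j$ drawn with
   probability $(1-\epsilon)\, w_{ij} / \sum_k w_{ik} + \epsilon/(N-1)$.
   The error mass $\epsilon$ is spread over the $N-1$ partners so that
   the no-self-visit invariant holds exactly (the alternative
   $\epsilon/N$ convention differs by $O(\epsilon/N)$ and would leak
   probability onto self).
2. **Play.** Both participants of every visit are paid. An agent takes
   part in its own visit plus any number of incoming visits, so it has
   between 1 and $N$ interactions per round.
3. **Learning.** All weights are discounted, $w \leftarrow (1-\delta)w$,
   then each *visitor* adds $R\,\pi_i$ to the link it just used, where
   $\pi_i$ is the payoff from the visit it initiated. Updating is
   asymmetric: being visited never changes one's own preferences; this
   is what lets social agents cluster while spiteful agents keep
   reaching them. Discounting all links (not only the used one) is what
   allows *unlearning* of links toward agents that turned spiteful; the
   literal used-link-only reading is kept as
   `discount_scope = "visited_only"` for sensitivity checks.
4. **Imitation.** Each agent independently considers imitation with
   probability `lam`. With probability `e` it errs and adopts a uniform
   random strategy (possibly its own). Otherwise it picks a candidate
   among the agents it *interacted with this round*, in proportion to
   the combined link weight $w_{ij} + w_{ji}$, and copies the
   candidate's strategy iff the candidate's average payoff per
   interaction this round is strictly greater than its own. Updates are
   synchronous: everyone copies pre-round strategies.

### Why the candidate pool is the round's interaction set

The candidate pool was the one genuinely open design point. A
population-wide pool weighted by $w_{ij} + w_{ji}$ (available as
`candidate_pool = "all_agents"`) looks equivalent — weights concentrate
on frequent partners — but it is not: under it, a spiteful agent whose
row still carries weight on socials it is *not* currently exploiting
routinely compares itself against un-harmed socials earning the maximum
payoff, and converts back. Quantitatively this back-conversion overwhelms
the spread of spite at the baseline parameters; in our experiments the
population-wide pool never produced spiteful fixation at $N = 50$,
$\lambda = 0.01$ even over $10^6$ rounds, whereas the interaction-set
pool produces it in essentially every run by $2\times 10^5$ rounds.
The interaction-set pool is also exactly how the companion analytic
model imitates (its candidate set $B_i$ is drawn from the interaction
set $I_i$), so we made it the default and kept the population-wide pool
as an explicit toggle.

Two consequences are worth stating plainly. First, with interaction-set
imitation the invasion of spite from rare is largely insensitive to the
*network dynamics*: a lone spiteful agent earns $b$ per interaction on
almost any network, so it invades whenever its victims fall below $b$ —
the network matters for the co-existence phase and for protecting
spiteful agents from each other, not for the first foothold. Second,
under the population-wide pool on a *frozen* uniform network
(`R = 0, delta = 0`), spite is eliminated, which is the classical
random-mixing expectation; the test suite pins both behaviors.

### Parameters

| symbol | meaning | default | notes |
|--------|---------|---------|-------|
| `N` | population size | 50 | studied range 10–50 |
| `b`, `c` | game payoffs | 10/11, 1/11 | $b+c=1$; ratio $b/c$ is what matters |
| `lam` | imitation rate | 0.01 | per agent per round |
| `e` | imitation error | 0.01 | uniform re-draw of the outcome |
| `epsilon` | partner-choice error | 0.01 | uniform over partners |
| `delta` | weight discount | 0.01 | memory horizon $\sim 1/\delta$ rounds |
| `R` | learning rate | 1 | scales reinforcement vs. standing weights |
| `L` | initial-weight constant | 9 | weights start at $L/(N-1)$, so 1 at $N=10$ |
| `T` | rounds | $10^6$ | $2\times10^5$ suffices for fixation at baseline |

`L` is held constant across population sizes so that the initial row sum
(and hence relative learning speed) is the same for every `N`.

## Statistics

For agent $i$ with same-strategy set $\mathrm{Same}_i$ (which includes
$i$ itself, contributing zero weight since $w_{ii}=0$):

$$a_i = \frac{\sum_{j \in \mathrm{Same}_i} (w_{ij} + w_{ji})}
            {\sum_k (w_{ik} + w_{ki})} - \frac{|\mathrm{Same}_i|}{N}.$$

The self-inclusion convention is forced: it is the only reading under
which a lone spiteful agent has $a_i = -1/N$ and a homogeneous
population sits at 0. `correlation_summary()` averages $a_i$ overall
($\bar a$) and within each strategy; extinct strategies are reported as
0 (they can be re-seeded by imitation error, and the time series stays
rectangular). The exact identity
$\bar a = (n_\text{soc}\,a_\text{soc} + n_\text{spite}\,a_\text{spite})/N$
is pinned to $10^{-12}$ in the tests.

Per round we also export the four ordered visitor–host coupling shares,
per-strategy means *and* medians of per-agent average payoffs (the
imitation rule uses per-agent averages; medians are the conventional
display), the spiteful fraction, and — on demand — incoming weight by
strategy, which is the quantity behind the core–periphery pattern.

## The analytic model

The simplified model replaces learned weights with one discrete
best-response out-link per agent (everyone links to a uniformly chosen
social agent, since social partners dominate for both strategies),
payoffs averaged over the undirected interaction set, and imitation by a
uniform draw from the weakly-better performers in that set. Closed
forms follow:

* a single spiteful invader earns $\bar U = b$; its host expects
  $z = 1$ extra social visitors ($z \sim \mathrm{Binomial}(N-2,
  \tfrac{1}{N-2})$, mean exactly 1) and hence payoff $(c+2)/3$, so spite
  spreads iff $3b - c > 2$ (`single_invader_condition()`,
  `invasion_threshold_constant()`);
* with $x$ social and $y$ spiteful agents the condition generalizes to
  $b(3 + \tfrac{y-1}{x}) - c(1 + \tfrac{y-1}{x}) > 2$, monotone in
  $y/x$: once spreading starts it is expected to finish
  (`general_invasion_condition()`);
* the population correlation at the moment of invasion is
  $\bar a = \tfrac{1}{N}(\tfrac{2}{3} - \tfrac{2}{N})$: *positive* for
  all $N > 3$. Spite invades positively-correlated populations, so the
  classical necessary-looking condition $\bar a < -c/b$ is not necessary
  at all (`abar_at_invasion()`, `smallest_positive_abar_N()`).

One approximation should be noted: the closed form substitutes
$E[z] = 1$ inside the nonlinear share $(1+z)/(2+z)$. The exact
expectation $E[(1+z)/(2+z)] \approx 0.632$ (vs. $2/3$), so the exact
$\bar a$ at invasion differs from the closed form by about $0.035/N$.
The Monte-Carlo cross-check in the tests therefore compares against the
exact binomial expectation and separately bounds the closed form's gap
by $0.04/N$; the smallest-$N$-positive answer (4) is identical under
both.

`meanfield_fitness_gap()` implements the classical benchmark: with
exogenous anti-correlation $r$ the full expected-payoff computation
collapses to $W_\text{spite} - W_\text{social} = r b - c$ for every
social frequency, so the sign flips exactly at $r = c/b$
(`meanfield_threshold()` locates it by bisection).

`simulate_simplified()` is the stochastic oracle for these claims:
iterating link formation, payoffs and uniform imitation from the
candidate sets reproduces the $3b - c > 2$ threshold empirically.

## Numerical and reproducibility choices

* **One master RNG per run.** `run_simulation()` seeds R's generator
  once; every stochastic sub-step consumes deviates in a fixed,
  documented order (partner error branch, partner walk; imitation
  consider, error, candidate/strategy draw; Moran reproducer, target,
  error, strategy). Identical configuration and seed give bit-identical
  output.
* **Compiled core, readable reference.** The inner loop is C++
  (`run_rounds_cpp`); `run_round()` is the pure-R reference. Both
  accumulate cumulative sums in extended precision the way R's
  `cumsum()` does, so the two engines are *bit-identical*, which the
  tests assert — an unusually strong guard against transcription bugs
  in the compiled path.
* **Weight underflow.** In an all-spiteful population every payoff is 0
  and weights decay geometrically forever; around round $7\times10^4$
  they reach the subnormal range, where x86 arithmetic slows by an
  order of magnitude. Discounted weights below $10^{-280}$ are flushed
  to exact zero, and any weighted draw whose total is exactly zero
  falls back to a uniform choice — the random-mixing limit such a
  population is heading to anyway. Both engines apply the same rule.
* **Ties.** Imitation requires a *strictly* greater comparison value;
  equal payoffs never trigger a copy. In the analytic model the
  candidate set uses the weak inequality (so ties put neighbors in
  $B_i$), matching the spread-iff-strict convention of the invasion
  argument.
* **Scales used in the test suite.** The headline fixation checks run
  20 seeds of $2\times10^5$ rounds at $N = 50$ (about 2 s per run in
  the compiled engine); the full-scale $10^6$-round, 200-seed design
  is supported but not exercised by default. Analytic Monte-Carlo
  checks use $10^5$ link draws for the expected-visitor count and a few
  hundred to a few thousand replicates elsewhere, with 3-standard-error
  tolerances computed from the sample.

## The Moran and total-payoff variants

`rule = "total_payoff"` compares round totals instead of per-interaction
averages. This reverses the verdict in exactly the situation that powers
spite: a harmed social host with three interactions still out-*totals*
a spiteful visitor with one ($2 + c > b$ always), so spite collapses —
the package reproduces this as a 20-seed check. `rule = "moran"`
replaces per-agent imitation with one birth–death event per round
(reproduction proportional to average payoff per interaction, a uniform
victim, error `e` on the adopted strategy); with one event per round its
strategy dynamics are much slower than the baseline's at the same `T`.
Embedding a Moran process into a round-based model admits several event
cadences; one event per round is the standard minimal embedding, and we
label it an interpretation rather than the only possible one.

## What the generator emulates, and what it does not

All inputs are synthetic by construction — the model *is* the data
generator. The defaults are the study conditions (half/half random
initial strategies, uniform initial weights $L/(N-1)$, the Table-1
parameter values). Passing tests therefore show internal consistency
and reproduction of the model's expected quantitative behavior at
reduced replication; they do not validate the model against any
empirical interaction data.

Known limitations:

* Slow discounting is expected to dampen assortment and protect social
  populations (agents cannot unlearn links to partners that turned
  spiteful). Under the interaction-set candidate pool, however,
  `delta = 0.001` does *not* suppress spite in our runs — invasion from
  rare barely depends on the network — while the population-wide pool
  suppresses spite at *all* discount rates. The discount sweep is
  therefore the most pool-sensitive part of the model and results from
  it should be interpreted with the pool choice in mind.
* From the half/half start the takeover is fast (order $10^3$ rounds at
  the defaults), and during its late stage the *population-mean*
  correlation $\bar a$ dips to roughly $-0.2$, below $-c/b$. The
  per-strategy signs behave as advertised throughout
  ($a_\text{social} > 0$, $a_\text{spiteful} < 0$), and invasion from
  rare starts at $\bar a > 0$, but the claim that $\bar a$ stays above
  $-c/b$ during the whole spread does not hold in this implementation;
  the corresponding check in the test suite fails by design rather than
  being weakened.
* Fixation-time distributions are sensitive to `lam` relative to the
  network timescale $1/\delta$; claims in the tests are majority/large-
  majority statements over seeds, not point estimates.
* The Moran variant's event cadence is an interpretation (above).
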