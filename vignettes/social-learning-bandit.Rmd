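---
title: "Social-learning equilibria in a restless bandit: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Social-learning equilibria in a restless bandit: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmabgame)
```

## The model

A population of $N$ agents faces a restless multi-armed bandit with a single
good arm among infinitely many bad ones. The state of the system is the
vector $\sigma = (\sigma_1,\dots,\sigma_N)$ of indicators, $\sigma_n = 1$
when agent $n$ currently knows the good arm. One turn consists of exactly
one of two events:

* with probability $q_C/N$ the good arm relocates; every agent forgets it
  (global reset to $\sigma = \vec 0$);
* otherwise one agent is chosen uniformly. An informed agent exploits the
  good arm (no state change). An uninformed agent $n$ attempts social
  learning with probability $r_n$ — copying an informed agent, which
  succeeds with probability $q_O$ but is possible only while at least one
  agent is informed — and otherwise searches at random, succeeding with
  probability $q_I$.

The strategy of agent $n$ is the single number $r_n \in [0,1)$, the
probability of choosing copying over searching when uninformed. We exclude
$r_n = 1$: a population of pure copiers produces no information, and the
chain over knowledge states would lose its unique stationary law. All of
$q_C, q_I, q_O$ are required positive for the same reason.

The **fitness** of agent $n$ is the stationary probability of being
informed, $w_n = E[\sigma_n]$ — not a cumulative reward. Scaling by the
$1/N$ chance of acting per turn relates it to per-turn payoff, but the
package deliberately works with the occupancy probability itself.

Two derived quantities recur. The *effective turnover rate*

$$a = \frac{q_C}{1 - q_C/N}$$

is recomputed on demand (`effective_rate()`) rather than stored, so it can
never go stale when parameters are built programmatically. The
*leave-one-out mean* $\bar r_n = \frac{1}{N-1}\sum_{k \ne n} r_k$ is the
mean field a focal agent faces; for $N = 1$ we define $\bar r = 0$ by
convention — the $(N-1)$-weighted terms vanish identically at $N = 1$, so
the value is immaterial, and 0 keeps every formula finite.

## Closed-form fitness and its oracle

The stationary marginals admit the closed form

$$w(r,\bar r)=\frac{1}{a+q_I+(q_O-q_I)r}\left\{q_I+(q_O-q_I)r
  -\frac{a q_O r}{a+(N-1)q_I(1-\bar r)+q_I(1-r)}\right\},$$

with $w_n = w(r_n, \bar r_n)$. Because this expression is the package's
load-bearing primitive, it is validated against a brute-force oracle: the
exact Markov chain over all $2^N$ knowledge states
(`knowledge_chain()`), whose transition matrix is the mixture

$$T(\sigma'|\sigma)=\Bigl(1-\tfrac{q_C}{N}\Bigr)
 \Bigl\{\bigl(1-\textstyle\sum_n p_n(\sigma)\bigr)\delta_{\sigma',\sigma}
 +\sum_n p_n(\sigma)\,\delta_{\sigma',\sigma+e_n}\Bigr\}
 +\tfrac{q_C}{N}\,\delta_{\sigma',\vec 0},
 \qquad
 p_n(\sigma)=\frac{\delta_{\sigma_n,0}}{N}\bigl\{r_n(1-\delta_{N_1,0})q_O
 +(1-r_n)q_I\bigr\}.$$

Columns index the source state (distributions evolve as $p' = Tp$). The
stationary vector is obtained by a linear solve with one balance row
replaced by the normalization constraint; power iteration (tolerance
$10^{-12}$) is the fallback if the solve fails. The test suite checks
closed-form/chain agreement to $10^{-8}$ entrywise over randomized
parameters and profiles for every $N$ from 1 to 10.

The dense chain is capped at $N \le 14$ ($2^{14}$ states): it is an oracle
and a teaching tool, not a production path, and a lumped or sparse variant
would only be valid for homogeneous profiles anyway.

`spectral_gap()` reports the modulus $\rho < 1$ of the largest non-unit
eigenvalue and the relaxation time $\tau = -1/\log\rho$. We use the
standard sign convention, under which $\tau$ is positive and
$\lVert P(t)-P\rVert \sim \rho^t = e^{-t/\tau}$.

## Pure strategies and the scrounger pattern

Splitting the population into $N_I$ pure searchers and $N - N_I$ pure
copiers gives

$$w_I=\frac{q_I}{a+q_I},\qquad
  w_S=\frac{N_I\,q_I\,q_O}{(a+N_I q_I)(a+q_O)} .$$

`group_fitness()` evaluates these; the cross-check
$w_S = w(1, (N_S-1)/(N-1))$ ties them back to the mixed-strategy formula
(the only place $r = 1$ is accepted for evaluation). As the share of
copiers grows, $w_S$ falls from above $w_I$ to zero — information
scrounging undermines itself, which is the paradoxical pure-strategy
outcome the equilibrium analysis resolves.

## Best response, Nash equilibrium, ESS

For $q_O > q_I$ the focal fitness $r \mapsto w(r, \bar r)$ has a unique
maximizer, the clamp to $[0,1]$ of

$$\bar f(\bar r)=\frac{-\zeta+\sqrt{q_O(N-1)(1-\bar r)}\sqrt{\zeta}}
  {q_O-q_I},\qquad \zeta=a+q_I+q_I(N-1)(1-\bar r);$$

for $q_O \le q_I$ the best response is identically 0. The equilibrium is
the unique fixed point of the induced map on the strategy cube and is
homogeneous. Its closed form is

$$r_{\mathrm{Nash}}=\begin{cases}1-\eta,&(q_O-q_I)N>a+q_O,\\
 0,&\text{otherwise},\end{cases}\qquad
 \eta=\frac{2(a+q_O)^2}{(q_O-q_IN)(a+q_O)+(aN+q_O)(q_O-q_I)+\sqrt{D_1}}.$$

The condition $(q_O-q_I)N>a+q_O$ — the *regime* — separates positive
equilibrium social learning from none; rearranged for $q_I$ it gives the
threshold $((N-1)q_O-a)/N$ exposed by `regime_boundary()`. Parameters
exactly on the boundary are classified as outside the regime, matching the
closed forms' zero branch.

Three independent routes to $r_{\mathrm{Nash}}$ are implemented and must
agree to $10^{-8}$:

1. the closed form above (`nash_closed()`);
2. bisection on $h(r) = r - f(r)$ (`nash_bisect()`), valid because $h$ is
   strictly increasing with $h(0)\le 0\le h(1)$; tolerance $10^{-10}$,
   at most 200 iterations. Bisection was chosen over Newton for
   unconditional convergence;
3. damped fixed-point iteration $r \leftarrow (1-\lambda)r + \lambda f(r)$
   (`nash_fixed_point()`). The damping starts at $\lambda = 1/2$ and is
   halved whenever the residual $|r - f(r)|$ fails to contract. The
   adaptivity matters: at the reference parameters below,
   $f'(r_{\mathrm{Nash}}) \approx -3.7$, so any *fixed*
   $\lambda \gtrsim 0.43$ — including $1/2$ — produces a divergent
   oscillation. Because $f$ is decreasing, $|r - f(r)| \ge |r -
   r_{\mathrm{Nash}}|$, so the stopping rule bounds the true error.

Uniqueness is certified through the self-consistency map
$g(r) = f\bigl((s-r)/(N-1)\bigr)$ for a candidate fixed-point sum $s$
(`self_consistency_map()`): on its clamp-free interval
$[\,s-(N-1)r^*,\ s-(N-1)r_*\,]$, where $r^*$ is the zero of $\bar f$ and
$r_*$ its unit crossing, $g$ is strictly increasing and concave with
derivative at most $1/2$, attained at the left endpoint — so fixed-point
components cannot split. The tests verify the $1/2$ bound by central
differences to $10^{-3}$.

The equilibrium is a strict Nash point and an ESS in the sense of Thomas:

$$w(r_{\mathrm{Nash}},r_{\mathrm{Nash}})>w(r,r_{\mathrm{Nash}}),\qquad
  w(r_{\mathrm{Nash}},r)>w(r,r)\qquad\text{for }r\ne r_{\mathrm{Nash}}.$$

`verify_ess()` certifies both numerically on a grid (default 1001 points)
with a strictness margin of $10^{-9}$, excluding a ball of two grid steps
around the equilibrium where both slacks vanish by construction. The
certificate is only claimed for regime parameters; at $r_{\mathrm{Nash}}=0$
the inequalities are boundary cases and the tests assert weak dominance
only.

## Pareto point and the fitness ordering

The total fitness over the cube is maximized on the diagonal at

$$r_{\mathrm{Pareto}}=\frac{(a+q_IN)X-(a+q_I)Y}{q_INX+(q_O-q_I)Y},\qquad
 X=\sqrt{(N-1)(a+q_O)(q_O-q_I)},\quad Y=\sqrt{(a+Nq_I)Nq_O}$$

in the regime, and at 0 otherwise (`pareto_closed()`). Negative radicands
raise an error rather than clamping: they cannot occur for validated
parameters, so their appearance would signal a transcription bug, and
silent clamping would mask it.

The ordering $r_{\mathrm{Pareto}} < r_{\mathrm{Nash}} < r_I$, where
$r_I = 1-(a+q_O)/((q_O-q_I)N)$ is the non-trivial diagonal point with
$w(r_I,r_I)=w_I$, is certified through the quadratic in $u = 1/(1-r)$

$$k(u)=(a+q_O)^2u^2-\bigl\{(q_O-q_IN)(a+q_O)+(aN+q_O)(q_O-q_I)\bigr\}u
 +(q_O-q_I)(q_O-q_IN^2),$$

obtained by squaring the interior fixed-point relation
$r = \bar f(r)$; its larger root is exactly $1/(1-r_{\mathrm{Nash}})$ and
its discriminant is the $D_1$ of the Nash closed form (both identities are
tested to $10^{-8}$). The sign pattern $k(1)<0$,
$k(1/(1-r_{\mathrm{Pareto}}))<0$, $k(1/(1-r_I))>0$ pins the ordering.
Consequently the fitness triple satisfies

$$w_P > w_N > w_I \quad\text{in the regime},\qquad
  w_P = w_N = w_I \quad\text{otherwise},$$

which is the resolution of the social-learning paradox: at the mixed ESS,
social learning strictly pays relative to pure individual learning —
though less than the cooperative optimum would.

```{r}
eq <- equilibrium(rmab(N = 10, q_C = 0.2, q_I = 0.3, q_O = 0.8))
eq
```

## The Monte Carlo simulator

`simulate()` runs the turn-by-turn narrative in compiled code. Design
choices that matter for exactness:

* **Event ordering.** The reset and the agent action are *mutually
  exclusive* within a turn, exactly as in the transition-matrix mixture.
  (A narrative reading where an action is followed by a possible reset in
  the same turn yields a slightly different one-turn kernel; we implement
  the matrix form, which is the mathematical definition of the process,
  so the simulator and `knowledge_chain()` estimate the same law — this
  equality is tested against empirical one-step transition frequencies.)
* **Draw order.** Each turn draws, in fixed order from R's RNG: the reset
  uniform; if no reset, the agent index; if the agent is uninformed, the
  action choice and then a success uniform (always consumed, so a copy
  attempt in an empty population fails but keeps the stream aligned).
  `set.seed()` therefore reproduces traces bit for bit.
* **Copy feasibility** is evaluated on the informed count before the
  action; the copier is uninformed by construction, so the count refers to
  the other agents.
* **Storage.** The per-turn state bitmask is kept (4 bytes/turn, so a
  $10^6$-turn trace is a few MB), which allows the burn-in to be chosen at
  estimation time; the full event log is opt-in. This caps the simulator
  at $N \le 30$, far beyond any desk-scale use here.

`estimate_fitness()` reports per-agent occupancy means after a burn-in,
with batch-means standard errors over at least 20 equal consecutive
batches, plus a variance-based effective sample size. The default burn-in
is $\max(100, \lceil 20N/q_C\rceil)$ — a deliberately generous surrogate
for $20\tau$ that avoids the $2^N$ eigenproblem; `default_burn_in(...,
spectral = TRUE)` computes $\lceil 20\tau\rceil$ exactly for $N \le 14$,
and the tests confirm the surrogate dominates it. Agreement with the
closed form is asserted at 4 batch-means SEs; at the $10^6$-turn scale
used in the acceptance-style tests the SEs are a few $10^{-3}$, so this is
a sub-percent check.

## What the generated data do and do not show

All inputs are generated in code: random parameter/profile draws under
fixed seeds, the exact chain, and seeded simulations. Passing tests
demonstrate internal consistency of the three routes (closed form, exact
chain, stochastic simulation) and of the closed-form solvers against their
numeric counterparts, under the model's own assumptions — a single good
arm, uniform turn order, memoryless reset, strategies fixed over time.
They say nothing about behavioural realism: no learning dynamics on the
$r_n$, no payoff accounting, no heterogeneous copy networks, and only
steady states (a time-dependent theory is out of scope). Problem sizes in
the tests ($N \le 10$ for the exact chain, $10^6$-turn simulations,
201-point response-field grids, 1001-point certificate grids) were chosen
so each certificate is decisive at its stated tolerance while the whole
suite stays interactive on a laptop.

## Numerical conventions

* Probabilities are validated with strict inequalities at a boundary
  tolerance of $10^{-12}$; `strategy_profile()` rejects $r_n = 1$,
  `fitness_closed()` accepts it for the group-fitness cross-check only.
* Bisection: tolerance $10^{-10}$, cap 200 iterations; fixed-point:
  residual tolerance $10^{-10}$, cap 500, adaptive damping as above.
* Square-root guards raise errors instead of clamping (see the Pareto
  section); the discriminants $D_1, D_2$ are provably nonnegative in the
  regime, so a negative value indicates a bug rather than bad input.
* Two-group evaluations through the chain or simulator replace $r = 1$ by
  $1 - 10^{-9}$; the resulting bias is below $10^{-5}$ and the tests
  account for it.
* The equality branch of the regime condition is classified as
  no-social-learning, so the solvers are total on valid parameters.
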