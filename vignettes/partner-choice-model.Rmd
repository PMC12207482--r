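---
title: "Statistical discrimination in iterated partner choice: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical discrimination in iterated partner choice: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(partnerbias)
```

## The problem

Statistical discrimination arises when a decision maker cannot observe the
quality of a potential partner directly and instead leans on a perceptible
feature — here, color — that correlated with quality in their past
experience. `partnerbias` models this in the simplest setting that still has
the essential temporal structure: an iterated Stag hunt in which one *focal*
individual repeatedly chooses a partner, interacts, observes the outcome,
and chooses again. Coplayers play unconditional strategies (always cooperate
or always defect) and come in two colors, purple and teal; the population is
described by the cooperator proportions by color, $\rho$ (purple) and
$\tau$ (teal).

The interaction is a Stag hunt with payoffs $R > T \ge P > S$: coordinating
on cooperation beats the safe option, but cooperating with a defector is
worst. Payoff values never enter the association statistics, so only the
ordering is enforced (`stag_hunt_payoffs()`, defaults $R=4, T=3, P=3,
S=1$).

## The focal agent

Three probabilities summarise a boundedly rational focal:

| parameter | meaning | default |
|---|---|---|
| $\omega$ (awareness) | probability of identifying and picking a cooperator when forced to choose a new partner | 0.5 |
| $s$ (stickiness) | probability of re-pairing with the previous partner after that partner cooperated | 0.5 |
| $b$ (bias) | probability of choosing a purple partner when both channels above fail | 0.5 |

All three live in $[0,1]$ and are validated once, at construction
(`focal_params()`); operations assume valid inputs thereafter.

## The analytical recursion

The association distribution $P(i)$ gives the probability that the race-$i$
partner is each of the four types, always in the canonical order
$\{(p,c), (p,d), (t,c), (t,d)\}$. The first choice is by color alone,

$$P(0) = \big(b\rho,\; b(1-\rho),\; (1-b)\tau,\; (1-b)(1-\tau)\big),$$

because no interaction has been observed yet. When choosing anew, the focal
finds a cooperator with probability $\omega$ (colors split by cooperation
prevalence, $C = (\tfrac{\rho}{\rho+\tau}, 0, \tfrac{\tau}{\rho+\tau}, 0)$)
and otherwise falls back on bias, so the new-partner distribution is
$\nu = \omega C + (1-\omega) P(0)$. Writing
$\gamma(i) = P_{pc}(i) + P_{tc}(i)$ for the cooperator mass and $g(i)$ for
the cooperator-conditional color distribution, one iteration is

$$P(i+1) = (1 - s\,\gamma(i))\,\nu + s\,\gamma(i)\, g(i).$$

The cooperator mass obeys an affine first-order autonomous recursion with
the closed form

$$\gamma(i) = e\,\frac{1-f^i}{1-f} + f^i \gamma_0, \qquad
  e = 1-(1-\omega)(1-\gamma_0),\quad f = s(1-\omega)(1-\gamma_0),$$

converging geometrically to $e/(1-f)$. We take
$\gamma_0 = b\rho + (1-b)\tau$, the cooperator mass of $P(0)$. The package
computes $P(i)$ by the recursion (`trajectory()`) and uses the closed form
(`gamma_closed_form()`) as an independent cross-check: the test suite
verifies agreement to $10^{-10}$ over a thousand random parameter tuples.

Numerical choices worth knowing:

* **One canonical ordering.** Cooperator-only vectors ($C$, $g$) are stored
  in the same canonical type order as $P$, so convex combinations are always
  of like-indexed vectors.
* **$f = 1$** (possible only for $s=1$, $\omega=0$, $\gamma_0=0$): the
  geometric sum is replaced by its continuity limit $e\,i + \gamma_0$ when
  $|1-f| < 10^{-14}$.
* **$\gamma(i) = 0$**: $g(i)$ is undefined but its coefficient is zero, so
  the step returns $\nu$ without evaluating $g$.
* **Validation tolerance** $10^{-12}$: entries within tolerance of 0 or 1
  are clipped; anything further out raises an error, so float noise is
  forgiven but logic errors are not.

## The discrimination index

For the $2\times 2$ association matrix (colors by rows, strategies by
columns),

$$D = \big(|P_{pc}-P_{pd}| + |P_{tc}-P_{td}|\big)
    - \big(|P_{pc}-P_{tc}| + |P_{pd}-P_{td}|\big) \in [-1, 1].$$

$D>0$ means association driven by behavior, $D<0$ by color, and $D=0$ means
any oversampling of a color is exactly matched by oversampling of a
behavior. The index negates exactly under exchanging the roles of rows and
columns and is invariant under relabelling the colors; both symmetries are
property-tested against a brute-force evaluation on random simplex points.

## The episode simulator

`run_episodes()` plays the four-phase protocol (free mixing, partner
choice, interaction, outcome) for `n_races` races per episode (default 8)
with 6 players (focal plus `n_coplayers = 5` sampled from a community).
The focal decision cascade per race is: stick with probability $s$ if the
previous partner cooperated; otherwise identify a cooperator (intervention
flags first, then base awareness); otherwise pick a color by $b$ and a
uniform coplayer of that color, falling back to the other color when
necessary. The first race of an episode uses bias alone, matching $P(0)$:
neither flags nor observed interactions exist yet.

Two deliberate simplifications:

* **The focal always cooperates.** Against unconditional coplayers the Stag
  hunt best response to a chosen cooperator is to cooperate, and the object
  of study is partner choice, not the rowing policy. The focal payoff is
  therefore $R$ against a cooperator and $S$ against a defector.
* **Nonfocal pairings are not simulated.** With unconditional strategies and
  frozen parameters, the other players' pairings cannot influence any
  recorded (focal-centric) quantity.

Communities are generated by `make_community()`: exactly half of each
color; with training bias $c$, within-color cooperator fractions
$\rho = (1+c)/2$ and $\tau = (1-c)/2$ — the unique linear map that keeps
half of all agents cooperating while making $c$ the color–strategy
correlation. The *evaluation community* is the $c=0$ case. The episode
protocol fixes only the 6 players per race, not the pool they are drawn
from; we default to a community of 20 (10 cooperators, 10 defectors), large
enough that rosters vary across episodes yet small enough that the sampled
composition stays balanced in expectation.

**Infinite-population mode** draws the partner's type directly from the
analytic choice distributions, so each new partner is a fresh individual.
This mode exists as the simulator's oracle: its per-race frequencies must
match `trajectory()` to Monte-Carlo accuracy, which the suite checks over a
parameter grid. It is also the cleanest setting for parameter recovery
(e.g. `empirical_behavior()` recovering $s$ against always-cooperating
partners).

**Seeding.** Finite parametric runs spawn one child seed per episode from
the root seed, so growing the episode count never perturbs earlier
episodes. The uniform-random-policy and infinite-population paths are
vectorised across episodes and consume a single stream derived from the
root seed. Either way, a seed pins the full record table bit-for-bit.

## The perceptual intervention

The intervention places an honest flag ("crown") on players who cooperated
during the last interaction (threshold 0.75 of actions, trivially met by
unconditional cooperators). Its persistence into the next partner-choice
phase is the availability $q(\beta)$, a monotone interpolation through
$q(0)=1$, $q(0.002)=0.75$, $q(0.005)=0.5$, $q(0.02)=0$; the exact temporal
geometry of the decay is environment-specific, so `intervention_spec()`
also accepts an explicit availability. Because the flag check and the base
awareness check are independent channels, the effective awareness from race
1 onward is

$$\omega' = 1 - (1-\omega)\,\big(1-q(\beta)\big),$$

and race 0 is untouched — the flag cannot exist before the first
interaction. `trajectory(..., intervention = )` applies $\omega'$ to every
recursion step while leaving $P(0)$ alone.

```{r intervention}
trajectory(focal_params(omega = 0, s = 0.5, b = 0.9),
           population_params(0.5, 0.5), n_iters = 3,
           intervention = intervention_spec(beta = 0))
```

## Estimation from episodes

* `association_proportions()` pools the per-race partner-type counts across
  episodes (races without a partner are dropped from that race's
  denominator).
* `discrimination_trace()` reports the index of the pooled proportions per
  race, with a percentile bootstrap that resamples **whole episodes**
  (default 5,000 resamples, 95% level) — the same episode resample is used
  at every race index so the within-episode dependence survives. The
  percentile method is the simplest one consistent with an episode-level
  resampling design; the level is a free choice exposed as an argument.
* `empirical_behavior()` estimates awareness as the share of partnered
  races with a cooperator partner, and stickiness as the share of
  consecutive partnered race pairs with the same partner. Both are
  *unconditional*, as behavior would be measured from observed episodes;
  the stickiness denominator includes only race pairs partnered on both
  sides, since the quantity is undefined otherwise. Under uniform random
  choice among $k$ coplayers the expected stickiness is exactly $1/k$
  (0.2 at the default 5), and a balanced community gives awareness 0.5 —
  the two calibration baselines `random_baselines()` recomputes by
  simulation.

Because the first race is chosen by bias alone, the all-races awareness
estimate of an $\omega = 1$ focal converges to $(\gamma_0 + n - 1)/n$ over
$n$ races, not to 1; filtering the record table to races $\ge 1$ (a plain
`dplyr::filter`) recovers the generating parameter exactly.

## Sweeps

`contour_sweep()` evaluates $D$ at iteration 8 (the caption-level choice:
the distribution after eight recursion steps) over a stickiness–awareness
grid, averaged over a color-bias grid — by default the unweighted mean of
$D$ over 11 evenly spaced $b$ values, computed in the evaluation
composition $\rho=\tau=0.5$, i.e. the measurement context; any other
composition can be passed via `pop`. `bias_sweep()` mirrors the evaluation
protocol: a focal with $b = (1+c)/2$ — the purple preference acquired when
purple correlated with cooperation at level $c$ during training, so $c=0$
is color-blind — plays against the unbiased community, 600 episodes per
bias by default.

```{r contour, eval = FALSE}
sw <- contour_sweep()   # 21 x 21 grid, 11 b values, deterministic
autoplot(sw)
```

On this surface $D$ is non-decreasing in $\omega$ at every $s$ (verified on
the full grid in the tests). The role of $s$ deserves care, and is a known
limitation of reading the surface casually: the *transient* of the
recursion is geometric with rate $f \propto s$, so the distance of
$\gamma(8)$ from its limit is bounded by $f^8$ — negligible for
$s \le 0.8$ and substantial only near $s = 1$ (asserted in the tests).
But the value of $D(8)$ also depends on $s$ through the recursion's
*fixed point* $(1-s\gamma)\nu + s\gamma g$, and that dependence is spread
smoothly across the whole $[0,1]$ range. A reading of the surface that
attributes all low-$s$ structure to the transient will therefore
mispredict it; the package asserts the transient statement, which is the
one the mathematics supports.

## What the simulations do and do not show

The synthetic episodes emulate the protocol-level structure: biased
training communities, unbiased evaluation communities, roster sampling,
within-episode partner persistence, and the intervention signal. They do
not emulate a spatial environment — no movement, no pixel perception, no
race disqualification (which in richer environments shrinks the partner
pool and inflates empirical stickiness; our estimator therefore need not
reproduce above-random stickiness values observed there), and no learning
agents: focal parameters are fixed, matching a frozen-agent evaluation.
Passing tests certify the mathematics of the model and the calibration of
the estimators, not the behavior of any trained agent.

## Problem sizes used by the test and acceptance code

Chosen as the package's own trade-off between Monte-Carlo error and a
comfortable desk-scale run: calibration baselines use 20,000 episodes
(binomial standard errors near $10^{-3}$); the simulator-versus-recursion
oracle uses 50,000 episodes per cell of a $3^3$ parameter grid; closed-form
agreement uses 1,000 random tuples to iteration 32; index symmetries use
10,000 random simplex points. A note on reading many simultaneous 3-SE
comparisons: with several hundred of them, an occasional chance excursion
slightly past 3 SE is the expected behavior of a *correct* simulator, so a
single marginal exceedance should be judged against independent replicates
of the affected cell rather than read as a defect.
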