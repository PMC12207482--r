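# partnerbias

Analytical and Monte-Carlo models of **statistical discrimination in
iterated partner choice**, for researchers in behavioral game theory and
social evolution who want to study how color-based association arises — and
how perceptual interventions undo it — without training any learning
agents.

A focal individual repeatedly picks a partner for an iterated Stag hunt
(payoffs `R > T ≥ P > S`) from a population of unconditional cooperators
and defectors in two colors (purple cooperator proportion ρ, teal τ). The
focal is characterised by three probabilities: **awareness** ω (picking a
cooperator when choosing anew), **stickiness** s (re-pairing after a good
interaction), and **color bias** b (preferring purple otherwise). The
association distribution over partner types evolves by the recursion

    P(i+1) = (1 − s·γ(i))·ν + s·γ(i)·g(i),
    ν = ω·C + (1 − ω)·P(0),      P(0) = (bρ, b(1−ρ), (1−b)τ, (1−b)(1−τ)),

whose cooperator mass γ(i) = P_pc(i) + P_tc(i) has the closed form
γ(i) = e·(1−f^i)/(1−f) + f^i·γ0 with e = 1−(1−ω)(1−γ0),
f = s(1−ω)(1−γ0). Discrimination is measured by the index

    D = (|P_pc − P_pd| + |P_tc − P_td|) − (|P_pc − P_tc| + |P_pd − P_td|),

positive when the focal associates by behavior, negative when by color.

The package provides:

* the exact recursion and closed form (`trajectory()`,
  `gamma_closed_form()`, `partner_model()` with `tidy()`/`glance()`);
* the discrimination index and its estimation from episodes
  (`discrimination_index()`, `discrimination_trace()` with an
  episode-level percentile bootstrap, `empirical_behavior()`);
* an agent-based episode simulator of the full protocol, including biased
  training communities, unbiased evaluation communities and the
  perceptual-intervention signal (`make_community()`, `run_episodes()`,
  `intervention_spec()`);
* parameter sweeps and calibration baselines (`contour_sweep()`,
  `bias_sweep()`, `random_baselines()`), `autoplot()` methods, a YAML
  config layer and a small CLI (`exec/partnerbias`).

## Worked example

```r
library(partnerbias)

focal <- focal_params(omega = 0.5, s = 0.5, b = 0.5)
pop   <- population_params(rho = 0.75, tau = 0.25)
m <- partner_model(focal, pop, n_races = 8)
m
#> <partner_model> omega = 0.5, s = 0.5, b = 0.5 | rho = 0.75, tau = 0.25 | 8 iterations
#>   gamma0 = 0.5000, e = 0.7500, f = 0.1250, D(last) = 0.2143
glance(m)
#> # A tibble: 1 × 7
#>   gamma0     e     f gamma_limit d_first d_last n_iters
#>    <dbl> <dbl> <dbl>       <dbl>   <dbl>  <dbl>   <int>
#> 1    0.5  0.75 0.125       0.857       0  0.214       8
tidy(m)
#> # A tibble: 9 × 7
#>   iteration  p_pc   p_pd  p_tc  p_td gamma     d
#>       <int> <dbl>  <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1         0 0.375 0.125  0.125 0.375 0.5   0
#> 2         1 0.609 0.0469 0.203 0.141 0.812 0.125
#> 3         2 0.639 0.0371 0.213 0.111 0.852 0.203
#> # …
```

Half the focal's first choices are cooperators (γ0 = 0.5, so D = 0 at race
0: bias alone conveys no behavioral information here), but stickiness and
awareness compound across races: the cooperator mass climbs toward its
limit 6/7 ≈ 0.857 and the index after eight races is 0.214 — association
has tilted toward behavior. A Monte-Carlo calibration of the estimators:

```r
random_baselines(n_episodes = 20000, seed = 1)
#> # A tibble: 1 × 9
#>   awareness_hat stickiness_hat se_awareness se_stickiness n_episodes ...
#> 1         0.499          0.199      0.00125       0.00107      20000
```

A focal that picks uniformly among its 5 coplayers in a balanced community
hits the analytic baselines: awareness 0.5 (half the partners cooperate)
and stickiness 1/5 (one coplayer in five is the previous partner).

The same things are available from the shell:

```sh
Rscript exec/partnerbias analytic --omega 0.5 --s 0.5 --b 0.5 \
    --rho 0.75 --tau 0.25 --races 8 --out trajectory.csv
Rscript exec/partnerbias baselines --episodes 20000 --seed 1 --out baselines.csv
```

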