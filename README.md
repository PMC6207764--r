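# coopcost

Cost-efficient external incentives for cooperation in finite populations.

`coopcost` is for researchers in evolutionary game theory and institutional
incentive design who ask: if an *external* decision-maker (an institution, a
fund, a wildlife manager) can pay cooperators to steer a population playing
the one-shot Prisoner's Dilemma, **when** should it pay, and **how much**, so
that a target level of cooperation is guaranteed at the lowest expected total
cost?

## The model

A well-mixed population of `N` self-regarding players repeatedly revises
strategies (cooperate, C, or defect, D) by pairwise comparison: a focal
player imitates a random model player with the Fermi probability
`(1 + exp(-β Δf))⁻¹`, where `β` is the selection intensity. Payoffs come
from the PD matrix `(R, T, S, P)` with `T > R > P > S`, averaged over all
co-players. An **interference scheme** `Θ = {θ₁, …, θ_{N−1}}` invests a
total `θ_i` whenever the population holds `i` cooperators, raising each
cooperator's payoff by `θ_i / i`; the **individual-based** family pays each
cooperator a fixed `θ` whenever the cooperator count is at most a threshold
`t` (`t = N − 1` is FULL-INVEST, the classic always-pay institutional
reward).

In the small-mutation limit the population hops between the two homogeneous
states, and three exact quantities drive everything:

* the fixation probabilities `ρ_DC`, `ρ_CD` of a single mutant, whose ratio
  telescopes to `ρ_DC/ρ_CD = exp{β [N(R+S−T−P)/2 + (P−R) + G]}` with
  `G = Σ_k θ_k/k` — so the stationary cooperation frequency
  `ρ_DC/(ρ_DC+ρ_CD)` depends on a scheme only through the scalar `G`
  (`G = tθ` for the individual-based family);
* the expected total cost `EC = ½ Σ_i (n_{1i} + n_{N−1,i}) θ_i`, from the
  fundamental matrix `(I − U)⁻¹` of the absorbing cooperator-count chain
  under the convention that mutants appear at `S₁` or `S_{N−1}` with equal
  probability;
* the sufficient condition
  `G ≥ (1/β) ln(ω/(1−ω)) + N(T+P−R−S)/2 + (R−P)`, which is exact in both
  directions and converts directly into minimal investments `θ` and minimal
  thresholds `t` for any target cooperation fraction `ω`.

The interesting phenomenon is that `EC` is *non-monotone* in `t`: below a
selection-intensity-dependent point, paying in fewer states (smaller `t`)
is cheaper, so an intermediate threshold `t*` beats FULL-INVEST while
guaranteeing the same cooperation level. An agent-based Monte-Carlo
simulator (`simulate_episodes()`, `simulate_stationary()`) provides an
independent stochastic check of every analytic quantity at small `N`.

## Worked example

```r
library(coopcost)

game   <- pd_game(R = 1, T = 2, S = -1, P = 0)
params <- evo_params(N = 100, beta = 0.1)

# How widely must we invest theta = 1 per cooperator to reach 40% cooperation?
min_t(theta = 1, omega = 0.4, game, params)
#> t_min = 97, feasible = TRUE        (g_bound = 96.95)
min_t(theta = 1, omega = 0.5, game, params)
#> t_min = 101, feasible = FALSE      (needs more than N - 1 = 99 states)
min_t(theta = 5, omega = 0.99, game, params)$t_min   #> 30
min_t(theta = 40, omega = 0.99, game, params)$t_min  #> 4

# The scheme (theta = 5, t = 30) indeed sustains 99% cooperation:
cooperation_frequency(game, params, scheme_individual(5, 30, 100))$coop_frequency
#> 0.9926085

# Cost-optimal threshold for a 90% target at theta = 5:
opt <- optimal_threshold(theta = 5, omega = 0.9, game, params)
glance(opt)
#> t_star = 91, ec_at_t_star = 173010.2  (FULL-INVEST costs 239124.7)
length(opt$better_than_full_set)
#> 20 thresholds beat FULL-INVEST while keeping >= 90% cooperation
```

`t_min` is the smallest number of cooperators up to which each of them must
be paid; `coop_frequency` is the long-run fraction of time the population is
fully cooperative; `ec_at_t_star` is the expected cumulative payout (payoff
units) over the chain's lifetime under the ½/½ mutant-start convention.

A command-line front end wrapping these functions is installed at
`inst/cli/coopctl.R` (e.g. `Rscript inst/cli/coopctl.R min-t --theta 5
--omega 0.99`).

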