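---
title: "Cost-efficient external interference in finite-population games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-efficient external interference in finite-population games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopcost)
```

## The question

An external decision-maker watches a finite, well-mixed population of `N`
players locked in a one-shot Prisoner's Dilemma and can spend money on
cooperators: whenever the population contains `i` cooperators, a total
amount `θ_i` is paid out and split equally among them. Defection keeps
reappearing through rare mutation, so the institution must keep paying
forever; the design problem is to pick the per-state amounts so that a
target fraction `ω` of long-run cooperation is guaranteed while the
expected cumulative payout stays as small as possible. `coopcost`
implements the exact analytic machinery for this problem together with a
stochastic simulator used as an independent check.

## Dynamics and assumptions

Strategy revision follows the pairwise-comparison rule: a focal player
adopts a random model player's strategy with the Fermi probability
$(1 + e^{-\beta(f_B - f_A)})^{-1}$, where $\beta \ge 0$ is the selection
intensity. Payoffs are averages over all $N - 1$ co-players (no
self-interaction), and the interference bonus enters *additively* as
$\theta_k/k$ on each cooperator's average payoff — this is the only channel
through which the institution touches the dynamics. We work throughout in
the small-mutation limit: mutations are rare enough that at most two
strategies coexist, so the population state is the cooperator count
$k \in \{0, \dots, N\}$, performing a birth–death chain whose one-step
probabilities are

$$T^{\pm}(k) = \frac{N-k}{N}\,\frac{k}{N}\,
  \left[1 + e^{\mp\beta \Delta_k}\right]^{-1}, \qquad
  \Delta_k = \Pi_C(k) + \theta_k/k - \Pi_D(k).$$

Key structural facts the package exploits:

* the one-step ratio is exactly $T^-(k)/T^+(k) = e^{-\beta\Delta_k}$, so
  the product in the classic fixation-probability formula telescopes;
* consequently $\log(\rho_{D,C}/\rho_{C,D}) =
  \beta\,[\,N(R+S-T-P)/2 + (P-R) + G\,]$ with $G = \sum_k \theta_k/k$: the
  stationary cooperation frequency $\rho_{D,C}/(\rho_{D,C}+\rho_{C,D})$
  depends on the scheme **only through the scalar $G$**;
* reaching at least an $\omega$ fraction of cooperation is therefore
  *equivalent* (both directions, not merely sufficient in practice) to
  $G \ge \frac{1}{\beta}\ln\frac{\omega}{1-\omega} +
  N(T+P-R-S)/2 + (R-P)$, which `g_bound()`, `min_theta()` and `min_t()`
  expose for the individual-based family $G = t\theta$.

At $\beta = 0$ every scheme yields exactly 50% cooperation and fixation
$1/N$; these neutral values are special-cased as exact identities rather
than limits of the general formulas, and the condition functions refuse
$\beta = 0$ with a pointer to that rule.

## Cost accounting

The transient states $S_1 \dots S_{N-1}$ of the absorbing chain have the
tridiagonal transition matrix $U$; entry $(i, j)$ of the fundamental matrix
$(I-U)^{-1}$ counts the expected time steps spent in $S_j$ from $S_i$,
*including* self-loop steps. With mutants appearing at $S_1$ or $S_{N-1}$
with probability $\tfrac12$ each, the expected visits are
$v_i = (n_{1i} + n_{N-1,i})/2$ and the expected cost is
$EC = \sum_i v_i \theta_i$. We charge $\theta_i$ for *every* step spent in
$S_i$, self-loops included: that is the fundamental-matrix notion of
"time spent in a state", and the simulator deliberately mirrors the same
convention so that the two accountings are comparable step for step. The
reported "expected number of interferences" is the expected visits to
states that actually pay ($\theta_i > 0$); whether self-loop dwell steps
should count is a modelling choice, and we count them.

### Numerical route for the visits

A linear solve of $I - U$ (banded or dense) is accurate only while the
chain is well conditioned. Under strong selection with an interior drift
attractor — e.g. $\theta = 5$, $\beta = 1$, intermediate $t$: upward drift
below $t$, downward above — absorption times reach $e^{\text{hundreds}}$,
the smallest singular value of $I - U$ collapses, and any floating-point
solve returns noise (we observed negative "visit counts" and costs
understated by fifteen orders of magnitude). The default `"analytic"`
method of `expected_visits()` therefore evaluates the exact birth–death
closed form of the two needed fundamental-matrix rows in log space: with
$w_i = \prod_{m \le i} e^{-\beta\Delta_m}$, gambler's-ruin identities give
$n_{jj}$ via the escape probabilities on either side of $j$ and
$n_{1j}, n_{N-1,j}$ via first-passage ratios, every term being a ratio of
prefix/suffix log-sum-exp sums of $\log w_i$. This stays accurate for
arbitrarily extreme $\beta N \theta$ (overflow beyond the double range is
reported as an error rather than silently truncated). The `"banded"`
(tridiagonal Thomas solves, $O(N)$) and `"dense"` (full inversion) methods
are retained as independent cross-checks; in benign regimes all three agree
to about $10^{-13}$ relative, and the test suite pins that agreement.

The same log-space machinery underlies `fixation_probabilities()`:
$\rho_{D,C}^{-1} = \sum_{i=0}^{N-1} e^{-\beta C_i}$ with
$C_i = \sum_{k \le i} \Delta_k$ is computed by log-sum-exp, and products of
Fermi ratios are never formed directly.

## Optimising the threshold

`optimal_threshold()` scans every $t \in 1..N-1$ of the scheme
$(\theta, t)$: frequency from the closed form, cost from the log-space
visits. Ties in $EC$ break toward the smallest $t$ (fewest paying states,
deterministic output). Infeasibility (no $t$ reaches $\omega$) is an
explicit result, not an exception — at $\beta = 0.001$, $\theta = 5$,
$\omega = 0.9$, $N = 100$ with the standard payoffs the maximal
$G = 99 \times 5$ is far below the required bound, so no threshold works
and the scan says so. The boundary integer computation uses
$\lceil x - 10^{-9}\rceil$ so that analytically exact integer bounds (the
$\omega = 0.5$ case yields exactly 101) are themselves admissible.

Two regimes emerge, and the experiment drivers (`threshold_profile()`,
`optimal_threshold_map()`, `full_invest_comparison()`) tabulate them: under
weak selection ($\beta \lesssim 0.1$) the cost curve is non-monotone in $t$
and an intermediate $t^*$ beats FULL-INVEST ($t = N-1$) — at
$\beta = 0.1, \theta = 5, \omega = 0.9$ the scan gives $t^* = 91$ with
$EC = 173010$ against $239125$ for FULL-INVEST, and twenty thresholds beat
the baseline; under strong selection ($\beta = 1$) intermediate thresholds
create a metastable interior attractor with astronomically large dwell
costs, so $t^* = N - 1$ is forced. The cheaper-than-FULL-INVEST range
widens as $\beta$ decreases.

Target cooperation levels are restricted to $\omega \in (0, 1)$: the
bound diverges at the endpoints, so they are rejected rather than
approximated. Similarly, nothing is ever paid at the homogeneous states
$S_0, S_N$ — the scheme vector is defined on $1..N-1$ only, consistent
with the cost sum running over transient states.

## The stochastic oracle

`simulate_episodes()` and `simulate_stationary()` are an agent-level
implementation of the same dynamics, written so that its *event* kernel
equals $T^{\pm}(k)$ with no rescaling: one time step is one focal–model
revision event, with both individuals drawn uniformly with replacement
(drawing with replacement makes the focal's and model's strategies
independent, giving exactly the $\frac{k(N-k)}{N^2}$ discordant-pair
probability). Costs accrue $\theta_k$ per step, self-loops included,
mirroring the analytic convention.

* *Episode mode* starts a single mutant at $S_1$ or $S_{N-1}$ with equal
  probability and runs to absorption, estimating $\rho_{D,C}$,
  $\rho_{C,D}$, per-state visit counts and cumulative payout, each with a
  standard error. Episodes are vectorised across replicates, so $10^5$
  episodes at $N = 10$ run in seconds; a soft cap warns beyond $N = 50$.
* *Stationary mode* adds an explicit mutation step — with probability
  $\mu$ the revising individual adopts a uniformly random strategy instead
  of imitating — and measures the fraction of time spent in the
  all-cooperator state among time spent homogeneous. With
  $\mu \le 1/N^2$ (default $10^{-3}$ at $N = 10$) this estimates the
  small-mutation stationary frequency; $\mu$ is an approximation knob, not
  part of the analytic model. Independent replicate chains all start from
  all-defectors, and the standard error is taken across chains; chains
  much shorter than the mean homogeneous dwell time
  ($\approx 2/(\mu\rho)$ events) under-sample rare fixations, which is why
  the defaults use tens of chains of $2\times10^5$ events.

What the simulator emulates — and what it does not: it reproduces the
idealised model (well-mixed population, average payoffs, simultaneous rare
mutation) exactly, so agreement with the analytic layer validates the
*implementation*, not the model's fit to any empirical population.
Structured populations, payoff noise, finite mutation rates with interior
coexistence, and strategy spaces beyond C/D are all outside its scope.

## Problem sizes and tolerances used in the tests

The suite checks the analytic layer against dense first-step solves at
$N \le 40$ (agreement $10^{-8}$), the product-form versus closed-form
log-ratio over randomized games with $N \le 200$ and $\beta \le 2$
($10^{-8}$), and the simulator against the analytic layer at $N = 10$,
$\beta = 0.5$ with $10^5$ episodes and $50 \times 2\times10^5$ stationary
events (three Monte-Carlo standard errors, fixed seeds). Threshold scans
use the full $t = 1..99$ grid at $N = 100$; the experiment drivers default
to the $\theta$ grid $0.5, 1, \dots, 50$, recorded in each output's
manifest. These sizes keep the whole suite in the minutes range on a
single core while exercising every regime the analysis distinguishes,
including the metastable one.

## Known limitations

* The cooperation frequency is the two-strategy small-mutation-limit
  stationary measure; time-averaged interior occupancy at finite mutation
  rates is a different quantity and is not computed.
* Cost optimisation searches the individual-based family $(\theta, t)$
  only; since frequency depends on a general scheme only through $G$,
  optimising the full vector $\Theta$ against $EC$ is a separate
  (and degenerate-in-frequency) allocation problem left out of scope.
* The expected cost is undiscounted and mutation-rate-free: it prices one
  mutant invasion under the ½/½ start convention, not a renewal process of
  invasions.
* `stationary_distribution()` handles any number of strategies, but the
  rest of the package is specialised to the two-strategy C/D setting.
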