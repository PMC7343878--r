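---
title: "Threshold models of social tipping: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold models of social tipping: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipcascade)
```

## The model

Granovetter's threshold model describes binary participation decisions with
externalities: each individual joins a collective action once the number of
others already participating reaches their personal threshold. With `F` the
cumulative threshold distribution over a population of size $N$, the active
count evolves as $R(t+1) = N\,F(R(t))$, and equilibria are intersections of
$F$ with the diagonal; intersections where $F$ crosses from above are
stable, because the cobweb iteration contracts toward them from both sides.

Two features limit the original model as a numerical tool. First, for
bell-shaped threshold distributions of moderate spread the only stable
equilibria are typically $R^*=0$ and $R^*=N$: everyone or no one acts. The
package's `critical_sigma()` quantifies this knife edge for the classic
cut-off Gaussian example ($N=100$, mean threshold $\mu=25$): a single
instigator tips the whole population only once the standard deviation
reaches $\sigma = 12.2$. Second, real populations contain people who will
act regardless of others and people who will never act regardless of
others, and encoding them as thresholds of 0% or 100% forces the threshold
distribution to be re-estimated whenever attitudes shift.

The refined model therefore partitions the population into $A$ *certainly
acting*, $C = P - A$ *contingent* and $N - P$ *never-acting* individuals,
with the contingent group sharing the population's threshold distribution,
and iterates
$$R(t+1) = A + C\,F(R(t)).$$
All equilibria lie in $[A, P]$, and changing $A$ or $P$ only re-anchors the
diagonal — from $(0,0)$–$(N,N)$ to $(A,0)$–$(P,1)$ on the rescaled axis —
while $F$ is estimated once. In fractions ($a = A/N$, $p = P/N$,
$c = p - a$) the fixed-point condition reads $(r-a)/c = F(r)$. With $A=0$,
$P=N$ the refinement degenerates exactly to the original recursion, which
is how the package represents the classic model (`granovetter(F, N)`).

## The emergent threshold distribution

The macroscopic thresholds are not primitives: the package's microscopic
layer assumes a single behavioural primitive, the *threshold fraction*
$\rho$ — the share of a node's own network neighbours that must be active
before it joins — and derives the broad macroscopic distribution from
network embedding. On an Erdős–Rényi graph with linking probability
$\ell$, a node's active and inactive neighbour counts are independent
binomials, $a_i \sim \mathrm{Bin}(R, \ell)$ and
$b_i \sim \mathrm{Bin}(P', \ell)$ with $P' = N - 1 - R$ (one's own state is
not counted), and the probability that the activation condition
$a_i > \rho\,(a_i + b_i)$ holds is `F_exact()`. Taking $N \to \infty$ at
fixed mean degree $K = \ell (N - 1)$ turns both binomials into Poisson
variables with rates $Kr$ and $K - Kr$, giving the analytic form
(`F_poisson()`)
$$F(r) \;=\; 1 - e^{-K} \sum_{b=0}^{\infty} \frac{(K - Kr)^{b}}{b!}
\sum_{a=0}^{\lfloor \rho b/(1-\rho)\rfloor} \frac{(Kr)^{a}}{a!},$$
whose inner factor is a Poisson CDF and hence, by the exact
Poisson–gamma identity, a regularised incomplete gamma function
(`F_gamma()`). The distribution saturates at $1 - e^{-K}$: isolated nodes
(mass $e^{-K}$) can never be recruited. $K$ mainly needs to be
"sufficiently larger than zero"; the package default $K = 10$ matches the
reference simulation setting and is of the order of close-contact circle
sizes.

Conventions, chosen once and kept consistent across the microscopic and
analytic layers:

* **Strict activation.** A node activates only if its active-neighbour
  share *strictly exceeds* $\rho$; ties do not activate, so $\rho = 0.5$ is
  a true majority rule on even degrees. Correspondingly the inner sum's
  upper limit uses `floor`, and an exactly integer $\rho b/(1-\rho)$ counts
  as non-activating. Comparisons carry a $10^{-9}$ absolute guard so that
  exact rational ties are classified identically under floating point.
* **Zero-degree nodes.** A contingent node with no neighbours has active
  share 0 and $0 > \rho \cdot 0$ is false: it never activates. This makes
  $F(0) = 0$ in all analytic forms.
* **Limits in $\rho$.** At $\rho = 0$ one active neighbour suffices
  ($F = 1 - e^{-Kr}$); at $\rho = 1$ activation is impossible and
  $F \equiv 0$ (strictly exceeding a share of 1 cannot happen).
* **Truncation.** Outer sums are truncated where the Poisson/binomial tail
  mass falls below $10^{-13}$. Because the *activation* (complement) event
  is summed, truncation strictly underestimates by at most the tail mass
  and $F(0)=0$ holds exactly. Binomial and Poisson terms are evaluated via
  R's numerically stable `dbinom`/`pbinom`/`dpois`/`ppois`, so no explicit
  log-space bookkeeping is needed even at $N \sim 10^5$.

`empirical_threshold_curve()` inverts the refined recursion on simulated
trajectories — plotting $r(t)$ against $(r(t+1)-a)/c$ — to measure $F$
directly from cascades. The mean-field derivation assumes active nodes are
well mixed, which holds at the start ($t=0$) and near the stopping point
($t = t_{max}-1$) but not mid-transient, where activation clusters around
the growing front; the `near_equilibrium_only` flag (default on) therefore
restricts to those two times. The transient mismatch is worst at
intermediate $\rho$ and is deliberately exposed, not corrected — pair
approximations or moment-generating-function closures are out of scope.

## The cascade simulator

`er_network()` draws $G(N,\ell)$ via igraph and stores a sparse adjacency
matrix; `assign_groups()` samples $P$ potentially active nodes uniformly,
then $A$ certainly acting nodes among them, with exact group sizes every
draw; `run_cascade()` starts with the certain nodes active ($R(0) = A$),
updates all contingent nodes synchronously under the strict rule, and stops
when no node activates, closing the trajectory with the repeated state
$R(t_{max}) = R(t_{max}-1)$. Activation is irreversible, so $R(t)$ is
nondecreasing and $a \le r^* \le p$ always.

The generator accepts either $\ell$ or $K$ (then $\ell = K/(N-1)$). The
two reference parameterisations are not identical — $\ell = 9\times10^{-5}$
at $N = 10^5$ gives $K = 9.0$ — and the package keeps both available
rather than silently preferring one; analytic-vs-exact comparisons use the
mathematically consistent pair $K = \ell(N-1)$.

Ensemble sweeps (`sweep_final_share()`) regenerate the network *and* the
assignment for every replicate. Replicate seeds are a documented pure
function of the master seed, cell index and replicate index
(`replicate_seed()`; assignment seeds use the offset master `+ 524287` so
topology and labels never share a stream), which makes every replicate
reproducible in isolation and sweeps bit-identical under a fixed master
seed. `tipping_share()` reports, per $(p, \rho)$ cell, the smallest $a$
whose ensemble-median $r^*$ exceeds $0.9\,p$ — the operational definition
of the microscopic tipping point used throughout.

What the synthetic networks do and do not emulate: Erdős–Rényi graphs
reproduce the Poisson degree mixing that the analytic $F$ assumes, but real
social networks have clustering, degree heterogeneity (hubs), homophily and
community structure, all of which the analytic layer ignores. Passing
micro/macro agreement tests therefore validates the *internal* consistency
of the two layers under the stated assumptions, not the model's fidelity on
empirical contact networks; arbitrary edge lists can be simulated
(`network_from_edges()`, `read_network()`), but no analytic $F$ is provided
for them.

## Numerical choices

* **Recursion.** Real-valued iteration with fixed-point tolerance
  $10^{-6} N$ (the analytic treatment is continuous even though $R$ counts
  people), capped at $10^4$ steps.
* **Equilibria.** $g(R) = A + C F(R) - R$ is scanned on a $10^4$-point
  grid over $[A,P]$ and sign changes are bisected to $10^{-8}$ relative
  tolerance; pure Newton steps are unsafe because $F$ may be flat over wide
  ranges. Stability uses the crossing-direction rule evaluated a small
  offset ($10^{-5}$ of the span) either side of each root; tangential
  contacts (equal signs both sides, as at a fold) are labelled
  `semi-stable`, and flat-zero segments — e.g. uniform thresholds, where
  every state is an equilibrium — collapse to one representative root.
* **Critical sigma.** The cut-off Gaussian is *censored*, not
  renormalised: the untruncated normal CDF is evaluated on $[0, N]$, so
  mass below 0 acts as threshold-0 individuals and mass above $N$ as
  never-actors. This convention is adopted because it reproduces the
  classic worked example's 12.2 under the original construction; which
  cut-off was meant is genuinely underdetermined in the literature. A
  "full cascade" is an equilibrium $\ge N - 1$, since under censoring the
  fixed point approaches but need not equal $N$. Because very diffuse
  distributions also fail (too much mass above $N$), the full-cascade
  region in $\sigma$ is an interval; `critical_sigma()` scans upward at the
  requested resolution, bisects the lower boundary to 1% of that
  resolution, and reports it rounded to the resolution grid. The
  boundary for the classic example sits at $\sigma^* \approx 12.22$.
* **Folds, cusp, hysteresis.** `saddle_node()` scans the parameter,
  counts stable roots, and bisects each count change to $10^{-4}$.
  Bistability means two stable fixed points separated by more than
  $10^{-4}$ in $r$, so grid noise near the cusp cannot create spurious
  folds. The bistable $a$-window at given $p$ is computed from the
  stable-count profile directly (its boundary can be a fold *or* the edge
  of the feasible range — for large $p$ the window extends to $a = 0$),
  and `cusp_point()` bisects $p$ against the last monostable value.
  `hysteresis()` follows branches by warm-started continuation — at each
  sweep step the stable root nearest the previous state is selected — so
  the state jumps exactly where its branch is destroyed at a fold; the
  trapezoidal loop area is 0 precisely when the up and down traces
  coincide. Solutions with $r^* \notin [a, p]$ cannot occur by
  construction (roots are sought on $[a, p]$), which plays the role of the
  feasibility masking in the reference diagrams; `min_stable_surface()`
  masks infeasible cells $a > p$ with `NA`.

## Problem sizes and what the tests show

The test suite and the acceptance script run the study at deliberately
scaled sizes chosen to keep every stochastic check comfortably resolved:
microscopic ensembles use $N = 10^4$, $K = 10$ with 20 replicates per cell
and an $a$-grid of resolution 0.01 around the transition (the tipping
point at $p = 0.56$, $\rho = 0.2$ resolves to $a = 0.05 \pm 0.01$);
near-equilibrium threshold scatter uses $N = 10^4$ with an RMS band of
0.05 against `F_poisson()` — a package-defined quantification of the
qualitative "matches well" claim; analytic/exact agreement is checked at
the full reference scale $N = 10^5$, $\ell = 9\times 10^{-5}$, where the
sup-norm gap is below $10^{-3}$ (and in fact $\sim 3\times10^{-5}$). The
full-scale ensemble setting ($N = 10^5$, $n = 100$ replicates,
logarithmic $a$-grids) remains available through `sweep_final_share()` and
the `figure2` experiment preset.

## Known limitations

* The analytic $F$ is exact only for Erdős–Rényi mixing near equilibrium;
  transients and clustered topologies need pair-approximation or
  moment-closure extensions.
* Activation is deterministic and irreversible: no spontaneous adoption or
  abandonment noise, hence no early-warning-indicator machinery.
* Parameters are static within a run; slow time variation of $a$, $p$ or
  $\rho$ can be emulated by re-running along a parameter path (as
  `hysteresis()` does quasi-statically) but is not integrated dynamics.
* `cusp_point()` reports the collapse of the bistable window on a finite
  grid; it is an estimate of the organising point, not a normal-form
  computation.
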