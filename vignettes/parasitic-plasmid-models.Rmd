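---
title: "Modeling parasitic plasmids: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling parasitic plasmids: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidecology)
```

Plasmids that carry no benefit to their host can still persist if they
spread infectiously faster than they are lost to reduced host growth and
segregation. `plasmidecology` implements a connected stack of models for
such parasitic plasmids — single-plasmid ecology, multi-plasmid
co-infection, and metapopulation selection — together with the statistical
machinery to confront the metapopulation model with plasmid-count data
from genome collections. This vignette documents the models, their
assumptions, and the numerical and design decisions a user should know
about.

## Single-plasmid chemostat models

Both single-plasmid models track plasmid-free cells $\rho$,
plasmid-bearing cells $\rho_p$, and a nutrient $C$ supplied at rate $S$
in a well-mixed, flow-free habitat with per-capita death rate $\delta$.
Cells grow at $\alpha C$ (plasmid-free) or $(1-\Delta)\alpha C$
(plasmid-bearing, cost $\Delta \in [0,1)$). At division a daughter loses
the plasmid with probability $p_\ell$; the mother regenerates its copy
number. Transfer is mass action:

* **Conjugation** (`conjugation_rhs()`): donors infect recipients on
  contact at rate $\gamma_c \rho \rho_p$.
* **Transformation** (`transformation_rhs()`): each cell death releases
  $n_{\mathrm{eff}}$ viable free plasmids $P$, which decay at $\delta_p$
  and infect at rate $\gamma_t \rho P$.

The plasmid-free state $(\rho^* = S/\delta,\; C^* = \delta/\alpha)$ is
destabilized — the plasmid invades — when the transfer rate exceeds an
analytic threshold: for conjugation
$\gamma_c^* = \delta\,(\Delta + p_\ell(1-\Delta))/\rho^*$, and for
transformation
$\gamma_t^* = \delta_p (\Delta + p_\ell(1-\Delta)) / (\rho^*
(n_{\mathrm{eff}} - \Delta - p_\ell(1-\Delta)))$. When
$n_{\mathrm{eff}}$ does not exceed the replication deficit the
transformation inequality reverses and `Inf` is returned as a no-invasion
sentinel. Equality at the threshold is treated as non-invading (the
boundary itself is marginal; the convention matters only on a measure-zero
set).

Copy number $n_p$ enters through three scalings: cost
$\Delta = \Delta_p n_p$, segregation loss $p_\ell = 2^{1-n_p}$, and (for
transformation) $n_{\mathrm{eff}} = p_v n_p$. The conjugative invasion
barrier $\delta(\Delta_p n_p + 2^{1-n_p}(1-\Delta_p n_p))$ has an interior
minimum — `optimal_copy_number()` reports its integer argmin (plasmid
copies are discrete; ties resolve to the smaller $n_p$, and the continuous
minimizer is reported alongside for diagnostics). The transformative
optimum is the budget-exhausting $n_p = 1/\Delta_p$, a phage-like
strategy; it is reported as `NA` when even full release cannot cover the
deficit ($p_v \le \Delta_p$).

### Equilibria, stability, and phase diagrams

`find_equilibria()` returns every equilibrium in closed or semi-closed
form. The key reduction: summing the two cell equations and imposing
nutrient balance shows that *any* steady state has total cell density
$\rho + \rho_p = S/\delta$. Parametrizing interior equilibria by $\rho$
then yields closed expressions for $C$ (and $P$), leaving a single scalar
residual whose roots are located by a sign-change scan (2000 points) plus
`uniroot` at tolerance `1e-14`. Candidates are accepted only if they zero
the full right-hand side to a relative `1e-10`. This is deterministic and
fast enough to classify dense parameter grids; the plasmid-only state
($\rho = 0$) exists exactly only for $p_\ell = 0$, since segregation
otherwise regenerates plasmid-free cells.

Stability is classified from the eigenvalues of hand-derived analytic
Jacobians (`dynamics_jacobian()`, checked in the test suite against
central differences), with `stable` meaning all real parts below
`-tol_eig`, `tol_eig = 1e-8`; real parts within `tol_eig` of zero set a
`marginal` flag. `phase_diagram()` labels each $(\Delta, \gamma)$ grid
point from the set of stable equilibria: `no_plasmid`, `coexistence`
(a stable interior state), `plasmid_only`, or `bistable` (plasmid-free
and plasmid-only simultaneously stable, which arises for transformative
plasmids with $n_{\mathrm{eff}} < 1$). Default grids are 100 points,
linear in $\Delta$ over $(0,1)$ and log-spaced in the transfer rate;
main-text-style diagrams use $p_\ell = 0$ (finite loss is supported but
not the default). Analytic boundaries are not used — labels are computed
numerically point by point, so the diagrams should be read as numerical
reconstructions.

### Integration

`integrate_dynamics()` is a fixed-step classical fourth-order Runge–Kutta
integrator (default step 0.01 time units; the test suite cross-checks it
against an adaptive LSODA reference). Components driven below zero by
no more than `1e-12` are clipped to zero; anything larger aborts with a
step-size error. `run_to_steady_state()` integrates in chunks until the
largest derivative, relative to the overall state scale
($\max_i |dx_i/dt| / \max(\max_i |x_i|, 10^{-12})$), falls below `1e-9`,
with a default ceiling of $t = 10^5$. The state-scale normalization is
deliberate: a per-component criterion can never be met by an
exponentially decaying component (its relative derivative is constant),
e.g. a sub-threshold inoculum.

## Multi-plasmid co-infection

For $m$ compatible plasmid types (distinct incompatibility groups,
independent transfer, one type per transfer event), `build_full_rhs()`
constructs the $2^m + 1$-dimensional system over all plasmid-content
subsets. Segregation is per-type independent Bernoulli retention
(probability $1 - p_\ell$ each), so a divider carrying set $A$ places its
offspring in $B \subseteq A$ with weight
$(1-p_\ell)^{|B|} p_\ell^{|A|-|B|}$ — the natural generalization that
reduces exactly to the single-plasmid equations at $m = 1$ (asserted in
tests, as is conservation of offspring across the redistribution). Costs
combine multiplicatively, $\Delta_{\mathrm{tot}}(k) = 1 - (1-\Delta)^k$,
or additively with a clamp at 1 (growth rates cannot go negative).
Donors of type $i$ are all carriers of $i$ regardless of other content.
The full system is capped at $m \le 12$; for identical types
`build_reduced_rhs()` collapses it to $m + 2$ equations over the number
of carried types, with binomial segregation weights and promotion rate
$\gamma_c (m - k) x_k D$, $D = \sum_j x_j\, j/m$. Full and reduced
trajectories agree to $10^{-8}$ for $m \in \{2,3,4\}$ in the suite.

`steady_state_type_distribution()` integrates from the plasmid-free state
plus a $10^{-6}\rho^*$ inoculum in each single-type class and normalizes
the steady-state class densities. Transfer rates are conveniently given
as multiples of the single-type threshold $\gamma_c^*$. The
Poisson-binomial reference (`poisson_binomial()`, exact iterative
convolution) describes fully independent plasmids; the coupling through
host fitness makes the true distribution deviate, and the deviation grows
with $\Delta$ — the package measures this with total variation distance
(`tv_distance()`). `mean_types_and_fitness()` summarizes the tragedy of
the commons: mean carried types rise roughly proportionally with the type
pool while mean host fitness $E[1 - \Delta_{\mathrm{tot}}(k)]$ falls.

## Wright–Fisher metapopulation

`simulate_epochs()` models $N$ demes; each epoch synchronously replaces
all demes with one multinomial draw of size $N$ whose class probabilities
weight deme counts by fitness $w_i = 1 - \Delta_{\mathrm{tot}}(i)$ and
shift mass upward with invasion probability $q$
(`epoch_probabilities()`). Counts beyond the truncation cap `i_max`
(default 50) fold into the top bin with a one-time warning. Epistasis
forms (`epistasis_spec()`): `none` (multiplicative), `positive`
(constant cost, sub-multiplicative), `negative`
(exponent $m^{3/2}$, super-multiplicative), `power`
($\Delta_{\mathrm{tot}} = 1 - (1-\Delta)^{m^a}$) and `custom`. The power
form is defined to carry zero cost at $m = 0$ for every $a \ge 0$, so its
$a = 0$ member is *exactly* the constant-cost form — this makes the power
family properly nest the positive form, which the fitting module relies
on.

`stationary_distribution()` solves the deterministic (infinite-$N$)
fixed point of the epoch map by the recursion
$f_i = f_{i-1} w_{i-1} q / ((1-q)(1-w_i))$ with $w_0 = 1$, computed in
log space and normalized; the support grows automatically until the tail
mass beyond it is below `1e-10`. Cost-free classes ($w_i = 1$ for some
$i \ge 1$) or a non-decaying tail are rejected with errors, since no
normalizable fixed point exists. Under constant cost the consecutive
ratio $f_{i+1}/f_i = (1-\Delta)q/((1-q)\Delta)$ is constant — an
exponential tail; with no epistasis the ratios decay like a Poisson's;
negative epistasis thins the tail further.
`generalized_stationary_distribution()` extends the recursion to
arbitrary count-dependent costs and invasion probabilities; an exact
geometric distribution results whenever cost and invasion probability are
count-independent beyond the first plasmid.
`tail_ratio_diagnostics()` quantifies ratio constancy against the
geometric mean of the ratios (ratios are taken from the second positive
bin on, because the $0 \to 1$ step involves $w_0$ and differs even in the
constant-cost case).

**A finite-$N$ caveat.** The analytic stationary distribution is a
mean-field object. In stochastic runs its persistence requires the
plasmid-free class (the fitness anchor) to survive drift: with
$\Delta = 0.01$, $q = 0.005$ and $N = 1000$ the anchor is held by a
selection differential of only about 0.5% per epoch, and once it drifts
to extinction the remaining classes are mutually neutral under positive
epistasis, so invasion ratchets the whole metapopulation upward without
bound. Long small-$N$ simulations therefore depart from the analytic
distribution on accessible timescales, and the suite validates
simulation-versus-analytic agreement in the many-deme regime
($N = 10^5$, where anchor extinction is effectively impossible) while the
acceptance tests also document the small-$N$ behavior. Users comparing
simulations to `stationary_distribution()` should treat $N$ as an
explicit regime choice, not a nuisance parameter.

## Fitting stationary distributions to histograms

`fit_model()` fits an epistasis form to a plasmid-count histogram by
minimizing the sum of squared differences between logarithms of model and
observed bin probabilities. Conventions, where the procedure is
underdetermined by common practice:

* Bins with fewer than 10 observations are excluded from the objective
  (`truncate_for_fit()`, threshold inclusive), but observed probabilities
  keep the **full-histogram total** as denominator, preserving the
  empirical scale of the retained bins; fewer than 3 surviving bins is an
  error (under-determined fit).
* Model probabilities are the stationary $f$ normalized over a fixed
  support `0..i_max` with `i_max = 4 * max(bins) + 50` by default — wide
  enough that the truncation is immaterial for convergent fits, while
  keeping the objective finite and continuous when the optimizer visits
  divergent-tail parameter combinations.
* Optimization is bounded nonlinear least squares (`minpack.lm::nls.lm`)
  on $(\log\Delta, \log q$ [, $a$]$)$ with 10 Latin-hypercube starts
  (default bounds $\Delta, q \in [10^{-6}, 0.5]$, $a \in [0, 3]$); the
  power fit additionally starts from the fitted constant-cost solution at
  $a = 0$, so its objective never exceeds the positive form's.
* In the strong-positive-epistasis limit the stationary shape depends on
  $(\Delta, q)$ nearly only through $q/\Delta$; `fit_model()` detects the
  flat direction from the numeric Hessian of the objective (smallest
  eigenvalue below $10^{-6}$ of the largest) and sets an identifiability
  warning, in which case `ratio_q_Delta` is the robust quantity to
  report.

`compare_fits()` ranks forms by objective. No uncertainty beyond the
identifiability flag is attempted — the objective is a least-squares
distance in log space, not a likelihood.

## Genome tables and the synthetic generator

`load_assembly_table()` reads a flat, tab-separated surrogate for
assembly summaries (columns `assembly_accession`, `replicon_name`,
`replicon_role`, `length_bp`, `genus`). Conventions follow the strictest
reading of standard filters: completeness requires a chromosome-role
replicon **strictly** longer than 0.5 Mb ($5 \times 10^5$ bp,
Mb $= 10^6$ bp); plasmid counting matches the role label
case-insensitively and ignores replicon names; cas positivity requires at
least one profile-HMM hit with E-value **strictly** below $10^{-30}$;
genus exclusion is case-insensitive exact matching against a user list
(no canonical exclusion list ships with the package). No length floor is
applied to plasmid-labeled replicons.

The synthetic generator (`generator_spec()` and friends) emulates the
*structure* of a complete-genome collection so every pipeline stage is
testable offline: per-genome type counts drawn from a chosen stationary
distribution (default scale 17,725 genomes, the size of the collection
the models are aimed at; tests use a few hundred to 20,000), one
chromosome row plus one row per plasmid, genus labels from a weighted
pool, a configurable fraction of sub-threshold "chromosomes" to exercise
the completeness filter, and cas hit tables with true hits at E-values in
$[10^{-60}, 10^{-31}]$ plus decoys in $[10^{-29}, 10^{-5}]$ (default
carriage 0.4, independent of plasmid count — a null model). Replicon
lengths (chromosomes uniform 1–6 Mb, plasmids log-uniform 2–200 kb,
incomplete "chromosomes" 100–450 kb) are plausibility dressing: nothing
downstream depends on them except the 0.5 Mb filter. What the generator
does **not** emulate: sequence content, within-genus count structure,
oversampling of clinical taxa, correlated cas/plasmid carriage, or
mislabeled replicon roles. Passing round-trip tests therefore certify the
pipeline's bookkeeping, not the realism of any particular genome
collection.

All generator functions take an explicit seed and restore the caller's
RNG state; identical spec + seed gives byte-identical outputs.

## Problem sizes in the shipped tests

The test and acceptance suites are sized to run in minutes on one CPU:
phase diagrams at $50 \times 50$, co-infection steady states up to
$m = 8$ (reduced system), Wright–Fisher runs of 3,000–22,000 epochs,
fit-recovery experiments at 17,725 multinomial draws, and synthetic
collections of 1,000–20,000 genomes. These sizes are choices, and every
threshold asserted in the tests was computed from the models themselves
(closed forms, enumeration, or independent reference integrators), never
assumed.

## Known limitations

* The ecological models are deterministic and well-mixed; finite
  single-population sizes, extinction, and spatial structure are out of
  scope, as are incompatibility interactions between plasmid types.
* Copy number enters only through the $\Delta$, $p_\ell$ and
  $n_{\mathrm{eff}}$ scalings; intracellular copy-number dynamics are not
  modeled.
* The Wright–Fisher stationary solver is the infinite-$N$ mean field; see
  the finite-$N$ caveat above.
* The fitter matches stationary shapes. Distributions with sharp
  discontinuities between the zero-plasmid class and the rest of the
  distribution are not captured by any of the built-in epistasis forms.
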