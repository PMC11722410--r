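---
title: "Multilevel selection of cooperators and cheaters: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel selection of cooperators and cheaters: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlscoop)
```

## The model

`mlscoop` simulates a two-level (individual and group) selection process.
A population is a collection of groups; each group has `K` sites occupied
by social individuals (cooperators, "A"), asocial individuals (cheaters,
"B"), or free resources. Time is discrete, and within one step three
things can happen, in this order by default:

1. **Within-group reproduction.** Every group below the threshold
   updates in parallel: one individual is born with probability
   `pA = (nA/K)(1 - n/K)` for a cooperator or `pB = b (nB/K)(1 - n/K)`
   for a cheater, where `n = nA + nB`. The factor `b >= 1` is the
   cheater's frequency-independent reproductive advantage. The state
   with the largest total birth probability is `nA = 0`, `nB = K/2`,
   where it equals `b/4`; probabilities remain a distribution for every
   state exactly when `b <= 4`, which fixes the admissible range.
   Resources are fixed at group formation, so the free-site count is
   always `K - n` and is never tracked separately.
2. **Group splitting.** If any group has filled its `K` sites and the
   population is below the group carrying capacity `Kg`, exactly one
   such group (chosen uniformly) splits. Each daughter receives
   `mA ~ U{0..nA}` and `mB ~ U{0..nB}` — two independent uniform draws,
   deliberately *not* a hypergeometric partition of the K sites. If a
   daughter ends up empty it is discarded (an *abortive* split; the
   parent survives unchanged and may split again). For a pure parent the
   abortive probability is exactly `2/(K+1)`.
3. **Group death.** At most one group dies per step; `mu` is the total
   probability that any death occurs. Three regimes map `mu` onto
   groups: *neutral* (uniform `mu/Ng`), *relative* (proportional to
   `1 - a f_j` normalized across groups, where `f_j` is the group's
   cooperator fraction and `a` the social trait strength — total death
   probability is exactly `mu` regardless of composition), and
   *absolute* (`(mu/Ng)(1 - a f_j)`, unnormalized — cooperators reduce
   the total death pressure). In the relative regime at `a = 1` a
   population consisting solely of pure-A groups has all death weights
   equal to zero; we define this edge case as "no death can occur",
   matching the limit from any mixed composition.

Extinction (no groups) is absorbing. Whether the death draw sees the
compositions before or after the step's reproduction and split is not
fixed by the process description; it is a configuration switch
(`event_order`), defaulting to the ordering above so that freshly split
daughters are immediately exposed to death.

The compiled stepping loop (Rcpp) and the exported R reference
functions (`step_population()` and the per-event operations) consume
random draws in the same order and are tested to produce bit-identical
trajectories from the same RNG state; the R path defines the intended
semantics, the C++ path is what `run_simulation()` uses.

## Initial conditions

Initializations mirror the study designs the package reproduces:

* `neutral_uniform`: `Ng` single-type groups, sizes uniform on
  `1..K-1` (sizes of `K` would split at `t = 0`; empty groups are
  invalid).
* `homogeneous_mix`: `NgA` pure-A plus `NgB` pure-B groups, sizes again
  uniform on `1..K-1`. The size rule for competition runs is not pinned
  by the source experiments; we reuse the neutral-case rule for
  consistency with the averaging range of the absorption analytics.
* `heterogeneous`: `nA` and `nB` independently uniform on
  `0..floor(K/2)`; `(0, 0)` draws are resampled so `Ng` is exact.
* `at_capacity`: homogeneous groups all at the threshold — the
  configuration of the rare-death (Moran) limit.

Replicates derive their seeds from the root seed by a counter scheme
(`derive_seed()`), recorded in the run manifest, so any cell of any
sweep can be re-executed bit-exactly in isolation.

## Analytics

A group of size `n` that survives each step with probability `delta`
reaches `K` before elimination with probability

\[ \psi_n \;=\; \prod_{l=n}^{K-1}
   \frac{\delta b T^+_l}{\,1-\delta+\delta b T^+_l\,},
   \qquad T^+_l = \tfrac{l}{K}\bigl(1-\tfrac{l}{K}\bigr). \]

`psi()` implements the product; `psi_recursion_solve()` solves the
defining first-step recursion as a linear system and is the module's
master oracle (agreement to 1e-10 across the tested grids);
`mc_psi()` estimates the same quantity by direct simulation. Averaging
over initial sizes `1..K-1` gives `psi_avg()`, and the proliferation
condition is `psi_avg > 1/2`: on average more than one daughter of a
split must reach the threshold again.

Near `delta = 1`,

\[ \langle\psi\rangle \approx 1 - (1-\delta)\,\frac{H_{K-1}K^2}{b(K-1)}, \]

which yields closed-form thresholds: the survival threshold
`delta_star()`, the death-probability/group-number relation
`neutral_threshold()`, and the competition thresholds `a*` and `b*(a)`
(`competition_thresholds()`) obtained by inserting the homogeneous
survival probabilities (`survival_probs()`) of the relative or absolute
regime. `solve_threshold_numeric()` and `psi_half_curves()` solve the
same `psi = 1/2` conditions by bracketed root finding (tolerance 1e-8)
without the high-survival assumption.

**The two curve families bracket; they do not converge to each other at
the threshold.** The expansion is evaluated at the `psi = 1/2` level,
where `1 - psi` is not small: writing
`psi ~ exp(-(1-delta) C)` with `C = H_{K-1}K^2/(b(K-1))`, the true
threshold sits at `(1-delta) C = log 2 = 0.693` while the linearized one
sits at `0.5`. The ratio of the two `(1-delta)` values therefore tends
to a constant (~1.39) rather than to 1, and thresholds expressed in
`mu`, `a`, or `b` inherit an O(30%) systematic offset *in any regime*.
On the survival-probability scale the two thresholds agree closely
(within 2% for `K >= 20`, tightening as `K` grows) because
`delta* ~ 1`. Consequently the package
treats the numeric curves and the closed-form curves as joint
upper/lower boundary estimates: in the phase-diagram checks a grid cell
is counted as consistent with the analytics when its simulated regime
matches *either* assignment. Cells at `a = 1` in the relative regime are
a genuine edge: pure-A groups cannot die while any B group exists
(`delta_A = 1` exactly), so cooperators can establish from initial
conditions that the fixed-`Ng` absorption analysis labels subcritical.

In the rare-death limit (`mu << 1`, population at `Kg`, all groups at
threshold) the number of all-A groups performs a one-step birth-death
chain (`moran_limit_transitions()`) whose down/up ratio is `1 - a` in
both fitness regimes, giving the fixation probability

\[ \varphi = \frac{1-(1-a)^{N_{gA}(0)}}{1-(1-a)^{K_g}} \]

(`fixation_probability()`), independent of `mu`. The test suite checks
this closed form against an absorbing-chain linear solve and against
the full simulator at `mu = 0.001`.

## Experiments

`sweep_theta()`, `sweep_S()`, `sweep_KNg()` and
`scenario_extinction_by_sociality()` script the package's computational
experiments: the neutral survival map over `(mu, K)`, the competition
heatmaps over `(a, b)` (group-purity statistic `s_statistic()` for
homogeneous starts, individual-composition statistic for heterogeneous
starts), the `(K, Ng)` outcome map with `NgA = floor(Ng/2)`, and the
resource-limited scenario in which the environment supports a
homogeneous cheater population but not a cooperator one
(`psi_B > 1/2 > psi_A` at capacity) — there the mixed population grows
to capacity on the back of the fast-splitting cheater groups, the
cheater fraction rises first, cooperators then outcompete them, and the
homogenized population collapses, while the all-cheater control
persists.

Automated checks run these at reduced scale (7x7 grids, 10-20
replicates); the functions default to the full designs (for example
`M = 50`, sampling times 1000-5000) and everything is seed-addressable
per cell, so full-size maps are a matter of compute time, not code
changes. The default sampling times are the ones under which the
shipped phase diagrams are interpretable; they are configuration, not
constants.

## The biofilm model

The agent-based biofilm realizes the same selection structure in a
spatial system. Cells live in 3D above a reflective substrate carrying
a square grid of anchor points with spacing `D` (the length unit).
Forces are pairwise, `H/d^6 - \bar G/d^2` along the separation axis;
the asocial attraction constant satisfies `H/D^4 = G` so that an
asocial pair is force-free at distance `D`; matrix (ECM) producers have
`100 G` and divide five-fold slower. Motion advances every cell one
grid spacing per step along the normalized blend
`(1-F) u_force + F u_rand` with `F = 0.5`. Division is Poisson with
logistic mean `n r (1 - N/K_BF) dt`; removal is Poisson with mean
`m L dt` restricted to the predation interface — the topmost cell in
each `D`-sized substrate window. Defaults: `K_BF = 500`, 20x20 anchors,
`r = log 2`, `L = 0.1`, `dt = 0.01`.

Two conventions are not determined by the force-law description and are
exposed as switches, with the defaults used throughout:

* the anchor attraction constant is the *baseline* `G/2` for all cells
  (`substrate_by_phenotype = TRUE` uses the cell's own `G/2` instead —
  ECM production would then also anchor producers to the substrate);
* the blended direction is renormalized to unit length before scaling
  by the speed (`renormalize_direction = FALSE` instead moves by the
  blend's length, slowing cells whose force and random directions
  disagree).

Switching either convention changes the producer-mutant fixation
outcome at reduced carrying capacity by less than the run-to-run
variation (both were measured), so neither is load-bearing for the
results below.

For reduced carrying capacities the anchor grid side shrinks as
`sqrt(K_BF/500)` at fixed spacing, keeping the grid roughly twice the
colony footprint. Initial cells are placed uniformly in a central
column of width 5% of the grid extent and settled by 1000 deterministic
motion steps (`F = 0`, no division or removal) before the full dynamics.

**What the scaled-down model does and does not reproduce.** At the
reference scale the model's published behaviors are: equal steady-state
sizes for homogeneous producer and non-producer films; a roughly
four-fold seeding advantage for non-producers (single founder racing
death at rate `L` against division); and near-certain fixation of a
single producer mutant inside a non-producer film. The package
reproduces the first two at reduced scale (`K_BF = 80-500`; producer
interface fraction is 2.5-3x smaller than non-producer, steady-state
sizes statistically indistinguishable; seeding succeeds in roughly 90%
of non-producer and 35-50% of producer trials — a decisive asymmetry in
the right direction, though both rates run above the reference values,
i.e. early colonies in this implementation stack and shelter themselves
somewhat faster than in the reference behavior). Mutant fixation, however, is *scale-dependent*: the
producer pays a five-fold division cost, so invasion requires its
interface exposure to be less than one fifth of the non-producer's.
Exposure falls with burial depth, and mean stack height grows with
colony size (roughly as the cube root of `K_BF`). At `K_BF = 150` the
measured per-capita birth and death rates of a rare producer lineage
are equal to within measurement error (0.0039 vs 0.0040 per unit time)
— the mutation is effectively neutral there, and a 10-trial fixation
check fails as a consequence, while at `K_BF = 500` buried producers
are almost never exposed and fixation is nearly deterministic. The
corresponding acceptance check is left failing deliberately rather than
re-scaled: it documents where the mechanism's finite-size validity
begins. Full-scale fixation runs remain available via
`biofilm_fixation(biofilm_params())`.

The neutrality control relabels one cell of a steady-state film with a
phenotype that has identical rates and constants. Labels then have no
effect on the dynamics, so by exchangeability the relabelled lineage
fixes with probability exactly `1/N0` (`N0` = film size at relabelling)
— a direct check that the machinery carries no hidden label bias; the
shipped check compares 500 trials at `K_BF = 60` against the summed
`1/N0` reference with a binomial band.

## Numerical choices

* Free-site factors are computed as `(K - nA - nB)/K` in integer
  arithmetic before division; probability complements are `1 - pA - pB`.
* Categorical draws partition a single uniform variate; uniform integer
  draws use `floor(u (n+1))` capped at `n`. These conventions are shared
  verbatim by the R and C++ paths.
* Relative-regime death probabilities are validated to sum to `mu`
  within 1e-12; a draw at or above `mu` skips the group scan (an exact
  shortcut, since the scan can only assign total mass `mu`).
* Root finding uses bracketed `uniroot` at tolerance 1e-8 (1e-9 for
  curve points); out-of-regime thresholds are flagged (`in_regime`,
  `admissible`, `NA` curve points), never clipped.
* Harmonic numbers are direct sums; no asymptotics.
* Biofilm uniqueness jitter is uniform per axis with magnitude
  `1e-6 D`, applied after motion and after duplication.

## Limitations

* No individual death within groups; the recurrence and thresholds
  change quantitatively (not qualitatively) if it is added, and the
  package does not implement that variant.
* Group death is at most one per step by construction; regimes where
  multiple simultaneous deaths matter (`mu` near 1 with very few
  groups) are outside the model.
* The biofilm model resolves no explicit ECM field or nutrient
  diffusion; ECM is a force-constant and division-rate modifier only.
* Reduced-capacity biofilm films are shallow; mechanism strength for
  mutant invasion at `K_BF` below a few hundred cells is materially
  weaker than at the reference scale (see above).
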