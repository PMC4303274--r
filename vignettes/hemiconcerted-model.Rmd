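---
title: "A hemiconcerted two-state model of calmodulin: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hemiconcerted two-state model of calmodulin: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Calmodulin consists of two globular lobes, each containing two EF-hand
calcium-binding sites that act as one cooperative unit. `hemicam` models
each lobe as a classical two-state MWC molecule: the lobe exists in a
low-affinity T conformation and a high-affinity R conformation in
thermodynamic equilibrium, and both sites on a lobe always share the
lobe's conformation (concerted within the lobe). The two lobes of the
intact protein, however, switch independently — a *hemiconcerted*
scheme — so intact calmodulin samples four conformations (RR, RT, TR,
TT; first letter N lobe, second C-lobe).

A single lobe is described by three parameters:

* `L` — the allosteric constant, the ratio `[T]/[R]` of unliganded
  conformer concentrations (dimensionless; large `L` means the apo lobe
  is almost entirely in T);
* `K_R`, `K_T` — calcium dissociation constants of the R and T states
  (molar), with the derived ratio `c = K_R/K_T <= 1`.

With `alpha = [Ca]free / K_R`, the fractional saturation is

```
Y = (alpha (1 + alpha) + L' c alpha (1 + c alpha)) /
    ((1 + alpha)^2 + L' (1 + c alpha)^2)
```

Cooperativity is emergent: calcium binds R more tightly, so binding
shifts the population towards R, which raises the apparent affinity of
the remaining sites.

### Target modulation

A binding partner (peptide or protein) that prefers one conformation
shifts the same equilibrium, which is exactly equivalent to replacing
`L` by an effective value

```
L' = L * ((1 + gamma e) / (1 + gamma))^m
```

where `gamma = [A]free / K_Rt`, `e = K_Rt / K_Tt` is the ratio of the
target's dissociation constants for the two conformations, and `m` is
the number of target sites that sense the transition. Targets with
`e < 1` stabilise R and left-shift the calcium curve (e.g. the skMLCK
peptide WFF); `e > 1` stabilises T and right-shifts it (IQ-motif
peptides such as the NaV1.2 IQ domain, or neurogranin).

Two stoichiometry conventions exist in the allosteric literature: the
per-subunit convention (`m = 2` for a two-site lobe, the classical
effector treatment, and the package default in
`effective_allosteric_constant()`) and per-molecule binding (`m = 1`,
one peptide per molecule). `hemicam` implements both as a per-target
flag. The bundled peptide fixtures use **per-molecule** binding: a
calmodulin-binding domain occupies the lobe's hydrophobic groove, so one
peptide per lobe is the physically sensible picture, and it is the
convention that reproduces the observed saturation of the effect — with
one site per molecule, raising the NaV1.2 IQ peptide from a 1:1.4 to a
1:2.8 molar ratio moves the half-saturation point by less than 0.01
log10 units (the effect is already saturated), whereas a two-site
convention predicts a further ~0.4-decade shift that contradicts the
published observation. Intact calmodulin binds at most one target per
molecule, exclusively, in all cases.

### Intact calmodulin

The intact molecule is the product of its lobes: conformation weights
multiply, calcium binds each lobe as in isolation, and a whole-molecule
target contributes a factor `(1 + [A]free / K_conf)` where `K_conf` is
its dissociation constant for the joint conformation (RR, RT, TR, TT).
With no targets the saturation curve is exactly the mean of the two
lobe curves. The four target affinities are rarely all measured;
`assign_intact_target_affinities()` encodes the standard assignment:
K(RR) from the calcium-saturated affinity, K(TT) from the apo affinity,
K(TR) from the calcium-saturated affinity for the isolated C-lobe, and
K(RT) taken equal to K(TT). Literature inequality bounds (e.g.
"< 0.1 nM", "> 600 uM") are encoded at their bound value and flagged;
one published table gives the C-lobe R-state affinity of the WF10
peptide as 735 nM while another lists 712 nM for the isolated fragment
— both are preserved as printed, the intact-molecule fixtures using
735 nM and the lobe fixture 712 nM.

## Equilibrium solving with total concentrations

Titration experiments buffer free calcium but report *total* peptide
concentrations, so the analytic saturation function cannot be applied
directly. `cam_mixture()` + `titration_curve()` solve the mass balance
`total = free + bound(free)` for every target at each calcium point.
Because every binding polynomial is monotone in the free concentration,
each one-dimensional problem has a unique root; the solver uses 62
vectorised bisection steps per target (machine precision on the
bracket), with Gauss–Seidel sweeps across targets until every relative
conservation residual falls below 1e-12. Calcium is clamped free by
default; a `conserved_total` mode instead treats total calcium as known
and finds the free level by outer bisection. Degenerate inputs (zero
protein, zero target) short-circuit to the trivial solution.

Competing targets are treated as mutually exclusive on one protein
molecule (`competing_targets_curve()`); with a single target this
reduces exactly to the ordinary curve.

## The combinatorial network and SBML export

`enumerate_species()` spells out every microstate: 2 conformations per
lobe x 2^4 site occupancies = 64 calmodulin species, doubled per
exclusive target. `build_network()` derives every reaction from a
single thermodynamic potential: per-site calcium binding with the
conformation's microscopic constant, concerted per-lobe flips with
equilibrium constant `L * c^(calcium bound on that lobe)` (times the
ratio of target affinities when a target is bound), and target
binding to every conformation. Because all equilibrium constants come
from one potential, the Wegscheider condition (cycle products equal to
one) holds by construction; `wegscheider_residuals()` verifies it edge
by edge against a spanning tree. Rate constants are not part of the
scientific content: forward rates are set to one nominal value and
backward rates derived from the equilibrium constants, so only
equilibria are meaningful. `network_equilibrium()` computes species
concentrations from statistical weights relative to the apo-TT state
plus the same mass-balance machinery, and agrees with the closed forms
to better than 1e-8 — this dual route (explicit network vs closed-form
partition function) is the package's main internal consistency oracle.

`export_sbml()` writes the network as SBML Level 3 with stable species
identifiers (`CaM_RT_A1B0C1D0_tWFF`), reversible mass-action kinetic
laws, and clamped calcium as a boundary species; `read_sbml()` recovers
the stoichiometry and equilibrium constants for round-trip checks.

## Hill analysis

`hill_coefficient()` evaluates the Hill-plane slope
`d log(Y/(1-Y)) / d log [Ca]`. For curves built from the lobe closed
form the exact analytic derivative is used; for arbitrary curves,
central differences on the log axis with an initial relative step of
1e-3, Richardson-refined until successive estimates agree to 1e-6. The
half-saturation point is found by bracketing bisection to a relative
tolerance of 1e-10. For a two-identical-site MWC lobe the Hill profile
is a symmetric bell on the log axis with its maximum at half-saturation;
both the value at half-saturation (the headline statistic, 1.92 for the
reference C-lobe parameters) and the curve maximum are reported.
`fit_hill()` provides the phenomenological comparison fit
`Y = x^n / (K^n + x^n)` with equal weight per point (no weighting
scheme is reported for the source data, so the simplest choice is
used).

## The fitting protocol

`fit_tr2c()` reproduces the estimation protocol for the C-lobe
fragment: four free parameters (`L`, `K_R`, `K_T`, and the T-state
affinity of the NaV1.2 IQ peptide) fitted simultaneously against three
titrations (fragment alone, + WFF at 1:1.4, + NaV peptide at 1:1.4),
with the WFF affinities fixed at their measured values and the NaV
R-state affinity fixed at its literature upper bound. The score is the
weighted sum of squared residuals with per-dataset weights `1/n_k`, so
datasets with different point counts contribute comparably. Constraints
derived from the pure-state bounding curves are enforced:
`K_R <= 20 nM`, `K_T >= 10 uM`, `c <= 0.002`.

The optimiser is a seeded real-coded genetic algorithm in log-parameter
space (population 20, 1000 generations by default, BLX blend crossover,
geometrically decaying Gaussian mutation) with feasibility-first
tournament selection standing in for stochastic-ranking constraint
handling: a feasible candidate always beats an infeasible one, feasible
candidates compare by score, infeasible ones by violation, and exact
score ties break towards the lower `L` for deterministic reporting. The
best feasible point is polished by Nelder–Mead inside a feasibility
barrier; because the score surface carries a long, nearly flat ridge in
the `(L, K_R)` plane (see Identifiability below), the polish is
restarted from a deterministic ladder of ridge-shifted points spanning
the full `L` range, so a single stalled local descent cannot trap the
reported optimum far along the ridge. Search bounds: `L` in [1, 1e8], `K_R` in [0.1 nM, 20 nM],
`K_T` in [10 uM, 1 mM], NaV `K_T` in [0.01 nM, 25 nM]. Uncertainty is
available through a seeded residual-resampling bootstrap
(`bootstrap_fit()`), off by default.

The N-lobe uses the two-step route (`fit_nlobe()`): the T-state
affinity comes from a non-cooperative `Y = x/(K+x)` fit to a
conformationally locked mutant titration (with a cooperativity warning
if that dataset has Hill n > 1.2), the R-state affinity is shared with
the C-lobe, and only `L` remains to be fitted on the N-lobe curve.

### Identifiability

`score_landscape()` exposes the structural identifiability problem: on
a target-free titration the score surface over `(L, c)` (with `K_T`
fixed and `K_R = c K_T` implied) has a long flat valley — many
parameter pairs fit a single sigmoid equally well, because the
transformation `L -> lambda L`, `K_R -> K_R / sqrt(lambda)` preserves
both the half-saturation point and the curve shape wherever
`alpha >> 1` and `L c^2` is held. Target titrations add information and
narrow the valley, but the remaining likelihood is still shallow along
this ridge relative to realistic saturation noise: the package's
diagnostic (`valley_width()`, the extent in decades of `L` of the
region within 5% of the minimum score) quantifies exactly how much the
target data constrain `L`, and the reference value of `K_R` sits on the
`K_R <= 20 nM` constraint boundary, consistent with a
constraint-limited rather than likelihood-limited estimate. Users
should treat fitted `L` values as order-of-magnitude estimates (the
reported uncertainty on the reference fit is itself ~60%), and rely on
the robustness property that a factor-two error in `L` moves the curve
by less than the scatter between published datasets.

## The synthetic-data generator

`generate_titration()` draws datasets from the model itself: a clean
curve over a log-spaced grid (25 points from 10 nM to 1 mM by default,
matching typical published titrations), additive Gaussian saturation
noise, and optional log-normal jitter on the reported calcium values.
Defaults are `sigma_Y = 0.03` and no x-jitter, since free calcium in
buffered titrations is known to high precision; with
`sigma_Y = 0.05` and `sigma_logCa = 0.1` the spread of per-replicate
half-saturation estimates reproduces the roughly factor-two scatter
seen across published curves of the same fragment. Saturation values
are clipped to [-0.1, 1.1] (the plausible reporting range of a
normalised fluorescence signal). Every dataset records its full
provenance (generating mixture, seed, noise model) and round-trips
through a commented CSV header.

`make_benchmark_suite()` builds the five-dataset benchmark mirroring
the fit/validation split of the original protocol (three fitting
datasets, two held-out validations) at `sigma_Y = 0.02` and a total
fragment concentration of 5 uM — the source experiments report only
molar ratios, so the absolute concentration is an explicit
configuration choice, not a literature fact.

What the generator does *not* emulate: fluorescence-to-saturation
transformation nonlinearities, correlated (drift-like) errors within a
titration, magnesium or buffer composition effects, and protein purity
variation. Passing recovery tests on these synthetic data therefore
demonstrates correctness of the machinery and the information content
of ideal titrations, not robustness to every systematic error in real
experiments.

## Problem sizes and numerical choices

The bundled tests run the full protocol at the study scale: 25-point
datasets, population 20, 1000 generations (~2-3 minutes), landscape
grids of 81 x 25 points over 8 decades of `L`. Key tolerances:
conservation residuals < 1e-12 relative (asserted at 1e-10), network vs
closed-form agreement 1e-8, Wegscheider residuals 1e-9 on the log
scale, half-saturation bisection 1e-10 relative. All concentrations are
molar internally; `Inf` calcium is handled as an analytic limit rather
than floating-point overflow.

## Known limitations

* Two conformations per lobe; no intermediate or additional states.
* The two sites within a lobe are identical; no site heterogeneity.
* No lobe-lobe coupling in the intact molecule (supported by the
  fragment literature, but weak coupling below the data noise cannot be
  excluded).
* One target per molecule; simultaneous multi-target binding of the
  PEP-19 kind is out of scope.
* Equilibrium only: rate constants in the exported SBML are nominal and
  only their ratios are meaningful.
* `L` is structurally weakly identified from saturation curves alone
  (see Identifiability above); the constraints, not the likelihood,
  pin its scale.
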