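---
title: "Multi-objective flux balance analysis and Pareto surface screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective flux balance analysis and Pareto surface screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paretometab)
```

## The model

Classical flux balance analysis (FBA) predicts steady-state metabolic
fluxes $v$ of a genome-scale metabolic network by optimizing a single
linear objective subject to the stoichiometric constraint $S v = 0$ and
flux bounds $lb \le v \le ub$. For proliferating cells — cancer cells in
particular — a single objective is a caricature: growth competes with
energy production, with the limited solvent capacity of the cytoplasm
(total enzyme that can be packed into a cell), and with nutrient economy.

`paretometab` treats metabolism as a four-objective optimization problem:

1. **biomass** — maximize flux through the biomass reaction (growth);
2. **atp** — maximize flux through the ATP-hydrolysis (maintenance/demand)
   reaction (energy);
3. **enzyme_cost** — minimize $\sum_i w_i |v_i|$, a linear proxy for total
   enzyme abundance. By default $w_i = 1$ for every gene-associated
   non-exchange reaction and 0 otherwise; a model may override $w_i$ per
   reaction (e.g. kcat- or molecular-weight-derived weights, or an
   expensive respiratory chain);
4. **carbon_uptake** — minimize total imported carbon,
   $\sum_j c_j \max(-v_j, 0)$ over exchange reactions, with $c_j$ the
   carbon count of the exchanged metabolite's elemental formula. Uptake is
   negative exchange flux by convention; secretion never offsets uptake.

A flux configuration is **Pareto-optimal** when no feasible configuration
improves all four objectives simultaneously. The object of study is the set
of such configurations — the Pareto surface — rather than a single optimum.

## Sampling the Pareto surface

The sampler uses the $\varepsilon$-constraint method: one objective
(biomass by default) is optimized while the other three are constrained at
levels $\varepsilon$ running over a grid. The grid ranges come from the
four single-objective extreme solutions; the default resolution is 10
levels per constrained objective. Three details matter in practice:

* **Lexicographic cleanup.** Each scalarized LP can have alternate optima
  (futile cycles, parallel routes). Every LP is therefore finished by a
  secondary enzyme-cost minimization (and tertiary carbon minimization)
  among the primary-optimal fluxes, with a fixing slack of $10^{-9}$, so
  stored fluxes are unique and bit-reproducible.
* **Dominance filtering.** The $\varepsilon$-constraint method emits weakly
  efficient points when a constraint is slack at the optimum; pooling all
  grid solutions with the extremes and applying a non-dominated filter
  (tolerance $\tau_{obj} = 10^{-6}$) removes them.
* **Near-duplicate removal.** Adjacent grid cells whose constraints are
  barely active at a shared facet return vertices that differ by far less
  than the grid resolution. Solutions closer than 0.1% in relative flux
  distance are stored once (`dedup_tol = 1e-3`); this is two orders of
  magnitude below the grid spacing and the omics noise considered below,
  so no information is lost.

The primary objective can be a vector (`primary = c("biomass", "atp")`),
in which case the grid is solved once per primary and pooled — rotating
the scalarization direction covers front facets that a single direction
visits only at isolated points.

Every LP is solved by the package's dense two-phase simplex with Bland's
anti-cycling rule. Flux polytopes are highly degenerate (many equality
constraints), and Bland's rule guarantees termination and bit-identical
reruns at the cost of some speed; at the problem sizes the package
targets in-session (tens of reactions, $10^2$–$10^3$ LPs per front) this
is never limiting. MOMA's quadratic program is solved by the dual
active-set method of Goldfarb and Idnani (`quadprog`), whose strictly
convex objective has a unique minimizer.

## Benchmark networks and what they probe

`make_fixture()` generates small networks whose fronts are analytically
understood, and `brute_force_pareto()` enumerates their flux polytopes
through a null-space parametrization (refusing more than 4 degrees of
freedom) as an independent oracle:

* **chain-net** (1 degree of freedom): biomass and ATP in fixed proportion;
  the front collapses to one efficient ray — a negative control for
  trade-off detection.
* **Y-net** (2 dof): one substrate split between a biomass path (yield 1)
  and a two-step ATP path (yield 2); the minimal growth/energy trade-off.
* **parallel-net** (4 dof): Y-net plus a duplicated first ATP-path step and
  a gene-bearing overflow (waste) route. Single knockouts of either
  duplicate are rescued by flux rerouting; the double knockout forces
  wasteful rerouting off the Pareto surface. The overflow route matters:
  in a model with two cost objectives, a *fully shut down* metabolism is
  itself Pareto-optimal (costs are zero), so a knockout only registers as
  a deviation when the rerouted flux is genuinely wasteful.
* **ferm-resp-net** (3 dof): glucose fermented to lactate (2 ATP/glucose,
  cheap enzymes) versus respired to CO2 (32 ATP/glucose, but the TCA/ETC
  reactions carry enzyme weights 2 and 16, making respiration roughly
  5.6 enzyme units per ATP against 4.0 for fermentation), with three
  further choices that shape the front's geometry:
  a mitochondrial capacity on the TCA flux at 70% of the glucose bound
  (just below the ATP-optimal respiration of a maximally growing cell, so
  fast-growing configurations sit *on* the respiratory capacity
  boundary); an ATP-hungry biomass reaction (9 ATP per unit); and a
  maintenance ATP demand equal to the uptake bound (fully scaled-down
  flux states are infeasible, as in genome-scale models with non-growth-
  associated maintenance). Under these conditions fermentation is
  cost-efficient per ATP, respiration is carbon-efficient per ATP, and the
  network exhibits the designed growth–Warburg trade-off.
* **random-net**: random sparse stoichiometry, regenerated until
  validation passes; exercises the loaders and validators.

Exchanged metabolites carry real formulas (`C6H12O6`, `C3H6O3`, `O2`,
`CO2`) so carbon accounting is non-trivial.

## Cell-line-specific models

A cell line's model is the subset of Pareto solutions that best matches its
omics. Two measured layers enter:

* **enzyme abundances** (gene-level, relative units) are compared with the
  solution's *gene-level flux engagement* — for each gene the sum of
  $|v_i|$ over reactions whose GPR references it — by Spearman rank
  correlation. Rank correlation is the right kernel for relative units: the
  score is invariant to rescaling of the abundance scale.
* **exchange fluxes** (consumption-release rates, absolute units, uptake
  negative) are compared by a scale-sensitive agreement score
  $1 - \lVert x - y \rVert / (\lVert x \rVert + \lVert y \rVert)$.
  This choice is deliberate: the Pareto front contains whole rays of
  proportional solutions (scaling a feasible flux scales all four
  objectives), and any purely rank-based kernel is invariant along those
  rays, leaving the magnitude of the flux state — and hence the growth
  rate — unidentifiable. Absolute exchange measurements are what pins the
  scale. A fully rank-based variant remains available
  (`exchange_kernel = "spearman"`).

The two components are blended with weight $\alpha = 0.5$ and the top
`top_fraction` (default 1%) of solutions is selected. Ties are resolved at
the score's statistical resolution (`sim_tol = 0.01`): a Spearman over $g$
genes moves in quanta of $6/(g^3-g)$ (about 0.007 at $g = 12$), so scores
closer than one rank swap are indistinguishable and are co-selected. The
line's predicted objective vector is the mean over selected solutions; its
single best solution is the *representative flux* used for perturbation
simulations.

The synthetic-data generator emulates this input: each synthetic line draws
a generating solution from the more proliferative half of the front (by
biomass flux — a cancer panel emulation), then emits its flux engagement
under multiplicative log-normal noise (abundances stay positive) and its
exchange fluxes under additive Gaussian noise scaled per metabolite
(relative noise level $\sigma$, default 0.05). What the generator does
*not* emulate: measurement platform biases, missing genes, regulatory
decoupling of abundance from flux, or any deviation of real cells from
Pareto optimality. Passing the recovery tests therefore shows that the
fitting machinery inverts its own forward model at realistic noise — not
that real proteomes identify flux states.

The recovery study in the acceptance suite runs at grid level 4 (a front of
roughly 20 solutions): there the front's spacing (~25% of each objective
range) is well above the 5% noise, so generating solutions are
statistically identifiable — the analogue, at desk scale, of selecting 1%
of a 42,930-solution front. On denser fronts neighboring solutions fall
inside the noise ball and exact recovery is no longer a meaningful target.

## The Pareto deviation score (PDS)

Gene knockdowns act through the GPR rules: the knocked gene's activity is
set to `knock_fraction` (0 = knockout), each reaction's availability is
re-evaluated (`and` = min over subunits, `or` = max over isozymes), and
flux bounds are scaled by the availability — bounds only ever tighten. The
post-perturbation flux is predicted by MOMA from the line's representative
flux, and its fitness cost is the **Pareto deviation score**: the Euclidean
distance, in min–max normalized objective space, from the perturbed
configuration's objective vector to the nearest sampled Pareto solution.

Choices worth making explicit:

* distance is measured in objective space (the axes in which optimality is
  defined, and the only space where the four quantities are
  commensurable), against the *discrete* sampled set rather than an
  interpolated manifold; `tol_pds = 1e-6` clamps grid-discreteness noise
  to zero. A raw-flux-space variant was considered and rejected as the
  default because flux units are incommensurable across reactions.
* objectives whose range over the front is degenerate are dropped from the
  distance with a warning;
* a configuration that *dominates* the sampled front (possible only
  through numerical slack or an incomplete sample) still scores a
  non-negative distance and is flagged;
* when a knockout empties the feasible set entirely, the screen scores the
  nearest bound-feasible point with the steady-state residual penalized —
  and logs it.

A gene is *essential* when its knockout yields a non-zero PDS in at least
one cell line, *nonessential* otherwise. `combinatorial_perturbation()`
applies a set of knockdowns jointly, enabling single-versus-double
comparisons such as the joint glycolysis/respiration inhibition pattern.

## Target identification on the projected surface

For a phenotype $\phi$ (growth rate, or the in-silico Warburg metric =
lactate secretion / oxygen uptake, the model-side proxy of the ECAR/OCR
ratio; anaerobic configurations are capped at a documented ceiling and
flagged), the sampled surface is projected onto the $(\phi,
\text{enzyme flux})$ plane. Enzyme-level flux is the same gene-level
engagement used for fitting, so multi-reaction enzymes aggregate
consistently. The projection's **envelopes** are per-bin extremes over
equal-count phenotype bins (default 20; tied phenotype values share a
bin; projections with fewer than 3 non-empty bins are refused).

The **monotonousness score** of an envelope is the Spearman correlation
between envelope knots and phenotype. Knots sit at bin boundaries and
pool the two flanking bins (running max/min over adjacent bin pairs):
raw per-bin extremes are order statistics whose downward bias
concentrates in bins with degenerate phenotype spread, and a single
biased head bin can invert the rank order of an otherwise clean envelope.
The pooled-knot estimator removes that bias while preserving strict
monotonicity of monotone envelopes — an exactly increasing lower envelope
still scores $+1$.

Calls follow the envelope geometry, with cutoffs `score_cutoff = 0.8` and
`proximity_cutoff = 0.5`:

* **promoting** (inhibition is the intervention): the lower envelope rises
  with the phenotype, so high-phenotype configurations cannot avoid the
  enzyme, and inhibiting it pushes exactly those off the surface;
* **suppressing** (activation is the intervention): the upper envelope
  falls, so forcing flux through the enzyme selectively harms
  high-phenotype configurations.

Both calls additionally require that at least half of the cell-line models
sit close to the projection's **boundary** — within
`proximity_tol = 0.25` of the local envelope separation, of either the
upper or the lower envelope (models with headroom in both directions
cannot be pulled off the surface by a moderate perturbation). Envelope
values at a model's phenotype are interpolated between the surface points
that attain the per-bin extremes; where the two envelopes essentially
coincide (separation below 2% of the flux range) every point between them
counts as boundary. Both phenotypes are evaluated for every enzyme, which
exposes the overlap structure — in particular the *ambiguous* class of
enzymes that promote growth while suppressing the Warburg effect, which on
ferm-resp-net contains the anabolic and respiratory enzymes by
construction.

## Worked example

```{r example, eval = FALSE}
net <- make_fixture("ferm-resp-net")
weights <- objective_weights(net)
pareto <- epsilon_constraint_sample(net, weights, grid_spec(8))
panel <- make_synthetic_panel(pareto, net, n_lines = 20,
                              noise_sigma = 0.05, seed = 1)
models <- lapply(panel$profiles, function(p) fit_cell_line(pareto, net, p))
screen <- gene_essentiality_screen(pareto, net, models)
calls <- classify_targets(pareto, net, models)
target_overlap(calls)$ambiguous
```

## Problem sizes, tolerances, limitations

The in-package test and acceptance workloads use grid levels 4–8 on the
benchmark networks (fronts of ~20–300 solutions, a few thousand LPs in
total), panels of 20–100 lines, and brute-force oracles at flux steps 1–2;
these sizes keep a full run in the order of a minute while leaving every
geometric feature of the method exercised. Defaults elsewhere:
$\tau_{feas} = 10^{-9}$, $\tau_{obj} = 10^{-6}$, $\tau_{pds} = 10^{-6}$,
projection values snapped at $10^{-6}$ before binning so solver noise
cannot split bins.

Known limitations. The enzyme-cost proxy is flux-linear; real enzyme
demand depends on kcat and saturation. The Warburg proxy ignores
CO2-derived acidification that contributes to measured ECAR. Distances to
the *sampled* surface underestimate distance to the true surface by up to
the grid resolution. The GPR semantics (min/max) is the standard
complex/isozyme convention but is not the only quantitative reading.
Boundary proximity depends on where the fitted models land, hence on the
omics panel; sparse or noisy panels weaken target calls before they
weaken essentiality calls.
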