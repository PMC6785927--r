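# paretometab

Multi-objective flux balance analysis of metabolic networks, and screening
of metabolic vulnerabilities by Pareto-surface geometry.

## What it does, and for whom

Constraint-based metabolic models are usually analysed by optimizing a
single objective (most often biomass). Proliferating cells — cancer cells
in particular — balance several competing demands at once. `paretometab`
models steady-state metabolism (S·v = 0, lb ≤ v ≤ ub) as a
**four-objective** optimization problem:

| objective      | sense    | definition                                             |
|----------------|----------|--------------------------------------------------------|
| biomass        | maximize | flux through the biomass reaction                      |
| atp            | maximize | flux through the ATP-hydrolysis (demand) reaction      |
| enzyme_cost    | minimize | Σᵢ wᵢ·\|vᵢ\| (solvent-capacity proxy for enzyme usage) |
| carbon_uptake  | minimize | Σⱼ cⱼ·max(−vⱼ, 0) over exchange reactions              |

and provides, for systems and cancer biologists working with genome-scale
or toy metabolic models:

* **Pareto surface sampling** by the ε-constraint method
  (`epsilon_constraint_sample()`): a grid of single-objective LPs with the
  other objectives constrained at ε levels, lexicographically cleaned and
  dominance-filtered, solved by a built-in deterministic two-phase simplex;
* **cell-line-specific models** (`fit_cell_line()`): the Pareto solutions
  whose gene-level flux engagement and exchange fluxes best match a line's
  proteomic and consumption-release (CORE) profiles;
* **gene essentiality by Pareto deviation** (`gene_essentiality_screen()`,
  `combinatorial_perturbation()`): knockdowns propagate through GPR rules,
  the perturbed flux is predicted by MOMA (minimization of metabolic
  adjustment, a quadratic program), and fitness cost is the **PDS** — the
  Euclidean distance in normalized objective space from the perturbed
  configuration to the sampled Pareto surface (zero exactly on the
  surface);
* **target identification** (`classify_targets()`): projecting the surface
  onto (phenotype, enzyme-flux) planes — phenotype being growth rate or an
  in-silico Warburg metric (lactate secretion / O₂ uptake, the model-side
  ECAR/OCR) — scoring the monotonousness of the projection's upper/lower
  envelopes, and calling enzymes *promoting* (rising lower bound:
  inhibition selectively harms high-phenotype cells) or *suppressing*
  (falling upper bound: activation does);
* **benchmark generators** (`make_fixture()`, `brute_force_pareto()`,
  `make_synthetic_panel()`): small networks with analytically known fronts
  and synthetic omics panels with ground truth, so the whole pipeline is
  verifiable end to end.

Models load from a tabular TSV dialect or SBML L3/fbc (`load_model()`).
A thin command-line wrapper ships in `inst/cli/pareto-metab`
(subcommands `model`, `sample`, `fit`, `pds`, `targets`, `synth`, `run`).

## Worked example

A fermentation-versus-respiration network in which fermentation is
enzyme-cheap per ATP and respiration is carbon-cheap per ATP:

```r
library(paretometab)

net     <- make_fixture("ferm-resp-net")
weights <- objective_weights(net)
pareto  <- epsilon_constraint_sample(net, weights, grid_spec(8))
pareto
#> pareto_set: 153 solutions, 4 objectives
#>      biomass atp enzyme_cost carbon_uptake
#> min  0.00000  10        40.0         1.875
#> max 12.77778 125       678.5        60.000

panel  <- make_synthetic_panel(pareto, net, n_lines = 20,
                               noise_sigma = 0.05, seed = 1)
models <- lapply(panel$profiles, function(p) fit_cell_line(pareto, net, p))
models[[1]]
#> cell_line_model 'line001': 2 solutions (top similarity 0.988)
#>       biomass           atp   enzyme_cost carbon_uptake
#>       8.37910      34.64286     587.28571      55.84821

calls <- classify_targets(pareto, net, models)
subset(calls, direction != "none",
       c(enzyme, phenotype, direction, monotonousness))
#>    enzyme phenotype   direction monotonousness
#> 1    gANA    growth   promoting      1.0000000
#> 3    gETC    growth   promoting      0.9063758
#> 10   gTCA    growth   promoting      0.9063758
#> 13   gETC   warburg suppressing     -0.8546298
#> 17   gLDH   warburg   promoting      0.9901750
#> 18   gMCT   warburg   promoting      0.9901750
#> 20   gTCA   warburg suppressing     -0.8546298
#> ...
target_overlap(calls)$ambiguous
#> [1] "gCO2T" "gETC"  "gO2T"  "gTCA"
```

Read: the anabolic enzyme (`gANA`) and the respiratory chain (`gTCA`,
`gETC`) are required for fast growth (rising lower flux bound, score ~1);
forcing extra respiratory flux suppresses the Warburg phenotype (falling
upper bound, score −0.85); lactate dehydrogenase and the lactate
transporter promote it (score 0.99). The respiratory enzymes fall in the
*ambiguous* class — growth-promoting **and** Warburg-suppressing — so
inhibiting them trades one cancer phenotype against the other.

Knockout fitness from the same objects:

```r
screen <- gene_essentiality_screen(pareto, net, models)
head(screen$essential, 3)
#>    gene n_lines_nonzero essential
#> 1  gANA              20      TRUE
#> 2 gCO2T              17      TRUE
#> 3  gETC              17      TRUE
```

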