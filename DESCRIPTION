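Package: paretometab
Title: Multi-Objective Flux Balance Analysis and Pareto Surface Analysis of
    Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based modelling of cellular metabolism under the
    assumption that flux configurations are shaped by trade-offs among four
    objectives: maximization of biomass synthesis, maximization of ATP
    production, minimization of total enzyme usage, and minimization of total
    carbon uptake. Samples Pareto-optimal flux configurations of a
    genome-scale metabolic model by the epsilon-constraint method, builds
    cell-line-specific models by matching Pareto solutions to proteomic and
    exometabolomic (consumption-release) profiles, scores gene-ablation
    fitness effects as the deviation of the post-knockdown flux configuration
    (predicted by minimization of metabolic adjustment, MOMA) from the Pareto
    surface, and classifies metabolic enzymes as promoting or suppressing
    proliferation or the Warburg effect from the geometry of the projected
    Pareto surface. Ships generators for small benchmark networks with
    analytically known Pareto fronts and for synthetic omics panels with
    ground truth, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    quadprog,
    jsonlite,
    stats,
    utils,
    tools,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
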