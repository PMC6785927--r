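# Shared fixtures and cached Pareto fronts (sampling is deterministic, the
# cache only avoids re-solving the same LP grids across test files).

.cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, ...) {
  key <- paste0("net_", name)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- make_fixture(name, ...)
  .cache[[key]]
}

cached_weights <- function(name) {
  key <- paste0("w_", name)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- suppressWarnings(objective_weights(cached_fixture(name)))
  .cache[[key]]
}

cached_front <- function(name, levels = 5, primary = "biomass") {
  key <- paste0("ps_", name, "_", levels, "_", paste(primary, collapse = "+"))
  if (is.null(.cache[[key]]))
    .cache[[key]] <- epsilon_constraint_sample(
      cached_fixture(name), cached_weights(name), grid_spec(levels),
      primary = primary)
  .cache[[key]]
}

cached_oracle <- function(name, step) {
  key <- paste0("bf_", name, "_", step)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- brute_force_pareto(cached_fixture(name), step,
                                        cached_weights(name))
  .cache[[key]]
}

# A cell-line model anchored at one Pareto solution that uses both the
# biomass and the energy pathway (a metabolically "mixed" line). Built
# directly rather than through fitting: the perturbation tests probe the
# PDS mechanics, not profile matching, and tiny fixtures with three genes
# are rank-degenerate for the similarity kernel.
mixed_line <- function(pareto, network, frac = 0.25) {
  obj <- pareto$objectives
  mix <- which(obj[, "biomass"] > frac * max(obj[, "biomass"]) &
                 obj[, "atp"] > frac * max(obj[, "atp"]))[1]
  stopifnot(!is.na(mix))
  model <- structure(list(
    cell_line_id = "mixed",
    selected = mix,
    similarity = 1,
    representative = mix,
    predicted_objectives = obj[mix, ]
  ), class = "cell_line_model")
  list(model = model, truth = mix)
}

# Brute-force dominance scan used as the oracle against pareto_filter and
# pds_score (independent of the package's vectorized implementations).
oracle_nondominated <- function(points, senses = objective_senses()) {
  n <- nrow(points)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(points[j, ], points[i, ], senses)) { dominated <- TRUE; break }
    }
    keep[i] <- !dominated
  }
  which(keep)
}

oracle_pds <- function(point, pareto) {
  lo <- pareto$normalization["min", ]
  hi <- pareto$normalization["max", ]
  span <- hi - lo
  keep <- span > 1e-12
  best <- Inf
  for (i in seq_len(n_solutions(pareto))) {
    d <- sqrt(sum(((pareto$objectives[i, keep] - point[keep]) / span[keep])^2))
    best <- min(best, d)
  }
  best
}

# random feasible fluxes as convex combinations of sampled Pareto fluxes
# (the flux polytope is convex, so any mixture is feasible)
random_feasible <- function(pareto, n, seed) {
  set.seed(seed)
  out <- t(vapply(seq_len(n), function(i) {
    w <- stats::rexp(n_solutions(pareto))
    w <- w / sum(w)
    as.numeric(w %*% pareto$fluxes)
  }, numeric(ncol(pareto$fluxes))))
  colnames(out) <- colnames(pareto$fluxes)
  out
}

tiny_sbml <- function() {
  path <- tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" level="3" version="1">
<model id="toy">
<listOfParameters>
<parameter id="lb_neg10" value="-10" constant="true"/>
<parameter id="ub_0" value="0" constant="true"/>
<parameter id="lb_0" value="0" constant="true"/>
<parameter id="ub_1000" value="1000" constant="true"/>
</listOfParameters>
<listOfCompartments><compartment id="c" constant="true"/><compartment id="e" constant="true"/></listOfCompartments>
<listOfSpecies>
<species id="glc_e" compartment="e" fbc:chemicalFormula="C6H12O6" constant="false"/>
<species id="pyr" compartment="c" constant="false"/>
<species id="atp" compartment="c" constant="false"/>
</listOfSpecies>
<listOfReactions>
<reaction id="EX_glc" reversible="true" fbc:lowerFluxBound="lb_neg10" fbc:upperFluxBound="ub_0">
<listOfReactants><speciesReference species="glc_e" stoichiometry="1" constant="true"/></listOfReactants>
</reaction>
<reaction id="GLY" reversible="false" fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_1000">
<listOfReactants><speciesReference species="glc_e" stoichiometry="1" constant="true"/></listOfReactants>
<listOfProducts><speciesReference species="pyr" stoichiometry="1" constant="true"/><speciesReference species="atp" stoichiometry="2" constant="true"/></listOfProducts>
<fbc:geneProductAssociation><fbc:and><fbc:geneProductRef fbc:geneProduct="g1"/><fbc:geneProductRef fbc:geneProduct="g2"/></fbc:and></fbc:geneProductAssociation>
</reaction>
<reaction id="BIOMASS" reversible="false" fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_1000">
<listOfReactants><speciesReference species="pyr" stoichiometry="1" constant="true"/></listOfReactants>
<fbc:geneProductAssociation><fbc:or><fbc:geneProductRef fbc:geneProduct="gB1"/><fbc:geneProductRef fbc:geneProduct="gB2"/></fbc:or></fbc:geneProductAssociation>
</reaction>
<reaction id="ATPM" reversible="false" fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_1000">
<listOfReactants><speciesReference species="atp" stoichiometry="1" constant="true"/></listOfReactants>
</reaction>
</listOfReactions>
</model></sbml>', path)
  path
}

write_tabular_toy <- function(dir = tempfile()) {
  dir.create(dir)
  write.table(
    data.frame(reaction = c("EX_A", "CONV", "BIOMASS_SINK", "ATPM"),
               equation = c("A -> ", "A -> B + atp", "B -> ", "atp -> "),
               lower_bound = c(-10, 0, 0, 0),
               upper_bound = c(0, 1000, 1000, 1000),
               gpr = c("", "g1", "gB", "")),
    file.path(dir, "reactions.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write.table(
    data.frame(metabolite = c("A", "B", "atp"),
               name = c("substrate", "intermediate", "ATP"),
               compartment = c("e", "c", "c"),
               formula = c("C2H4O2", "C2H4O2", "")),
    file.path(dir, "metabolites.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  dir
}
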