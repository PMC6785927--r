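#' Objective weights for the four-objective model
#'
#' Holds the per-reaction enzyme-usage weights and the per-exchange carbon
#' coefficients that parametrize the two cost objectives.
#'
#' By default every gene-associated reaction gets enzyme weight 1 and every
#' exchange or non-gene-associated reaction weight 0, a flux-sum proxy for
#' total enzyme abundance motivated by the solvent-capacity argument (the
#' total protein a cell can pack is limited, and flux through a reaction
#' needs enzyme roughly in proportion). A network may override weights per
#' reaction via its `enzyme_weight` column (e.g. to make a pathway
#' enzymatically expensive per unit flux, as respiration is compared to
#' fermentation); kcat- or molecular-weight-based weights can be supplied
#' the same way.
#'
#' Carbon coefficients count the carbon atoms of each exchanged metabolite
#' (from its elemental formula; metabolites without a formula contribute 0
#' with a warning at build time).
#'
#' @param network a `metabolic_network`.
#' @param enzyme_weight optional named numeric vector overriding weights.
#' @param carbon_coeff optional named numeric vector (exchange reaction id
#'   -> carbons) overriding formula-derived counts.
#' @return object of class `objective_weights`.
#' @export
objective_weights <- function(network, enzyme_weight = NULL,
                              carbon_coeff = NULL) {
  rxn <- network$reactions
  gene_assoc <- vapply(network$gpr_ast, function(g) !is.null(g), logical(1))
  w <- ifelse(gene_assoc & !rxn$is_exchange, 1, 0)
  names(w) <- rxn$id
  own <- rxn$enzyme_weight
  if (!is.null(own)) w[!is.na(own)] <- own[!is.na(own)]
  if (!is.null(enzyme_weight)) w[names(enzyme_weight)] <- enzyme_weight
  stopifnot(all(w >= 0))

  exch <- exchange_metabolites(network)
  cc <- vapply(exch, function(m) {
    f <- network$metabolites$formula[network$metabolites$id == m]
    suppressWarnings(as.numeric(carbon_content(f)))
  }, numeric(1))
  if (!is.null(carbon_coeff)) cc[names(carbon_coeff)] <- carbon_coeff
  stopifnot(all(cc >= 0))
  structure(list(enzyme_weight = w, carbon_coeff = cc),
            class = "objective_weights")
}

#' Build the four metabolic objective functionals
#'
#' Constructs the four objectives of the multi-objective model:
#' \describe{
#'   \item{biomass}{maximize flux through the biomass reaction (growth).}
#'   \item{atp}{maximize flux through the ATP-hydrolysis reaction (energy).}
#'   \item{enzyme_cost}{minimize the weighted sum of absolute fluxes,
#'     `sum_i w_i |v_i|`, a proxy for total enzyme abundance under the
#'     solvent-capacity constraint.}
#'   \item{carbon_uptake}{minimize total carbon imported, summing carbon
#'     atoms times the uptake part of each exchange flux (uptake is negative
#'     exchange flux by convention; secretion does not offset uptake).}
#' }
#'
#' @param network a `metabolic_network`.
#' @param weights an [objective_weights()]; built with defaults when `NULL`.
#' @return named list of four [linear_functional()]s, in the order
#'   biomass, atp, enzyme_cost, carbon_uptake.
#' @export
build_objectives <- function(network, weights = NULL) {
  if (is.null(weights)) weights <- objective_weights(network)
  if (is.null(network$biomass_reaction_id) ||
      !network$biomass_reaction_id %in% network$reactions$id)
    stop("configuration error: biomass reaction id not resolved")
  if (is.null(network$atp_reaction_id) ||
      !network$atp_reaction_id %in% network$reactions$id)
    stop("configuration error: ATP-hydrolysis reaction id not resolved")
  w <- weights$enzyme_weight[weights$enzyme_weight > 0]
  # uptake = negative exchange flux; uptake carbon of v_j is c_j * max(-v_j, 0)
  # = c_j * |v_j| when secretion is excluded per reaction via split parts:
  # realized as abs-part minus signed part over 2: c*(|v| - v)/2
  cc <- weights$carbon_coeff[weights$carbon_coeff > 0]
  list(
    biomass = linear_functional(
      stats::setNames(1, network$biomass_reaction_id),
      sense = "maximize", name = "biomass"),
    atp = linear_functional(
      stats::setNames(1, network$atp_reaction_id),
      sense = "maximize", name = "atp"),
    enzyme_cost = linear_functional(
      sense = "minimize", name = "enzyme_cost", abs_coefficients = w),
    carbon_uptake = linear_functional(
      coefficients = -cc / 2, abs_coefficients = cc / 2,
      sense = "minimize", name = "carbon_uptake")
  )
}

#' Objective senses of the four-objective model
#' @return character vector (`"max"`/`"min"`) named by objective.
#' @export
objective_senses <- function() {
  c(biomass = "max", atp = "max", enzyme_cost = "min", carbon_uptake = "min")
}

#' Evaluate a flux configuration in 4-D objective space
#'
#' Maps any flux configuration to its objective vector (biomass, atp,
#' enzyme_cost, carbon_uptake). Deterministic; the enzyme cost is the exact
#' weighted sum of absolute fluxes and the carbon uptake counts only the
#' uptake direction of exchange fluxes.
#'
#' @param network a `metabolic_network`.
#' @param weights an [objective_weights()] or `NULL` for defaults.
#' @param flux named flux vector or `flux_configuration`.
#' @return named numeric vector of length 4.
#' @export
evaluate_objectives <- function(network, weights = NULL, flux) {
  if (is.null(weights)) weights <- objective_weights(network)
  v <- flux_vector(flux)[network$reactions$id]
  biomass <- unname(v[network$biomass_reaction_id])
  atp <- unname(v[network$atp_reaction_id])
  enzyme_cost <- sum(weights$enzyme_weight * abs(v))
  up <- pmax(-v[names(weights$carbon_coeff)], 0)
  carbon_uptake <- sum(weights$carbon_coeff * up)
  c(biomass = biomass, atp = atp, enzyme_cost = enzyme_cost,
    carbon_uptake = carbon_uptake)
}
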