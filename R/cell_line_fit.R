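#' An omics profile for one cell line
#'
#' Bundles the two measured layers used to individualize models: relative
#' enzyme/protein abundances per gene and consumption-release (CORE)
#' exchange fluxes per metabolite, with uptake negative by convention.
#'
#' @param cell_line_id identifier.
#' @param enzyme_abundance named non-negative numeric (gene -> abundance).
#' @param exchange_flux named numeric (metabolite -> mmol/gDW/h; negative =
#'   consumption).
#' @return object of class `omics_profile`.
#' @export
omics_profile <- function(cell_line_id, enzyme_abundance = numeric(),
                          exchange_flux = numeric()) {
  if (!length(enzyme_abundance) && !length(exchange_flux))
    stop("omics profile needs at least one of enzyme_abundance/exchange_flux")
  stopifnot(all(enzyme_abundance >= 0))
  structure(list(cell_line_id = cell_line_id,
                 enzyme_abundance = enzyme_abundance,
                 exchange_flux = exchange_flux),
            class = "omics_profile")
}

#' @export
print.omics_profile <- function(x, ...) {
  cat("omics_profile '", x$cell_line_id, "': ",
      length(x$enzyme_abundance), " proteins, ",
      length(x$exchange_flux), " exchange fluxes\n", sep = "")
  invisible(x)
}

#' Gene-level flux engagement of a flux configuration
#'
#' The model-side analogue of protein abundance: for each gene, the sum of
#' absolute fluxes over all reactions whose GPR references it. Rests on the
#' assumption that the enzyme abundance of a pathway tracks the flux it
#' carries. Genes absent from all GPRs score 0.
#'
#' @param network a `metabolic_network`.
#' @param flux named flux vector or `flux_configuration`.
#' @return named non-negative numeric over `network$genes`.
#' @export
pathway_flux_features <- function(network, flux) {
  v <- abs(flux_vector(flux)[network$reactions$id])
  out <- stats::setNames(numeric(length(network$genes)), network$genes)
  for (i in seq_along(network$gpr_ast)) {
    g <- gpr_genes(network$gpr_ast[[i]])
    if (length(g)) out[g] <- out[g] + v[i]
  }
  out
}

# genes x solutions feature matrix for a sampled Pareto set
pareto_features <- function(pareto, network) {
  stopifnot(!is.null(pareto$fluxes))
  vapply(seq_len(n_solutions(pareto)), function(i)
    pathway_flux_features(network, pareto$fluxes[i, ]),
    numeric(length(network$genes)))
}

# exchanged-metabolite x solutions flux matrix (sign as in the model:
# negative = uptake)
pareto_exchange <- function(pareto, network) {
  stopifnot(!is.null(pareto$fluxes))
  exch <- exchange_metabolites(network)
  m <- t(pareto$fluxes[, names(exch), drop = FALSE])
  rownames(m) <- unname(exch)
  m
}

#' Similarity between an omics profile and one Pareto solution
#'
#' Blended agreement score between a cell line's measurements and one
#' Pareto solution's fluxes, combined as
#' `alpha * s_protein + (1 - alpha) * s_exchange`.
#'
#' The protein component is the Spearman rank correlation between measured
#' enzyme abundances and the solution's gene-level flux engagement over
#' shared genes: abundances come in relative units, so only their ranking is
#' trustworthy, and the rank kernel makes the score invariant to positive
#' rescaling of abundance units. The exchange component compares measured
#' and model exchange fluxes (both on the uptake-negative convention) and is
#' scale-sensitive by default, `1 - ||x - y|| / (||x|| + ||y||)` over shared
#' metabolites: consumption-release rates are absolute measurements, and a
#' rank-based kernel here would be blind to the overall flux magnitude (the
#' Pareto front contains whole rays of proportional solutions that rank
#' identically), leaving growth rate unidentifiable. Set
#' `exchange_kernel = "spearman"` for a fully rank-based score.
#'
#' A component with fewer than `min_shared` shared items drops out and the
#' other is reweighted to 1; if both drop, an insufficient-overlap error is
#' raised. A rank component whose values are constant on either side (e.g.
#' an all-zero flux configuration) has undefined correlation and scores 0:
#' it carries no evidence for or against a match.
#'
#' @param profile an [omics_profile()].
#' @param solution_features named numeric, gene -> flux engagement.
#' @param solution_exchange named numeric, metabolite -> exchange flux.
#' @param alpha blending weight of the protein component.
#' @param min_shared minimum shared items per component.
#' @param exchange_kernel `"distance"` (default) or `"spearman"`.
#' @return similarity in `[-1, 1]`.
#' @export
solution_similarity <- function(profile, solution_features,
                                solution_exchange = numeric(),
                                alpha = 0.5, min_shared = 3,
                                exchange_kernel = c("distance", "spearman")) {
  exchange_kernel <- match.arg(exchange_kernel)
  comp <- function(x, y) {
    shared <- intersect(names(x), names(y))
    if (length(shared) < min_shared) return(NA_real_)
    xs <- x[shared]; ys <- y[shared]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(0)
    stats::cor(xs, ys, method = "spearman")
  }
  comp_dist <- function(x, y) {
    shared <- intersect(names(x), names(y))
    if (length(shared) < min_shared) return(NA_real_)
    xs <- x[shared]; ys <- y[shared]
    den <- sqrt(sum(xs^2)) + sqrt(sum(ys^2))
    if (den < 1e-12) return(1)        # both zero: perfect agreement
    1 - sqrt(sum((xs - ys)^2)) / den
  }
  rp <- comp(profile$enzyme_abundance, solution_features)
  re <- if (exchange_kernel == "distance")
    comp_dist(profile$exchange_flux, solution_exchange)
  else comp(profile$exchange_flux, solution_exchange)
  w <- c(alpha, 1 - alpha)
  r <- c(rp, re)
  ok <- !is.na(r)
  if (!any(ok))
    stop("insufficient overlap: fewer than ", min_shared,
         " shared genes and metabolites between profile '",
         profile$cell_line_id, "' and the model")
  sum(w[ok] * r[ok]) / sum(w[ok])
}

#' Fit a cell-line-specific model
#'
#' Scores every Pareto solution against the line's omics profile with
#' [solution_similarity()] and selects the top `top_fraction` of solutions
#' (at least one). Solutions tied with the cutoff similarity are all
#' retained, so the rule is stable under reordering; ties are resolved at
#' the score's statistical resolution `sim_tol` rather than machine
#' precision, because a rank correlation over a handful of genes moves in
#' discrete quanta (one adjacent rank swap over `g` genes changes Spearman
#' by `6/(g^3 - g)`, about 0.007 for 12 genes) and scores closer than that
#' are indistinguishable. The line's predicted objective vector is the mean
#' over selected solutions, and the single top-scoring solution serves as
#' the line's representative flux for perturbation simulations.
#'
#' @param pareto a `pareto_set` with fluxes.
#' @param network the generating `metabolic_network`.
#' @param profile an [omics_profile()].
#' @param top_fraction fraction of solutions selected, in `(0, 1]`.
#' @param sim_tol similarity differences below this count as ties.
#' @param alpha,min_shared,exchange_kernel passed to
#'   [solution_similarity()].
#' @return object of class `cell_line_model`: `cell_line_id`, `selected`
#'   (indices), `similarity` (per selected solution), `representative`
#'   (index of the top solution), `predicted_objectives`.
#' @export
fit_cell_line <- function(pareto, network, profile, top_fraction = 0.01,
                          sim_tol = 0.01, alpha = 0.5, min_shared = 3,
                          exchange_kernel = c("distance", "spearman")) {
  exchange_kernel <- match.arg(exchange_kernel)
  stopifnot(top_fraction > 0, top_fraction <= 1, n_solutions(pareto) > 0)
  feats <- pareto_features(pareto, network)
  exch <- pareto_exchange(pareto, network)
  n <- n_solutions(pareto)
  sim <- vapply(seq_len(n), function(i)
    solution_similarity(profile, feats[, i], exch[, i],
                        alpha = alpha, min_shared = min_shared,
                        exchange_kernel = exchange_kernel),
    numeric(1))
  k <- max(1L, ceiling(top_fraction * n))
  cutoff <- sort(sim, decreasing = TRUE)[k]
  selected <- which(sim >= cutoff - sim_tol)
  selected <- selected[order(-sim[selected], selected)]
  structure(list(
    cell_line_id = profile$cell_line_id,
    selected = selected,
    similarity = sim[selected],
    representative = selected[1],
    predicted_objectives = colMeans(
      pareto$objectives[selected, , drop = FALSE])
  ), class = "cell_line_model")
}

#' @export
print.cell_line_model <- function(x, ...) {
  cat("cell_line_model '", x$cell_line_id, "': ", length(x$selected),
      " solutions (top similarity ", format(x$similarity[1], digits = 3),
      ")\n", sep = "")
  print(x$predicted_objectives)
  invisible(x)
}

#' Predict growth across a panel of cell lines
#'
#' Fits every profile with [fit_cell_line()] and reports the predicted
#' biomass flux per line. When measured growth rates are supplied, the
#' Spearman rank correlation between measured and predicted growth is
#' computed with a permutation p-value (growth labels permuted, fixed
#' seed). With zero variance on either side the correlation is undefined
#' and flagged `NA`.
#'
#' @param pareto a `pareto_set` with fluxes.
#' @param network the generating `metabolic_network`.
#' @param profiles list of [omics_profile()]s (at least 2).
#' @param measured_growth optional named numeric (cell line -> growth rate).
#' @param top_fraction,alpha passed to [fit_cell_line()].
#' @param n_perm permutations for the p-value.
#' @param seed seed for the permutation test.
#' @return list with `table` (data.frame cell_line, predicted_biomass and,
#'   if supplied, measured_growth), `models`, and when measured growth is
#'   given `spearman` and `p_value`.
#' @export
predict_growth_panel <- function(pareto, network, profiles,
                                 measured_growth = NULL,
                                 top_fraction = 0.01, alpha = 0.5,
                                 n_perm = 1000, seed = 1) {
  stopifnot(length(profiles) >= 2)
  models <- lapply(profiles, function(p)
    fit_cell_line(pareto, network, p, top_fraction = top_fraction,
                  alpha = alpha))
  tab <- data.frame(
    cell_line = vapply(models, function(m) m$cell_line_id, character(1)),
    predicted_biomass = vapply(models, function(m)
      m$predicted_objectives[["biomass"]], numeric(1)),
    stringsAsFactors = FALSE)
  out <- list(table = tab, models = models)
  if (!is.null(measured_growth)) {
    g <- measured_growth[tab$cell_line]
    tab$measured_growth <- unname(g)
    out$table <- tab
    if (stats::sd(g) == 0 || stats::sd(tab$predicted_biomass) == 0) {
      out$spearman <- NA_real_
      out$p_value <- NA_real_
      warning("zero variance in growth panel: correlation undefined")
    } else {
      rho <- stats::cor(g, tab$predicted_biomass, method = "spearman")
      perm <- local_seed(seed, vapply(seq_len(n_perm), function(i)
        stats::cor(sample(g), tab$predicted_biomass, method = "spearman"),
        numeric(1)))
      out$spearman <- rho
      out$p_value <- (1 + sum(abs(perm) >= abs(rho))) / (n_perm + 1)
    }
  }
  out
}
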