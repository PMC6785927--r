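#' Apply a gene knockdown to a metabolic network
#'
#' Propagates reduced gene activity through the GPR rules: for every
#' gene-associated reaction the new availability is
#' `evaluate_gpr(gpr, activities)` with the targeted gene(s) set to
#' `knock_fraction` and all others to 1, and both flux bounds are scaled by
#' that availability. Bounds are only ever tightened (availability is in
#' `[0, 1]` and GPR evaluation is monotone); reactions without a GPR are
#' untouched, and isozyme (`or`) rules rescue single knockouts.
#'
#' @param network a `metabolic_network`.
#' @param gene_id one or more gene ids knocked down jointly.
#' @param knock_fraction residual activity in `[0, 1]`; 0 = full knockout.
#' @return the perturbed `metabolic_network`.
#' @export
apply_knockdown <- function(network, gene_id, knock_fraction = 0) {
  stopifnot(knock_fraction >= 0, knock_fraction <= 1)
  unknown <- setdiff(gene_id, network$genes)
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  act <- stats::setNames(rep(1, length(network$genes)), network$genes)
  act[gene_id] <- knock_fraction
  out <- network
  for (i in seq_along(network$gpr_ast)) {
    ast <- network$gpr_ast[[i]]
    if (is.null(ast)) next
    if (!any(gpr_genes(ast) %in% gene_id)) next
    a <- evaluate_gpr(ast, act)
    out$reactions$lower_bound[i] <- a * network$reactions$lower_bound[i]
    out$reactions$upper_bound[i] <- a * network$reactions$upper_bound[i]
  }
  out
}

#' Pareto deviation score (PDS)
#'
#' Distance of a flux configuration's objective point from the sampled
#' Pareto surface: each objective is min-max normalized to `[0, 1]` using
#' the Pareto set's own ranges, and the score is the minimum Euclidean
#' distance to any sampled Pareto solution. A configuration scores 0 (after
#' clamping below `tol_pds`, which absorbs grid discreteness) exactly when
#' it sits on the sampled surface; deviations in any direction — including
#' super-optimal points outside the front, which are flagged — are
#' non-negative distances.
#'
#' Objectives whose range over the Pareto set is degenerate (max = min) are
#' dropped from the distance with a warning.
#'
#' @param point objective vector (same columns as the Pareto set).
#' @param pareto a `pareto_set`.
#' @param tol_pds clamping threshold.
#' @param flag_super_optimal message when the point dominates the whole
#'   front.
#' @return non-negative numeric.
#' @export
pds_score <- function(point, pareto, tol_pds = 1e-6,
                      flag_super_optimal = TRUE) {
  stopifnot(n_solutions(pareto) > 0)
  obj <- pareto$objectives
  nm <- colnames(obj)
  point <- point[nm]
  lo <- pareto$normalization["min", ]
  hi <- pareto$normalization["max", ]
  span <- hi - lo
  keep <- span > 1e-12
  if (!all(keep)) {
    warning("degenerate normalization range for objective(s) ",
            paste(nm[!keep], collapse = ", "), "; dropped from PDS")
    if (!any(keep)) return(0)
  }
  Pn <- sweep(sweep(obj[, keep, drop = FALSE], 2, lo[keep], `-`),
              2, span[keep], `/`)
  pn <- (point[keep] - lo[keep]) / span[keep]
  d2 <- rowSums(sweep(Pn, 2, pn, `-`)^2)
  d <- sqrt(min(d2))
  if (flag_super_optimal &&
      all(vapply(seq_len(nrow(obj)), function(i)
        !dominates(obj[i, ], point, pareto$senses), logical(1))) &&
      any(vapply(seq_len(nrow(obj)), function(i)
        dominates(point, obj[i, ], pareto$senses), logical(1))))
    message("PDS: point dominates part of the front (super-optimal)")
  if (d < tol_pds) 0 else d
}

# MOMA with fallback: when the perturbed constraint set is empty, minimize
# the distance to the reference subject to the bounds only, with a heavy
# penalty on steady-state violation (nearest quasi-feasible point; logged).
moma_or_nearest <- function(network, reference_flux, penalty = 1e6) {
  fc <- moma_solve(network, reference_flux)
  if (fc$status == "optimal") return(fc)
  message("MOMA infeasible; scoring nearest bound-feasible point ",
          "(steady state penalized)")
  S <- network$stoichiometry
  rid <- colnames(S)
  ref <- flux_vector(reference_flux)[rid]
  nr <- length(rid)
  Dmat <- diag(nr) + penalty * crossprod(S)
  Amat <- rbind(diag(nr), -diag(nr))
  bvec <- c(network$reactions$lower_bound, -network$reactions$upper_bound)
  sol <- quadprog::solve.QP(Dmat = Dmat, dvec = ref, Amat = t(Amat),
                            bvec = bvec)
  v <- stats::setNames(sol$solution, rid)
  out <- new_flux_configuration(v, "quasi-feasible")
  out$objective_value <- sum((v - ref)^2)
  out
}

#' In-silico gene essentiality screen
#'
#' For every gene and cell line: knock the gene down, predict the
#' post-perturbation flux by MOMA from the line's representative Pareto
#' solution, evaluate the four objectives and score the deviation from the
#' Pareto surface. A gene with PDS 0 in all lines is nonessential; a gene
#' with non-zero PDS in at least one line is essential.
#'
#' @param pareto a `pareto_set` with fluxes.
#' @param network the generating `metabolic_network`.
#' @param cell_line_models list of [fit_cell_line()] results.
#' @param genes gene ids to screen (default: all model genes).
#' @param knock_fraction residual activity (0 = knockout).
#' @param weights [objective_weights()] or `NULL`.
#' @param tol_pds PDS clamping threshold.
#' @return list with `scores` (long data.frame: gene, cell_line, pds,
#'   status) and `essential` (data.frame: gene, n_lines_nonzero, essential).
#' @export
gene_essentiality_screen <- function(pareto, network, cell_line_models,
                                     genes = NULL, knock_fraction = 0,
                                     weights = NULL, tol_pds = 1e-6) {
  if (is.null(genes)) genes <- network$genes
  stopifnot(length(genes) > 0, length(cell_line_models) > 0)
  if (is.null(weights)) weights <- objective_weights(network)
  rows <- vector("list", length(genes) * length(cell_line_models))
  k <- 0L
  for (g in genes) {
    net_g <- apply_knockdown(network, g, knock_fraction)
    unchanged <- identical(net_g$reactions$lower_bound,
                           network$reactions$lower_bound) &&
      identical(net_g$reactions$upper_bound,
                network$reactions$upper_bound)
    for (m in cell_line_models) {
      k <- k + 1L
      ref <- solution_flux(pareto, m$representative)
      if (unchanged) {
        point <- pareto$objectives[m$representative, ]
        status <- "optimal"
      } else {
        fc <- suppressMessages(moma_or_nearest(net_g, ref))
        point <- evaluate_objectives(network, weights, fc)
        status <- fc$status
      }
      rows[[k]] <- data.frame(
        gene = g, cell_line = m$cell_line_id,
        pds = pds_score(point, pareto, tol_pds = tol_pds,
                        flag_super_optimal = FALSE),
        status = status, stringsAsFactors = FALSE)
    }
  }
  scores <- do.call(rbind, rows)
  n_quasi <- sum(scores$status != "optimal")
  if (n_quasi > 0)
    message(n_quasi, " of ", nrow(scores), " knockdowns left no feasible ",
            "steady state; scored at the nearest bound-feasible point")
  agg <- stats::aggregate(pds ~ gene, scores, function(x) sum(x > 0))
  names(agg)[2] <- "n_lines_nonzero"
  agg$essential <- agg$n_lines_nonzero > 0
  list(scores = scores, essential = agg[match(genes, agg$gene), ])
}

#' PDS of combinatorial perturbations
#'
#' Applies all knockdowns of each gene set jointly (a set of one reproduces
#' the single-gene screen entry) and scores the MOMA-predicted flux against
#' the Pareto surface, enabling single-versus-combination comparisons such
#' as joint inhibition of glycolysis and oxidative phosphorylation.
#'
#' @param pareto a `pareto_set` with fluxes.
#' @param network the generating `metabolic_network`.
#' @param cell_line_model one [fit_cell_line()] result.
#' @param gene_sets list of non-empty character vectors.
#' @param knock_fraction residual activity.
#' @param weights,tol_pds as in [gene_essentiality_screen()].
#' @return data.frame: genes (comma-joined), n_genes, pds, status.
#' @export
combinatorial_perturbation <- function(pareto, network, cell_line_model,
                                       gene_sets, knock_fraction = 0,
                                       weights = NULL, tol_pds = 1e-6) {
  stopifnot(length(gene_sets) > 0)
  if (any(vapply(gene_sets, length, integer(1)) == 0))
    stop("empty gene set")
  if (is.null(weights)) weights <- objective_weights(network)
  ref <- solution_flux(pareto, cell_line_model$representative)
  rows <- lapply(gene_sets, function(gs) {
    net_g <- apply_knockdown(network, gs, knock_fraction)
    fc <- moma_or_nearest(net_g, ref)
    point <- evaluate_objectives(network, weights, fc)
    data.frame(genes = paste(gs, collapse = ","), n_genes = length(gs),
               pds = pds_score(point, pareto, tol_pds = tol_pds,
                               flag_super_optimal = FALSE),
               status = fc$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
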