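#' Pareto dominance between objective vectors
#'
#' `a` dominates `b` when `a` is at least as good on every objective
#' (higher for maximized, lower for minimized) and strictly better on at
#' least one. Antisymmetric for distinct comparable points; a point never
#' dominates itself.
#'
#' @param a,b numeric objective vectors of equal length.
#' @param senses character vector of `"max"`/`"min"` per objective;
#'   defaults to the four-objective model's senses.
#' @return logical.
#' @export
dominates <- function(a, b, senses = objective_senses()) {
  stopifnot(length(a) == length(b), length(a) == length(senses))
  d <- ifelse(senses == "max", a - b, b - a)
  all(d >= 0) && any(d > 0)
}

#' Non-dominated subset of a point cloud
#'
#' Returns the indices of points not dominated by any other point. Points
#' equal within `tol` on all objectives are treated as duplicates of each
#' other and all retained; `tol` also pads the dominance comparison so that
#' solver noise below `tol` cannot knock out a genuinely efficient point.
#'
#' @param points numeric matrix (rows = points) or list of vectors.
#' @param senses `"max"`/`"min"` per column.
#' @param tol numerical tolerance on objective comparisons.
#' @return integer vector of retained row indices.
#' @export
pareto_filter <- function(points, senses = objective_senses(), tol = 0) {
  if (is.list(points) && !is.matrix(points))
    points <- do.call(rbind, points)
  points <- as.matrix(points)
  stopifnot(all(is.finite(points)))
  n <- nrow(points)
  if (n == 0) return(integer())
  sgn <- ifelse(senses == "max", 1, -1)
  P <- sweep(points, 2, sgn, `*`)   # now all maximized
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    d <- sweep(P, 2, P[i, ], `-`)
    dup <- rowSums(abs(d) <= tol) == ncol(P)
    dominated_by <- rowSums(d >= -tol) == ncol(P) & rowSums(d > tol) > 0 & !dup
    if (any(dominated_by)) keep[i] <- FALSE
  }
  which(keep)
}

#' Grid specification for epsilon-constraint sampling
#'
#' @param levels number of epsilon levels per constrained objective
#'   (scalar, recycled, or named by objective); at least 2.
#' @param ranges optional named list `objective -> c(lo, hi)` overriding the
#'   automatic ranges taken from the single-objective extreme solutions.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(levels = 10, ranges = NULL) {
  stopifnot(all(levels >= 2))
  structure(list(levels = levels, ranges = ranges), class = "grid_spec")
}

functional_constraint <- function(functional, dir, rhs) {
  flux_constraint(coefficients = functional$coefficients, dir = dir,
                  rhs = rhs, abs_coefficients = functional$abs_coefficients)
}

#' Lexicographic optimization over a sequence of objectives
#'
#' Optimizes the first objective, then, among solutions attaining its
#' optimum (within `tol_obj`), optimizes the next, and so on. Used to
#' resolve alternate optima of the epsilon-constraint LPs: secondary
#' minimization of enzyme cost drives futile cycles to zero and makes the
#' stored flux of each grid cell unique and reproducible.
#'
#' @param network a `metabolic_network`.
#' @param objective_order list of [linear_functional()]s or names into
#'   [build_objectives()] output.
#' @param extra_constraints list of [flux_constraint()]s active throughout.
#' @param weights [objective_weights()] used when objectives are named.
#' @param tol_obj slack kept on each fixed objective. The default is at the
#'   solver's feasibility scale so later stages cannot trade away more of an
#'   earlier optimum than numerical noise.
#' @return a `flux_configuration` (of the first infeasible stage if any).
#' @export
lexicographic_cleanup <- function(network, objective_order,
                                  extra_constraints = list(),
                                  weights = NULL, tol_obj = 1e-9) {
  if (is.character(objective_order)) {
    objs <- build_objectives(network, weights)
    objective_order <- objs[objective_order]
  }
  cons <- extra_constraints
  fc <- NULL
  for (obj in objective_order) {
    fc <- fba_solve(network, obj, cons)
    if (fc$status != "optimal") return(fc)
    z <- fc$objective_value
    cons <- c(cons, list(
      if (obj$sense == "maximize") functional_constraint(obj, ">=", z - tol_obj)
      else functional_constraint(obj, "<=", z + tol_obj)))
  }
  fc
}

#' Sample the Pareto surface by the epsilon-constraint method
#'
#' Transforms the four-objective problem into a grid of single-objective
#' LPs: one primary objective (biomass maximization by default) is optimized
#' subject to epsilon-constraints on the other three objectives, whose
#' levels run over a grid spanned by the single-objective extreme solutions.
#' Each LP is finished lexicographically (enzyme-cost minimization among
#' primary-optimal fluxes) so alternate optima resolve deterministically.
#' All resulting points are pooled with the extreme solutions and passed
#' through [pareto_filter()], which removes the weakly efficient artifacts
#' the epsilon-constraint method is known to emit.
#'
#' @param network a `metabolic_network`.
#' @param weights an [objective_weights()] or `NULL` for defaults.
#' @param grid a [grid_spec()].
#' @param primary name(s) of the scalarized objective. With more than one
#'   name the epsilon grid is solved once per primary objective and the
#'   solutions pooled: rotating the primary improves coverage of front
#'   facets that a single scalarization direction visits only at isolated
#'   grid points.
#' @param tol_obj objective-space tolerance (dominance padding).
#' @param dedup_tol relative flux-space tolerance below which two sampled
#'   solutions count as the same vertex and only one is stored. Adjacent
#'   grid cells whose epsilon-constraints are barely active at a shared
#'   facet produce solutions differing by far less than the grid
#'   resolution; such near-copies carry no information and inflate the set.
#' @return a `pareto_set`.
#' @export
epsilon_constraint_sample <- function(network, weights = NULL,
                                      grid = grid_spec(10),
                                      primary = "biomass", tol_obj = 1e-6,
                                      dedup_tol = 1e-3) {
  if (is.null(weights)) weights <- objective_weights(network)
  objs <- build_objectives(network, weights)
  stopifnot(all(primary %in% names(objs)))

  cleanup_order <- function(first)
    unique(c(first, "enzyme_cost", "carbon_uptake"))
  extremes <- lapply(names(objs), function(k)
    lexicographic_cleanup(network, cleanup_order(k), weights = weights))
  names(extremes) <- names(objs)
  ok <- vapply(extremes, function(f) f$status == "optimal", logical(1))
  if (!any(ok))
    stop("network admits no feasible flux: all extreme-point LPs failed")
  extremes <- extremes[ok]
  ext_pts <- t(vapply(extremes, function(f)
    evaluate_objectives(network, weights, f), numeric(4)))

  fluxes <- list()
  n_infeasible <- 0L
  eps_levels_all <- list()
  for (prim in primary) {
    constrained <- setdiff(names(objs), prim)
    levels <- grid$levels
    if (length(levels) == 1)
      levels <- stats::setNames(rep(levels, 3), constrained)
    eps_levels <- lapply(constrained, function(k) {
      rg <- if (!is.null(grid$ranges[[k]])) grid$ranges[[k]]
            else range(ext_pts[, k])
      seq(rg[1], rg[2], length.out = levels[[k]])
    })
    names(eps_levels) <- constrained
    eps_levels_all[[prim]] <- eps_levels
    cells <- expand.grid(eps_levels, KEEP.OUT.ATTRS = FALSE)
    for (i in seq_len(nrow(cells))) {
      cons <- lapply(constrained, function(k) {
        if (objective_senses()[[k]] == "max")
          functional_constraint(objs[[k]], ">=", cells[i, k])
        else functional_constraint(objs[[k]], "<=", cells[i, k])
      })
      fc <- lexicographic_cleanup(network, cleanup_order(prim),
                                  extra_constraints = cons,
                                  weights = weights)
      if (fc$status == "optimal") fluxes[[length(fluxes) + 1L]] <- fc$flux
      else n_infeasible <- n_infeasible + 1L
    }
  }
  fluxes <- c(fluxes, lapply(extremes, function(f) f$flux))
  if (!length(fluxes)) stop("epsilon-constraint sampling produced no solutions")
  Fm <- do.call(rbind, fluxes)
  rownames(Fm) <- NULL
  Fm <- unique(round(Fm, 9))                       # exact duplicate optima
  Fm <- dedup_rows(Fm, rel_tol = dedup_tol)        # near-duplicate vertices
  P <- t(apply(Fm, 1, function(v)
    evaluate_objectives(network, weights, v)))
  keep <- pareto_filter(P, tol = tol_obj)
  pareto_set(P[keep, , drop = FALSE], Fm[keep, , drop = FALSE],
             grid = list(levels = grid$levels, eps_levels = eps_levels_all,
                         primary = primary),
             n_infeasible = n_infeasible)
}

#' Construct a Pareto set
#'
#' Container for sampled Pareto-optimal solutions: the objective matrix,
#' the flux matrix, and the per-objective min-max normalization used by the
#' Pareto deviation score.
#'
#' @param objectives numeric matrix, solutions x objectives (columns named).
#' @param fluxes optional numeric matrix, solutions x reactions.
#' @param senses `"max"`/`"min"` per objective column.
#' @param grid,n_infeasible sampling provenance (kept in the manifest).
#' @return object of class `pareto_set`.
#' @export
pareto_set <- function(objectives, fluxes = NULL,
                       senses = objective_senses(),
                       grid = NULL, n_infeasible = 0L) {
  objectives <- as.matrix(objectives)
  if (is.null(colnames(objectives)) && length(senses) == ncol(objectives))
    colnames(objectives) <- names(senses)
  stopifnot(all(is.finite(objectives)))
  norm <- apply(objectives, 2, range)
  rownames(norm) <- c("min", "max")
  structure(list(objectives = objectives, fluxes = fluxes,
                 senses = senses, normalization = norm,
                 grid = grid, n_infeasible = n_infeasible),
            class = "pareto_set")
}

#' @export
print.pareto_set <- function(x, ...) {
  cat("pareto_set:", nrow(x$objectives), "solutions,",
      ncol(x$objectives), "objectives\n")
  print(x$normalization)
  invisible(x)
}

#' Number of solutions in a Pareto set
#' @param pareto a `pareto_set`.
#' @return integer.
#' @export
n_solutions <- function(pareto) nrow(pareto$objectives)

#' Solution flux of one Pareto set member
#' @param pareto a `pareto_set`.
#' @param i solution index.
#' @return named flux vector.
#' @export
solution_flux <- function(pareto, i) {
  stopifnot(!is.null(pareto$fluxes), i >= 1, i <= nrow(pareto$fluxes))
  pareto$fluxes[i, ]
}

#' Tolerant cross-front domination check
#'
#' For each point of `points`, reports whether some point of `by` dominates
#' it beyond numerical tolerance: at least as good on every objective up to
#' `tol`, and strictly better by more than `tol` on at least one. Used to
#' verify that two independently computed Pareto fronts describe the same
#' efficient surface.
#'
#' @param points,by numeric matrices (rows = objective vectors).
#' @param senses `"max"`/`"min"` per column.
#' @param tol tolerance.
#' @return logical vector, one entry per row of `points`.
#' @export
epsilon_dominated <- function(points, by, senses = objective_senses(),
                              tol = 1e-6) {
  points <- as.matrix(points); by <- as.matrix(by)
  sgn <- ifelse(senses == "max", 1, -1)
  P <- sweep(points, 2, sgn, `*`)
  B <- sweep(by, 2, sgn, `*`)
  vapply(seq_len(nrow(P)), function(i) {
    d <- sweep(B, 2, P[i, ], `-`)
    any(rowSums(d >= -tol) == ncol(B) & rowSums(d > tol) > 0)
  }, logical(1))
}

# Greedy deterministic removal of rows closer than rel_tol (relative
# Euclidean distance) to an already-kept row.
dedup_rows <- function(m, rel_tol) {
  if (nrow(m) <= 1 || rel_tol <= 0) return(m)
  keep <- 1L
  for (i in 2:nrow(m)) {
    d <- sqrt(rowSums((m[keep, , drop = FALSE] -
                         matrix(m[i, ], length(keep), ncol(m),
                                byrow = TRUE))^2))
    scale <- pmax(sqrt(rowSums(m[keep, , drop = FALSE]^2)),
                  sqrt(sum(m[i, ]^2)), 1)
    if (all(d > rel_tol * scale)) keep <- c(keep, i)
  }
  m[keep, , drop = FALSE]
}
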