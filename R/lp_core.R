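#' Linear functionals over flux space
#'
#' A named linear objective (or constraint left-hand side) over reaction
#' fluxes. `coefficients` act on the signed flux `v`; `abs_coefficients` act
#' on `|v|` and are realized exactly inside the LP by split variables
#' `v = v+ - v-`, `|v| = v+ + v-` (exact when the absolute-value term is
#' minimized or bounded above, which is the only way the package uses it).
#'
#' @param coefficients named numeric vector over reaction ids (signed flux).
#' @param sense `"maximize"` or `"minimize"`.
#' @param name label.
#' @param abs_coefficients named numeric vector over reaction ids applied to
#'   absolute fluxes (non-negative).
#' @return object of class `linear_functional`.
#' @export
linear_functional <- function(coefficients = numeric(),
                              sense = c("maximize", "minimize"),
                              name = "objective",
                              abs_coefficients = numeric()) {
  sense <- match.arg(sense)
  stopifnot(all(abs_coefficients >= 0))
  structure(list(coefficients = coefficients,
                 abs_coefficients = abs_coefficients,
                 sense = sense, name = name),
            class = "linear_functional")
}

#' @export
print.linear_functional <- function(x, ...) {
  cat("linear_functional '", x$name, "' (", x$sense, "): ",
      length(x$coefficients), " signed + ", length(x$abs_coefficients),
      " absolute terms\n", sep = "")
  invisible(x)
}

#' Evaluate a linear functional on a flux vector
#' @param functional a `linear_functional`.
#' @param flux named flux vector or `flux_configuration`.
#' @return numeric value.
#' @export
evaluate_functional <- function(functional, flux) {
  v <- flux_vector(flux)
  val <- 0
  if (length(functional$coefficients))
    val <- val + sum(functional$coefficients * v[names(functional$coefficients)])
  if (length(functional$abs_coefficients))
    val <- val + sum(functional$abs_coefficients *
                       abs(v[names(functional$abs_coefficients)]))
  val
}

#' A linear constraint over fluxes
#' @param coefficients named numeric over reaction ids (signed flux part).
#' @param dir one of `"<="`, `">="`, `"="`.
#' @param rhs right-hand side.
#' @param abs_coefficients named numeric over reaction ids applied to `|v|`
#'   (upper-bounding constraints on absolute flux are exact; see
#'   [linear_functional()]).
#' @return object of class `flux_constraint`.
#' @export
flux_constraint <- function(coefficients = numeric(), dir, rhs,
                            abs_coefficients = numeric()) {
  stopifnot(dir %in% c("<=", ">=", "="))
  structure(list(coefficients = coefficients,
                 abs_coefficients = abs_coefficients, dir = dir, rhs = rhs),
            class = "flux_constraint")
}

flux_vector <- function(flux) {
  if (inherits(flux, "flux_configuration")) flux$flux else flux
}

new_flux_configuration <- function(flux, status, objective_value = NA_real_) {
  structure(list(flux = flux, status = status,
                 objective_value = objective_value),
            class = "flux_configuration")
}

#' @export
print.flux_configuration <- function(x, ...) {
  cat("flux_configuration (", x$status, "), ", length(x$flux),
      " reactions, objective ", format(x$objective_value), "\n", sep = "")
  invisible(x)
}

# Build the split-variable LP skeleton shared by fba_solve and the sampler.
# Variables: x = [v+; v-] >= 0, v = v+ - v-.
# Rows: S v = 0; v <= ub; v >= lb; v+ <= max(ub,0); v- <= max(-lb,0); extras.
lp_skeleton <- function(network, extra_constraints = list()) {
  S <- network$stoichiometry
  nr <- ncol(S)
  rid <- colnames(S)
  lb <- network$reactions$lower_bound
  ub <- network$reactions$upper_bound
  Ieq <- cbind(S, -S)
  A <- rbind(Ieq,
             cbind(diag(nr), -diag(nr)),   # v <= ub
             cbind(-diag(nr), diag(nr)),   # -v <= -lb
             cbind(diag(nr), matrix(0, nr, nr)),   # v+ caps
             cbind(matrix(0, nr, nr), diag(nr)))   # v- caps
  b <- c(rep(0, nrow(S)), ub, -lb, pmax(ub, 0), pmax(-lb, 0))
  dir <- c(rep("=", nrow(S)), rep("<=", 4 * nr))
  for (ct in extra_constraints) {
    row <- numeric(2 * nr)
    if (length(ct$coefficients)) {
      idx <- match(names(ct$coefficients), rid)
      if (anyNA(idx))
        stop("constraint references unknown reaction(s): ",
             paste(names(ct$coefficients)[is.na(idx)], collapse = ", "))
      row[idx] <- row[idx] + ct$coefficients
      row[nr + idx] <- row[nr + idx] - ct$coefficients
    }
    if (length(ct$abs_coefficients)) {
      idx <- match(names(ct$abs_coefficients), rid)
      if (anyNA(idx))
        stop("constraint references unknown reaction(s): ",
             paste(names(ct$abs_coefficients)[is.na(idx)], collapse = ", "))
      row[idx] <- row[idx] + ct$abs_coefficients
      row[nr + idx] <- row[nr + idx] + ct$abs_coefficients
    }
    A <- rbind(A, row)
    b <- c(b, ct$rhs)
    dir <- c(dir, ct$dir)
  }
  list(A = A, b = b, dir = dir, nr = nr, rid = rid)
}

functional_lp_cost <- function(functional, nr, rid) {
  cc <- numeric(2 * nr)
  if (length(functional$coefficients)) {
    idx <- match(names(functional$coefficients), rid)
    if (anyNA(idx))
      stop("objective references unknown reaction(s): ",
           paste(names(functional$coefficients)[is.na(idx)], collapse = ", "))
    cc[idx] <- cc[idx] + functional$coefficients
    cc[nr + idx] <- cc[nr + idx] - functional$coefficients
  }
  if (length(functional$abs_coefficients)) {
    idx <- match(names(functional$abs_coefficients), rid)
    cc[idx] <- cc[idx] + functional$abs_coefficients
    cc[nr + idx] <- cc[nr + idx] + functional$abs_coefficients
  }
  if (functional$sense == "minimize") -cc else cc
}

#' Flux balance analysis
#'
#' Optimizes a linear functional of fluxes subject to the steady-state
#' constraint `S v = 0`, the reaction bounds, and optional extra linear
#' constraints, the standard FBA formulation. Reversible fluxes stay signed;
#' absolute-flux terms (enzyme cost) are linearized by split variables.
#'
#' @param network a `metabolic_network`.
#' @param objective a [linear_functional()].
#' @param extra_constraints list of [flux_constraint()]s.
#' @param tol_feas feasibility tolerance for the returned flux.
#' @return a `flux_configuration` with `status` `"optimal"`, `"infeasible"`
#'   or `"unbounded"`; the objective value is re-evaluated from the returned
#'   flux (see `evaluate_functional`), so it always matches the flux exactly.
#' @export
fba_solve <- function(network, objective, extra_constraints = list(),
                      tol_feas = 1e-9) {
  sk <- lp_skeleton(network, extra_constraints)
  cc <- functional_lp_cost(objective, sk$nr, sk$rid)
  sol <- simplex_solve(cc, sk$A, sk$b, sk$dir)
  if (sol$status != "optimal")
    return(new_flux_configuration(
      stats::setNames(rep(NA_real_, sk$nr), sk$rid), sol$status))
  v <- sol$x[seq_len(sk$nr)] - sol$x[sk$nr + seq_len(sk$nr)]
  names(v) <- sk$rid
  fc <- new_flux_configuration(v, "optimal")
  fc$objective_value <- evaluate_functional(objective, fc)
  fc
}

#' Minimization of metabolic adjustment (MOMA)
#'
#' Predicts the flux configuration after a perturbation as the feasible flux
#' closest (in squared Euclidean distance) to a reference flux: minimize
#' `sum_i (v_i - v_i_ref)^2` subject to `S v = 0` and the (possibly
#' perturbed) bounds. The rationale is that regulation does not instantly
#' re-optimize after a perturbation, so the cell's fluxes stay as close as
#' possible to the pre-perturbation state.
#'
#' Solved with the dual active-set method of Goldfarb and Idnani
#' (`quadprog`); the objective is strictly convex, so the minimizer is
#' unique and deterministic.
#'
#' @param network a `metabolic_network` (perturbed bounds included).
#' @param reference_flux named flux vector or `flux_configuration` covering
#'   all reactions of `network`.
#' @param extra_constraints list of signed-flux [flux_constraint()]s
#'   (absolute-value terms are not supported in the QP).
#' @return a `flux_configuration`; `objective_value` is the squared
#'   Euclidean distance to the reference, and `status` is `"infeasible"`
#'   when the constraint set is empty.
#' @export
moma_solve <- function(network, reference_flux, extra_constraints = list()) {
  ref <- flux_vector(reference_flux)
  S <- network$stoichiometry
  rid <- colnames(S)
  if (!all(rid %in% names(ref)))
    stop("reference flux does not cover all reactions")
  ref <- ref[rid]
  nr <- length(rid)
  lb <- network$reactions$lower_bound
  ub <- network$reactions$upper_bound
  Amat <- rbind(S, diag(nr), -diag(nr))
  bvec <- c(rep(0, nrow(S)), lb, -ub)
  meq <- nrow(S)
  for (ct in extra_constraints) {
    if (length(ct$abs_coefficients))
      stop("absolute-flux constraints are not supported in moma_solve")
    row <- numeric(nr)
    row[match(names(ct$coefficients), rid)] <- ct$coefficients
    if (ct$dir == "=") { Amat <- rbind(Amat[seq_len(meq), , drop = FALSE], row,
                                       Amat[-seq_len(meq), , drop = FALSE])
                         bvec <- c(bvec[seq_len(meq)], ct$rhs, bvec[-seq_len(meq)])
                         meq <- meq + 1
    } else if (ct$dir == ">=") { Amat <- rbind(Amat, row); bvec <- c(bvec, ct$rhs)
    } else { Amat <- rbind(Amat, -row); bvec <- c(bvec, -ct$rhs) }
  }
  sol <- tryCatch(
    quadprog::solve.QP(Dmat = diag(nr), dvec = ref, Amat = t(Amat),
                       bvec = bvec, meq = meq),
    error = function(e) NULL)
  if (is.null(sol))
    return(new_flux_configuration(
      stats::setNames(rep(NA_real_, nr), rid), "infeasible"))
  v <- stats::setNames(sol$solution, rid)
  # snap to bounds within numerical noise
  v <- pmin(pmax(v, lb - 1e-9), ub + 1e-9)
  fc <- new_flux_configuration(v, "optimal")
  fc$objective_value <- sum((v - ref)^2)
  fc
}

#' Check steady-state feasibility of a flux vector
#' @param network a `metabolic_network`.
#' @param flux named flux vector or `flux_configuration`.
#' @param tol_feas tolerance on `S v = 0` and bounds.
#' @return logical.
#' @export
is_feasible_flux <- function(network, flux, tol_feas = 1e-9) {
  v <- flux_vector(flux)[colnames(network$stoichiometry)]
  scale <- max(1, max(abs(v)))
  all(abs(network$stoichiometry %*% v) <= tol_feas * scale) &&
    all(v >= network$reactions$lower_bound - tol_feas * scale) &&
    all(v <= network$reactions$upper_bound + tol_feas * scale)
}
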