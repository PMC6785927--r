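#' Benchmark metabolic networks with known trade-off structure
#'
#' Generates small networks whose Pareto fronts are analytically
#' understood, so every pipeline stage can be verified against enumeration:
#'
#' \describe{
#'   \item{chain-net}{a single linear route producing biomass and ATP in
#'     fixed proportion: one flux degree of freedom, no trade-off; the
#'     front collapses to one efficient ray.}
#'   \item{Y-net}{one substrate split between a biomass path (yield 1) and a
#'     two-step ATP path (yield 2 ATP per substrate): the minimal
#'     biomass/ATP trade-off.}
#'   \item{parallel-net}{Y-net plus a redundant duplicate of the first ATP
#'     path step and a gene-bearing overflow (waste) route; single knockouts
#'     of either duplicate are rescued, the double knockout forces wasteful
#'     rerouting off the Pareto surface.}
#'   \item{ferm-resp-net}{glucose fermented to lactate (fast, 2 ATP/glucose,
#'     enzymatically cheap) versus respired to CO2 (32 ATP/glucose, but the
#'     respiratory chain carries a high enzyme weight), with biomass
#'     synthesis drawing pyruvate and ATP: guarantees a growth-Warburg
#'     trade-off in which fermentation is cost-efficient and respiration
#'     carbon-efficient per ATP.}
#'   \item{random-net}{random sparse stoichiometry over internal metabolites
#'     plus exchange reactions, resampled until validation passes.}
#' }
#'
#' Exchanged metabolites carry real elemental formulas (glucose `C6H12O6`,
#' lactate `C3H6O3`, `O2`, `CO2`) so the carbon-uptake objective is
#' non-trivial and carbon balance is checkable.
#'
#' @param name fixture name (see above).
#' @param uptake_bound glucose uptake capacity (mmol/gDW/h), default 10.
#' @param bound_scale generic bound for unconstrained internal fluxes.
#' @param n_mets,n_rxns,seed,max_tries random-net parameters.
#' @return a validated `metabolic_network`.
#' @export
make_fixture <- function(name = c("Y-net", "chain-net", "parallel-net",
                                  "ferm-resp-net", "random-net"),
                         uptake_bound = 10, bound_scale = 1000,
                         n_mets = 6, n_rxns = 12, seed = 1, max_tries = 50) {
  name <- match.arg(name)
  B <- bound_scale
  rxn <- function(id, eq, lb, ub, gpr = "", w = NA_real_)
    data.frame(reaction = id, equation = eq, lower_bound = lb,
               upper_bound = ub, gpr = gpr, enzyme_weight = w,
               stringsAsFactors = FALSE)
  build <- function(rx, mets) {
    eqs <- lapply(rx$equation, parse_equation)
    met_ids <- sort(unique(unlist(lapply(eqs, names))))
    S <- matrix(0, length(met_ids), nrow(rx),
                dimnames = list(met_ids, rx$reaction))
    for (i in seq_along(eqs)) S[names(eqs[[i]]), i] <- eqs[[i]]
    mt <- data.frame(id = met_ids, stringsAsFactors = FALSE)
    idx <- match(mt$id, mets$id)
    mt$formula <- ifelse(is.na(idx), "", mets$formula[idx])
    mt$compartment <- ifelse(grepl("_e$", mt$id), "e", "c")
    reactions <- data.frame(id = rx$reaction, lower_bound = rx$lower_bound,
                            upper_bound = rx$upper_bound, gpr = rx$gpr,
                            enzyme_weight = rx$enzyme_weight,
                            stringsAsFactors = FALSE)
    nnz <- colSums(S != 0)
    reactions$is_exchange <- grepl("^EX_", reactions$id) & nnz == 1
    metabolic_network(mt, reactions, S)
  }
  formulas <- data.frame(
    id = c("glc_e", "lac_e", "o2_e", "co2_e", "waste_e"),
    formula = c("C6H12O6", "C3H6O3", "O2", "CO2", "C6H12O6"),
    stringsAsFactors = FALSE)

  if (name == "chain-net") {
    rx <- rbind(
      rxn("EX_glc", "glc_e -> ", -uptake_bound, 0),
      rxn("GLY", "glc_e -> pyr + 2 atp", 0, B, "g1"),
      rxn("BIOMASS", "pyr -> ", 0, B, "gB"),
      rxn("ATPM", "atp -> ", 0, B))
    return(build(rx, formulas))
  }
  if (name == "Y-net") {
    rx <- rbind(
      rxn("EX_glc", "glc_e -> ", -uptake_bound, 0),
      rxn("BIOMASS", "glc_e -> ", 0, B, "gB"),
      rxn("CAT1", "glc_e -> pyr", 0, B, "gA1"),
      rxn("CAT2", "pyr -> 2 atp", 0, B, "gA2"),
      rxn("ATPM", "atp -> ", 0, B))
    return(build(rx, formulas))
  }
  if (name == "parallel-net") {
    rx <- rbind(
      rxn("EX_glc", "glc_e -> ", -uptake_bound, 0),
      rxn("BIOMASS", "glc_e -> ", 0, B, "gB"),
      rxn("CAT1A", "glc_e -> pyr", 0, B, "gA1"),
      rxn("CAT1B", "glc_e -> pyr", 0, B, "gA1b"),
      rxn("CAT2", "pyr -> 2 atp", 0, B, "gA2"),
      rxn("ATPM", "atp -> ", 0, B),
      rxn("WASTE", "glc_e -> waste_e", 0, B, "gW"),
      rxn("EX_waste", "waste_e -> ", 0, B))
    return(build(rx, formulas))
  }
  if (name == "ferm-resp-net") {
    # Respiration is enzymatically expensive per unit flux (solvent-capacity
    # argument) and capacity-limited (mitochondrial vmax just below the
    # ATP-optimal respiration rate of a maximally growing cell), biomass is
    # ATP-hungry, and a maintenance ATP demand keeps fully scaled-down flux
    # states infeasible. Together these give fermentation the cost
    # advantage per ATP, respiration the carbon advantage, and place
    # fast-growing flux states on the respiratory capacity boundary.
    rx <- rbind(
      rxn("EX_glc", "glc_e -> ", -uptake_bound, 0),
      rxn("EX_o2", "o2_e -> ", -2 * uptake_bound, 0),
      rxn("EX_lac", "lac_e -> ", 0, B),
      rxn("EX_co2", "co2_e -> ", 0, B),
      rxn("GLUT", "glc_e -> glc_c", 0, B, "gGLUT"),
      rxn("GLY1", "glc_c -> 2 g3p", 0, B, "gGLY1"),
      rxn("GLY2", "g3p -> pyr + atp", 0, B, "gGLY2"),
      rxn("LDH", "pyr -> lac_c", 0, B, "gLDH"),
      rxn("MCT", "lac_c -> lac_e", 0, B, "gMCT"),
      rxn("O2T", "o2_e -> o2_c", 0, B, "gO2T"),
      rxn("TCA", "pyr -> 3 co2_c + 5 nadh", 0, 0.7 * uptake_bound,
          "gTCA", w = 2),
      rxn("ETC", "nadh + 0.5 o2_c -> 3 atp", 0, B, "gETC", w = 16),
      rxn("CO2T", "co2_c -> co2_e", 0, B, "gCO2T"),
      rxn("ANA", "pyr + 9 atp -> prec", 0, B, "gANA"),
      rxn("BIOMASS", "prec -> ", 0, B),
      rxn("ATPM", "atp -> ", uptake_bound, B))
    return(build(rx, formulas))
  }
  # random-net
  for (try in seq_len(max_tries)) {
    net <- local_seed(seed + try - 1L, {
      ids <- paste0("m", seq_len(n_mets))
      rows <- list(
        rxn("EX_glc", "glc_e -> ", -uptake_bound, 0),
        rxn("UPT", paste("glc_e ->", ids[1]), 0, B, "gU"),
        rxn("BIOMASS", paste(ids[n_mets], "-> "), 0, B, "gB"),
        rxn("SYN", paste(ids[1], "-> atp"), 0, B, "gS"),
        rxn("ATPM", "atp -> ", 0, B))
      for (j in seq_len(max(0, n_rxns - 5))) {
        from <- sample(n_mets - 1, 1)
        to <- sample((from + 1):n_mets, 1)
        cf <- sample(1:2, 2, replace = TRUE)
        rows[[length(rows) + 1]] <- rxn(
          paste0("R", j),
          paste(cf[1], ids[from], "->", cf[2], ids[to]),
          0, B, paste0("g", j))
      }
      tryCatch(build(do.call(rbind, rows), formulas),
               error = function(e) NULL)
    })
    if (!is.null(net) && length(validate_network(net)) == 0) return(net)
  }
  stop("random-net generation failed after ", max_tries, " tries")
}

#' Enumerate the Pareto front by brute force
#'
#' Oracle for [epsilon_constraint_sample()]: parametrizes the steady-state
#' flux space by a null-space basis of the stoichiometric matrix, bounds
#' each null-space coordinate by LP, enumerates a regular grid over the
#' coordinate box, keeps the grid points whose fluxes satisfy all bounds,
#' evaluates the four objectives and applies [pareto_filter()]. Exponential
#' in the degrees of freedom; refuses more than `max_dof`.
#'
#' @param network a `metabolic_network`.
#' @param flux_grid_step grid step in flux units (applied to each
#'   null-space coordinate).
#' @param weights an [objective_weights()] or `NULL`.
#' @param max_dof refusal threshold on flux degrees of freedom.
#' @param tol bound tolerance for keeping a grid point.
#' @return a `pareto_set`.
#' @export
brute_force_pareto <- function(network, flux_grid_step = 0.5, weights = NULL,
                               max_dof = 4, tol = 1e-9) {
  if (is.null(weights)) weights <- objective_weights(network)
  S <- network$stoichiometry
  V <- null_space(S)
  d <- ncol(V)
  if (d == 0) stop("network has no flux degrees of freedom")
  if (d > max_dof)
    stop("brute-force enumeration refused: ", d,
         " degrees of freedom exceeds max_dof = ", max_dof)
  rid <- colnames(S)
  # bound each coordinate via LP on z: lb <= V z <= ub
  zbox <- vapply(seq_len(d), function(k) {
    c(lp_over_nullspace(network, V, k, maximize = FALSE),
      lp_over_nullspace(network, V, k, maximize = TRUE))
  }, numeric(2))
  grids <- lapply(seq_len(d), function(k) {
    lo <- zbox[1, k]; hi <- zbox[2, k]
    if (hi - lo < flux_grid_step) c(lo, hi)
    else seq(lo, hi, by = flux_grid_step)
  })
  Z <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  Fm <- Z %*% t(V)                         # candidate fluxes, rows
  colnames(Fm) <- rid
  lb <- network$reactions$lower_bound
  ub <- network$reactions$upper_bound
  ok <- apply(Fm, 1, function(v) all(v >= lb - tol) && all(v <= ub + tol))
  Fm <- Fm[ok, , drop = FALSE]
  if (!nrow(Fm)) stop("no feasible grid point found")
  P <- t(apply(Fm, 1, function(v) evaluate_objectives(network, weights, v)))
  keep <- pareto_filter(P, tol = 1e-9)
  pareto_set(P[keep, , drop = FALSE], Fm[keep, , drop = FALSE],
             grid = list(flux_grid_step = flux_grid_step, dof = d))
}

null_space <- function(S) {
  qr_t <- qr(t(S))
  R <- ncol(S)
  rank <- qr_t$rank
  if (rank == R) return(matrix(0, R, 0))
  Q <- qr.Q(qr_t, complete = TRUE)
  V <- Q[, (rank + 1):R, drop = FALSE]
  round(V, 12)
}

lp_over_nullspace <- function(network, V, k, maximize) {
  # optimize z_k subject to lb <= V z <= ub, z free (split variables)
  nr <- nrow(V); d <- ncol(V)
  A <- rbind(cbind(V, -V), cbind(-V, V))
  b <- c(network$reactions$upper_bound, -network$reactions$lower_bound)
  dir <- rep("<=", 2 * nr)
  cc <- numeric(2 * d); cc[k] <- 1; cc[d + k] <- -1
  if (!maximize) cc <- -cc
  sol <- simplex_solve(cc, A, b, dir)
  if (sol$status != "optimal")
    stop("null-space coordinate LP not optimal: ", sol$status)
  z <- sol$x[seq_len(d)] - sol$x[d + seq_len(d)]
  z[k]
}

#' Generate a synthetic omics panel with ground truth
#'
#' Emulates the two omics inputs of the cell-line fitting stage for a panel
#' of synthetic cell lines. For each line a generating Pareto solution is
#' drawn (by default uniformly from the more proliferative half of the
#' front, ranked by biomass flux, emulating a cancer cell panel), and the
#' line's profile is the solution's gene-level flux engagement under
#' multiplicative log-normal noise (protein abundances are positive) plus
#' its exchange fluxes under additive Gaussian noise scaled per metabolite.
#'
#' @param pareto a `pareto_set` with fluxes.
#' @param network the `metabolic_network` that produced it.
#' @param n_lines number of cell lines.
#' @param noise_sigma noise level relative to feature scale.
#' @param seed integer seed; regeneration with the same seed is identical.
#' @param bias `"proliferative"` (top half by biomass) or `"uniform"`.
#' @return object of class `synthetic_panel`: list with `profiles` (list of
#'   [omics_profile()]), `ground_truth` (data.frame of line, generating
#'   solution index and true objectives), `noise_sigma`, `seed`.
#' @export
make_synthetic_panel <- function(pareto, network, n_lines = 20,
                                 noise_sigma = 0.05, seed = 1,
                                 bias = c("proliferative", "uniform")) {
  bias <- match.arg(bias)
  stopifnot(n_solutions(pareto) > 0, !is.null(pareto$fluxes))
  feats <- pareto_features(pareto, network)        # genes x N
  exch <- pareto_exchange(pareto, network)         # metabolites x N
  biomass <- pareto$objectives[, "biomass"]
  pool <- if (bias == "proliferative")
    which(rank(biomass, ties.method = "first") > n_solutions(pareto) / 2)
  else seq_len(n_solutions(pareto))
  ex_scale <- apply(exch, 1, function(x) max(diff(range(x)), max(abs(x)), 1e-6))

  local_seed(seed, {
    idx <- sample(pool, n_lines, replace = TRUE)
    profiles <- vector("list", n_lines)
    for (i in seq_len(n_lines)) {
      f <- feats[, idx[i]]
      ab <- f * exp(stats::rnorm(length(f), 0, noise_sigma))
      ex <- exch[, idx[i]] +
        stats::rnorm(nrow(exch), 0, noise_sigma * ex_scale)
      profiles[[i]] <- omics_profile(
        cell_line_id = sprintf("line%03d", i),
        enzyme_abundance = ab, exchange_flux = ex)
    }
    gt <- data.frame(cell_line_id = sprintf("line%03d", seq_len(n_lines)),
                     solution = idx, stringsAsFactors = FALSE)
    gt <- cbind(gt, pareto$objectives[idx, , drop = FALSE])
    structure(list(profiles = profiles, ground_truth = gt,
                   noise_sigma = noise_sigma, seed = seed),
              class = "synthetic_panel")
  })
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat("synthetic_panel:", length(x$profiles), "cell lines, sigma =",
      x$noise_sigma, ", seed =", x$seed, "\n")
  invisible(x)
}

# Evaluate an expression under a local RNG seed without touching the
# caller's RNG state.
local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
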