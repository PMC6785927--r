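#' Construct a metabolic network
#'
#' The central container of the package: a stoichiometric matrix with flux
#' bounds, gene-protein-reaction (GPR) rules, metabolite annotations and the
#' identities of the biomass and ATP-hydrolysis reactions. All linear and
#' quadratic programs of the package are built from this object.
#'
#' @param metabolites data.frame with columns `id`, and optionally `name`,
#'   `compartment`, `formula`, `is_extracellular`. Missing optional columns
#'   are filled with defaults (empty formula, compartment `"c"`).
#' @param reactions data.frame with columns `id`, `lower_bound`,
#'   `upper_bound`, and optionally `gpr` (boolean expression over gene ids
#'   with `and`/`or`/parentheses), `is_exchange`, `enzyme_weight`.
#' @param stoichiometry numeric matrix, metabolites x reactions, with
#'   dimnames matching the two tables.
#' @param biomass_reaction_id,atp_reaction_id reaction ids of the biomass
#'   and ATP-hydrolysis (maintenance) reactions. If `NULL` they are
#'   auto-detected: a reaction id matching `biomass` (case-insensitive) and
#'   one matching `ATPM`, `DM_atp` or `atp_hydrolysis`/`atp_maint`.
#' @param validate run [validate_network()] and stop on violations.
#' @return object of class `metabolic_network`.
#' @export
metabolic_network <- function(metabolites, reactions, stoichiometry,
                              biomass_reaction_id = NULL,
                              atp_reaction_id = NULL,
                              validate = TRUE) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment))
    metabolites$compartment <- ifelse(grepl("_e$|\\[e\\]$", metabolites$id), "e", "c")
  if (is.null(metabolites$formula)) metabolites$formula <- ""
  metabolites$formula[is.na(metabolites$formula)] <- ""
  if (is.null(metabolites$is_extracellular))
    metabolites$is_extracellular <- metabolites$compartment == "e"
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (is.null(reactions$is_exchange))
    reactions$is_exchange <- grepl("^EX_", reactions$id)
  if (is.null(reactions$enzyme_weight)) reactions$enzyme_weight <- NA_real_
  stoichiometry <- as.matrix(stoichiometry)
  rownames(stoichiometry) <- metabolites$id
  colnames(stoichiometry) <- reactions$id

  gpr_ast <- lapply(reactions$gpr, parse_gpr)
  names(gpr_ast) <- reactions$id
  genes <- sort(unique(unlist(lapply(gpr_ast, gpr_genes))))

  if (is.null(biomass_reaction_id)) {
    hit <- grep("biomass", reactions$id, ignore.case = TRUE, value = TRUE)
    if (length(hit) >= 1) biomass_reaction_id <- hit[1]
  }
  if (is.null(atp_reaction_id)) {
    hit <- grep("^ATPM$|^DM_atp|atp_hydrolysis|atp_maint", reactions$id,
                ignore.case = TRUE, value = TRUE)
    if (length(hit) >= 1) atp_reaction_id <- hit[1]
  }
  net <- structure(list(
    metabolites = metabolites,
    reactions = reactions,
    stoichiometry = stoichiometry,
    genes = genes,
    gpr_ast = gpr_ast,
    biomass_reaction_id = biomass_reaction_id,
    atp_reaction_id = atp_reaction_id
  ), class = "metabolic_network")
  if (validate) {
    problems <- validate_network(net)
    if (length(problems))
      stop("invalid metabolic network:\n  ", paste(problems, collapse = "\n  "))
  }
  net
}

#' Validate a metabolic network
#'
#' Checks the structural invariants: unique ids, bound ordering
#' (`lower_bound <= upper_bound`), stoichiometry referencing declared
#' metabolites, exchange reactions touching exactly one metabolite,
#' resolvable biomass/ATP reaction ids, and parseable formulas.
#'
#' @param network a `metabolic_network`.
#' @return character vector of problems (empty when valid).
#' @export
validate_network <- function(network) {
  p <- character()
  met <- network$metabolites; rxn <- network$reactions
  if (anyDuplicated(met$id)) p <- c(p, "duplicated metabolite ids")
  if (anyDuplicated(rxn$id)) p <- c(p, "duplicated reaction ids")
  bad <- rxn$id[rxn$lower_bound > rxn$upper_bound]
  if (length(bad))
    p <- c(p, paste0("lower_bound > upper_bound in reaction(s): ",
                     paste(bad, collapse = ", ")))
  if (!identical(rownames(network$stoichiometry), met$id))
    p <- c(p, "stoichiometry rows do not match metabolite table")
  if (!identical(colnames(network$stoichiometry), rxn$id))
    p <- c(p, "stoichiometry columns do not match reaction table")
  nnz <- colSums(network$stoichiometry != 0)
  empty <- rxn$id[nnz == 0]
  if (length(empty))
    p <- c(p, paste0("empty stoichiometry in reaction(s): ",
                     paste(empty, collapse = ", ")))
  bad_ex <- rxn$id[rxn$is_exchange & nnz != 1]
  if (length(bad_ex))
    p <- c(p, paste0("exchange reaction(s) touching != 1 metabolite: ",
                     paste(bad_ex, collapse = ", ")))
  if (is.null(network$biomass_reaction_id) ||
      !network$biomass_reaction_id %in% rxn$id)
    p <- c(p, "biomass reaction id does not resolve")
  if (is.null(network$atp_reaction_id) ||
      !network$atp_reaction_id %in% rxn$id)
    p <- c(p, "ATP-hydrolysis reaction id does not resolve")
  for (i in seq_len(nrow(met))) {
    f <- met$formula[i]
    if (nzchar(f)) {
      ok <- tryCatch({ parse_formula(f); TRUE }, error = function(e) FALSE)
      if (!ok) p <- c(p, paste0("malformed formula for metabolite ", met$id[i]))
    }
  }
  p
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("metabolic_network:", nrow(x$metabolites), "metabolites,",
      nrow(x$reactions), "reactions,", length(x$genes), "genes\n")
  cat("  biomass:", x$biomass_reaction_id,
      " atp hydrolysis:", x$atp_reaction_id, "\n")
  invisible(x)
}

# ---- GPR rules ---------------------------------------------------------

#' Parse a gene-protein-reaction rule
#'
#' Parses a boolean expression over gene ids (`and`, `or`, parentheses;
#' case-insensitive operators) into an expression tree. The empty string
#' parses to `NULL` (no gene association).
#'
#' @param text GPR string, e.g. `"(g1 and g2) or g3"`.
#' @return `NULL`, a gene id (leaf), or `list(op =, args = list(...))`.
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- regmatches(text, gregexpr("\\(|\\)|[^()[:space:]]+", text))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_or <- function() {
    left <- parse_and()
    args <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1) left else list(op = "or", args = args)
  }
  parse_and <- function() {
    left <- parse_atom()
    args <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      args <- c(args, list(parse_atom()))
    }
    if (length(args) == 1) left else list(op = "and", args = args)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) stop("GPR parse error: unexpected end in '", text, "'")
    if (t == "(") {
      advance()
      e <- parse_or()
      if (is.na(peek()) || peek() != ")")
        stop("GPR parse error: missing ')' in '", text, "'")
      advance()
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      stop("GPR parse error: unexpected '", t, "' in '", text, "'")
    advance()
  }
  out <- parse_or()
  if (!is.na(peek()))
    stop("GPR parse error: trailing tokens in '", text, "'")
  out
}

#' Genes referenced by a GPR tree
#' @param gpr parsed GPR (see [parse_gpr()]) or a GPR string.
#' @return character vector of gene ids (may be empty).
#' @export
gpr_genes <- function(gpr) {
  if (is.character(gpr) && length(gpr) == 1 && !is.list(gpr) &&
      grepl("[()[:space:]]", gpr)) gpr <- parse_gpr(gpr)
  if (is.null(gpr)) return(character())
  if (is.character(gpr)) return(gpr)
  unique(unlist(lapply(gpr$args, gpr_genes)))
}

#' Evaluate a GPR rule on quantitative gene activities
#'
#' Quantitative semantics for enzyme availability: `and` nodes (enzyme
#' complexes, all subunits required) combine by the minimum of their
#' arguments; `or` nodes (isozymes, either suffices) combine by the maximum.
#' An empty rule evaluates to 1 (reaction not gene-associated, never
#' restricted). The result is monotone non-decreasing in every gene's
#' activity.
#'
#' @param gpr parsed GPR tree, GPR string, or `NULL`.
#' @param gene_activity named numeric vector of activities in `[0, 1]`.
#' @param and_fun,or_fun combination rules, configurable; defaults `min`/`max`.
#' @return activity in `[0, 1]`.
#' @export
#' @examples
#' evaluate_gpr("g1 and g2", c(g1 = 0, g2 = 1))        # 0
#' evaluate_gpr("g1 or g2", c(g1 = 0, g2 = 1))         # 1
#' evaluate_gpr("(g1 and g2) or g3", c(g1 = 1, g2 = 0.5, g3 = 0.2))  # 0.5
evaluate_gpr <- function(gpr, gene_activity, and_fun = min, or_fun = max) {
  if (is.character(gpr) && length(gpr) == 1) gpr <- parse_gpr(gpr)
  if (is.null(gpr)) return(1)
  ev <- function(node) {
    if (is.character(node)) {
      if (!node %in% names(gene_activity))
        stop("unknown gene id in GPR: ", node)
      return(gene_activity[[node]])
    }
    vals <- vapply(node$args, ev, numeric(1))
    if (node$op == "and") and_fun(vals) else or_fun(vals)
  }
  ev(gpr)
}

#' Count distinct GPR-referenced genes
#'
#' Number of distinct gene ids referenced by at least one reaction's GPR
#' rule; the model's metabolic-gene census.
#'
#' @param network a `metabolic_network`.
#' @return integer.
#' @export
count_genes <- function(network) {
  length(unique(unlist(lapply(network$gpr_ast, gpr_genes))))
}

# ---- Elemental formulas ------------------------------------------------

#' Parse an elemental formula
#' @param formula string such as `"C6H12O6"`.
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(integer())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)
  parts <- regmatches(formula, m)[[1]]
  m <- m[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula) || !length(parts))
    stop("malformed elemental formula: '", formula, "'")
  el <- sub("[0-9]*$", "", parts)
  ct <- sub("^[A-Z][a-z]?", "", parts)
  ct <- ifelse(nzchar(ct), as.integer(ct), 1L)
  tapply(ct, el, sum)[unique(el)]
}

#' Carbon atoms per molecule
#'
#' Number of carbon atoms in an elemental formula; used to weigh uptake
#' fluxes in the carbon-uptake objective. An empty formula contributes 0
#' carbons (with a warning), matching how annotation gaps in genome-scale
#' models are treated.
#'
#' @param formula elemental formula string.
#' @return non-negative integer.
#' @export
#' @examples
#' carbon_content("C6H12O6")  # 6
#' carbon_content("H2O")      # 0
carbon_content <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) {
    warning("empty formula: assuming 0 carbon atoms")
    return(0L)
  }
  counts <- parse_formula(formula)
  if ("C" %in% names(counts)) unname(counts[["C"]]) else 0L
}

# ---- Exchange helpers --------------------------------------------------

#' Metabolite exchanged by each exchange reaction
#' @param network a `metabolic_network`.
#' @return named character vector: exchange reaction id -> metabolite id.
#' @export
exchange_metabolites <- function(network) {
  ex <- network$reactions$id[network$reactions$is_exchange]
  out <- vapply(ex, function(r) {
    rownames(network$stoichiometry)[network$stoichiometry[, r] != 0][1]
  }, character(1))
  out
}
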