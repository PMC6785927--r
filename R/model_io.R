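#' Load a metabolic model
#'
#' Reads a genome-scale (or toy) metabolic model from either the package's
#' tabular TSV dialect or SBML, validates it, and resolves the biomass and
#' ATP-hydrolysis reactions (auto-detected by id pattern unless given).
#'
#' The tabular dialect is a directory (or a `reactions.tsv` file path)
#' holding `reactions.tsv` with columns `reaction`, `equation`, `lower_bound`,
#' `upper_bound`, `gpr` and optionally `enzyme_weight`, plus an optional
#' `metabolites.tsv` with columns `metabolite`, `name`, `compartment`,
#' `formula`. Equations are written `"1 A + 2 B -> 1 C"`; the arrow `<=>`
#' marks a conventionally reversible reaction (bounds are still taken from
#' the bound columns). An empty equation side is allowed (demand/exchange).
#'
#' @param path directory or file path.
#' @param format `"tabular"` or `"sbml"`.
#' @param biomass_reaction_id,atp_reaction_id optional overrides for
#'   auto-detection.
#' @return a validated [metabolic_network()].
#' @export
load_model <- function(path, format = c("tabular", "sbml"),
                       biomass_reaction_id = NULL, atp_reaction_id = NULL) {
  format <- match.arg(format)
  if (format == "sbml")
    return(read_sbml(path, biomass_reaction_id = biomass_reaction_id,
                     atp_reaction_id = atp_reaction_id))
  rxn_path <- if (dir.exists(path)) file.path(path, "reactions.tsv") else path
  if (!file.exists(rxn_path))
    stop("model file not found: ", rxn_path)
  met_path <- file.path(dirname(rxn_path), "metabolites.tsv")
  rx <- utils::read.delim(rxn_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("reaction", "equation", "lower_bound", "upper_bound")
  miss <- setdiff(need, names(rx))
  if (length(miss))
    stop("tabular model format error: missing column(s) ",
         paste(miss, collapse = ", "), " in ", rxn_path)
  if (is.null(rx$gpr)) rx$gpr <- ""
  rx$gpr[is.na(rx$gpr)] <- ""

  eqs <- lapply(seq_len(nrow(rx)), function(i) {
    tryCatch(parse_equation(rx$equation[i]),
             error = function(e) stop("tabular model format error in reaction '",
                                      rx$reaction[i], "': ", conditionMessage(e)))
  })
  met_ids <- sort(unique(unlist(lapply(eqs, names))))
  S <- matrix(0, length(met_ids), nrow(rx),
              dimnames = list(met_ids, rx$reaction))
  for (i in seq_along(eqs)) S[names(eqs[[i]]), i] <- eqs[[i]]

  mets <- data.frame(id = met_ids, stringsAsFactors = FALSE)
  if (file.exists(met_path)) {
    mt <- utils::read.delim(met_path, stringsAsFactors = FALSE)
    if (!"metabolite" %in% names(mt))
      stop("tabular model format error: metabolites.tsv lacks 'metabolite' column")
    idx <- match(mets$id, mt$metabolite)
    for (col in c("name", "compartment", "formula"))
      if (col %in% names(mt)) mets[[col]] <- mt[[col]][idx]
    if (!is.null(mets$formula)) mets$formula[is.na(mets$formula)] <- ""
  }
  reactions <- data.frame(
    id = rx$reaction,
    lower_bound = as.numeric(rx$lower_bound),
    upper_bound = as.numeric(rx$upper_bound),
    gpr = rx$gpr,
    stringsAsFactors = FALSE
  )
  if (!is.null(rx$enzyme_weight)) reactions$enzyme_weight <- as.numeric(rx$enzyme_weight)
  nnz <- colSums(S != 0)
  reactions$is_exchange <- grepl("^EX_", reactions$id) & nnz == 1
  metabolic_network(mets, reactions, S,
                    biomass_reaction_id = biomass_reaction_id,
                    atp_reaction_id = atp_reaction_id)
}

#' Write a metabolic model in the tabular dialect
#' @param network a `metabolic_network`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_model <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  S <- network$stoichiometry
  eq <- vapply(seq_len(ncol(S)), function(j) {
    deparse_equation(S[, j])
  }, character(1))
  rx <- data.frame(
    reaction = network$reactions$id,
    equation = eq,
    lower_bound = network$reactions$lower_bound,
    upper_bound = network$reactions$upper_bound,
    gpr = network$reactions$gpr,
    enzyme_weight = network$reactions$enzyme_weight,
    stringsAsFactors = FALSE
  )
  utils::write.table(rx, file.path(dir, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mt <- data.frame(
    metabolite = network$metabolites$id,
    name = network$metabolites$name,
    compartment = network$metabolites$compartment,
    formula = network$metabolites$formula,
    stringsAsFactors = FALSE
  )
  utils::write.table(mt, file.path(dir, "metabolites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

parse_equation <- function(eq) {
  if (is.na(eq)) stop("missing equation")
  arrow <- if (grepl("<=>", eq, fixed = TRUE)) "<=>" else
    if (grepl("->", eq, fixed = TRUE)) "->" else
      stop("no reaction arrow ('->' or '<=>') in equation '", eq, "'")
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1) sides <- c(sides, "")
  coefs <- c(parse_side(sides[1], -1), parse_side(sides[2], +1))
  if (!length(coefs)) stop("equation has no metabolites: '", eq, "'")
  tapply(coefs, names(coefs), sum)
}

parse_side <- function(side, sign) {
  side <- trimws(side)
  if (!nzchar(side)) return(numeric())
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  terms <- terms[nzchar(terms)]
  out <- numeric(length(terms))
  nm <- character(length(terms))
  for (i in seq_along(terms)) {
    tk <- strsplit(terms[i], "[[:space:]]+")[[1]]
    if (length(tk) == 1) { out[i] <- sign; nm[i] <- tk }
    else if (length(tk) == 2) {
      cf <- suppressWarnings(as.numeric(tk[1]))
      if (is.na(cf)) stop("bad stoichiometric coefficient in term '", terms[i], "'")
      out[i] <- sign * cf; nm[i] <- tk[2]
    } else stop("bad equation term '", terms[i], "'")
  }
  stats::setNames(out, nm)
}

deparse_equation <- function(col) {
  lhs <- col[col < 0]; rhs <- col[col > 0]
  fmt <- function(v) paste(paste(format(abs(unname(v)), trim = TRUE), names(v)),
                           collapse = " + ")
  paste(if (length(lhs)) fmt(lhs) else "", "->",
        if (length(rhs)) fmt(rhs) else "")
}

# ---- SBML --------------------------------------------------------------

#' Read an SBML model (Level 3 + fbc)
#'
#' Minimal reader for SBML Level 3 Version 1 documents using the `fbc`
#' package for flux bounds and gene-product associations, which is how
#' genome-scale models are distributed today. Species compartments ending
#' in `e` (or named `extracellular`) are flagged extracellular.
#'
#' @param path SBML file.
#' @param biomass_reaction_id,atp_reaction_id optional overrides.
#' @param default_bound bound magnitude used when a reaction carries no
#'   explicit flux-bound parameters.
#' @return a validated [metabolic_network()].
#' @export
read_sbml <- function(path, biomass_reaction_id = NULL,
                      atp_reaction_id = NULL, default_bound = 1000) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(sp)) stop("SBML format error: no species found in ", path)
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = ifelse(is.na(xml2::xml_attr(sp, "chemicalFormula")), "",
                     xml2::xml_attr(sp, "chemicalFormula")),
    stringsAsFactors = FALSE
  )
  mets$is_extracellular <- grepl("^e$|extracellular", mets$compartment,
                                 ignore.case = TRUE)

  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  rnodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rnodes)) stop("SBML format error: no reactions found in ", path)
  n <- length(rnodes)
  rid <- xml2::xml_attr(rnodes, "id")
  rev <- xml2::xml_attr(rnodes, "reversible") %in% c("true", "1")
  lbp <- xml2::xml_attr(rnodes, "lowerFluxBound")
  ubp <- xml2::xml_attr(rnodes, "upperFluxBound")
  lb <- ifelse(!is.na(lbp), pval[lbp], ifelse(rev, -default_bound, 0))
  ub <- ifelse(!is.na(ubp), pval[ubp], default_bound)

  S <- matrix(0, nrow(mets), n, dimnames = list(mets$id, rid))
  gprs <- character(n)
  for (i in seq_len(n)) {
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(rnodes[[i]], paste0("./", side, "/speciesReference"))
      if (length(refs)) {
        sid <- xml2::xml_attr(refs, "species")
        st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
        st[is.na(st)] <- 1
        sgn <- if (side == "listOfReactants") -1 else 1
        bad <- setdiff(sid, mets$id)
        if (length(bad))
          stop("SBML format error: reaction '", rid[i],
               "' references unknown species ", paste(bad, collapse = ", "))
        S[sid, i] <- S[sid, i] + sgn * st
      }
    }
    ga <- xml2::xml_find_first(
      rnodes[[i]], "./*[local-name()='geneProductAssociation']")
    gprs[i] <- if (inherits(ga, "xml_missing")) "" else sbml_gpr(xml2::xml_children(ga)[[1]])
  }
  reactions <- data.frame(id = rid, lower_bound = lb, upper_bound = ub,
                          gpr = gprs, stringsAsFactors = FALSE)
  nnz <- colSums(S != 0)
  touches_e <- colSums(S[mets$is_extracellular, , drop = FALSE] != 0)
  reactions$is_exchange <- nnz == 1 & (grepl("^EX_|^R_EX_", rid) | touches_e == 1)
  metabolic_network(mets, reactions, S,
                    biomass_reaction_id = biomass_reaction_id,
                    atp_reaction_id = atp_reaction_id)
}

sbml_gpr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") return(xml2::xml_attr(node, "geneProduct"))
  kids <- vapply(xml2::xml_children(node), sbml_gpr, character(1))
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(kids, collapse = op), ")")
}
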