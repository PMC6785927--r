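#' Persist a Pareto set as plain-text tables
#'
#' Writes `objectives.tsv` (solution x objective), `fluxes.tsv`
#' (solution x reaction) and a JSON `manifest.json` recording the grid,
#' the normalization ranges and a model hash, sufficient to reproduce and
#' audit the sampling run.
#'
#' @param pareto a `pareto_set`.
#' @param dir output directory.
#' @param network optional network, hashed into the manifest.
#' @param extra named list merged into the manifest (e.g. seed, config).
#' @return `dir`, invisibly.
#' @export
write_pareto_set <- function(pareto, dir, network = NULL, extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obj <- data.frame(solution = seq_len(n_solutions(pareto)),
                    pareto$objectives, check.names = FALSE)
  utils::write.table(obj, file.path(dir, "objectives.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(pareto$fluxes)) {
    fl <- data.frame(solution = seq_len(n_solutions(pareto)),
                     pareto$fluxes, check.names = FALSE)
    utils::write.table(fl, file.path(dir, "fluxes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  manifest <- c(list(
    n_solutions = n_solutions(pareto),
    senses = as.list(pareto$senses),
    normalization = apply(pareto$normalization, 2, as.list),
    grid = pareto$grid,
    n_infeasible = pareto$n_infeasible,
    model_hash = if (!is.null(network)) model_hash(network) else NULL,
    package_version = as.character(utils::packageVersion("paretometab"))
  ), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a persisted Pareto set
#' @param dir directory written by [write_pareto_set()].
#' @return a `pareto_set`.
#' @export
read_pareto_set <- function(dir) {
  obj <- utils::read.delim(file.path(dir, "objectives.tsv"),
                           check.names = FALSE)
  objectives <- as.matrix(obj[, -1, drop = FALSE])
  fluxes <- NULL
  fp <- file.path(dir, "fluxes.tsv")
  if (file.exists(fp)) {
    fl <- utils::read.delim(fp, check.names = FALSE)
    fluxes <- as.matrix(fl[, -1, drop = FALSE])
  }
  mp <- file.path(dir, "manifest.json")
  grid <- NULL; n_inf <- 0L
  senses <- objective_senses()
  if (file.exists(mp)) {
    man <- jsonlite::read_json(mp, simplifyVector = TRUE)
    if (!is.null(man$grid)) grid <- man$grid
    if (!is.null(man$n_infeasible)) n_inf <- man$n_infeasible
    if (!is.null(man$senses)) senses <- unlist(man$senses)
  }
  pareto_set(objectives, fluxes, senses = senses, grid = grid,
             n_infeasible = n_inf)
}

#' Stable content hash of a metabolic network
#' @param network a `metabolic_network`.
#' @return md5 string.
#' @export
model_hash <- function(network) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  serialize(list(network$stoichiometry,
                 network$reactions[c("id", "lower_bound", "upper_bound",
                                     "gpr")],
                 network$metabolites[c("id", "formula")]),
            con, version = 2)
  close(con)
  unname(tools::md5sum(tmp))
}

#' Read omics tables into per-line profiles
#'
#' Reads the two wide TSVs of the fitting stage — proteomics (gene x cell
#' line, first column `gene`) and consumption-release exchange fluxes
#' (metabolite x cell line, first column `metabolite`, uptake negative) —
#' and splits them into one [omics_profile()] per cell line. Either path
#' may be `NULL`.
#'
#' @param proteomics_path,core_path TSV paths.
#' @return named list of [omics_profile()]s.
#' @export
read_omics <- function(proteomics_path = NULL, core_path = NULL) {
  if (is.null(proteomics_path) && is.null(core_path))
    stop("configuration error: need at least one omics table")
  ab <- ex <- NULL
  if (!is.null(proteomics_path)) {
    ab <- utils::read.delim(proteomics_path, check.names = FALSE)
    if (names(ab)[1] != "gene")
      stop("proteomics table must have first column 'gene'")
  }
  if (!is.null(core_path)) {
    ex <- utils::read.delim(core_path, check.names = FALSE)
    if (names(ex)[1] != "metabolite")
      stop("exchange-flux table must have first column 'metabolite'")
  }
  lines <- union(if (!is.null(ab)) names(ab)[-1] else character(),
                 if (!is.null(ex)) names(ex)[-1] else character())
  out <- lapply(lines, function(cl) {
    omics_profile(
      cell_line_id = cl,
      enzyme_abundance = if (!is.null(ab) && cl %in% names(ab))
        stats::setNames(ab[[cl]], ab$gene) else numeric(),
      exchange_flux = if (!is.null(ex) && cl %in% names(ex))
        stats::setNames(ex[[cl]], ex$metabolite) else numeric())
  })
  stats::setNames(out, lines)
}

#' Write a synthetic panel as omics TSVs
#' @param panel a [make_synthetic_panel()] result.
#' @param dir output directory; writes `proteomics.tsv`, `core.tsv`,
#'   `ground_truth.tsv`, `manifest.json`.
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(panel$profiles, function(p) p$cell_line_id, character(1))
  ab <- do.call(cbind, lapply(panel$profiles, function(p) p$enzyme_abundance))
  colnames(ab) <- ids
  utils::write.table(
    data.frame(gene = rownames(ab), ab, check.names = FALSE),
    file.path(dir, "proteomics.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  ex <- do.call(cbind, lapply(panel$profiles, function(p) p$exchange_flux))
  colnames(ex) <- ids
  utils::write.table(
    data.frame(metabolite = rownames(ex), ex, check.names = FALSE),
    file.path(dir, "core.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(panel$ground_truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(n_lines = length(panel$profiles),
                            noise_sigma = panel$noise_sigma,
                            seed = panel$seed),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
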