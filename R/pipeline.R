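#' Pipeline configuration
#'
#' Collects every tunable of the workflow in one validated object that is
#' serialized verbatim into each output manifest.
#'
#' @param model_path path to a model (tabular dir or SBML file); `NULL` when
#'   `fixture` is used.
#' @param fixture benchmark network name passed to [make_fixture()].
#' @param format model format for [load_model()].
#' @param proteomics_path,core_path omics tables for the fitting stage.
#' @param grid_levels epsilon levels per constrained objective.
#' @param primary primary objective of the scalarization.
#' @param tol_feas,tol_obj,tol_pds numerical tolerances.
#' @param alpha,top_fraction fitting parameters (see [fit_cell_line()]).
#' @param knock_fraction residual activity in the essentiality screen.
#' @param n_bins,score_cutoff,proximity_cutoff,proximity_tol target-calling
#'   parameters (see [classify_targets()]).
#' @param phenotypes phenotypes to classify.
#' @param synthetic_lines,noise_sigma synthetic-panel fallback when no omics
#'   tables are given.
#' @param seed integer seed for all stochastic steps.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(model_path = NULL, fixture = "Y-net",
                       format = "tabular",
                       proteomics_path = NULL, core_path = NULL,
                       grid_levels = 10, primary = "biomass",
                       tol_feas = 1e-9, tol_obj = 1e-6, tol_pds = 1e-6,
                       alpha = 0.5, top_fraction = 0.01,
                       knock_fraction = 0, n_bins = 20,
                       score_cutoff = 0.8, proximity_cutoff = 0.5,
                       proximity_tol = 0.25,
                       phenotypes = c("growth", "warburg"),
                       synthetic_lines = 20, noise_sigma = 0.05, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(grid_levels >= 2, tol_feas > 0, tol_obj > 0, tol_pds >= 0,
            alpha >= 0, alpha <= 1, top_fraction > 0, top_fraction <= 1,
            knock_fraction >= 0, knock_fraction <= 1, n_bins >= 3,
            score_cutoff >= 0, score_cutoff <= 1,
            proximity_cutoff >= 0, proximity_cutoff <= 1,
            synthetic_lines >= 2, noise_sigma >= 0)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "run_config")
}

#' Run the full workflow
#'
#' Executes the stages in order — load/generate model, sample the Pareto
#' surface, fit cell-line models (from supplied omics tables, or from a
#' seeded synthetic panel when none are given), screen gene essentiality by
#' PDS, classify targets — writing each stage's outputs and a manifest into
#' `out_dir`. A stage failure stops with an error naming the stage; outputs
#' of completed stages are preserved.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created).
#' @return `out_dir`, invisibly; side effect: files under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config)[!vapply(config, is.null, logical(1))],
                       cfg_json, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)

  network <- stage("model", {
    if (!is.null(config$model_path))
      load_model(config$model_path, config$format)
    else make_fixture(config$fixture)
  })
  weights <- suppressWarnings(objective_weights(network))

  pareto <- stage("sample", epsilon_constraint_sample(
    network, weights, grid_spec(config$grid_levels),
    primary = config$primary, tol_obj = config$tol_obj))
  write_pareto_set(pareto, file.path(out_dir, "pareto"), network,
                   extra = list(seed = config$seed))

  profiles <- stage("fit", {
    if (!is.null(config$proteomics_path) || !is.null(config$core_path))
      read_omics(config$proteomics_path, config$core_path)
    else {
      panel <- make_synthetic_panel(pareto, network,
                                    n_lines = config$synthetic_lines,
                                    noise_sigma = config$noise_sigma,
                                    seed = config$seed)
      write_panel(panel, file.path(out_dir, "panel"))
      panel$profiles
    }
  })
  models <- stage("fit", lapply(profiles, function(p)
    fit_cell_line(pareto, network, p, top_fraction = config$top_fraction,
                  alpha = config$alpha)))
  fit_tab <- data.frame(
    cell_line = vapply(models, function(m) m$cell_line_id, character(1)),
    representative = vapply(models, function(m) m$representative, numeric(1)),
    n_selected = vapply(models, function(m) length(m$selected), numeric(1)),
    t(vapply(models, function(m) m$predicted_objectives, numeric(4))),
    check.names = FALSE)
  utils::write.table(fit_tab, file.path(out_dir, "cell_line_models.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  screen <- stage("pds", gene_essentiality_screen(
    pareto, network, models, knock_fraction = config$knock_fraction,
    weights = weights, tol_pds = config$tol_pds))
  utils::write.table(screen$scores, file.path(out_dir, "pds_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(screen$essential, file.path(out_dir, "essentiality.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  calls <- stage("targets", {
    ph <- config$phenotypes
    has_warburg <- !inherits(
      try(find_warburg_exchanges(network), silent = TRUE), "try-error")
    if (!has_warburg) ph <- setdiff(ph, "warburg")
    suppressMessages(classify_targets(
      pareto, network, models, phenotypes = ph,
      score_cutoff = config$score_cutoff,
      proximity_cutoff = config$proximity_cutoff,
      n_bins = config$n_bins, proximity_tol = config$proximity_tol))
  })
  utils::write.table(calls, file.path(out_dir, "target_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ov <- target_overlap(calls)
  jsonlite::write_json(
    list(categories = ov$categories, ambiguous = ov$ambiguous,
         overlap = as.data.frame(ov$overlap)),
    file.path(out_dir, "target_overlap.json"), auto_unbox = TRUE,
    pretty = TRUE)

  jsonlite::write_json(list(
    model_hash = model_hash(network),
    n_pareto_solutions = n_solutions(pareto),
    n_cell_lines = length(models),
    n_essential = sum(screen$essential$essential),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("paretometab"))
  ), file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
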