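#' In-silico Warburg metric of a flux configuration
#'
#' Proxy for the experimental ECAR/OCR ratio: lactate secretion flux
#' divided by oxygen uptake flux. When oxygen uptake falls below `tol` with
#' positive lactate secretion the ratio is capped at `ceiling` and flagged
#' (attribute `capped`); with neither lactate secretion nor oxygen uptake
#' the metric is 0. The proxy ignores CO2-derived acidification, which
#' contributes to real ECAR.
#'
#' @param network a `metabolic_network` with lactate and O2 exchange
#'   reactions (auto-detected from the exchanged metabolite id/name matching
#'   `lac` / `o2`, or given explicitly).
#' @param flux named flux vector or `flux_configuration`.
#' @param lactate_exchange,o2_exchange exchange reaction ids (auto-detected
#'   when `NULL`).
#' @param tol fluxes below this count as zero.
#' @param ceiling cap for the anaerobic limit.
#' @return non-negative numeric, possibly with attribute `capped = TRUE`.
#' @export
warburg_metric <- function(network, flux, lactate_exchange = NULL,
                           o2_exchange = NULL, tol = 1e-9, ceiling = 1e3) {
  ids <- find_warburg_exchanges(network, lactate_exchange, o2_exchange)
  v <- flux_vector(flux)
  lac_out <- max(v[[ids["lactate"]]], 0)     # secretion = positive exchange
  o2_in <- max(-v[[ids["o2"]]], 0)           # uptake = negative exchange
  if (lac_out <= tol) return(0)
  if (o2_in <= tol) {
    out <- ceiling
    attr(out, "capped") <- TRUE
    return(out)
  }
  min(lac_out / o2_in, ceiling)
}

find_warburg_exchanges <- function(network, lactate_exchange = NULL,
                                   o2_exchange = NULL) {
  exch <- exchange_metabolites(network)
  pick <- function(given, pattern, what) {
    if (!is.null(given)) {
      if (!given %in% names(exch))
        stop("configuration error: '", given, "' is not an exchange reaction")
      return(given)
    }
    hit <- names(exch)[grepl(pattern, exch, ignore.case = TRUE) |
                         grepl(pattern, names(exch), ignore.case = TRUE)]
    if (!length(hit))
      stop("configuration error: no ", what, " exchange reaction found")
    hit[1]
  }
  c(lactate = pick(lactate_exchange, "lac", "lactate"),
    o2 = pick(o2_exchange, "(^|_)o2", "oxygen"))
}

#' Project the Pareto surface onto a (phenotype, flux) plane
#'
#' For every sampled Pareto solution, computes a phenotype value (biomass
#' flux for `"growth"`, the [warburg_metric()] for `"warburg"`) and a flux
#' value (absolute flux through a reaction, or the gene-level flux
#' engagement of an enzyme), then estimates the projected surface's lower
#' and upper bounds as the per-bin minimum and maximum of the flux value
#' over equal-count phenotype bins. Bins emptied by ties are merged with
#' their neighbors; fewer than 3 non-empty bins is an error.
#'
#' @param pareto a `pareto_set` with fluxes.
#' @param network the generating `metabolic_network`.
#' @param phenotype `"growth"` or `"warburg"`.
#' @param target a reaction id or a gene id of `network`.
#' @param n_bins number of equal-count bins.
#' @param ... passed to [warburg_metric()].
#' @return object of class `surface_projection`: `points` (data.frame
#'   phenotype, flux, bin), `bins` (data.frame center, lower, upper, n),
#'   plus the projection's metadata.
#' @export
project <- function(pareto, network, phenotype = c("growth", "warburg"),
                    target, n_bins = 20, ...) {
  phenotype <- match.arg(phenotype)
  stopifnot(!is.null(pareto$fluxes))
  n <- n_solutions(pareto)
  if (n < 2 * 3) stop("insufficient data: need at least 6 Pareto solutions")
  ph <- if (phenotype == "growth") {
    pareto$objectives[, "biomass"]
  } else {
    vapply(seq_len(n), function(i)
      as.numeric(warburg_metric(network, pareto$fluxes[i, ], ...)),
      numeric(1))
  }
  fl <- if (target %in% network$reactions$id) {
    abs(pareto$fluxes[, target])
  } else if (target %in% network$genes) {
    feats <- pareto_features(pareto, network)
    feats[target, ]
  } else stop("unknown projection target '", target, "'")
  # snap to numerical precision so solver noise cannot split or reorder bins
  ph <- round(ph, 6)
  fl <- round(fl, 6)

  n_bins <- min(n_bins, max(3L, floor(n / 2)))
  ord <- order(ph)
  # equal-count bins; solutions with identical phenotype stay in one bin
  raw_bin <- ceiling(seq_along(ord) / (n / n_bins))
  bin_of <- integer(n)
  bin_of[ord] <- raw_bin
  for (u in unique(ph)) {           # ties span one bin
    idx <- which(ph == u)
    if (length(idx) > 1) bin_of[idx] <- min(bin_of[idx])
  }
  ids <- sort(unique(bin_of))
  bins <- data.frame(
    center = vapply(ids, function(b) mean(ph[bin_of == b]), numeric(1)),
    lower = vapply(ids, function(b) min(fl[bin_of == b]), numeric(1)),
    upper = vapply(ids, function(b) max(fl[bin_of == b]), numeric(1)),
    lo_ph = vapply(ids, function(b) min(ph[bin_of == b]), numeric(1)),
    hi_ph = vapply(ids, function(b) max(ph[bin_of == b]), numeric(1)),
    # phenotype at which each extreme is attained: anchors the envelope
    # polylines at real surface points instead of bin centers
    lower_ph = vapply(ids, function(b) {
      idx <- which(bin_of == b); ph[idx[which.min(fl[idx])]] }, numeric(1)),
    upper_ph = vapply(ids, function(b) {
      idx <- which(bin_of == b); ph[idx[which.max(fl[idx])]] }, numeric(1)),
    n = vapply(ids, function(b) sum(bin_of == b), numeric(1)))
  if (nrow(bins) < 3)
    stop("insufficient data: fewer than 3 non-empty phenotype bins")
  structure(list(
    points = data.frame(phenotype = ph, flux = fl, bin = match(bin_of, ids)),
    bins = bins, phenotype = phenotype, target = target),
    class = "surface_projection")
}

#' @export
print.surface_projection <- function(x, ...) {
  cat("surface_projection of '", x$target, "' vs ", x$phenotype, ": ",
      nrow(x$points), " points in ", nrow(x$bins), " bins\n", sep = "")
  invisible(x)
}

#' Monotonousness score of a projected envelope
#'
#' Correlation-based score of how monotonically the chosen envelope (upper
#' or lower bound of the projected Pareto surface) varies with the
#' phenotype: the Spearman rank correlation between envelope knot positions
#' and the envelope's flux values, in `[-1, 1]`. A constant envelope scores
#' 0 by convention (flagged with a message).
#'
#' With 4 or more bins the envelope knots sit at bin boundaries and each
#' knot's value is estimated from the two flanking bins (the running
#' maximum/minimum over adjacent bin pairs). Per-bin extremes are
#' order statistics and systematically undershoot the true envelope where a
#' bin's phenotype spread is degenerate (e.g. a bin made of tied phenotype
#' values samples a measure-zero slice of the surface); pooling flanking
#' bins removes that bias while preserving strict monotonicity of any
#' monotone envelope. With exactly 3 bins the raw per-bin envelope is used.
#'
#' @param projection a [project()] result.
#' @param which `"upper"` or `"lower"`.
#' @return numeric in `[-1, 1]`.
#' @export
monotonousness <- function(projection, which = c("upper", "lower")) {
  which <- match.arg(which)
  env <- projection$bins[[which]]
  x <- projection$bins$center
  if (length(env) < 3) stop("insufficient data: fewer than 3 envelope points")
  if (length(env) >= 4) {
    n <- length(env)
    pool <- if (which == "upper") pmax else pmin
    env <- pool(env[-n], env[-1])
    x <- (x[-n] + x[-1]) / 2
  }
  if (stats::sd(env) == 0) {
    message("constant ", which, " envelope for '", projection$target,
            "': monotonousness 0")
    return(0)
  }
  stats::cor(x, env, method = "spearman")
}

#' Fraction of cell-line models near a projected envelope
#'
#' The target-identification criterion requires that the individualized
#' models sit close to the envelope being exploited; this computes the
#' fraction of cell-line representative points lying close to the chosen
#' envelope curve. Both envelopes are interpolated linearly between bin
#' centers and evaluated at each point's own phenotype value; a point is
#' close when its vertical distance to the chosen envelope is within
#' `tol` times the local envelope separation (upper minus lower at that
#' phenotype). Where the two envelopes essentially coincide (separation
#' below 2\% of the target's global flux range) every point between them is
#' on the boundary by construction and counts as close.
#'
#' @param projection a [project()] result.
#' @param pareto,network the sampled surface and its network.
#' @param cell_line_models list of [fit_cell_line()] results.
#' @param which `"upper"`, `"lower"`, or `"either"` (close to at least one
#'   boundary, the criterion's reading of models sitting on the rim of the
#'   projected band).
#' @param tol relative closeness threshold.
#' @param ... passed to [warburg_metric()] for the warburg phenotype.
#' @return fraction in `[0, 1]`.
#' @export
boundary_proximity <- function(projection, pareto, network,
                               cell_line_models,
                               which = c("upper", "lower", "either"),
                               tol = 0.25, ...) {
  which <- match.arg(which)
  stopifnot(length(cell_line_models) >= 1)
  pts <- representative_points(projection, pareto, network,
                               cell_line_models, ...)
  bins <- projection$bins
  interp <- function(col, xcol, x) {
    if (nrow(bins) == 1) return(rep(bins[[col]], length(x)))
    stats::approx(bins[[xcol]], bins[[col]], xout = x, rule = 2,
                  ties = mean)$y
  }
  up <- interp("upper", "upper_ph", pts$phenotype)
  lo <- interp("lower", "lower_ph", pts$phenotype)
  sep <- up - lo
  floor_sep <- 0.02 * max(diff(range(projection$points$flux)), 1e-12)
  close_u <- abs(pts$flux - up) <= tol * sep | sep <= floor_sep
  close_l <- abs(pts$flux - lo) <= tol * sep | sep <= floor_sep
  mean(switch(which, upper = close_u, lower = close_l,
              either = close_u | close_l))
}

representative_points <- function(projection, pareto, network,
                                  cell_line_models, ...) {
  idx <- vapply(cell_line_models, function(m) m$representative, numeric(1))
  ph <- if (projection$phenotype == "growth") {
    pareto$objectives[idx, "biomass"]
  } else {
    vapply(idx, function(i)
      as.numeric(warburg_metric(network, pareto$fluxes[i, ], ...)),
      numeric(1))
  }
  fl <- if (projection$target %in% network$reactions$id) {
    abs(pareto$fluxes[idx, projection$target])
  } else {
    vapply(idx, function(i)
      pathway_flux_features(network, pareto$fluxes[i, ])[[projection$target]],
      numeric(1))
  }
  data.frame(phenotype = ph, flux = fl)
}

find_bin <- function(bins, ph) {
  b <- which(ph >= bins$lo_ph & ph <= bins$hi_ph)
  if (length(b)) return(b[1])
  which.min(pmin(abs(bins$lo_ph - ph), abs(bins$hi_ph - ph)))
}

#' Classify metabolic enzymes as phenotype-promoting or -suppressing
#'
#' Implements the Pareto-surface target-identification criteria. For each
#' enzyme and phenotype the Pareto surface is projected onto the
#' (phenotype, enzyme flux) plane and its envelopes are scored:
#' \itemize{
#'   \item \emph{promoting} (pro-oncogenic for growth; inhibition is the
#'     intervention): the lower envelope rises monotonically with the
#'     phenotype — `monotonousness(lower) >= score_cutoff` — so cells with a
#'     high phenotype value cannot avoid using the enzyme, and inhibiting it
#'     selectively pushes them off the Pareto surface.
#'   \item \emph{suppressing} (tumor-suppressive; activation is the
#'     intervention): the upper envelope falls —
#'     `monotonousness(upper) <= -score_cutoff` — so forcing extra flux
#'     through the enzyme selectively harms high-phenotype cells.
#' }
#' Either call additionally requires that at least `proximity_cutoff` of the
#' cell-line models lie close to the projection's boundary (its upper or
#' lower envelope, [boundary_proximity()] with `which = "either"`);
#' mid-band models have headroom in both directions and the perturbation
#' cannot pull them off the surface. Enzymes failing the criteria get
#' direction `"none"` (with the reason when the projection is degenerate).
#'
#' @param pareto a `pareto_set` with fluxes.
#' @param network the generating `metabolic_network`.
#' @param cell_line_models list of [fit_cell_line()] results.
#' @param enzymes gene ids (default all model genes) or reaction ids.
#' @param phenotypes subset of `c("growth", "warburg")`.
#' @param score_cutoff monotonousness cutoff (default 0.8).
#' @param proximity_cutoff boundary-proximity cutoff (default 0.5).
#' @param n_bins,proximity_tol envelope estimation parameters.
#' @param ... passed to [warburg_metric()].
#' @return data.frame of target calls: enzyme, phenotype, direction,
#'   monotonousness (of the envelope backing the call, or the stronger one),
#'   mono_upper, mono_lower, prox_upper, prox_lower, reason.
#' @export
classify_targets <- function(pareto, network, cell_line_models,
                             enzymes = NULL,
                             phenotypes = c("growth", "warburg"),
                             score_cutoff = 0.8, proximity_cutoff = 0.5,
                             n_bins = 20, proximity_tol = 0.25, ...) {
  if (is.null(enzymes)) enzymes <- network$genes
  rows <- list()
  for (ph in phenotypes) {
    for (e in enzymes) {
      res <- tryCatch({
        pr <- project(pareto, network, ph, e, n_bins = n_bins, ...)
        mu <- suppressMessages(monotonousness(pr, "upper"))
        ml <- suppressMessages(monotonousness(pr, "lower"))
        pu <- boundary_proximity(pr, pareto, network, cell_line_models,
                                 "upper", tol = proximity_tol, ...)
        pl <- boundary_proximity(pr, pareto, network, cell_line_models,
                                 "lower", tol = proximity_tol, ...)
        pe <- boundary_proximity(pr, pareto, network, cell_line_models,
                                 "either", tol = proximity_tol, ...)
        promoting <- ml >= score_cutoff && pe >= proximity_cutoff
        suppressing <- mu <= -score_cutoff && pe >= proximity_cutoff
        direction <- if (promoting && suppressing) {
          if (ml >= -mu) "promoting" else "suppressing"
        } else if (promoting) "promoting"
        else if (suppressing) "suppressing"
        else "none"
        data.frame(enzyme = e, phenotype = ph, direction = direction,
                   monotonousness = if (direction == "suppressing") mu
                                    else if (direction == "promoting") ml
                                    else if (abs(mu) >= abs(ml)) mu else ml,
                   mono_upper = mu, mono_lower = ml,
                   prox_upper = pu, prox_lower = pl,
                   reason = "", stringsAsFactors = FALSE)
      }, error = function(err)
        data.frame(enzyme = e, phenotype = ph, direction = "none",
                   monotonousness = NA_real_, mono_upper = NA_real_,
                   mono_lower = NA_real_, prox_upper = NA_real_,
                   prox_lower = NA_real_,
                   reason = conditionMessage(err), stringsAsFactors = FALSE))
      rows[[length(rows) + 1]] <- res
    }
  }
  do.call(rbind, rows)
}

#' Overlap structure of the four target categories
#'
#' Cross-tabulates target calls into the four categories
#' (promoting/suppressing x growth/warburg) and reports all pairwise
#' overlaps, including the "ambiguous" class of enzymes simultaneously
#' growth-promoting and warburg-suppressing.
#'
#' @param calls output of [classify_targets()].
#' @return list with `categories` (named list of enzyme vectors) and
#'   `overlap` (matrix of pairwise overlap counts).
#' @export
target_overlap <- function(calls) {
  cats <- list(
    growth_promoting = unique(calls$enzyme[
      calls$phenotype == "growth" & calls$direction == "promoting"]),
    growth_suppressing = unique(calls$enzyme[
      calls$phenotype == "growth" & calls$direction == "suppressing"]),
    warburg_promoting = unique(calls$enzyme[
      calls$phenotype == "warburg" & calls$direction == "promoting"]),
    warburg_suppressing = unique(calls$enzyme[
      calls$phenotype == "warburg" & calls$direction == "suppressing"]))
  ov <- outer(seq_along(cats), seq_along(cats),
              Vectorize(function(i, j) length(intersect(cats[[i]], cats[[j]]))))
  dimnames(ov) <- list(names(cats), names(cats))
  list(categories = cats, overlap = ov,
       ambiguous = intersect(cats$growth_promoting, cats$warburg_suppressing))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of p-values; validates the input
#' range and delegates to the standard implementation.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values, same length.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
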