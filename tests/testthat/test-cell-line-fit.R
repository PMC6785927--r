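test_that("gene-level flux engagement sums absolute fluxes over GPR hits", {
  dir <- tempfile(); dir.create(dir)
  write.table(
    data.frame(reaction = c("EX_A", "R1", "R2", "BIOMASS", "ATPM"),
               equation = c("A -> ", "A -> B", "B -> A",
                            "B -> atp", "atp -> "),
               lower_bound = c(-10, -5, 0, 0, 0),
               upper_bound = c(0, 10, 10, 10, 10),
               gpr = c("", "g1", "g1 or g2", "gB", "")),
    file.path(dir, "reactions.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  net <- load_model(dir)
  v <- c(EX_A = 0, R1 = -3, R2 = 5, BIOMASS = 2, ATPM = 2)
  f <- pathway_flux_features(net, v)
  expect_equal(unname(f["g1"]), 3 + 5)   # |−3| + 5 over its two reactions
  expect_equal(unname(f["g2"]), 5)
  expect_equal(unname(f["gB"]), 2)
  # a gene absent from all GPRs scores 0
  v0 <- v; v0[] <- 0; v0["BIOMASS"] <- 1
  expect_equal(unname(pathway_flux_features(net, v0)["g1"]), 0)
})

test_that("similarity is 1 under monotone transforms and ~0 under permutation", {
  set.seed(9)
  g <- paste0("g", 1:40)
  feats <- setNames(runif(40, 0.1, 10), g)
  prof <- omics_profile("L", enzyme_abundance = sqrt(feats) * 3) # monotone
  expect_equal(solution_similarity(prof, feats), 1)

  sims <- replicate(50, {
    p <- omics_profile("L", enzyme_abundance = setNames(sample(feats), g))
    solution_similarity(p, feats)
  })
  expect_lt(abs(mean(sims)), 0.1)
})

test_that("similarity is invariant to rescaling of abundance units", {
  set.seed(3)
  g <- paste0("g", 1:12)
  feats <- setNames(runif(12), g)
  ab <- setNames(runif(12), g)
  s1 <- solution_similarity(omics_profile("L", enzyme_abundance = ab), feats)
  s2 <- solution_similarity(omics_profile("L", enzyme_abundance = 173 * ab),
                            feats)
  expect_equal(s1, s2)
})

test_that("insufficient overlap raises an error; one component can carry the score", {
  feats <- c(g1 = 1, g2 = 2)
  prof <- omics_profile("L", enzyme_abundance = c(g1 = 1, g2 = 2))
  expect_error(solution_similarity(prof, feats), "insufficient overlap")
  # exchange component alone is enough
  prof2 <- omics_profile("L", enzyme_abundance = c(g1 = 1, g2 = 2),
                         exchange_flux = c(a = -1, b = 2, c = 0.5))
  expect_equal(
    solution_similarity(prof2, feats, c(a = -1, b = 2, c = 0.5)), 1)
})

test_that("fitting selects the generating solution and honours top_fraction", {
  ps <- cached_front("ferm-resp-net", 4)
  net <- cached_fixture("ferm-resp-net")
  panel <- make_synthetic_panel(ps, net, n_lines = 5, noise_sigma = 0,
                                seed = 2)
  m <- fit_cell_line(ps, net, panel$profiles[[1]],
                     top_fraction = 1 / n_solutions(ps))
  expect_true(panel$ground_truth$solution[1] %in% m$selected)
  expect_equal(m$representative, m$selected[1])

  # top_fraction = 1 averages the whole front
  m_all <- fit_cell_line(ps, net, panel$profiles[[1]], top_fraction = 1)
  expect_equal(m_all$predicted_objectives, colMeans(ps$objectives))
})

test_that("solutions tied at the cutoff are co-selected", {
  # two identical solutions in a hand-made Pareto set
  obj <- rbind(c(4, 1, 1, 1), c(4, 1, 1, 1), c(1, 4, 2, 2))
  colnames(obj) <- names(objective_senses())
  fl <- rbind(c(EX_glc = -4, BIOMASS = 4, CAT1 = 0, CAT2 = 0, ATPM = 0),
              c(EX_glc = -4, BIOMASS = 4, CAT1 = 0, CAT2 = 0, ATPM = 0),
              c(EX_glc = -3, BIOMASS = 1, CAT1 = 2, CAT2 = 2, ATPM = 4))
  ps <- pareto_set(obj, fl)
  net <- cached_fixture("Y-net")
  prof <- omics_profile(
    "L", enzyme_abundance = pathway_flux_features(net, fl[1, ]),
    exchange_flux = c(glc_e = -4))
  m <- fit_cell_line(ps, net, prof, top_fraction = 1e-9, min_shared = 1)
  expect_true(all(c(1L, 2L) %in% m$selected))
})

test_that("growth panels report rank correlation with permutation p-value", {
  ps <- cached_front("ferm-resp-net", 4)
  net <- cached_fixture("ferm-resp-net")
  panel <- make_synthetic_panel(ps, net, n_lines = 12, noise_sigma = 0,
                                seed = 4)
  truth <- setNames(panel$ground_truth$biomass,
                    panel$ground_truth$cell_line_id)
  res <- predict_growth_panel(ps, net, panel$profiles,
                              measured_growth = truth, n_perm = 200,
                              seed = 1)
  expect_equal(nrow(res$table), 12)
  expect_gt(res$spearman, 0.95)
  expect_lt(res$p_value, 0.05)
})

test_that("degenerate growth panels flag an undefined correlation", {
  ps <- cached_front("Y-net", 5)
  net <- cached_fixture("Y-net")
  panel <- make_synthetic_panel(ps, net, n_lines = 4, noise_sigma = 0,
                                seed = 1)
  prof <- panel$profiles[[1]]
  profs <- lapply(1:4, function(i) {
    p <- prof; p$cell_line_id <- paste0("L", i); p
  })
  g <- setNames(rep(1, 4), paste0("L", 1:4))
  expect_warning(
    res <- predict_growth_panel(ps, net, profs, measured_growth = g),
    "zero variance")
  expect_true(is.na(res$spearman))
})
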