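test_that("knockdowns tighten bounds through the GPR rules", {
  net <- cached_fixture("parallel-net")
  # residual activity 1 leaves the network untouched
  same <- apply_knockdown(net, "gA1", 1)
  expect_identical(same$reactions, net$reactions)
  # full knockout of a sole-gene reaction zeroes its bounds
  ko <- apply_knockdown(net, "gA1", 0)
  i <- which(ko$reactions$id == "CAT1A")
  expect_equal(ko$reactions$lower_bound[i], 0)
  expect_equal(ko$reactions$upper_bound[i], 0)
  # other reactions untouched
  j <- which(ko$reactions$id == "CAT1B")
  expect_equal(ko$reactions$upper_bound[j], net$reactions$upper_bound[j])
  # partial knockdown scales bounds
  kd <- apply_knockdown(net, "gA1", 0.5)
  expect_equal(kd$reactions$upper_bound[i], 0.5 * net$reactions$upper_bound[i])
  expect_error(apply_knockdown(net, "nope", 0), "unknown gene")
})

test_that("isozyme rules rescue single knockouts", {
  dir <- tempfile(); dir.create(dir)
  write.table(
    data.frame(reaction = c("EX_A", "BIOMASS", "ATPM"),
               equation = c("A -> ", "A -> atp", "atp -> "),
               lower_bound = c(-10, 0, 0), upper_bound = c(0, 100, 100),
               gpr = c("", "g1 or g2", "")),
    file.path(dir, "reactions.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  net <- load_model(dir)
  ko <- apply_knockdown(net, "g1", 0)
  expect_equal(ko$reactions$upper_bound[2], 100)   # rescued by g2
  ko2 <- apply_knockdown(net, c("g1", "g2"), 0)
  expect_equal(ko2$reactions$upper_bound[2], 0)    # joint knockout kills it
})

test_that("PDS is zero exactly on the sampled surface and matches hand geometry", {
  ps <- cached_front("Y-net", 5)
  for (i in seq_len(n_solutions(ps)))
    expect_equal(pds_score(ps$objectives[i, ], ps), 0)

  # two-objective front {(1,0), (0,1)}: the origin is at distance 1 of both
  front <- pareto_set(rbind(c(1, 0), c(0, 1)),
                      senses = c(a = "max", b = "max"))
  expect_equal(pds_score(c(a = 0, b = 0), front), 1)
  # and a point on the front scores 0
  expect_equal(pds_score(c(a = 1, b = 0), front), 0)
})

test_that("PDS of super-optimal points is still a non-negative distance", {
  front <- pareto_set(rbind(c(1, 0), c(0, 1)),
                      senses = c(a = "max", b = "max"))
  expect_message(d <- pds_score(c(a = 2, b = 2), front), "super-optimal")
  expect_equal(d, sqrt(5))
})

test_that("PDS equals the brute-force minimum-distance loop", {
  ps <- cached_front("parallel-net", 5)
  net <- cached_fixture("parallel-net")
  w <- cached_weights("parallel-net")
  V <- random_feasible(ps, 50, seed = 13)
  colnames(V) <- colnames(ps$fluxes)
  for (i in seq_len(nrow(V))) {
    pt <- evaluate_objectives(net, w, V[i, ])
    d <- pds_score(pt, ps)
    d0 <- oracle_pds(pt, ps)
    expect_equal(d, if (d0 < 1e-6) 0 else d0)
    expect_gte(d, 0)
  }
})

test_that("degenerate normalization ranges are dropped with a warning", {
  front <- pareto_set(rbind(c(1, 5, 0), c(0, 5, 1)),
                      senses = c(a = "max", b = "max", c = "min"))
  expect_warning(d <- pds_score(c(a = 0, b = 5, c = 0), front),
                 "degenerate")
  expect_equal(d, 1)
})

test_that("the essentiality screen separates pathway-bound genes from rescued ones", {
  net <- cached_fixture("Y-net")
  ps <- cached_front("Y-net", 5)
  m <- mixed_line(ps, net)$model
  sc <- gene_essentiality_screen(ps, net, list(m))
  ess <- setNames(sc$essential$essential, sc$essential$gene)
  # the single biomass path and both steps of the ATP path are essential
  expect_true(all(ess[c("gB", "gA1", "gA2")]))

  # knock_fraction 1 perturbs nothing: every PDS is zero
  sc1 <- gene_essentiality_screen(ps, net, list(m), knock_fraction = 1)
  expect_true(all(sc1$scores$pds == 0))
  expect_false(any(sc1$essential$essential))

  # in parallel-net the duplicated path step and the waste route are
  # nonessential, the shared downstream step is essential
  net2 <- cached_fixture("parallel-net")
  ps2 <- cached_front("parallel-net", 5)
  m2 <- mixed_line(ps2, net2)$model
  sc2 <- gene_essentiality_screen(ps2, net2, list(m2))
  ess2 <- setNames(sc2$essential$essential, sc2$essential$gene)
  expect_false(ess2[["gA1b"]])   # rescued by the duplicate
  expect_false(ess2[["gW"]])     # overflow route carries no flux
  expect_true(ess2[["gA2"]])     # no isozyme downstream
})

test_that("combinatorial knockouts reproduce the single-gene screen and exceed it jointly", {
  net <- cached_fixture("parallel-net")
  ps <- cached_front("parallel-net", 5)
  m <- mixed_line(ps, net)$model
  sc <- gene_essentiality_screen(ps, net, list(m), genes = c("gA1", "gA1b"))
  cp <- combinatorial_perturbation(ps, net, m,
                                   list("gA1", "gA1b", c("gA1", "gA1b")))
  # singletons agree with the screen
  expect_equal(cp$pds[1], sc$scores$pds[sc$scores$gene == "gA1"])
  expect_equal(cp$pds[2], sc$scores$pds[sc$scores$gene == "gA1b"])
  # the double knockout hurts strictly more than either single
  expect_gt(cp$pds[3], max(cp$pds[1:2]))
  # and set inclusion is monotone on this rescue-free pair
  expect_gte(cp$pds[3], max(cp$pds[1:2]) - 1e-6)
  expect_error(combinatorial_perturbation(ps, net, m, list(character(0))),
               "empty gene set")
})
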