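test_that("tabular models load with correct structure and validation", {
  # minimal 3-reaction, 2-metabolite model
  dir <- tempfile(); dir.create(dir)
  write.table(
    data.frame(reaction = c("EX_A", "BIOMASS", "ATPM"),
               equation = c("A -> ", "A -> atp", "atp -> "),
               lower_bound = c(-10, 0, 0), upper_bound = c(0, 1000, 1000),
               gpr = c("", "gB", "")),
    file.path(dir, "reactions.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  net <- load_model(dir)
  expect_s3_class(net, "metabolic_network")
  expect_equal(nrow(net$reactions), 3)
  expect_equal(nrow(net$metabolites), 2)
  expect_equal(net$biomass_reaction_id, "BIOMASS")
  expect_equal(net$atp_reaction_id, "ATPM")
  expect_true(net$reactions$is_exchange[net$reactions$id == "EX_A"])

  # lower_bound > upper_bound is rejected, naming the reaction
  bad <- file.path(dir, "reactions.tsv")
  rx <- read.delim(bad)
  rx$lower_bound[2] <- 5; rx$upper_bound[2] <- 1
  write.table(rx, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_model(dir), "BIOMASS")

  expect_error(load_model(tempfile()), "not found")
})

test_that("tabular write/load round-trips the stoichiometric matrix and bounds", {
  net <- cached_fixture("ferm-resp-net")
  dir <- tempfile()
  write_model(net, dir)
  net2 <- load_model(dir)
  S2 <- net2$stoichiometry[rownames(net$stoichiometry),
                           colnames(net$stoichiometry)]
  expect_equal(unname(net$stoichiometry), unname(S2))
  expect_equal(net$reactions$lower_bound, net2$reactions$lower_bound)
  expect_equal(net$reactions$upper_bound, net2$reactions$upper_bound)
  expect_equal(net$genes, net2$genes)
  expect_equal(net$metabolites$formula[order(net$metabolites$id)],
               net2$metabolites$formula[order(net2$metabolites$id)])
})

test_that("SBML reader recovers species, bounds, formulas and GPR rules", {
  net <- read_sbml(tiny_sbml())
  expect_equal(nrow(net$reactions), 4)
  expect_equal(sort(net$genes), c("g1", "g2", "gB1", "gB2"))
  ex <- net$reactions[net$reactions$id == "EX_glc", ]
  expect_equal(ex$lower_bound, -10)
  expect_equal(ex$upper_bound, 0)
  expect_true(ex$is_exchange)
  expect_equal(net$metabolites$formula[net$metabolites$id == "glc_e"],
               "C6H12O6")
  # complex (and) and isozyme (or) associations survive the round trip
  expect_equal(sort(gpr_genes(net$gpr_ast[["GLY"]])), c("g1", "g2"))
  expect_equal(evaluate_gpr(net$gpr_ast[["GLY"]], c(g1 = 0.3, g2 = 1)), 0.3)
  expect_equal(evaluate_gpr(net$gpr_ast[["BIOMASS"]],
                            c(gB1 = 0, gB2 = 0.8)), 0.8)
  # the loaded model is solvable
  objs <- build_objectives(net, suppressWarnings(objective_weights(net)))
  fc <- fba_solve(net, objs$biomass)
  expect_equal(fc$objective_value, 10)
})

test_that("count_genes counts distinct GPR-referenced genes", {
  dir <- tempfile(); dir.create(dir)
  write.table(
    data.frame(reaction = c("EX_A", "R1", "BIOMASS", "ATPM"),
               equation = c("A -> ", "A -> B", "B -> atp", "atp -> "),
               lower_bound = c(-1, 0, 0, 0), upper_bound = c(0, 1, 1, 1),
               gpr = c("", "g1", "g1 or g2", "")),
    file.path(dir, "reactions.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  expect_equal(count_genes(load_model(dir)), 2)

  rx <- read.delim(file.path(dir, "reactions.tsv"))
  rx$gpr <- ""
  write.table(rx, file.path(dir, "reactions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_equal(count_genes(load_model(dir)), 0)
})

test_that("GPR evaluation uses min for complexes and max for isozymes", {
  expect_equal(evaluate_gpr("g1 and g2", c(g1 = 0, g2 = 1)), 0)
  expect_equal(evaluate_gpr("g1 or g2", c(g1 = 0, g2 = 1)), 1)
  expect_equal(
    evaluate_gpr("(g1 and g2) or g3", c(g1 = 1, g2 = 0.5, g3 = 0.2)), 0.5)
  expect_equal(evaluate_gpr(NULL, c(g1 = 0)), 1)
  expect_equal(evaluate_gpr("", c(g1 = 0)), 1)
  expect_error(evaluate_gpr("g1 and gX", c(g1 = 1)), "unknown gene")
  expect_error(parse_gpr("g1 and (g2"), "parse error")
  expect_error(parse_gpr("g1 g2"), "parse error")
})

test_that("GPR evaluation is monotone in every gene's activity", {
  rules <- c("g1", "g1 and g2", "g1 or g2", "(g1 and g2) or (g3 and g4)",
             "g1 and (g2 or g3) and g4")
  set.seed(5)
  for (rule in rules) {
    ast <- parse_gpr(rule)
    genes <- gpr_genes(ast)
    for (rep in 1:20) {
      act <- setNames(runif(length(genes)), genes)
      base <- evaluate_gpr(ast, act)
      g <- sample(genes, 1)
      act2 <- act
      act2[g] <- min(1, act[g] + runif(1, 0, 1 - act[g]))
      expect_gte(evaluate_gpr(ast, act2), base)
    }
  }
})

test_that("carbon counting parses formulas and is additive", {
  expect_equal(carbon_content("C6H12O6"), 6)
  expect_equal(carbon_content("H2O"), 0)
  expect_equal(carbon_content("C63H88CoN14O14P"), 63)
  expect_warning(z <- carbon_content(""), "empty formula")
  expect_equal(z, 0)
  expect_error(carbon_content("C6H12O6!"), "malformed")
  expect_error(carbon_content("c6"), "malformed")
  # additivity over concatenation
  set.seed(2)
  pool <- c("C6H12O6", "C3H6O3", "CO2", "H2O", "C63H88CoN14O14P", "O2")
  for (rep in 1:10) {
    f1 <- sample(pool, 1); f2 <- sample(pool, 1)
    expect_equal(carbon_content(paste0(f1, f2)),
                 carbon_content(f1) + carbon_content(f2))
  }
})

test_that("validation reports exchange reactions touching several metabolites", {
  net <- cached_fixture("Y-net")
  net$reactions$is_exchange[net$reactions$id == "CAT2"] <- TRUE
  expect_match(paste(validate_network(net), collapse = "; "), "CAT2")
})
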