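test_that("FBA solves bound-limited and infeasible problems on the linear chain", {
  net <- cached_fixture("chain-net")
  objs <- build_objectives(net, cached_weights("chain-net"))
  fc <- fba_solve(net, objs$biomass)
  expect_equal(fc$status, "optimal")
  expect_equal(fc$objective_value, 10)
  expect_equal(unname(fc$flux["EX_glc"]), -10)
  expect_true(is_feasible_flux(net, fc))

  inf <- fba_solve(net, objs$biomass,
                   list(flux_constraint(c(BIOMASS = 1), ">=", 11)))
  expect_equal(inf$status, "infeasible")
})

test_that("FBA resolves the Y-net biomass/ATP trade-off", {
  net <- cached_fixture("Y-net")
  objs <- build_objectives(net, cached_weights("Y-net"))
  fc <- fba_solve(net, objs$atp,
                  list(flux_constraint(c(BIOMASS = 1), ">=", 5)))
  expect_equal(fc$objective_value, 10)
  expect_equal(unname(fc$flux["BIOMASS"]), 5)
  expect_equal(unname(fc$flux["CAT1"]), 5)
})

test_that("reported FBA objective equals the functional evaluated on the flux", {
  for (nm in c("chain-net", "Y-net", "parallel-net")) {
    net <- cached_fixture(nm)
    objs <- build_objectives(net, cached_weights(nm))
    for (obj in objs) {
      fc <- fba_solve(net, obj)
      expect_equal(fc$status, "optimal")
      expect_equal(fc$objective_value, evaluate_functional(obj, fc),
                   tolerance = 1e-9)
    }
  }
})

test_that("MOMA returns the reference when it stays feasible", {
  net <- cached_fixture("Y-net")
  ref <- c(EX_glc = -10, BIOMASS = 5, CAT1 = 5, CAT2 = 5, ATPM = 10)
  fc <- moma_solve(net, ref)
  expect_equal(fc$status, "optimal")
  expect_equal(fc$flux, ref, tolerance = 1e-7)
  expect_equal(fc$objective_value, 0, tolerance = 1e-10)
})

test_that("MOMA matches the closed-form projection when biomass is blocked", {
  # reference splits uptake (5, 5); blocking the biomass path leaves one
  # degree of freedom C = CAT1 flux; minimizing
  # (10-C)^2 + 25 + 2 (C-5)^2 + (2C-10)^2 gives C = 40/7
  net <- cached_fixture("Y-net")
  net$reactions$upper_bound[net$reactions$id == "BIOMASS"] <- 0
  ref <- c(EX_glc = -10, BIOMASS = 5, CAT1 = 5, CAT2 = 5, ATPM = 10)
  fc <- moma_solve(net, ref)
  expect_equal(fc$status, "optimal")
  expect_equal(unname(fc$flux["CAT1"]), 40 / 7, tolerance = 1e-7)
  expect_equal(unname(fc$flux["BIOMASS"]), 0)
  expect_equal(unname(fc$flux["ATPM"]), 80 / 7, tolerance = 1e-7)
  expect_equal(fc$objective_value, 1050 / 49 + 25, tolerance = 1e-7)
})

test_that("MOMA with all-zero bounds and zero reference returns zero flux", {
  net <- cached_fixture("Y-net")
  net$reactions$lower_bound[] <- 0
  net$reactions$upper_bound[] <- 0
  ref <- setNames(rep(0, nrow(net$reactions)), net$reactions$id)
  fc <- moma_solve(net, ref)
  expect_equal(fc$status, "optimal")
  expect_equal(unname(fc$objective_value), 0)
  expect_true(all(fc$flux == 0))
})

test_that("MOMA reports infeasibility when the constraint set is empty", {
  net <- cached_fixture("Y-net")
  # demand ATP maintenance but block all ATP production
  net$reactions$lower_bound[net$reactions$id == "ATPM"] <- 5
  net$reactions$upper_bound[net$reactions$id == "CAT2"] <- 0
  ref <- c(EX_glc = -10, BIOMASS = 5, CAT1 = 5, CAT2 = 5, ATPM = 10)
  fc <- moma_solve(net, ref)
  expect_equal(fc$status, "infeasible")
})

test_that("MOMA scales homogeneously with bounds and reference", {
  net <- cached_fixture("Y-net")
  net$reactions$upper_bound[net$reactions$id == "BIOMASS"] <- 2
  ref <- c(EX_glc = -10, BIOMASS = 5, CAT1 = 5, CAT2 = 5, ATPM = 10)
  f1 <- moma_solve(net, ref)
  k <- 3
  net2 <- net
  net2$reactions$lower_bound <- k * net$reactions$lower_bound
  net2$reactions$upper_bound <- k * net$reactions$upper_bound
  f2 <- moma_solve(net2, k * ref)
  expect_equal(f2$flux, k * f1$flux, tolerance = 1e-6)
  expect_equal(f2$objective_value, k^2 * f1$objective_value,
               tolerance = 1e-6)
})

test_that("MOMA distance is zero exactly when the reference is feasible", {
  net <- cached_fixture("parallel-net")
  ps <- cached_front("parallel-net", 5)
  set.seed(7)
  for (v in asplit(random_feasible(ps, 5, seed = 7), 1)) {
    fc <- moma_solve(net, v)
    expect_equal(fc$objective_value, 0, tolerance = 1e-8)
  }
  # an infeasible reference (violates uptake bound) has positive distance
  bad <- c(EX_glc = -20, BIOMASS = 10, CAT1A = 10, CAT1B = 0, CAT2 = 10,
           ATPM = 20, WASTE = 0, EX_waste = 0)
  fc <- moma_solve(net, bad)
  expect_gt(fc$objective_value, 1e-3)
})
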