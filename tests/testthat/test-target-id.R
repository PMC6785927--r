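# hand-made Pareto sets with known projection geometry ---------------------

# front whose BIOMASS flux IS the phenotype (identity projection for gB) and
# whose CAT fluxes are phenotype-independent noise in [0, cap]
identity_set <- function(n = 60, cap = 4, seed = 1) {
  set.seed(seed)
  b <- seq(0.5, 10, length.out = n)
  free <- runif(n, 0, cap)
  fl <- cbind(EX_glc = -(b + free), BIOMASS = b, CAT1 = free, CAT2 = free,
              ATPM = 2 * free)
  obj <- cbind(biomass = b, atp = 2 * free, enzyme_cost = b + 2 * free,
               carbon_uptake = 6 * (b + free))
  pareto_set(obj, fl)
}

test_that("the in-silico Warburg metric is the lactate/oxygen flux ratio", {
  net <- cached_fixture("ferm-resp-net")
  v <- setNames(rep(0, nrow(net$reactions)), net$reactions$id)
  v["EX_lac"] <- 10; v["EX_o2"] <- -5
  expect_equal(as.numeric(warburg_metric(net, v)), 2)
  v["EX_lac"] <- 0
  expect_equal(as.numeric(warburg_metric(net, v)), 0)
  # anaerobic limit is capped and flagged
  v["EX_lac"] <- 10; v["EX_o2"] <- 0
  m <- warburg_metric(net, v, ceiling = 500)
  expect_equal(as.numeric(m), 500)
  expect_true(isTRUE(attr(m, "capped")))
  # a model without lactate exchange cannot be scored
  expect_error(warburg_metric(cached_fixture("Y-net"),
                              setNames(rep(0, 5),
                                       cached_fixture("Y-net")$reactions$id)),
               "configuration error")
})

test_that("projections of deterministic fluxes give coinciding envelopes", {
  ps <- identity_set()
  net <- cached_fixture("Y-net")
  pr <- project(ps, net, "growth", "gB", n_bins = 10)
  # flux == phenotype: each bin's envelopes sit exactly on its phenotype
  # range, so the projected band is the identity line
  expect_equal(pr$bins$lower, pr$bins$lo_ph)
  expect_equal(pr$bins$upper, pr$bins$hi_ph)
  expect_equal(monotonousness(pr, "lower"), 1)
  expect_equal(monotonousness(pr, "upper"), 1)
  # every projected point lies within its bin's envelopes
  expect_true(all(pr$points$flux >= pr$bins$lower[pr$points$bin] - 1e-12))
  expect_true(all(pr$points$flux <= pr$bins$upper[pr$points$bin] + 1e-12))
})

test_that("phenotype-independent fluxes give flat envelopes and no call", {
  ps <- identity_set(n = 200, cap = 4)
  net <- cached_fixture("Y-net")
  pr <- project(ps, net, "growth", "gA1", n_bins = 10)
  # envelopes hug 0 and the cap; monotonousness is ~0
  expect_lt(max(abs(pr$bins$lower)), 1)
  expect_gt(min(pr$bins$upper), 2.5)
  expect_lt(abs(suppressMessages(monotonousness(pr, "upper"))), 0.5)
})

test_that("monotonousness scores monotone, constant and noisy envelopes", {
  mk <- function(env) {
    # minimal synthetic projection object
    n <- length(env)
    structure(list(
      bins = data.frame(center = seq_len(n), lower = env, upper = env,
                        lo_ph = seq_len(n), hi_ph = seq_len(n),
                        lower_ph = seq_len(n), upper_ph = seq_len(n),
                        n = rep(1, n)),
      points = data.frame(phenotype = seq_len(n), flux = env,
                          bin = seq_len(n)),
      phenotype = "growth", target = "x"), class = "surface_projection")
  }
  expect_equal(monotonousness(mk(1:12), "lower"), 1)
  expect_equal(monotonousness(mk(12:1), "upper"), -1)
  expect_message(z <- monotonousness(mk(rep(2, 8)), "upper"), "constant")
  expect_equal(z, 0)
  set.seed(8)
  noise <- sapply(1:30, function(i) monotonousness(mk(rnorm(25)), "upper"))
  expect_lt(abs(mean(noise)), 0.15)
  expect_error(monotonousness(mk(c(1, 2)), "upper"), "insufficient")
})

test_that("boundary proximity is 1 on the envelope and 0 mid-band", {
  # band: half the solutions on the lower rim, half on the upper rim
  set.seed(4)
  n <- 80
  b <- rep(seq(1, 10, length.out = n / 2), 2)
  rim <- rep(c(0, 4), each = n / 2)
  fl <- cbind(EX_glc = -(b + rim), BIOMASS = b, CAT1 = rim, CAT2 = rim,
              ATPM = 2 * rim)
  obj <- cbind(biomass = b, atp = 2 * rim, enzyme_cost = b + 2 * rim,
               carbon_uptake = 6 * (b + rim))
  ps <- pareto_set(obj, fl)
  net <- cached_fixture("Y-net")
  pr <- project(ps, net, "growth", "gA1", n_bins = 8)
  upper_lines <- lapply(which(rim == 4)[1:5], function(i)
    structure(list(cell_line_id = "u", representative = i),
              class = "cell_line_model"))
  lower_lines <- lapply(which(rim == 0)[1:5], function(i)
    structure(list(cell_line_id = "l", representative = i),
              class = "cell_line_model"))
  expect_equal(boundary_proximity(pr, ps, net, upper_lines, "upper"), 1)
  expect_equal(boundary_proximity(pr, ps, net, lower_lines, "lower"), 1)
  expect_equal(boundary_proximity(pr, ps, net, upper_lines, "lower"), 0)
  expect_equal(boundary_proximity(pr, ps, net, upper_lines, "either"), 1)

  # mid-band points are close to neither envelope
  mid <- fl[1:5, ]; mid[, "CAT1"] <- 2; mid[, "CAT2"] <- 2
  ps_mid <- pareto_set(rbind(obj, obj[1:5, ]), rbind(fl, mid))
  mid_lines <- lapply(n + 1:5, function(i)
    structure(list(cell_line_id = "m", representative = i),
              class = "cell_line_model"))
  pr2 <- project(ps_mid, net, "growth", "gA1", n_bins = 8)
  expect_equal(boundary_proximity(pr2, ps_mid, net, mid_lines, "either",
                                  tol = 0.2), 0)
})

test_that("classification recovers the designed Y-net geometry", {
  net <- cached_fixture("Y-net")
  ps <- cached_front("Y-net", 6)
  panel <- make_synthetic_panel(ps, net, n_lines = 12, noise_sigma = 0.05,
                                seed = 1)
  models <- lapply(panel$profiles, function(p) fit_cell_line(ps, net, p))
  calls <- suppressMessages(
    classify_targets(ps, net, models, phenotypes = "growth"))
  gb <- calls[calls$enzyme == "gB", ]
  expect_equal(gb$direction, "promoting")
  expect_equal(gb$mono_lower, 1)
})

test_that("enzymes on an isolated futile cycle get no call", {
  dir <- tempfile(); dir.create(dir)
  write.table(
    data.frame(
      reaction = c("EX_A", "BIOMASS", "CAT", "ATPM", "CYC1", "CYC2"),
      equation = c("A -> ", "A -> ", "A -> 2 atp", "atp -> ",
                   "X -> Y", "Y -> X"),
      lower_bound = c(-10, 0, 0, 0, 0, 0),
      upper_bound = c(0, 1e3, 1e3, 1e3, 5, 5),
      gpr = c("", "gB", "gC", "", "gF1", "gF2")),
    file.path(dir, "reactions.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  net <- load_model(dir)
  w <- suppressWarnings(objective_weights(net))
  ps <- epsilon_constraint_sample(net, w, grid_spec(5))
  panel <- make_synthetic_panel(ps, net, n_lines = 8, noise_sigma = 0.05,
                                seed = 1)
  models <- lapply(panel$profiles, function(p)
    fit_cell_line(ps, net, p, min_shared = 2))
  calls <- suppressMessages(
    classify_targets(ps, net, models, enzymes = "gF1",
                     phenotypes = "growth"))
  expect_equal(calls$direction, "none")
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.05, 6)), rep(0.05, 6))
  expect_error(bh_adjust(c(0.5, 1.2)), "must be in")
  expect_error(bh_adjust(c(0.5, NA)), "must be in")
  # ten-element vector, adjusted by hand with the step-up rule
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.060, 0.074, 0.205, 0.212,
         0.216)
  expect_equal(bh_adjust(p),
               c(0.01, 0.04, 0.084, 0.084, 0.084, 0.1, 0.074 * 10 / 7,
                 0.216, 0.216, 0.216))
  # adjusted values are monotone after sorting by raw p
  expect_true(!is.unsorted(bh_adjust(p)))
})

test_that("category overlaps include the ambiguous class structure", {
  calls <- data.frame(
    enzyme = c("e1", "e1", "e2", "e3", "e3"),
    phenotype = c("growth", "warburg", "growth", "growth", "warburg"),
    direction = c("promoting", "suppressing", "suppressing", "promoting",
                  "promoting"),
    stringsAsFactors = FALSE)
  ov <- target_overlap(calls)
  expect_equal(ov$ambiguous, "e1")
  expect_equal(ov$overlap["growth_promoting", "warburg_suppressing"], 1)
  expect_equal(ov$overlap["growth_promoting", "growth_promoting"], 2)
  expect_equal(sort(ov$categories$growth_promoting), c("e1", "e3"))
})
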