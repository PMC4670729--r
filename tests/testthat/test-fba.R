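# Flux balance analysis on the toy glucose-to-glycerol network.

test_that("the bundled toy model loads with the expected dimensions", {
  path <- system.file("extdata", "toy_glycerol.json", package = "growthswitch")
  m <- suppressMessages(readMetabolicModel(
    path, glucose = "EX_glc", product = "EX_gly", oxygen = "EX_o2",
    maintenance = "NGAM", biomass = "BIOS"))
  expect_equal(length(m@metabolites), 7L)
  expect_equal(length(m@reactions), 9L)
  ref <- toyGlycerolModel()
  expect_equal(m@S, ref@S)
  expect_equal(m@lb, ref@lb)
  expect_equal(m@ub, ref@ub)
})

test_that("the SBML reader agrees with the JSON reader on the toy network", {
  xml <- system.file("extdata", "toy_glycerol.xml", package = "growthswitch")
  m <- suppressMessages(readMetabolicModel(
    xml, glucose = "EX_glc", product = "EX_gly", oxygen = "EX_o2",
    maintenance = "NGAM", biomass = "BIOS"))
  ref <- toyGlycerolModel()
  # SBML writes exchanges as consumption-only reactants: same stoichiometry
  expect_equal(m@S[rownames(ref@S), colnames(ref@S)], ref@S)
  expect_equal(m@lb, ref@lb)
  expect_equal(m@ub, ref@ub)
})

test_that("model JSON round-trips identically", {
  ref <- toyGlycerolModel()
  tmp <- tempfile(fileext = ".json")
  writeModelJSON(ref, tmp)
  m <- suppressMessages(readMetabolicModel(
    tmp, glucose = "EX_glc", product = "EX_gly", oxygen = "EX_o2",
    maintenance = "NGAM", biomass = "BIOS"))
  expect_identical(m@S, ref@S)
  expect_identical(m@lb, ref@lb)
  expect_identical(m@ub, ref@ub)
})

test_that("missing designated reactions are a configuration error", {
  path <- system.file("extdata", "toy_glycerol.json", package = "growthswitch")
  expect_error(suppressMessages(readMetabolicModel(path)),
               "not found")
  tmp <- tempfile(fileext = ".json")
  writeLines("{ not json", tmp)
  expect_error(suppressMessages(readMetabolicModel(tmp)), "malformed")
})

test_that("the reference constraints are applied and idempotent", {
  m1 <- applyYieldConstraints(toyGlycerolModel())
  g <- match("EX_glc", m1@reactions)
  expect_identical(c(m1@lb[g], m1@ub[g]), c(-1, -1))
  n <- match("NGAM", m1@reactions)
  expect_identical(c(m1@lb[n], m1@ub[n]), c(6.75, 6.75))
  o <- match("EX_o2", m1@reactions)
  expect_true(m1@lb[o] <= -1e5 && m1@ub[o] >= 1e5)
  m2 <- applyYieldConstraints(m1)
  expect_identical(m1@S, m2@S)
  expect_identical(m1@lb, m2@lb)
  expect_identical(m1@ub, m2@ub)
})

test_that("the unconstrained network converts all carbon: hand-solved optimum", {
  m <- toyGlycerolModel()
  g <- match("EX_glc", m@reactions)
  m@lb[g] <- -1; m@ub[g] <- -1
  res <- maximizeProductYield(m)
  expect_equal(res@objective_flux, 2, tolerance = 1e-9)
  expect_equal(res@mass_yield, 2 * 92.09 / 180.16, tolerance = 1e-9)
  expect_equal(res@mass_yield, 1.0224, tolerance = 1e-4)
})

test_that("the maintenance constraint diverts half a triose to oxidation", {
  m <- applyYieldConstraints(toyGlycerolModel())
  res <- maximizeProductYield(m)
  expect_equal(res@objective_flux, 1.5, tolerance = 1e-9)
  expect_equal(unname(res@fluxes["OXI"]), 0.5, tolerance = 1e-9)
  # vertex-enumeration oracle over the bounded polytope
  obj <- numeric(9); obj[match("EX_gly", m@reactions)] <- 1
  lb <- m@lb; ub <- m@ub
  lb[match("EX_o2", m@reactions)] <- -100   # finite box for enumeration
  ub[ub > 100] <- 100
  best <- vertexEnumerationMax(obj, m@S, lb, ub)
  expect_equal(res@objective_flux, best, tolerance = 1e-8)
})

test_that("solutions satisfy steady state and bounds", {
  m <- applyYieldConstraints(toyGlycerolModel())
  res <- maximizeProductYield(m)
  expect_lt(max(abs(m@S %*% res@fluxes)), 1e-8)
  expect_true(all(res@fluxes >= m@lb - 1e-9))
  expect_true(all(res@fluxes <= m@ub + 1e-9))
})

test_that("the optimum is invariant under metabolite permutation", {
  m <- applyYieldConstraints(toyGlycerolModel())
  set.seed(2)
  perm <- sample(length(m@metabolites))
  mp <- MetabolicModel(m@metabolites[perm], m@reactions,
                       m@S[perm, , drop = FALSE], m@lb, m@ub,
                       glucose = "EX_glc", product = "EX_gly",
                       oxygen = "EX_o2", maintenance = "NGAM")
  expect_equal(maximizeProductYield(mp)@objective_flux,
               maximizeProductYield(m)@objective_flux, tolerance = 1e-9)
})

test_that("non-binding bounds do not move the optimum; the homogeneous LP is linear", {
  m <- applyYieldConstraints(toyGlycerolModel())
  base <- maximizeProductYield(m)@objective_flux
  m2 <- m
  j <- match("GLK", m2@reactions)
  m2@ub[j] <- 1e6                       # relax a non-binding bound
  expect_equal(maximizeProductYield(m2)@objective_flux, base,
               tolerance = 1e-9)
  # with maintenance released the LP is homogeneous: halving the uptake
  # exactly halves the product flux
  relax <- function(uptake) {
    m3 <- toyGlycerolModel()
    g <- match("EX_glc", m3@reactions)
    m3@lb[g] <- uptake; m3@ub[g] <- uptake
    maximizeProductYield(m3)@objective_flux
  }
  expect_equal(relax(-0.5), relax(-1) / 2, tolerance = 1e-9)
})

test_that("infeasible and unbounded problems are reported as such", {
  m <- applyYieldConstraints(toyGlycerolModel())
  o <- match("EX_o2", m@reactions)
  m@lb[o] <- 0; m@ub[o] <- 0   # no oxygen: maintenance ATP cannot be made
  expect_error(maximizeProductYield(m), "no steady-state")
  # a free two-reaction cycle is unbounded
  S <- matrix(c(1, -1), 1, 2, dimnames = list("A", c("r1", "r2")))
  cyc <- MetabolicModel("A", c("r1", "r2"), S, lb = c(-Inf, -Inf),
                        ub = c(Inf, Inf), glucose = "r1", product = "r2",
                        oxygen = "r1", maintenance = "r1")
  expect_error(maximizeProductYield(cyc, product = "r2"), "unbounded")
})
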