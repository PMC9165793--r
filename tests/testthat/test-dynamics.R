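test_that("chemical potential follows u = RT ln(Kq q)", {
  expect_identical(chemicalPotential(1, 1, ctx1), 0)
  expect_equal(chemicalPotential(2, 3, ctx1), log(6))
  ctx <- thermoContext()  # 310 K default
  expect_equal(chemicalPotential(2, 3, ctx), ctx@RT * log(6))
  expect_error(chemicalPotential(1, 0, ctx1), "undefined")
  expect_error(chemicalPotential(-1, 1, ctx1), "positive")
})

test_that("reaction flux matches the hand-evaluated mass-action form", {
  r <- reactionComponent("r", c(A = 1), c(B = 1), kappa = 1)
  expect_equal(reactionFlux(r, c(A = 3, B = 1), c(A = 2, B = 1)), 5)

  # kappa = 2; 2A + B -> C + D
  r2 <- reactionComponent("r2", c(A = 2, B = 1), c(C = 1, D = 1), kappa = 2)
  expect_equal(
    reactionFlux(r2, c(A = 2, B = 1, C = 4, D = 1),
                 c(A = 1, B = 3, C = 1, D = 1)),
    2 * ((1 * 2)^2 * 3 - 4))

  # equilibrium: equal activity products give zero flux
  expect_equal(reactionFlux(r, c(A = 1, B = 2), c(A = 2, B = 1)), 0)

  expect_error(reactionFlux(r, c(A = 1), c(A = 1, B = 1)), "missing amount")
  expect_error(reactionFlux(r, c(A = 1, B = 1), c(A = 1)), "missing Kq")
})

test_that("flux equals the Marcelin-de Donder exponential-potential form", {
  # v = kappa*(exp(ur/RT) - exp(up/RT)) with ur/up total side potentials
  net <- makeTwoSided(alpha = 2, beta = 3)
  r <- net@reactions[[1]]
  Kq <- setNames(vapply(net@species, function(s) s@Kq, 0), speciesNames(net))
  for (seed in 1:5) {
    st <- randomState(net, seed)
    ur <- sum(r@reactants * chemicalPotential(Kq[names(r@reactants)],
                                              st[names(r@reactants)], ctx1))
    up <- sum(r@products * chemicalPotential(Kq[names(r@products)],
                                             st[names(r@products)], ctx1))
    expect_equal(reactionFlux(r, st, Kq),
                 r@kappa * (exp(ur / ctx1@RT) - exp(up / ctx1@RT)),
                 tolerance = 1e-12)
  }
})

test_that("assembled rates equal the brute-force stoichiometric oracle", {
  for (seed in 1:20) {
    fx <- randomConsistentNetwork(sample(3:8, 1), sample(2:6, 1),
                                  seed = 1000 + seed)
    sys <- assembleODEs(fx$network)
    for (k in 1:10) {
      st <- randomState(fx$network, seed * 100 + k)
      got <- sys@rate(st)
      want <- oracleRates(fx$network, st)
      expect_equal(got, want[names(got)], tolerance = 1e-12)
    }
  }
})

test_that("flow balance at a shared junction is the signed flux sum", {
  # species C produced by reaction 1 and consumed by reaction 2
  net <- buildNetwork(
    list(speciesComponent("A", 1, 2), speciesComponent("C", 1, 0),
         speciesComponent("B", 1, 0)),
    list(reactionComponent("r1", c(A = 1), c(C = 1), kappa = 1),
         reactionComponent("r2", c(C = 1), c(B = 1), kappa = 2)),
    ctx1)
  sys <- assembleODEs(net)
  st <- c(A = 0.7, C = 1.3, B = 0.2)
  v <- sys@flux(st)
  expect_equal(unname(sys@rate(st)["C"]), unname(v["r1"] - v["r2"]))
  # closed A <-> B: moiety (1, 1)
  ab <- assembleODEs(makeAB())
  expect_equal(ncol(ab@conservedMoieties), 1)
  m <- ab@conservedMoieties[, 1]
  expect_equal(m[["A"]], m[["B"]], tolerance = 1e-12)
})

test_that("unparameterised components are reported by name", {
  net <- buildNetwork(
    list(speciesComponent("A", 1, 1), speciesComponent("B")),
    list(reactionComponent("r", c(A = 1), c(B = 1))), ctx1)
  expect_error(assembleODEs(net), "species 'B'")
  expect_error(assembleODEs(net), "reaction 'r'")
})

test_that("simulation conserves moieties and reaches known equilibria", {
  # equal constants: symmetric equilibrium and exact mass conservation
  sys <- assembleODEs(makeAB(qA = 2, qB = 0))
  traj <- simulateODE(sys, tMax = 50)
  expect_equal(unname(rowSums(traj@states)), rep(2, length(traj@times)),
               tolerance = 1e-6)
  end <- traj@states[nrow(traj@states), ]
  expect_equal(unname(end), c(1, 1), tolerance = 1e-6)

  # unequal constants: equilibrium from KA qA = KB qB with qA + qB = 4
  ss <- steadyState(assembleODEs(makeAB(KA = 1, KB = 3, qA = 4, qB = 0)))
  expect_equal(unname(ss[c("A", "B")]), c(3, 1), tolerance = 1e-6)
})

test_that("steady state returns a fixed point unchanged and honours chemostats", {
  ss <- steadyState(assembleODEs(makeAB()), q0 = c(A = 1, B = 1))
  expect_equal(unname(ss[c("A", "B")]), c(1, 1))
  expect_equal(attr(ss, "time"), 0)

  # open system: chemostats at both ends drive a nonzero steady flux
  open <- buildNetwork(
    list(speciesComponent("S", 1, 5, chemostat = TRUE),
         speciesComponent("X", 1, 0),
         speciesComponent("P", 1, 1, chemostat = TRUE)),
    list(reactionComponent("r1", c(S = 1), c(X = 1), kappa = 1),
         reactionComponent("r2", c(X = 1), c(P = 1), kappa = 1)), ctx1)
  sys <- assembleODEs(open)
  ss <- steadyState(sys)
  expect_equal(unname(ss["S"]), 5)  # chemostat untouched
  expect_gt(abs(sys@flux(ss)[["r1"]]), 0.1)
  expect_lt(max(abs(sys@rate(ss))), 1e-9 * max(1, max(abs(ss))))
})

test_that("every flux dissipates: v has the sign of the affinity", {
  for (seed in 1:10) {
    fx <- randomConsistentNetwork(sample(3:6, 1), sample(2:5, 1),
                                  seed = 500 + seed)
    net <- fx$network
    sys <- assembleODEs(net)
    Kq <- setNames(vapply(net@species, function(s) s@Kq, 0),
                   speciesNames(net))
    for (k in 1:10) {
      st <- randomState(net, seed * 77 + k)
      for (r in net@reactions) {
        ur <- sum(r@reactants * log(Kq[names(r@reactants)] *
                                      st[names(r@reactants)]))
        up <- sum(r@products * log(Kq[names(r@products)] *
                                     st[names(r@products)]))
        v <- reactionFlux(r, st, Kq)
        expect_gte(v * (ur - up), 0)
      }
    }
  }
})

test_that("closed networks equilibrate with zero flux in every loop", {
  # a triangle of reactions parameterised thermodynamically must reach
  # detailed balance: every individual flux vanishes
  tri <- buildNetwork(
    list(speciesComponent("A", 2, 3), speciesComponent("B", 0.5, 1),
         speciesComponent("C", 1.5, 0.2)),
    list(reactionComponent("rAB", c(A = 1), c(B = 1), kappa = 1),
         reactionComponent("rBC", c(B = 1), c(C = 1), kappa = 0.3),
         reactionComponent("rCA", c(C = 1), c(A = 1), kappa = 2)), ctx1)
  sys <- assembleODEs(tri)
  ss <- steadyState(sys, tol = 1e-12)
  expect_lt(max(abs(sys@flux(ss))), 1e-9)
  for (seed in 1:5) {
    fx <- randomConsistentNetwork(4, 3, seed = 900 + seed)
    sys <- assembleODEs(fx$network)
    ss <- steadyState(sys, tol = 1e-12)
    expect_lt(max(abs(sys@flux(ss))), 1e-9)
  }
})

test_that("trajectory export and equation listing are well formed", {
  sys <- assembleODEs(makeAB())
  traj <- simulateODE(sys, tMax = 1)
  path <- tempfile(fileext = ".csv")
  writeTrajectoryCSV(traj, path, fluxes = TRUE)
  tab <- read.csv(path)
  expect_identical(names(tab), c("time", "A", "B", "v_r1"))
  expect_equal(nrow(tab), length(traj@times))
  listing <- odeListing(sys)
  expect_true(any(grepl("dq_A/dt = -v_r1", listing, fixed = TRUE)))
  expect_true(any(grepl("dq_B/dt = \\+?v_r1", listing)))
})
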