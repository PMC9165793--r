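test_that("log-linear system has two rows per reaction and gauge absorbs fixed species", {
  ab <- kineticReaction("r1", c(A = 1), c(B = 1), kPlus = 2, kMinus = 1)
  sys <- buildLogLinearSystem(list(ab))
  expect_equal(dim(sys$A), c(2L, 3L))
  expect_setequal(sys$unknowns, c("kappa:r1", "Kq:A", "Kq:B"))

  sysFixed <- buildLogLinearSystem(list(ab), fixed = c(A = 1))
  expect_equal(dim(sysFixed$A), c(2L, 2L))
  expect_equal(sysFixed$b, c(log(2), log(1)))

  triangle <- list(
    kineticReaction("rAB", c(A = 1), c(B = 1), kPlus = 1, kMinus = 2),
    kineticReaction("rBC", c(B = 1), c(C = 1), kPlus = 3, kMinus = 1),
    kineticReaction("rCA", c(C = 1), c(A = 1), kPlus = 1, kMinus = 1))
  sys3 <- buildLogLinearSystem(triangle)
  expect_equal(dim(sys3$A), c(6L, 6L))  # 3 kappa + 3 Kq unknowns

  expect_warning(buildLogLinearSystem(list(ab), fixed = c(Z = 1)),
                 "not in any reaction")
  expect_error(buildLogLinearSystem(list(
    kineticReaction("bad", c(A = 1), c(B = 1), kPlus = 1)), numeric()),
    "approximate it first")
})

test_that("solving recovers the hand-solved A<->B conversion", {
  ab <- kineticReaction("r1", c(A = 1), c(B = 1), kPlus = 2, kMinus = 1)
  res <- solveParameters(buildLogLinearSystem(list(ab), fixed = c(A = 1)))
  expect_equal(unname(res@kappa[["r1"]]), 2, tolerance = 1e-12)
  expect_equal(unname(res@Kq[["B"]]), 0.5, tolerance = 1e-12)
  expect_lt(res@residual, 1e-20)
  expect_true(res@consistent)
})

test_that("consistent loops are exactly solvable, inconsistent ones are flagged", {
  # Wegscheider condition: product of equilibrium constants around the
  # loop is 1 -> residual vanishes
  good <- list(
    kineticReaction("rAB", c(A = 1), c(B = 1), kPlus = 2, kMinus = 1),
    kineticReaction("rBC", c(B = 1), c(C = 1), kPlus = 3, kMinus = 1),
    kineticReaction("rCA", c(C = 1), c(A = 1), kPlus = 1, kMinus = 6))
  expect_lt(detailedBalanceResidual(good), 1e-18)

  # single reversible reaction alone is always consistent
  expect_lt(detailedBalanceResidual(list(good[[1]])), 1e-18)

  # perturb one forward constant: the loop product becomes 2
  bad <- good
  bad[[2]] <- kineticReaction("rBC", c(B = 1), c(C = 1), kPlus = 6,
                              kMinus = 1)
  resBad <- convertKinetics(bad)
  expect_gt(resBad@residual, 1e-6)
  expect_false(resBad@consistent)

  # cross-check the misfit against the normal-equation oracle on the
  # gauge-fixed system
  sys <- buildLogLinearSystem(bad, fixed = c(A = 1))
  xOracle <- solve(t(sys$A) %*% sys$A, t(sys$A) %*% sys$b)
  residOracle <- sum((sys$A %*% xOracle - sys$b)^2)
  expect_equal(solveParameters(sys)@residual, residOracle,
               tolerance = 1e-10)
})

test_that("residual grows monotonically with the perturbation of one loop constant", {
  base <- list(
    kineticReaction("rAB", c(A = 1), c(B = 1), kPlus = 2, kMinus = 1),
    kineticReaction("rBC", c(B = 1), c(C = 1), kPlus = 3, kMinus = 1),
    kineticReaction("rCA", c(C = 1), c(A = 1), kPlus = 1, kMinus = 6))
  factors <- c(1, 1.5, 2, 4, 8)
  residuals <- vapply(factors, function(f) {
    pert <- base
    pert[[1]] <- kineticReaction("rAB", c(A = 1), c(B = 1),
                                 kPlus = 2 * f, kMinus = 1)
    detailedBalanceResidual(pert)
  }, numeric(1))
  expect_lt(residuals[1], 1e-18)
  expect_true(all(diff(residuals) > 0))
})

test_that("fixture kinetics round-trip: fluxes are recovered exactly", {
  for (seed in 1:10) {
    fx <- randomConsistentNetwork(sample(3:8, 1), sample(2:6, 1),
                                  seed = 40 + seed)
    res <- convertKinetics(fx$kinetics)
    expect_true(res@consistent)
    net <- fx$network
    spNames <- speciesNames(net)
    for (k in 1:10) {
      st <- randomState(net, seed * 13 + k)
      for (j in seq_along(fx$kinetics)) {
        vKin <- oracleKineticFlux(fx$kinetics[[j]], st)
        rBG <- reactionComponent(fx$kinetics[[j]]@name,
                                 fx$kinetics[[j]]@reactants,
                                 fx$kinetics[[j]]@products,
                                 kappa = res@kappa[[fx$kinetics[[j]]@name]])
        vBG <- reactionFlux(rBG, st, res@Kq[spNames])
        expect_equal(vBG, vKin, tolerance = 1e-8)
      }
    }
  }
})

test_that("predicted fluxes are invariant to the gauge choice", {
  # chain A <-> B <-> C: the gauge freedom rescales all three constants
  # together, so any single species may be pinned at any positive value
  # and only the K/kappa split changes, never the fluxes
  chain <- list(
    kineticReaction("r1", c(A = 1), c(B = 1), kPlus = 2, kMinus = 0.5),
    kineticReaction("r2", c(B = 1), c(C = 1), kPlus = 1.5, kMinus = 4))
  gauges <- list(numeric(), c(A = 1), c(B = 3), c(C = 0.2))
  st <- c(A = 0.8, B = 1.9, C = 0.4)
  fluxes <- lapply(gauges, function(g) {
    res <- convertKinetics(chain, fixed = g)
    expect_true(res@consistent)
    vapply(chain, function(k)
      reactionFlux(reactionComponent(k@name, k@reactants, k@products,
                                     kappa = res@kappa[[k@name]]),
                   st, res@Kq[c("A", "B", "C")]), numeric(1))
  })
  for (f in fluxes[-1])
    expect_equal(f, fluxes[[1]], tolerance = 1e-8)
  # the split itself differs between gauges
  expect_false(isTRUE(all.equal(
    convertKinetics(chain, fixed = c(B = 3))@Kq[["A"]],
    convertKinetics(chain)@Kq[["A"]])))
})

test_that("irreversible reactions are approximated by a small reverse constant", {
  irr <- kineticReaction("step4", c(RP = 1), c(R2 = 1), kPlus = 10)
  ap <- approximateIrreversible(irr, mode = "small-kminus")
  expect_equal(ap$kMinusEffective, 1e-5)
  # kappa from the forward constraint once constants are known
  ap2 <- approximateIrreversible(irr, mode = "small-kminus",
                                 constants = c(RP = 4, R2 = 1))
  expect_equal(ap2$kappa, 10 / 4)

  # Michaelis-Menten input: low-saturation slope Vmax/Km
  mm <- kineticReaction("step8", c(S = 1), c(P = 1), Vmax = 3, Km = 0.5)
  apMM <- approximateIrreversible(mm, mode = "small-kminus", epsilon = 1e-6)
  expect_equal(apMM$kPlus, 6)
  expect_equal(apMM$kMinusEffective, 6e-6)

  # forward:reverse flux ratio at comparable activities is >= 1/epsilon
  expect_gte(ap$kPlus / ap$kMinusEffective, 1e6)

  rev <- kineticReaction("r", c(A = 1), c(B = 1), kPlus = 1, kMinus = 1)
  expect_error(approximateIrreversible(rev), "not irreversible")
})

test_that("trajectory fit recovers a known rate constant within 1%", {
  kappaTrue <- 0.7
  constants <- c(S = 2, P = 0.5)
  net <- buildNetwork(
    list(speciesComponent("S", 2, 3), speciesComponent("P", 0.5, 0)),
    list(reactionComponent("step", c(S = 1), c(P = 1),
                           kappa = kappaTrue)), ctx1)
  ref <- simulateODE(assembleODEs(net), times = seq(0, 2, by = 0.1),
                     tMax = 2, keepFluxes = FALSE)
  data <- data.frame(time = ref@times, S = ref@states[, "S"],
                     P = ref@states[, "P"])
  irr <- kineticReaction("step", c(S = 1), c(P = 1), kPlus = 1)
  fit <- approximateIrreversible(irr, mode = "trajectory-fit",
                                 constants = constants, data = data,
                                 ctx = ctx1)
  expect_equal(fit$kappa, kappaTrue, tolerance = 0.01)
  expect_error(
    approximateIrreversible(irr, mode = "trajectory-fit",
                            constants = constants),
    "requires reference data")
})

test_that("conversion report CSV carries kappa, Kq and the residual", {
  fx <- randomConsistentNetwork(3, 2, seed = 5)
  res <- convertKinetics(fx$kinetics)
  path <- tempfile(fileext = ".csv")
  expect_message(writeConversionCSV(res, path), "consistent")
  tab <- read.csv(path)
  expect_setequal(unique(tab$field), c("kappa", "Kq", "residual"))
  expect_equal(nrow(tab), length(res@kappa) + length(res@Kq) + 1)
})
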