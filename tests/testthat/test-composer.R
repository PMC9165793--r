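test_that("annotation extraction yields matchable entities with values", {
  path <- tmpModelFile(neutralCycleLines)
  doc <- readModelDocument(path)
  ents <- extractAnnotations(doc)
  expect_length(ents, 3)
  atp <- ents[[which(vapply(ents, function(e) e@localName, "") == "ATP")]]
  expect_identical(atp@kind, "chemostat")
  expect_true("SYN:chebi:ATP" %in% atp@annotations)
  expect_equal(atp@values$q0, 100)

  # no annotations at all -> warning, nothing matchable
  bare <- tmpModelFile(c("model m", "species X q0=1 Kq=1"))
  expect_warning(extractAnnotations(readModelDocument(bare)),
                 "no annotations")
})

test_that("matching groups identical annotation sets across modules only", {
  e <- function(mod, nm, terms)
    annotatedEntity(mod, nm, "species", terms, list(q0 = 0))
  groups <- matchEntities(list(
    egfr = list(e("egfr", "RShGS", c("OPB:1", "CHEBI:RShGS")),
                e("egfr", "EGF", c("OPB:1", "CHEBI:EGF"))),
    ras = list(e("ras", "RShGS", c("OPB:1", "CHEBI:RShGS")),
               e("ras", "Ras", c("OPB:1", "CHEBI:Ras")))))
  expect_length(groups, 1)
  expect_setequal(vapply(groups[[1]], function(x) x@module, ""),
                  c("egfr", "ras"))

  # three modules sharing one species -> one group of size three
  g3 <- matchEntities(list(
    m1 = list(e("m1", "ATP", "CHEBI:ATP")),
    m2 = list(e("m2", "ATP", "CHEBI:ATP")),
    m3 = list(e("m3", "ATP", "CHEBI:ATP"))))
  expect_length(g3, 1)
  expect_length(g3[[1]], 3)

  expect_warning(
    matchEntities(list(m1 = list(e("m1", "X", "CHEBI:X")),
                       m2 = list(e("m2", "Y", "CHEBI:Y")))),
    "no identical annotations")
})

test_that("mergeability is decided by entity kind", {
  sp <- annotatedEntity("m", "X", "species", "CHEBI:X")
  cs <- annotatedEntity("m", "ATP", "chemostat", "CHEBI:ATP")
  pm <- annotatedEntity("m", "temperature", "parameter", "OPB:temp")
  rx <- annotatedEntity("m", "r1", "reaction", "GO:rx")
  expect_true(checkMergeable(sp))
  expect_true(checkMergeable(cs))
  expect_message(expect_false(checkMergeable(pm)), "cannot be merged")
  expect_message(expect_false(checkMergeable(rx)), "not merged")
  weird <- sp
  slot(weird, "kind", check = FALSE) <- "gizmo"
  expect_error(checkMergeable(weird), "unknown entity kind")
})

test_that("merge plan keeps the first module's entity and rewires its bonds", {
  mods <- makeSharedSpeciesModules()
  ents <- list(m1 = annotatedEntities(mods$m1, "m1"),
               m2 = annotatedEntities(mods$m2, "m2"))
  plan <- planMerge(mods, matchEntities(ents))
  expect_equal(nrow(plan@removed), 1)
  expect_identical(plan@removed$module, "m2")
  expect_identical(plan@removed$name, "C")
  # the removed junction's single partner (Re of r2) is re-bonded to the
  # representative's junction
  expect_equal(nrow(plan@newBonds), 1)
  expect_identical(plan@newBonds[1, ], c("m1:0:C", "m2:Re:r2"))
  expect_length(plan@conflicts, 0)

  # two identically annotated entities inside one module is ambiguous
  dup <- mods$m1
  dup@species <- c(dup@species, list(
    speciesComponent("C2", 1, 0,
                     annotations = c("OPB:00340", "SYN:chebi:C"))))
  expect_error(
    planMerge(list(m1 = dup, m2 = mods$m2),
              matchEntities(list(m1 = annotatedEntities(dup, "m1"),
                                 m2 = annotatedEntities(mods$m2, "m2")))),
    "two entities with identical annotations")
})

test_that("value conflicts are detected and resolved by policy", {
  mods <- makeSharedSpeciesModules()
  # introduce a Kq disagreement on the shared species
  mods$m2@species[[1]]@Kq <- 7
  plan <- planMerge(mods, matchEntities(
    list(m1 = annotatedEntities(mods$m1, "m1"),
         m2 = annotatedEntities(mods$m2, "m2"))))
  expect_length(plan@conflicts, 1)
  expect_identical(plan@conflicts[[1]]$field, "Kq")
  expect_equal(sort(unname(plan@conflicts[[1]]$values)), c(1, 7))

  expect_message(resolveConflicts(plan, "keep-first"), "resolved to 1")
  res <- suppressMessages(resolveConflicts(plan, "keep-first"))
  expect_equal(res[["m1:C"]]$Kq, 1)

  res2 <- suppressMessages(
    resolveConflicts(plan, "keep-module", module = "m2"))
  expect_equal(res2[["m1:C"]]$Kq, 7)

  res3 <- suppressMessages(
    resolveConflicts(plan, "override",
                     overrides = list(C = list(Kq = 0.25))))
  expect_equal(res3[["m1:C"]]$Kq, 0.25)
  expect_error(
    resolveConflicts(plan, "override",
                     overrides = list(Zz = list(Kq = 1))),
    "unknown merged species")

  # unresolved conflicts block composition
  expect_error(composeNetworks(mods, plan), "unresolved value conflicts")
})

test_that("composition realises the merged flow balance dqC/dt = v1 - v2", {
  mods <- makeSharedSpeciesModules()
  res <- suppressMessages(mergeNetworks(mods))
  net <- res$network
  expect_setequal(speciesNames(net), c("m1:A", "m1:C", "m2:B"))
  sys <- res$system
  st <- c("m1:A" = 0.8, "m1:C" = 1.7, "m2:B" = 0.3)
  v <- sys@flux(st)
  expect_equal(unname(sys@rate(st)["m1:C"]),
               unname(v[["m1:r1"]] - v[["m2:r2"]]))
  # the merged species' rate equals the sum of its per-module rates at the
  # shared state
  r1 <- assembleODEs(mods$m1)@rate(c(A = 0.8, C = 1.7))
  r2 <- assembleODEs(mods$m2)@rate(c(C = 1.7, B = 0.3))
  expect_equal(unname(sys@rate(st)["m1:C"]),
               unname(r1["C"] + r2["C"]))
})

test_that("block-diagonal bookkeeping holds on a two-cycle merge", {
  # two instances of the cycle template sharing exactly one species: the
  # phosphorylated kinase of cycle 1 is the kinase of cycle 2
  tpl <- mapkCycleTemplate()
  inst <- function(mod, nm) {
    names(nm) <- c("S", "SP", "E", "F", "E_S", "F_SP", "ATP", "ADP", "Pi")
    instantiateTemplate(tpl, names = nm)
  }
  c1 <- inst("c1", c("MKKK", "MKKKP", "Ras", "P1", "X1", "Y1",
                     "ATP1", "ADP1", "Pi1"))
  c2 <- inst("c2", c("MKK", "MKKP", "MKKKP", "P2", "X2", "Y2",
                     "ATP2", "ADP2", "Pi2"))
  mods <- list(c1 = c1, c2 = c2)
  plan <- planMerge(mods, matchEntities(
    list(c1 = annotatedEntities(c1, "c1"),
         c2 = annotatedEntities(c2, "c2"))))
  expect_equal(nrow(plan@removed), 1)  # only MKKKP is shared
  res <- composeNetworks(mods, plan)
  n1 <- length(toConnectivityMatrix(c1)@labels)
  n2 <- length(toConnectivityMatrix(c2)@labels)
  expect_length(res$matrix@labels, n1 + n2 - 1)
  # inserted 1s come in symmetric pairs, one pair per planned bond
  before <- editMatrix(blockDiag <- bgnet:::blockDiagonalMatrix(
    lapply(mods, toConnectivityMatrix), names(mods)),
    remove = "c2:0:MKKKP")
  expect_equal(sum(res$matrix@matrix) - sum(before@matrix),
               2 * nrow(plan@newBonds))
})

test_that("composition is order invariant and idempotent", {
  annot <- function(nm) c("OPB:00340", paste0("SYN:chebi:", nm))
  sp <- function(nm, q0 = 1) speciesComponent(nm, 1, q0,
                                              annotations = annot(nm))
  m1 <- buildNetwork(list(sp("A", 2), sp("X", 0)),
                     list(reactionComponent("r1", c(A = 1), c(X = 1),
                                            kappa = 1)), ctx1)
  m2 <- buildNetwork(list(sp("X", 0), sp("Y", 0)),
                     list(reactionComponent("r2", c(X = 1), c(Y = 1),
                                            kappa = 2)), ctx1)
  m3 <- buildNetwork(list(sp("Y", 0), sp("B", 0.5)),
                     list(reactionComponent("r3", c(Y = 1), c(B = 1),
                                            kappa = 3)), ctx1)
  resA <- suppressMessages(mergeNetworks(list(m1 = m1, m2 = m2, m3 = m3)))
  resB <- suppressMessages(mergeNetworks(list(m3 = m3, m2 = m2, m1 = m1)))
  # same composed dimension, flux agreement at random canonical states
  expect_length(resB$network@species, length(resA$network@species))
  canonical <- function(x) setNames(x, sub("^[^:]+:", "", names(x)))
  set.seed(42)
  for (k in 1:10) {
    st <- setNames(10^runif(4, -1, 1), c("A", "X", "Y", "B"))
    stA <- setNames(st[sub("^[^:]+:", "", speciesNames(resA$network))],
                    speciesNames(resA$network))
    stB <- setNames(st[sub("^[^:]+:", "", speciesNames(resB$network))],
                    speciesNames(resB$network))
    vA <- canonical(resA$system@flux(stA))
    vB <- canonical(resB$system@flux(stB))
    expect_equal(vA[sort(names(vA))], vB[sort(names(vB))],
                 tolerance = 1e-12)
  }

  # disjoint modules stack block-diagonally and behave independently
  d1 <- buildNetwork(list(sp("P", 1), sp("Q", 0)),
                     list(reactionComponent("r", c(P = 1), c(Q = 1),
                                            kappa = 1)), ctx1)
  d2 <- buildNetwork(list(sp("U", 1), sp("V", 0)),
                     list(reactionComponent("r", c(U = 1), c(V = 1),
                                            kappa = 1)), ctx1)
  resD <- suppressWarnings(suppressMessages(
    mergeNetworks(list(d1 = d1, d2 = d2))))
  expect_length(resD$network@species, 4)
  expect_equal(sum(resD$matrix@matrix),
               sum(toConnectivityMatrix(d1)@matrix) +
                 sum(toConnectivityMatrix(d2)@matrix))

  # idempotence: composing a composed model with an empty match set is the
  # identity on wiring
  already <- resA$network
  plan0 <- planMerge(list(whole = already), list())
  res0 <- composeNetworks(list(whole = already), plan0)
  expect_length(res0$network@species, length(already@species))
  expect_equal(sum(res0$matrix@matrix),
               sum(toConnectivityMatrix(already)@matrix))
})

test_that("template selection matches signatures and surfaces ambiguity", {
  registry <- list(cycle = mapkCycleTemplate(), egfr = egfrTemplate(),
                   ras = rasTemplate())
  rasDocEnts <- annotatedEntities(rasTemplate()@structure, "doc")
  expect_identical(selectTemplate(rasDocEnts, registry["ras"]), "ras")
  expect_identical(selectTemplate(list(), registry), NA_character_)
  # overlapping signatures -> ambiguity listing both
  reg2 <- list(a = rasTemplate(), b = rasTemplate())
  expect_error(selectTemplate(rasDocEnts, reg2), "a, b")
})
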