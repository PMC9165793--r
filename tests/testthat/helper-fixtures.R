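# Fixtures are built in code; tests share these small constructors.

ctx1 <- normalisedContext()

# minimal A <-> B network (optionally with unequal constants)
makeAB <- function(KA = 1, KB = 1, kappa = 1, qA = 2, qB = 0) {
  buildNetwork(
    list(speciesComponent("A", Kq = KA, q0 = qA),
         speciesComponent("B", Kq = KB, q0 = qB)),
    list(reactionComponent("r1", c(A = 1), c(B = 1), kappa = kappa)),
    ctx1)
}

# the two-reactant/two-product reaction with stoichiometries alpha, beta
makeTwoSided <- function(alpha = 2, beta = 2) {
  buildNetwork(
    list(speciesComponent("A", 1, 1), speciesComponent("B", 1, 1),
         speciesComponent("C", 1, 1), speciesComponent("D", 1, 1)),
    list(reactionComponent("r1",
                           c(A = alpha, B = 1), c(C = beta, D = 1),
                           kappa = 1)),
    ctx1)
}

# two single-reaction modules sharing species C (A <-> C and C <-> B),
# the classic two-reaction composition fixture
makeSharedSpeciesModules <- function() {
  annot <- function(nm) paste0("SYN:chebi:", nm)
  sp <- function(nm, q0 = 1, Kq = 1)
    speciesComponent(nm, Kq = Kq, q0 = q0,
                     annotations = c("OPB:00340", annot(nm)))
  m1 <- buildNetwork(list(sp("A", 2), sp("C", 0)),
                     list(reactionComponent("r1", c(A = 1), c(C = 1),
                                            kappa = 1)), ctx1)
  m2 <- buildNetwork(list(sp("C", 0), sp("B", 0, Kq = 0.5)),
                     list(reactionComponent("r2", c(C = 1), c(B = 1),
                                            kappa = 2)), ctx1)
  list(m1 = m1, m2 = m2)
}

# independent brute-force oracle: stoichiometric matrix times mass-action
# flux vector, written against the rate-law definitions only (no reuse of
# package internals).
oracleRates <- function(network, state) {
  spNames <- vapply(network@species, function(s) s@name, "")
  Kq <- setNames(vapply(network@species, function(s) s@Kq, 0), spNames)
  chem <- setNames(vapply(network@species, function(s) s@isChemostat, NA),
                   spNames)
  rates <- setNames(numeric(length(spNames)), spNames)
  for (r in network@reactions) {
    fw <- 1
    for (sp in names(r@reactants))
      fw <- fw * (Kq[[sp]] * state[[sp]])^r@reactants[[sp]]
    bw <- 1
    for (sp in names(r@products))
      bw <- bw * (Kq[[sp]] * state[[sp]])^r@products[[sp]]
    v <- r@kappa * (fw - bw)
    for (sp in names(r@reactants))
      rates[[sp]] <- rates[[sp]] - r@reactants[[sp]] * v
    for (sp in names(r@products))
      rates[[sp]] <- rates[[sp]] + r@products[[sp]] * v
  }
  rates[chem] <- 0
  rates
}

# random strictly positive state for a network, deterministic given seed
randomState <- function(network, seed) {
  spNames <- vapply(network@species, function(s) s@name, "")
  bgnet:::withSeed(seed, setNames(10^runif(length(spNames), -1, 1), spNames))
}

# Eq-4 style kinetic flux oracle (independent of kineticFlux)
oracleKineticFlux <- function(kinetic, state) {
  fw <- 1
  for (sp in names(kinetic@reactants))
    fw <- fw * state[[sp]]^kinetic@reactants[[sp]]
  bw <- 1
  for (sp in names(kinetic@products))
    bw <- bw * state[[sp]]^kinetic@products[[sp]]
  km <- if (is.na(kinetic@kMinus)) 0 else kinetic@kMinus
  kinetic@kPlus * fw - km * bw
}

# write text lines to a temp file and return the path
tmpModelFile <- function(lines, ext = ".bg") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# small neutral-format cycle module document used across io/cli tests
neutralCycleLines <- c(
  "# one phosphorylation/dephosphorylation cycle",
  "model cyc",
  "species M q0=1 Kq=1 units=uM annot=OPB:00340;SYN:chebi:M",
  "species MP q0=0 Kq=1 units=uM annot=OPB:00340;SYN:chebi:MP",
  "species ATP chemostat q0=100 Kq=1 annot=OPB:00340;SYN:chebi:ATP;BG:chemostat",
  "reaction b1 : M + ATP -> MP kappa=2",
  "reaction b2 : MP -> M kappa=1")
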