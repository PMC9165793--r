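# Synthetic annotation scheme: every species carries a property term, an
# entity term derived from its canonical name, and a compartment term, in
# the subject-predicate-object spirit of ontology-annotated models. Matching
# is exact set equality, so identical canonical names merge across modules.
defaultAnnotations <- function(name, chemostat = FALSE) {
  c("OPB:00340",
    paste0("SYN:chebi:", name),
    "GO:0005829",
    if (chemostat) "BG:chemostat")
}

templateSpecies <- function(name, chemostat = FALSE) {
  speciesComponent(name, Kq = NA_real_, q0 = NA_real_, chemostat = chemostat,
                   annotations = defaultAnnotations(name, chemostat))
}

templateSlots <- function(network) {
  c(paste0("Kq:", speciesNames(network)),
    paste0("q0:", speciesNames(network)),
    paste0("kappa:", reactionNames(network)))
}

#' Symbolic template for one phosphorylation/dephosphorylation cycle
#'
#' The reusable building block of the MAPK cascade: a substrate `S` is
#' phosphorylated to `SP` by a kinase `E` and dephosphorylated by a
#' phosphatase `F`, each arm following the standard bind/catalyse motif
#' (enzyme-substrate complexes `E_S` and `F_SP`). Phosphorylation consumes
#' the ATP chemostat and releases ADP; dephosphorylation releases Pi. All
#' parameters ship unset; instantiate with [instantiateTemplate()].
#'
#' Reactions: `bind` S + E <-> E_S; `cat` E_S + ATP <-> SP + E + ADP;
#' `pbind` SP + F <-> F_SP; `rel` F_SP <-> S + F + Pi.
#'
#' @return a [SymbolicTemplate-class].
#' @export
mapkCycleTemplate <- function() {
  species <- list(
    templateSpecies("S"), templateSpecies("SP"),
    templateSpecies("E"), templateSpecies("F"),
    templateSpecies("E_S"), templateSpecies("F_SP"),
    templateSpecies("ATP", chemostat = TRUE),
    templateSpecies("ADP", chemostat = TRUE),
    templateSpecies("Pi", chemostat = TRUE))
  reactions <- list(
    reactionComponent("bind", c(S = 1, E = 1), c(E_S = 1)),
    reactionComponent("cat", c(E_S = 1, ATP = 1), c(SP = 1, E = 1, ADP = 1)),
    reactionComponent("pbind", c(SP = 1, F = 1), c(F_SP = 1)),
    reactionComponent("rel", c(F_SP = 1), c(S = 1, F = 1, Pi = 1)))
  net <- buildNetwork(species, reactions)
  new("SymbolicTemplate", structure = net,
      signature = c("SYN:chebi:S", "SYN:chebi:SP", "SYN:chebi:E",
                    "SYN:chebi:F", "SYN:chebi:ATP"),
      slots = templateSlots(net),
      roles = stats::setNames(speciesNames(net), speciesNames(net)))
}

#' Instantiate a symbolic template
#'
#' Renames the template's role species to concrete names, refreshes their
#' annotations from the concrete names (so identically named species in
#' different instances carry identical annotation sets and merge), and
#' optionally fills parameter slots. Two instances share no element labels
#' once composed, because composition namespaces components by module.
#'
#' @param template a [SymbolicTemplate-class].
#' @param names named character vector role -> concrete species name; roles
#'   not mentioned keep their template names.
#' @param Kq,q0,kappa named parameter vectors keyed by *concrete* species /
#'   reaction names (optional; missing values stay unset).
#' @return a [BondGraphNetwork-class].
#' @export
instantiateTemplate <- function(template, names = character(),
                                Kq = NULL, q0 = NULL, kappa = NULL) {
  stopifnot(is(template, "SymbolicTemplate"))
  net <- template@structure
  mapName <- function(nm) if (nm %in% base::names(names)) names[[nm]] else nm
  net@species <- lapply(net@species, function(s) {
    s@name <- mapName(s@name)
    s@annotations <- defaultAnnotations(s@name, s@isChemostat)
    s
  })
  net@reactions <- lapply(net@reactions, function(r) {
    base::names(r@reactants) <- vcapply(base::names(r@reactants), mapName)
    base::names(r@products) <- vcapply(base::names(r@products), mapName)
    r
  })
  validObject(net)
  setParameters(net, Kq = Kq, q0 = q0, kappa = kappa)
}

#' Symbolic template of the EGFR signalling pathway
#'
#' Structural reconstruction of the receptor-level EGFR module: ligand
#' binding and receptor dimerisation, receptor phosphorylation (ATP/ADP),
#' PLCg and Shc branches, Grb2/SOS complex assembly terminating in the
#' RShGS complex (the species shared with the Ras activation module).
#' Phosphorylation steps 3, 6 and 14 consume ATP and release ADP;
#' dephosphorylation steps 4, 8 and 16 release Pi. Parameters ship unset:
#' numeric values belong to user-supplied parameter files.
#'
#' @return a [SymbolicTemplate-class].
#' @export
egfrTemplate <- function() {
  sp <- function(n) templateSpecies(n)
  species <- c(lapply(
    c("EGF", "R", "Ra", "R2", "RP", "PLCg", "RPL", "RPLP", "PLCgP",
      "PLCgPI", "Grb", "RG", "SOS", "RGS", "GS", "Shc", "RSh", "RShP",
      "ShP", "ShG", "RShG", "ShGS", "RShGS"), sp),
    list(templateSpecies("ATP", chemostat = TRUE),
         templateSpecies("ADP", chemostat = TRUE),
         templateSpecies("Pi", chemostat = TRUE)))
  rx <- function(name, reactants, products)
    reactionComponent(name, reactants, products)
  reactions <- list(
    rx("r1", c(R = 1, EGF = 1), c(Ra = 1)),
    rx("r2", c(Ra = 2), c(R2 = 1)),
    rx("r3", c(R2 = 1, ATP = 1), c(RP = 1, ADP = 1)),        # phosphorylation
    rx("r4", c(RP = 1), c(R2 = 1, Pi = 1)),                  # dephosphorylation
    rx("r5", c(RP = 1, PLCg = 1), c(RPL = 1)),
    rx("r6", c(RPL = 1, ATP = 1), c(RPLP = 1, ADP = 1)),     # phosphorylation
    rx("r7", c(RPLP = 1), c(RP = 1, PLCgP = 1)),
    rx("r8", c(PLCgP = 1), c(PLCg = 1, Pi = 1)),             # dephosphorylation
    rx("r9", c(RP = 1, Grb = 1), c(RG = 1)),
    rx("r10", c(RG = 1, SOS = 1), c(RGS = 1)),
    rx("r11", c(RGS = 1), c(RP = 1, GS = 1)),
    rx("r12", c(GS = 1), c(Grb = 1, SOS = 1)),
    rx("r13", c(RP = 1, Shc = 1), c(RSh = 1)),
    rx("r14", c(RSh = 1, ATP = 1), c(RShP = 1, ADP = 1)),    # phosphorylation
    rx("r15", c(RShP = 1), c(ShP = 1, RP = 1)),
    rx("r16", c(ShP = 1), c(Shc = 1, Pi = 1)),               # dephosphorylation
    rx("r17", c(RShP = 1, GS = 1), c(RShGS = 1)),
    rx("r18", c(RShGS = 1), c(ShGS = 1, RP = 1)),
    rx("r19", c(ShP = 1, Grb = 1), c(ShG = 1)),
    rx("r20", c(RShP = 1, Grb = 1), c(RShG = 1)),
    rx("r21", c(RShG = 1), c(RP = 1, ShG = 1)),
    rx("r22", c(ShG = 1, SOS = 1), c(ShGS = 1)),
    rx("r23", c(RShG = 1, SOS = 1), c(RShGS = 1)),
    rx("r24", c(PLCgP = 1), c(PLCgPI = 1)),
    rx("r25", c(ShGS = 1), c(ShP = 1, GS = 1)))
  net <- buildNetwork(species, reactions)
  new("SymbolicTemplate", structure = net,
      signature = c("SYN:chebi:EGF", "SYN:chebi:RShGS", "SYN:chebi:R"),
      slots = templateSlots(net),
      roles = stats::setNames(speciesNames(net), speciesNames(net)))
}

#' Symbolic template of the Ras activation module
#'
#' Reduced activation module linking the EGFR and MAPK modules: the RShGS
#' complex catalyses nucleotide exchange on RasGDP yielding active Ras
#' (steps 1-2, step 2 irreversible in the kinetic source), and GAP
#' hydrolyses active Ras back to RasGDP (steps 3-4, step 4 irreversible).
#' RShGS and Ras are the annotated terminal (mergeable) species.
#'
#' @return a [SymbolicTemplate-class].
#' @export
rasTemplate <- function() {
  species <- lapply(c("RShGS", "RasGDP", "Ras", "GAP",
                      "RShGS_RasGDP", "GAP_Ras"), templateSpecies)
  reactions <- list(
    reactionComponent("r1", c(RShGS = 1, RasGDP = 1), c(RShGS_RasGDP = 1)),
    reactionComponent("r2", c(RShGS_RasGDP = 1), c(RShGS = 1, Ras = 1)),
    reactionComponent("r3", c(GAP = 1, Ras = 1), c(GAP_Ras = 1)),
    reactionComponent("r4", c(GAP_Ras = 1), c(GAP = 1, RasGDP = 1)))
  net <- buildNetwork(species, reactions)
  new("SymbolicTemplate", structure = net,
      signature = c("SYN:chebi:RShGS", "SYN:chebi:Ras", "SYN:chebi:GAP"),
      slots = templateSlots(net),
      roles = stats::setNames(speciesNames(net), speciesNames(net)))
}

#' Add (or remove) an enzymatic negative-feedback loop
#'
#' Wires `inhibitor` into the reactant side of `targetReaction` (the
#' binding step of a dephosphorylation pair) and into the product side of
#' the paired release reaction, so the inhibitor acts catalytically: it is
#' consumed and re-produced around the pair and its net stoichiometry over
#' the loop is zero. With the terminal kinase as inhibitor this strengthens
#' the first layer's dephosphorylation as the output rises.
#'
#' @param network a [BondGraphNetwork-class].
#' @param inhibitor species name acting as the feedback enzyme.
#' @param targetReaction name of the binding reaction of the target
#'   dephosphorylation pair.
#' @param releaseReaction name of the paired release reaction; by default
#'   it is auto-detected as the unique reaction consuming the complex that
#'   `targetReaction` produces.
#' @return the modified [BondGraphNetwork-class].
#' @export
addNegativeFeedback <- function(network, inhibitor, targetReaction,
                                releaseReaction = NULL) {
  spNames <- speciesNames(network)
  rxNames <- reactionNames(network)
  if (!(inhibitor %in% spNames))
    bgStop("bgLookupError", "no species named '%s'", inhibitor)
  it <- match(targetReaction, rxNames)
  if (is.na(it))
    bgStop("bgLookupError", "no reaction named '%s'", targetReaction)
  target <- network@reactions[[it]]
  if (is.null(releaseReaction)) {
    complexes <- names(target@products)
    candidates <- character()
    for (r in network@reactions) {
      if (r@name == targetReaction) next
      if (any(complexes %in% names(r@reactants)))
        candidates <- c(candidates, r@name)
    }
    if (length(candidates) != 1)
      bgStop("bgAmbiguityError",
             "cannot auto-detect the release reaction paired with '%s'%s",
             targetReaction,
             if (length(candidates))
               paste0(" (candidates: ", paste(candidates, collapse = ", "), ")")
             else "")
    releaseReaction <- candidates
  }
  ir <- match(releaseReaction, rxNames)
  if (is.na(ir))
    bgStop("bgLookupError", "no reaction named '%s'", releaseReaction)
  release <- network@reactions[[ir]]
  if (inhibitor %in% c(names(target@reactants), names(release@products)))
    bgStop("bgValidationError",
           "'%s' already participates in the feedback pair", inhibitor)
  target@reactants <- c(target@reactants, stats::setNames(1, inhibitor))
  release@products <- c(release@products, stats::setNames(1, inhibitor))
  network@reactions[[it]] <- target
  network@reactions[[ir]] <- release
  validObject(network)
  network
}

#' @rdname addNegativeFeedback
#' @export
removeNegativeFeedback <- function(network, inhibitor, targetReaction,
                                   releaseReaction = NULL) {
  rxNames <- reactionNames(network)
  it <- match(targetReaction, rxNames)
  if (is.na(it))
    bgStop("bgLookupError", "no reaction named '%s'", targetReaction)
  target <- network@reactions[[it]]
  if (is.null(releaseReaction)) {
    hits <- which(vlapply(network@reactions, function(r)
      inhibitor %in% names(r@products) &&
        any(names(target@products) %in% names(r@reactants))))
    if (length(hits) != 1)
      bgStop("bgAmbiguityError", "cannot identify the feedback release step")
    ir <- hits
  } else {
    ir <- match(releaseReaction, rxNames)
    if (is.na(ir))
      bgStop("bgLookupError", "no reaction named '%s'", releaseReaction)
  }
  release <- network@reactions[[ir]]
  if (!(inhibitor %in% names(target@reactants)) ||
      !(inhibitor %in% names(release@products)))
    bgStop("bgLookupError", "'%s' is not wired as feedback on '%s'",
           inhibitor, targetReaction)
  target@reactants <- target@reactants[names(target@reactants) != inhibitor]
  release@products <- release@products[names(release@products) != inhibitor]
  network@reactions[[it]] <- target
  network@reactions[[ir]] <- release
  validObject(network)
  network
}

setMethod("show", "SymbolicTemplate", function(object) {
  cat(sprintf("SymbolicTemplate: %d species, %d reactions, %d parameter slots\n",
              length(object@structure@species),
              length(object@structure@reactions), length(object@slots)))
})
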