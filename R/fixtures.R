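#' Generate a random detailed-balance-consistent network
#'
#' Draws species constants Kq and reaction constants kappa log-uniformly on
#' [1e-2, 1e2], builds random connected stoichiometries with coefficients
#' in {1, 2}, and derives the kinetic constants from the thermodynamic
#' parameterisation: kPlus = kappa * prod Kr^alpha and
#' kMinus = kappa * prod Kp^beta. The resulting kinetics satisfy detailed
#' balance by construction, which makes the pair (network, kinetics) an
#' exact round-trip fixture for the parameter conversion. Deterministic for
#' a fixed seed.
#'
#' @param nSpecies number of species (>= 2).
#' @param nReactions number of reactions (>= 1).
#' @param seed RNG seed; the caller's random stream is left untouched.
#' @param ctx thermodynamic context.
#' @return list with `network` (a parameterised [BondGraphNetwork-class])
#'   and `kinetics` (list of [KineticReaction-class]).
#' @export
randomConsistentNetwork <- function(nSpecies, nReactions, seed,
                                    ctx = thermoContext()) {
  if (nSpecies < 2)
    bgStop("bgUsageError", "need at least 2 species")
  if (nReactions < 1)
    bgStop("bgUsageError", "need at least 1 reaction")
  if (nSpecies > 4 * nReactions)
    bgStop("bgGenerationError",
           "cannot connect %d species with %d reactions (max 4 participants each)",
           nSpecies, nReactions)
  withSeed(seed, {
    spNames <- sprintf("S%d", seq_len(nSpecies))
    Kq <- stats::setNames(10^stats::runif(nSpecies, -2, 2), spNames)
    q0 <- stats::setNames(10^stats::runif(nSpecies, -1, 1), spNames)
    kappa <- 10^stats::runif(nReactions, -2, 2)

    unused <- spNames
    touched <- character()
    reactions <- vector("list", nReactions)
    for (j in seq_len(nReactions)) {
      # spread untouched species over the remaining reactions so every
      # species ends up connected
      mustTake <- max(0, min(4, nSpecies,
                             ceiling(length(unused) / (nReactions - j + 1))))
      nR <- sample(seq_len(min(2, nSpecies - 1)), 1)
      nP <- sample(seq_len(min(2, nSpecies - nR)), 1)
      while (nR + nP < max(2, mustTake) && nR + nP < nSpecies) {
        if (nR < 2) nR <- nR + 1 else nP <- nP + 1
      }
      take <- utils::head(unused, min(mustTake, nR + nP))
      pool <- setdiff(spNames, take)
      pick <- function(x, k) x[sample.int(length(x), k)]
      # anchor to the already-touched part of the network when possible
      anchor <- if (j > 1 && length(touched) && length(take) < nR + nP &&
                    !length(intersect(take, touched)))
        pick(touched, 1) else character()
      pool <- setdiff(pool, anchor)
      extra <- pick(pool, nR + nP - length(take) - length(anchor))
      participants <- pick(c(take, anchor, extra), nR + nP)
      reactants <- participants[seq_len(nR)]
      products <- participants[nR + seq_len(nP)]
      st <- function(nm) stats::setNames(sample(1:2, length(nm), TRUE), nm)
      reactions[[j]] <- reactionComponent(sprintf("r%d", j),
                                          st(reactants), st(products),
                                          kappa = kappa[j])
      touched <- union(touched, participants)
      unused <- setdiff(unused, participants)
    }
    if (length(unused))
      bgStop("bgGenerationError", "failed to connect species: %s",
             paste(unused, collapse = ", "))
    species <- lapply(spNames, function(nm)
      speciesComponent(nm, Kq = Kq[[nm]], q0 = q0[[nm]]))
    network <- buildNetwork(species, reactions, ctx)
    kinetics <- lapply(reactions, function(r) {
      kPlus <- r@kappa * prod(Kq[names(r@reactants)]^r@reactants)
      kMinus <- r@kappa * prod(Kq[names(r@products)]^r@products)
      kineticReaction(r@name, r@reactants, r@products,
                      kPlus = kPlus, kMinus = kMinus)
    })
    list(network = network, kinetics = kinetics)
  })
}
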