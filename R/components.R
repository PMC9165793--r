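#' Create a species component
#'
#' @param name species identifier.
#' @param Kq thermodynamic constant (> 0); `NA` for a symbolic template slot.
#' @param q0 initial amount (>= 0); `NA` for a template slot.
#' @param chemostat logical; a chemostat's amount never changes during
#'   simulation.
#' @param annotations character vector of ontology-term identifiers used for
#'   semantic matching (may be empty).
#' @return a [SpeciesComponent-class].
#' @examples
#' speciesComponent("A", Kq = 1, q0 = 2)
#' speciesComponent("ATP", Kq = 1, q0 = 1000, chemostat = TRUE)
#' @export
speciesComponent <- function(name, Kq = NA_real_, q0 = NA_real_,
                             chemostat = FALSE, annotations = character()) {
  new("SpeciesComponent", name = as.character(name),
      annotations = as.character(annotations),
      Kq = as.numeric(Kq), q0 = as.numeric(q0),
      isChemostat = isTRUE(chemostat))
}

#' Create a reaction component
#'
#' Stoichiometries are the transformer ratios of the bond graph and must be
#' positive integers; the reactant and product sets must be disjoint.
#'
#' @param name reaction identifier.
#' @param reactants,products named numeric vectors, species -> stoichiometry.
#' @param kappa rate constant (> 0); `NA` for a symbolic template slot.
#' @return a [ReactionComponent-class].
#' @examples
#' reactionComponent("r1", c(A = 2, B = 1), c(C = 1), kappa = 0.5)
#' @export
reactionComponent <- function(name, reactants, products, kappa = NA_real_) {
  new("ReactionComponent", name = as.character(name),
      kappa = as.numeric(kappa),
      reactants = namedNumeric(reactants), products = namedNumeric(products))
}

#' @rdname accessors
#' @export
setMethod("speciesNames", "BondGraphNetwork", function(x)
  vcapply(x@species, function(s) s@name))

#' @rdname accessors
#' @export
setMethod("reactionNames", "BondGraphNetwork", function(x)
  vcapply(x@reactions, function(r) r@name))

#' @rdname accessors
#' @export
setMethod("chemostatNames", "BondGraphNetwork", function(x)
  speciesNames(x)[vlapply(x@species, function(s) s@isChemostat)])

#' @rdname accessors
#' @export
setMethod("getSpecies", "BondGraphNetwork", function(x, name) {
  i <- match(name, speciesNames(x))
  if (is.na(i)) bgStop("bgLookupError", "no species named '%s'", name)
  x@species[[i]]
})

#' @rdname accessors
#' @export
setMethod("getReaction", "BondGraphNetwork", function(x, name) {
  i <- match(name, reactionNames(x))
  if (is.na(i)) bgStop("bgLookupError", "no reaction named '%s'", name)
  x@reactions[[i]]
})

#' @rdname accessors
#' @export
setMethod("initialState", "BondGraphNetwork", function(x)
  stats::setNames(vnapply(x@species, function(s) s@q0), speciesNames(x)))

setMethod("show", "SpeciesComponent", function(object) {
  cat(sprintf("%s '%s': Kq = %s, q0 = %s%s\n",
              if (object@isChemostat) "Chemostat" else "Species",
              object@name, format(object@Kq), format(object@q0),
              if (length(object@annotations))
                sprintf(" [%d annotations]", length(object@annotations))
              else ""))
})

setMethod("show", "ReactionComponent", function(object) {
  side <- function(st)
    paste(ifelse(st > 1, paste0(st, " ", names(st)), names(st)),
          collapse = " + ")
  cat(sprintf("Reaction '%s': %s <-> %s (kappa = %s)\n", object@name,
              side(object@reactants), side(object@products),
              format(object@kappa)))
})
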