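#' Build a validated bond-graph network
#'
#' Checks name uniqueness and that every reaction participant is declared,
#' then attaches the canonical junction wiring: each species owns a '0:u'
#' junction; each reaction an Re element; a reaction side acquires a '1:v'
#' junction when it has more than one participant or any stoichiometry above
#' one (otherwise the species junction bonds directly to the Re element); a
#' TF element encodes every stoichiometry above one.
#'
#' @param species list of [SpeciesComponent-class] objects.
#' @param reactions list of [ReactionComponent-class] objects.
#' @param ctx a [ThermoContext-class].
#' @return a [BondGraphNetwork-class].
#' @examples
#' net <- buildNetwork(
#'   list(speciesComponent("A", 1, 2), speciesComponent("B", 1, 0)),
#'   list(reactionComponent("r1", c(A = 1), c(B = 1), kappa = 1)))
#' elementLabels(net)
#' @export
buildNetwork <- function(species, reactions = list(), ctx = thermoContext()) {
  stopifnot(is.list(species), is.list(reactions))
  for (s in species) stopifnot(is(s, "SpeciesComponent"))
  for (r in reactions) stopifnot(is(r, "ReactionComponent"))
  spNames <- vcapply(species, function(s) s@name)
  dup <- spNames[duplicated(spNames)]
  if (length(dup))
    bgStop("bgValidationError", "duplicate species name: %s",
           paste(unique(dup), collapse = ", "))
  rxNames <- vcapply(reactions, function(r) r@name)
  dup <- rxNames[duplicated(rxNames)]
  if (length(dup))
    bgStop("bgValidationError", "duplicate reaction name: %s",
           paste(unique(dup), collapse = ", "))
  for (r in reactions) {
    undeclared <- setdiff(c(names(r@reactants), names(r@products)), spNames)
    if (length(undeclared))
      bgStop("bgValidationError",
             "reaction '%s' references undeclared species: %s", r@name,
             paste(undeclared, collapse = ", "))
  }
  new("BondGraphNetwork", species = species, reactions = reactions,
      context = ctx)
}

# Canonical element labels and bond list implied by the network structure.
# Labels: "0:<species>", "Re:<reaction>", "1:<reaction>:f" / ":r",
# "TF:<reaction>:<species>".
networkWiring <- function(network) {
  labels <- as.character(vapply(network@species,
                                function(s) paste0("0:", s@name), ""))
  bonds <- matrix(character(), 0, 2)
  for (r in network@reactions) {
    reLab <- paste0("Re:", r@name)
    labels <- c(labels, reLab)
    for (side in c("f", "r")) {
      st <- if (side == "f") r@reactants else r@products
      needsJunction <- length(st) > 1 || any(st > 1)
      if (needsJunction) {
        jLab <- paste0("1:", r@name, ":", side)
        labels <- c(labels, jLab)
        bonds <- rbind(bonds, c(jLab, reLab))
        for (sp in names(st)) {
          if (st[[sp]] > 1) {
            tfLab <- paste0("TF:", r@name, ":", sp)
            labels <- c(labels, tfLab)
            bonds <- rbind(bonds, c(paste0("0:", sp), tfLab),
                           c(tfLab, jLab))
          } else {
            bonds <- rbind(bonds, c(paste0("0:", sp), jLab))
          }
        }
      } else {
        bonds <- rbind(bonds, c(paste0("0:", names(st)), reLab))
      }
    }
  }
  list(labels = labels, bonds = bonds)
}

#' @rdname buildNetwork
#' @param network a [BondGraphNetwork-class].
#' @export
elementLabels <- function(network) networkWiring(network)$labels

setMethod("show", "BondGraphNetwork", function(object) {
  nChem <- length(chemostatNames(object))
  cat(sprintf(paste0("BondGraphNetwork: %d species (%d chemostats), ",
                     "%d reactions, %d elements\n"),
              length(object@species), nChem, length(object@reactions),
              length(elementLabels(object))))
  if (length(object@species)) {
    shown <- utils::head(speciesNames(object), 8)
    cat("  species:", paste(shown, collapse = ", "),
        if (length(object@species) > 8) "..." else "", "\n")
  }
})

#' Set or replace component parameter values
#'
#' Convenience for parameterising symbolic structures: assigns Kq/q0 per
#' species and kappa per reaction by name. Unknown names are an error;
#' omitted components keep their current values.
#'
#' @param network a [BondGraphNetwork-class].
#' @param Kq,q0 named numeric vectors keyed by species name.
#' @param kappa named numeric vector keyed by reaction name.
#' @return the updated network.
#' @export
setParameters <- function(network, Kq = NULL, q0 = NULL, kappa = NULL) {
  spNames <- speciesNames(network)
  rxNames <- reactionNames(network)
  for (nm in names(Kq)) {
    i <- match(nm, spNames)
    if (is.na(i)) bgStop("bgLookupError", "no species named '%s'", nm)
    network@species[[i]]@Kq <- as.numeric(Kq[[nm]])
  }
  for (nm in names(q0)) {
    i <- match(nm, spNames)
    if (is.na(i)) bgStop("bgLookupError", "no species named '%s'", nm)
    network@species[[i]]@q0 <- as.numeric(q0[[nm]])
  }
  for (nm in names(kappa)) {
    i <- match(nm, rxNames)
    if (is.na(i)) bgStop("bgLookupError", "no reaction named '%s'", nm)
    network@reactions[[i]]@kappa <- as.numeric(kappa[[nm]])
  }
  validObject(network)
  network
}

setValidity("BondGraphNetwork", function(object) {
  spNames <- vcapply(object@species, function(s) s@name)
  if (anyDuplicated(spNames)) return("duplicate species names")
  for (r in object@reactions) {
    undeclared <- setdiff(c(names(r@reactants), names(r@products)), spNames)
    if (length(undeclared))
      return(sprintf("reaction '%s' references undeclared species: %s",
                     r@name, paste(undeclared, collapse = ", ")))
  }
  TRUE
})
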