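#' Create an annotated entity
#'
#' @param module source module identifier.
#' @param localName name within the module.
#' @param kind "species", "chemostat", "reaction" or "parameter".
#' @param annotations character set of identifier strings.
#' @param values named list of any of Kq, q0, kappa, units.
#' @return an [AnnotatedEntity-class].
#' @export
annotatedEntity <- function(module, localName, kind,
                            annotations = character(), values = list()) {
  new("AnnotatedEntity", module = as.character(module),
      localName = as.character(localName), kind = as.character(kind),
      annotations = sort(unique(as.character(annotations))), values = values)
}

setMethod("show", "AnnotatedEntity", function(object) {
  cat(sprintf("AnnotatedEntity %s:%s (%s) [%d terms]\n", object@module,
              object@localName, object@kind, length(object@annotations)))
})

#' Annotated entities of a network's species
#'
#' Derives the matchable entity list of a module directly from its species
#' components (one entity per species, carrying Kq and q0).
#'
#' @param network a [BondGraphNetwork-class].
#' @param module module identifier to stamp on the entities.
#' @return list of [AnnotatedEntity-class].
#' @export
annotatedEntities <- function(network, module) {
  lapply(network@species, function(s)
    annotatedEntity(module, s@name,
                    if (s@isChemostat) "chemostat" else "species",
                    s@annotations,
                    list(Kq = s@Kq, q0 = s@q0)))
}

#' Match identically annotated entities across modules
#'
#' Entities match when their annotation sets are exactly equal (set
#' equality of identifier strings; fuzzy matching is deliberately out of
#' scope). Entities with empty annotation sets never match. Groups must span
#' at least two modules; an empty result is a warning, not an error.
#'
#' @param entitySets named list (module -> list of
#'   [AnnotatedEntity-class]), at least two modules.
#' @return list of matched groups (each a list of entities).
#' @export
matchEntities <- function(entitySets) {
  stopifnot(is.list(entitySets))
  if (length(entitySets) < 2)
    bgStop("bgUsageError", "matching needs at least two modules")
  all <- unlist(entitySets, recursive = FALSE)
  all <- Filter(function(e) length(e@annotations) > 0, all)
  keys <- vcapply(all, function(e) paste(e@annotations, collapse = "\x1f"))
  groups <- split(all, keys)
  groups <- Filter(function(g)
    length(unique(vcapply(g, function(e) e@module))) >= 2, groups)
  groups <- unname(groups)
  if (!length(groups))
    bgWarn("bgNoMatchWarning",
           "no identical annotations detected between the modules")
  groups
}

#' Mergeability of an annotated entity
#'
#' Biochemical species and chemostats can participate in several reactions
#' at once, so they are mergeable connection points. Scalar context
#' parameters (e.g. temperature) cannot become ports and are ignored with a
#' note; reactions are not merged either (every merge in the composition
#' workflow is a species merge).
#'
#' @param entity an [AnnotatedEntity-class].
#' @return logical flag.
#' @export
checkMergeable <- function(entity) {
  stopifnot(is(entity, "AnnotatedEntity"))
  switch(entity@kind,
    species = ,
    chemostat = TRUE,
    parameter = {
      message(sprintf(
        "entity %s:%s is a parameter and cannot be merged; ignored",
        entity@module, entity@localName))
      FALSE
    },
    reaction = {
      message(sprintf(
        "entity %s:%s is a reaction; reactions are not merged",
        entity@module, entity@localName))
      FALSE
    },
    bgStop("bgClassificationError", "unknown entity kind '%s'", entity@kind))
}
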