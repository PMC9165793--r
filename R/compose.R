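#' Plan a merge of annotated modules
#'
#' From the matched annotation groups, keeps one representative per group
#' (the entity from the earliest module in the order of `modules`), marks
#' the rest as removed duplicates, plans an inter-module bond from the
#' representative's 0-junction to every former bond partner of each removed
#' junction, and records value conflicts (differing q0 or Kq within a
#' group).
#'
#' @param modules named list of [BondGraphNetwork-class] objects; the name
#'   order defines representative priority.
#' @param groups matched groups from [matchEntities()], pre-filtered with
#'   [checkMergeable()] (non-mergeable entities are dropped here as well).
#' @return a [MergePlan-class].
#' @export
planMerge <- function(modules, groups) {
  stopifnot(is.list(modules), !is.null(names(modules)))
  moduleOrder <- names(modules)
  cms <- lapply(modules, toConnectivityMatrix)
  prefixed <- function(m, label) paste0(m, ":", label)

  representatives <- list()
  removed <- data.frame(module = character(), name = character(),
                        representativeModule = character(),
                        representativeName = character(),
                        stringsAsFactors = FALSE)
  newBonds <- matrix(character(), 0, 2)
  conflicts <- list()
  keptGroups <- list()

  gid <- 0
  for (g in groups) {
    g <- Filter(function(e) suppressMessages(checkMergeable(e)), g)
    if (length(g) < 2) next
    mods <- vcapply(g, function(e) e@module)
    if (anyDuplicated(mods)) {
      dupMod <- mods[duplicated(mods)][1]
      bgStop("bgAmbiguityError",
             "module '%s' contains two entities with identical annotations (%s)",
             dupMod,
             paste(vcapply(g[mods == dupMod], function(e) e@localName),
                   collapse = ", "))
    }
    gid <- gid + 1
    ord <- order(match(mods, moduleOrder))
    g <- g[ord]
    rep <- g[[1]]
    keptGroups[[gid]] <- g
    representatives[[gid]] <- rep
    repLabel <- prefixed(rep@module, paste0("0:", rep@localName))
    for (dup in g[-1]) {
      removed <- rbind(removed, data.frame(
        module = dup@module, name = dup@localName,
        representativeModule = rep@module,
        representativeName = rep@localName, stringsAsFactors = FALSE))
      cmDup <- cms[[dup@module]]
      dupLocal <- paste0("0:", dup@localName)
      partners <- cmDup@labels[cmDup@matrix[dupLocal, ] == 1]
      for (p in partners)
        newBonds <- rbind(newBonds, c(repLabel, prefixed(dup@module, p)))
    }
    for (field in c("q0", "Kq")) {
      vals <- vnapply(g, function(e) {
        v <- e@values[[field]]
        if (is.null(v)) NA_real_ else as.numeric(v)
      })
      known <- vals[!is.na(vals)]
      if (length(unique(known)) > 1)
        conflicts[[length(conflicts) + 1]] <- list(
          group = gid, field = field,
          species = rep@localName,
          values = stats::setNames(vals, mods[ord]))
    }
  }
  new("MergePlan", groups = keptGroups, representatives = representatives,
      removed = removed, newBonds = newBonds, conflicts = conflicts)
}

setMethod("show", "MergePlan", function(object) {
  cat(sprintf(
    "MergePlan: %d groups, %d duplicates removed, %d inter-module bonds, %d conflicts\n",
    length(object@groups), nrow(object@removed), nrow(object@newBonds),
    length(object@conflicts)))
})

#' Resolve value conflicts in a merge plan
#'
#' Policies: `"keep-first"` keeps the representative's value (first module
#' in user order); `"keep-module"` keeps the named module's value;
#' `"override"` takes values from `overrides`; `"interactive"` prompts the
#' user and is an error in non-interactive sessions. Every resolution is
#' logged with `message()`.
#'
#' @param plan a [MergePlan-class].
#' @param policy conflict policy.
#' @param module for `"keep-module"`: the module whose values win.
#' @param overrides for `"override"`: named list
#'   `list(<species> = list(q0 = ..., Kq = ...))`.
#' @return named list keyed `<representativeModule>:<species>`, each a list
#'   of resolved field values (empty fields omitted).
#' @export
resolveConflicts <- function(plan,
                             policy = c("keep-first", "keep-module",
                                        "override", "interactive"),
                             module = NULL, overrides = NULL) {
  policy <- match.arg(policy)
  stopifnot(is(plan, "MergePlan"))
  if (policy == "interactive" && !interactive())
    bgStop("bgUsageError",
           "interactive conflict resolution requires an interactive session")
  if (policy == "keep-module" && is.null(module))
    bgStop("bgUsageError", "policy keep-module needs a module name")
  if (policy == "override") {
    known <- vcapply(plan@representatives, function(e) e@localName)
    unknown <- setdiff(names(overrides), known)
    if (length(unknown))
      bgStop("bgLookupError", "override for unknown merged species: %s",
             paste(unknown, collapse = ", "))
  }
  resolved <- list()
  for (cf in plan@conflicts) {
    rep <- plan@representatives[[cf$group]]
    key <- paste0(rep@module, ":", rep@localName)
    value <- switch(policy,
      "keep-first" = unname(cf$values[[rep@module]]),
      "keep-module" = {
        if (!(module %in% names(cf$values)))
          bgStop("bgLookupError",
                 "module '%s' has no value for %s of %s", module, cf$field,
                 cf$species)
        unname(cf$values[[module]])
      },
      "override" = {
        ov <- overrides[[cf$species]][[cf$field]]
        if (is.null(ov))
          bgStop("bgLookupError", "no override supplied for %s of %s",
                 cf$field, cf$species)
        as.numeric(ov)
      },
      "interactive" = {
        cat(sprintf("Conflicting %s for %s: %s\n", cf$field, cf$species,
                    paste(sprintf("%s = %g", names(cf$values), cf$values),
                          collapse = ", ")))
        as.numeric(readline("value to use: "))
      })
    if (is.null(resolved[[key]])) resolved[[key]] <- list()
    resolved[[key]][[cf$field]] <- value
    message(sprintf("conflict on %s of %s resolved to %g (policy %s)",
                    cf$field, cf$species, value, policy))
  }
  resolved
}

#' Compose annotated modules into one network
#'
#' Carries out the plan: module components are namespaced
#' `<module>:<name>`, removed duplicates are dropped, their reactions are
#' rewired to the representative species, and resolved conflict values are
#' applied. The whole-system connectivity matrix is the block-diagonal
#' stack of per-module matrices with the duplicates' rows/columns deleted
#' and the planned inter-module 1-pairs inserted. The returned ODE system
#' realises the merged flow balance: at a merged junction dq/dt is the
#' signed sum of all adjacent reaction fluxes across modules.
#'
#' @param modules named list of [BondGraphNetwork-class] objects.
#' @param plan a [MergePlan-class] from [planMerge()].
#' @param resolved conflict resolutions from [resolveConflicts()]; required
#'   when the plan carries conflicts.
#' @return list with `network` (composed [BondGraphNetwork-class]), `system`
#'   (its [ODESystem-class], when fully parameterised), `matrix` (composed
#'   [ConnectivityMatrix-class]) and `plan`.
#' @export
composeNetworks <- function(modules, plan, resolved = list()) {
  stopifnot(is.list(modules), !is.null(names(modules)), is(plan, "MergePlan"))
  if (length(plan@conflicts)) {
    need <- unique(vcapply(plan@conflicts, function(cf) {
      rep <- plan@representatives[[cf$group]]
      paste0(rep@module, ":", rep@localName)
    }))
    unresolvedKeys <- setdiff(need, names(resolved))
    if (length(unresolvedKeys))
      bgStop("bgUsageError", "unresolved value conflicts for: %s",
             paste(unresolvedKeys, collapse = ", "))
  }
  qualified <- function(m, s) paste0(m, ":", s)
  # map every module-qualified species to its surviving qualified name
  rename <- list()
  if (nrow(plan@removed))
    for (i in seq_len(nrow(plan@removed)))
      rename[[qualified(plan@removed$module[i], plan@removed$name[i])]] <-
        qualified(plan@removed$representativeModule[i],
                  plan@removed$representativeName[i])

  ctx <- modules[[1]]@context
  for (m in modules[-1])
    if (!isTRUE(all.equal(m@context@RT, ctx@RT)))
      bgStop("bgValidationError", "modules disagree on thermodynamic context")

  species <- list()
  for (m in names(modules)) {
    for (s in modules[[m]]@species) {
      qn <- qualified(m, s@name)
      if (!is.null(rename[[qn]])) next  # removed duplicate
      s@name <- qn
      species[[qn]] <- s
    }
  }
  # apply resolved conflict values to representatives
  for (key in names(resolved)) {
    if (is.null(species[[key]]))
      bgStop("bgLookupError", "resolved value for unknown species '%s'", key)
    vals <- resolved[[key]]
    if (!is.null(vals$q0)) species[[key]]@q0 <- vals$q0
    if (!is.null(vals$Kq)) species[[key]]@Kq <- vals$Kq
  }
  reactions <- list()
  for (m in names(modules)) {
    for (r in modules[[m]]@reactions) {
      mapSide <- function(st) {
        nm <- vcapply(names(st), function(s) {
          qn <- qualified(m, s)
          if (!is.null(rename[[qn]])) rename[[qn]] else qn
        })
        stats::setNames(unname(st), unname(nm))
      }
      r@name <- qualified(m, r@name)
      r@reactants <- mapSide(r@reactants)
      r@products <- mapSide(r@products)
      reactions[[r@name]] <- r
    }
  }
  network <- buildNetwork(unname(species), unname(reactions), ctx)

  cms <- lapply(modules, toConnectivityMatrix)
  big <- blockDiagonalMatrix(cms, names(modules))
  removeLabels <- if (nrow(plan@removed))
    paste0(plan@removed$module, ":0:", plan@removed$name) else character()
  composedCM <- editMatrix(big, remove = removeLabels,
                           addBonds = plan@newBonds)

  system <- tryCatch(assembleODEs(network),
                     bgParameterError = function(e) NULL)
  list(network = network, system = system, matrix = composedCM, plan = plan)
}

#' One-call semantic composition of modules
#'
#' Extracts annotated entities from each module's species, matches identical
#' annotation sets, filters mergeability, plans the merge, resolves
#' conflicts under the given policy and composes. With no matches the
#' modules are stacked unmerged (block-diagonal) after a warning.
#'
#' @inheritParams composeNetworks
#' @inheritParams resolveConflicts
#' @return as [composeNetworks()].
#' @export
mergeNetworks <- function(modules, policy = "keep-first", module = NULL,
                          overrides = NULL) {
  stopifnot(is.list(modules), !is.null(names(modules)))
  entities <- lapply(names(modules), function(m)
    annotatedEntities(modules[[m]], m))
  names(entities) <- names(modules)
  groups <- withCallingHandlers(
    matchEntities(entities),
    bgNoMatchWarning = function(w) invokeRestart("muffleWarning"))
  if (!length(groups))
    bgWarn("bgNoMatchWarning",
           "no identical annotations detected; modules stacked without merging")
  plan <- planMerge(modules, groups)
  resolved <- resolveConflicts(plan, policy = policy, module = module,
                               overrides = overrides)
  composeNetworks(modules, plan, resolved)
}

#' Select a symbolic template matching a document's annotations
#'
#' Returns the id of the registry template whose signature annotation set
#' is a subset of the annotations present in the entities. No match yields
#' an explicit not-found result (`NA_character_`); several matches are an
#' ambiguity error naming all of them.
#'
#' @param entities list of [AnnotatedEntity-class] (e.g. from
#'   [extractAnnotations()]).
#' @param registry named list of [SymbolicTemplate-class] objects.
#' @return template id, or `NA_character_` when none matches.
#' @export
selectTemplate <- function(entities, registry) {
  present <- unique(unlist(lapply(entities, function(e) e@annotations)))
  hits <- names(registry)[vlapply(registry, function(tpl)
    length(tpl@signature) > 0 && all(tpl@signature %in% present))]
  if (length(hits) == 0) return(NA_character_)
  if (length(hits) > 1)
    bgStop("bgAmbiguityError", "multiple templates match: %s",
           paste(hits, collapse = ", "))
  hits
}
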