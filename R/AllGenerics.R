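#' @rdname toConnectivityMatrix
#' @export
setGeneric("toConnectivityMatrix",
  function(network) standardGeneric("toConnectivityMatrix"))

#' @rdname assembleODEs
#' @export
setGeneric("assembleODEs", function(network) standardGeneric("assembleODEs"))

#' @rdname simulateODE
#' @export
setGeneric("simulateODE",
  function(system, tMax, q0 = NULL, times = NULL,
           rtol = 1e-8, atol = 1e-12, keepFluxes = TRUE)
    standardGeneric("simulateODE"))

#' @rdname steadyState
#' @export
setGeneric("steadyState",
  function(system, q0 = NULL, tol = 1e-9, tFirst = 10, maxDoublings = 45,
           rtol = 1e-8, atol = 1e-12)
    standardGeneric("steadyState"))

#' Accessors for bond-graph objects
#'
#' `speciesNames()`, `reactionNames()`, `chemostatNames()` return component
#' identifiers; `getSpecies()`/`getReaction()` return a single component;
#' `initialState()` the named vector of initial amounts; `labels()` the
#' element labels of a connectivity matrix.
#'
#' @param x a [BondGraphNetwork-class] or [ConnectivityMatrix-class].
#' @param name component identifier.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname accessors
#' @export
setGeneric("reactionNames", function(x) standardGeneric("reactionNames"))

#' @rdname accessors
#' @export
setGeneric("chemostatNames", function(x) standardGeneric("chemostatNames"))

#' @rdname accessors
#' @export
setGeneric("getSpecies", function(x, name) standardGeneric("getSpecies"))

#' @rdname accessors
#' @export
setGeneric("getReaction", function(x, name) standardGeneric("getReaction"))

#' @rdname accessors
#' @export
setGeneric("initialState", function(x) standardGeneric("initialState"))
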