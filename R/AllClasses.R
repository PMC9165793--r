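#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Thermodynamic context
#'
#' Holds the ideal gas constant `R` (J mol^-1 K^-1), the absolute temperature
#' `T` (K) and their product `RT` (J mol^-1). All chemical potentials reported
#' by the package are on the `RT` scale set here; reaction fluxes in the
#' mass-action form do not depend on it.
#'
#' @slot R ideal gas constant (J mol^-1 K^-1).
#' @slot T absolute temperature (K).
#' @slot RT product R*T (J mol^-1).
#' @export
setClass("ThermoContext",
  representation(R = "numeric", T = "numeric", RT = "numeric"))

setValidity("ThermoContext", function(object) {
  msg <- character()
  if (length(object@R) != 1 || !is.finite(object@R) || object@R <= 0)
    msg <- c(msg, "R must be a single positive number")
  if (length(object@T) != 1 || !is.finite(object@T) || object@T <= 0)
    msg <- c(msg, "T must be a single positive number")
  if (length(object@RT) != 1 || !isTRUE(all.equal(object@RT, object@R * object@T)))
    msg <- c(msg, "RT must equal R*T")
  if (length(msg)) msg else TRUE
})

#' Species storage component
#'
#' A chemical species modelled as a nonlinear storage element with
#' constitutive relation u = RT*ln(Kq*q). A chemostat is a species whose
#' amount (hence chemical potential) is held fixed during simulation, e.g.
#' the ATP/ADP/Pi pools.
#'
#' @slot name species identifier, unique within a network.
#' @slot annotations character vector of ontology-term identifier strings
#'   used for semantic matching during composition (may be empty).
#' @slot Kq species thermodynamic constant (> 0, per concentration unit);
#'   `NA` in symbolic templates awaiting parameterisation.
#' @slot q0 initial amount (concentration units, >= 0; `NA` in templates).
#' @slot isChemostat logical flag.
#' @export
setClass("SpeciesComponent",
  representation(name = "character", annotations = "character",
                 Kq = "numeric", q0 = "numeric", isChemostat = "logical"))

setValidity("SpeciesComponent", function(object) {
  msg <- character()
  if (length(object@name) != 1 || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (length(object@Kq) != 1 || (!is.na(object@Kq) && object@Kq <= 0))
    msg <- c(msg, sprintf("Kq of '%s' must be a single positive number or NA",
                          object@name[1]))
  if (length(object@q0) != 1 || (!is.na(object@q0) && object@q0 < 0))
    msg <- c(msg, sprintf("q0 of '%s' must be a single non-negative number or NA",
                          object@name[1]))
  if (length(object@isChemostat) != 1 || is.na(object@isChemostat))
    msg <- c(msg, "isChemostat must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Reaction (dissipative) component
#'
#' A reversible mass-action reaction modelled as a Marcelin-de Donder
#' dissipative element with rate constant `kappa` and signed integer
#' stoichiometries (the transformer ratios of the bond graph).
#'
#' @slot name reaction identifier.
#' @slot kappa reaction rate constant (> 0; `NA` in symbolic templates).
#' @slot reactants named integer vector, species name -> stoichiometry >= 1.
#' @slot products named integer vector, species name -> stoichiometry >= 1.
#' @export
setClass("ReactionComponent",
  representation(name = "character", kappa = "numeric",
                 reactants = "numeric", products = "numeric"))

setValidity("ReactionComponent", function(object) {
  msg <- character()
  if (length(object@name) != 1 || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (length(object@kappa) != 1 || (!is.na(object@kappa) && object@kappa <= 0))
    msg <- c(msg, sprintf("kappa of '%s' must be positive or NA", object@name[1]))
  for (side in c("reactants", "products")) {
    st <- slot(object, side)
    if (length(st) == 0)
      msg <- c(msg, sprintf("%s of '%s' must be non-empty", side, object@name[1]))
    if (is.null(names(st)) || any(!nzchar(names(st))) || anyDuplicated(names(st)))
      msg <- c(msg, sprintf("%s of '%s' must have unique species names", side,
                            object@name[1]))
    if (any(st < 1) || any(st != round(st)))
      msg <- c(msg, sprintf("%s stoichiometries of '%s' must be positive integers",
                            side, object@name[1]))
  }
  if (length(intersect(names(object@reactants), names(object@products))))
    msg <- c(msg, sprintf(
      "reactants and products of '%s' must be disjoint (shared: %s)",
      object@name[1],
      paste(intersect(names(object@reactants), names(object@products)),
            collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Biochemical bond-graph network
#'
#' Species components plus reaction components under a thermodynamic context.
#' The junction wiring is canonical and implied by the structure: one '0:u'
#' junction per species, one Re element per reaction, a '1:v' junction on any
#' reaction side with more than one participant or a stoichiometry above one,
#' and a TF element per stoichiometry above one.
#'
#' @slot species list of [SpeciesComponent-class] objects.
#' @slot reactions list of [ReactionComponent-class] objects.
#' @slot context a [ThermoContext-class].
#' @export
setClass("BondGraphNetwork",
  representation(species = "list", reactions = "list",
                 context = "ThermoContext"))

#' Labelled symmetric binary connectivity matrix
#'
#' Dual view of a bond-graph network: rows/columns are bond-graph elements
#' (species 0-junctions, Re elements, side 1-junctions, TF elements) and a 1
#' marks a bond between two elements. Bonds are bidirectional, so the matrix
#' is symmetric with a zero diagonal.
#'
#' @slot labels ordered element identifiers.
#' @slot matrix square binary matrix with `labels` as dimnames.
#' @export
setClass("ConnectivityMatrix",
  representation(labels = "character", matrix = "matrix"))

setValidity("ConnectivityMatrix", function(object) {
  m <- object@matrix
  n <- length(object@labels)
  msg <- character()
  if (anyDuplicated(object@labels))
    msg <- c(msg, "labels must be unique")
  if (nrow(m) != n || ncol(m) != n)
    msg <- c(msg, "matrix dimension must equal the number of labels")
  else {
    if (!all(m %in% c(0, 1)))
      msg <- c(msg, "entries must be 0 or 1")
    if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE)))
      msg <- c(msg, "matrix must be symmetric")
    if (n > 0 && any(diag(m) != 0))
      msg <- c(msg, "diagonal must be zero")
    if (n > 0 && (!identical(rownames(m), object@labels) ||
                  !identical(colnames(m), object@labels)))
      msg <- c(msg, "dimnames must equal labels")
  }
  if (length(msg)) msg else TRUE
})

#' Kinetic description of a reaction awaiting conversion
#'
#' Either reversible mass action (`kPlus`, `kMinus`), irreversible mass
#' action (`kPlus` only), or irreversible Michaelis-Menten (`Vmax`, `Km`).
#'
#' @slot name reaction identifier.
#' @slot reactants,products named stoichiometry vectors as in
#'   [ReactionComponent-class].
#' @slot kPlus forward rate constant (NA if Michaelis-Menten).
#' @slot kMinus reverse rate constant (NA if irreversible).
#' @slot Vmax,Km Michaelis-Menten constants (NA unless irreversible MM).
#' @slot irreversible logical flag.
#' @export
setClass("KineticReaction",
  representation(name = "character", reactants = "numeric",
                 products = "numeric", kPlus = "numeric", kMinus = "numeric",
                 Vmax = "numeric", Km = "numeric", irreversible = "logical"))

setValidity("KineticReaction", function(object) {
  msg <- character()
  has <- function(x) length(x) == 1 && !is.na(x)
  pos <- function(x) !has(x) || x > 0
  massAction <- has(object@kPlus)
  mm <- has(object@Vmax) || has(object@Km)
  if (massAction && mm)
    msg <- c(msg, "provide either rate constants or Vmax/Km, not both")
  if (!massAction && !(has(object@Vmax) && has(object@Km)))
    msg <- c(msg, "provide kPlus (with optional kMinus) or both Vmax and Km")
  if (mm && !object@irreversible)
    msg <- c(msg, "Michaelis-Menten form is irreversible")
  if (has(object@kMinus) && object@irreversible)
    msg <- c(msg, "a reaction with kMinus cannot be flagged irreversible")
  if (massAction && !has(object@kMinus) && !object@irreversible)
    msg <- c(msg, "a reaction without kMinus must be flagged irreversible")
  for (x in c("kPlus", "kMinus", "Vmax", "Km"))
    if (!pos(slot(object, x))) msg <- c(msg, paste(x, "must be > 0"))
  if (length(msg)) msg else TRUE
})

#' Result of kinetic-to-bond-graph parameter conversion
#'
#' @slot kappa named numeric, reaction -> rate constant.
#' @slot Kq named numeric, species -> thermodynamic constant.
#' @slot residual sum of squared log-space constraint errors.
#' @slot consistent TRUE when residual is at or below `threshold`.
#' @slot threshold consistency threshold on the residual.
#' @slot fixed named numeric of species whose Kq was held fixed (gauge).
#' @slot gaugeUnderdetermined TRUE when the system was rank-deficient and
#'   solved by the minimum-norm convention.
#' @export
setClass("ConversionResult",
  representation(kappa = "numeric", Kq = "numeric", residual = "numeric",
                 consistent = "logical", threshold = "numeric",
                 fixed = "numeric", gaugeUnderdetermined = "logical"))

#' Assembled ODE system
#'
#' Mass-action rate equations of a parameterised network: for each
#' non-chemostat species, dq/dt is the flow balance at its 0-junction,
#' i.e. the stoichiometric matrix times the per-reaction flux vector.
#' Chemostat rates are identically zero.
#'
#' @slot stateLabels ordered species names (non-chemostats first).
#' @slot rate function(state) -> named rate vector.
#' @slot flux function(state) -> named per-reaction flux vector.
#' @slot potentials function(state) -> named chemical potential vector
#'   (J mol^-1); defined only for strictly positive amounts.
#' @slot stoichiometry species x reaction signed stoichiometric matrix.
#' @slot conservedMoieties matrix whose columns span the left null space of
#'   the stoichiometric matrix restricted to non-chemostat species.
#' @slot chemostats names of chemostat species.
#' @slot q0 named default initial state taken from the network.
#' @export
setClass("ODESystem",
  representation(stateLabels = "character", rate = "function",
                 flux = "function", potentials = "function",
                 stoichiometry = "matrix", conservedMoieties = "matrix",
                 chemostats = "character", q0 = "numeric"))

#' Simulated trajectory
#'
#' @slot times strictly increasing times (s).
#' @slot states time x species matrix of amounts.
#' @slot fluxes time x reaction matrix (optional; may have zero columns).
#' @export
setClass("Trajectory",
  representation(times = "numeric", states = "matrix", fluxes = "matrix"))

setValidity("Trajectory", function(object) {
  msg <- character()
  if (length(object@times) < 1 || any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (nrow(object@states) != length(object@times))
    msg <- c(msg, "states must have one row per time")
  if (length(msg)) msg else TRUE
})

#' Annotated model entity
#'
#' One annotated variable/component extracted from a module or model
#' document, the unit of semantic matching during composition.
#'
#' @slot module source module identifier.
#' @slot localName name within the module.
#' @slot kind one of "species", "chemostat", "reaction", "parameter".
#' @slot annotations character set of identifier strings.
#' @slot values named list with any of Kq, q0, kappa; units text preserved
#'   under "units" when known.
#' @export
setClass("AnnotatedEntity",
  representation(module = "character", localName = "character",
                 kind = "character", annotations = "character",
                 values = "list"))

setValidity("AnnotatedEntity", function(object) {
  kinds <- c("species", "chemostat", "reaction", "parameter")
  if (!(length(object@kind) == 1 && object@kind %in% kinds))
    return(sprintf("kind must be one of %s", paste(kinds, collapse = ", ")))
  TRUE
})

#' Merge plan for module composition
#'
#' @slot groups list of matched [AnnotatedEntity-class] groups.
#' @slot representatives list, one kept entity per group.
#' @slot removed data.frame with columns module, name, representativeModule,
#'   representativeName for every deduplicated species.
#' @slot newBonds two-column character matrix of inter-module bonds
#'   (representative 0-junction label, former bond partner label).
#' @slot conflicts list of records (group id, field, per-module values).
#' @export
setClass("MergePlan",
  representation(groups = "list", representatives = "list",
                 removed = "data.frame", newBonds = "matrix",
                 conflicts = "list"))

#' Symbolic bond-graph template
#'
#' A network with unset (NA) parameters plus the annotation signature used
#' for automatic template selection, and the parameter slots a document must
#' fill before the template can be simulated.
#'
#' @slot structure a [BondGraphNetwork-class] with NA parameters allowed.
#' @slot signature character set of annotation identifiers that identify the
#'   template.
#' @slot slots named character vector of parameter placeholders
#'   ("Kq:<species>", "q0:<species>", "kappa:<reaction>").
#' @slot roles named character vector mapping template role names to the
#'   species names in `structure` (used when instantiating).
#' @export
setClass("SymbolicTemplate",
  representation(structure = "BondGraphNetwork", signature = "character",
                 slots = "character", roles = "character"))

#' Dose-response scan
#'
#' @slot inputs strictly increasing input amounts (log-spaced grid).
#' @slot outputs input x observed-species matrix of steady-state amounts.
#' @slot normalised outputs with each column divided by its own maximum.
#' @slot inputSpecies name of the clamped input species.
#' @export
setClass("DoseResponse",
  representation(inputs = "numeric", outputs = "matrix",
                 normalised = "matrix", inputSpecies = "character"))

setValidity("DoseResponse", function(object) {
  msg <- character()
  if (any(diff(object@inputs) <= 0))
    msg <- c(msg, "inputs must be strictly increasing")
  if (nrow(object@outputs) != length(object@inputs))
    msg <- c(msg, "outputs must have one row per input")
  if (length(object@normalised) &&
      any(object@normalised < -1e-9 | object@normalised > 1 + 1e-9))
    msg <- c(msg, "normalised values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
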