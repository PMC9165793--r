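#' Create a kinetic reaction description
#'
#' Exactly one of three forms: reversible mass action (`kPlus` and
#' `kMinus`), irreversible mass action (`kPlus` only), or irreversible
#' Michaelis-Menten (`Vmax` and `Km`).
#'
#' @param name reaction identifier.
#' @param reactants,products named stoichiometry vectors.
#' @param kPlus,kMinus forward/reverse mass-action rate constants.
#' @param Vmax,Km Michaelis-Menten constants.
#' @return a [KineticReaction-class].
#' @examples
#' kineticReaction("r1", c(A = 1), c(B = 1), kPlus = 2, kMinus = 1)
#' kineticReaction("r2", c(S = 1), c(P = 1), Vmax = 10, Km = 0.3)
#' @export
kineticReaction <- function(name, reactants, products,
                            kPlus = NA_real_, kMinus = NA_real_,
                            Vmax = NA_real_, Km = NA_real_) {
  irr <- is.na(kMinus)
  new("KineticReaction", name = as.character(name),
      reactants = namedNumeric(reactants), products = namedNumeric(products),
      kPlus = as.numeric(kPlus), kMinus = as.numeric(kMinus),
      Vmax = as.numeric(Vmax), Km = as.numeric(Km),
      irreversible = irr)
}

#' Kinetic mass-action flux
#'
#' v = kPlus * prod qr^alpha - kMinus * prod qp^beta, the rate-law form the
#' conversion must reproduce.
#'
#' @param kinetic a reversible mass-action [KineticReaction-class].
#' @param amounts named numeric map species -> amount.
#' @return scalar flux.
#' @export
kineticFlux <- function(kinetic, amounts) {
  stopifnot(is(kinetic, "KineticReaction"))
  if (is.na(kinetic@kPlus))
    bgStop("bgUsageError", "kineticFlux needs mass-action constants")
  km <- if (is.na(kinetic@kMinus)) 0 else kinetic@kMinus
  fw <- prod(amounts[names(kinetic@reactants)]^kinetic@reactants)
  bw <- prod(amounts[names(kinetic@products)]^kinetic@products)
  unname(kinetic@kPlus * fw - km * bw)
}

#' Build the log-linear constraint system of a kinetic network
#'
#' Each reversible mass-action reaction contributes two constraints,
#' kPlus = kappa * prod Kr^alpha and kMinus = kappa * prod Kp^beta, which
#' become linear after taking logarithms. Unknowns are ln kappa per reaction
#' and ln Kq per non-fixed species; fixed species constants are moved to the
#' right-hand side (the natural place to pin shared chemostat potentials,
#' e.g. ATP/ADP/Pi constants inherited from an already-converted module).
#'
#' @param kinetics list of reversible mass-action [KineticReaction-class]
#'   objects (approximate irreversible ones first, see
#'   [approximateIrreversible()]).
#' @param fixed named numeric of species Kq values held fixed (> 0).
#' @return list with `A` (constraint matrix), `b` (rhs of log constraints),
#'   `unknowns` (column labels `kappa:<reaction>` / `Kq:<species>`),
#'   `fixed`, and `rows` (constraint labels).
#' @export
buildLogLinearSystem <- function(kinetics, fixed = numeric()) {
  stopifnot(is.list(kinetics))
  fixed <- namedNumeric(fixed)
  if (any(fixed <= 0))
    bgStop("bgDomainError", "fixed Kq values must be positive")
  for (k in kinetics) {
    stopifnot(is(k, "KineticReaction"))
    if (is.na(k@kPlus) || is.na(k@kMinus))
      bgStop("bgUsageError",
             "reaction '%s' is not reversible mass action; approximate it first",
             k@name)
    if (k@kPlus <= 0 || k@kMinus <= 0)
      bgStop("bgDomainError", "rate constants of '%s' must be positive",
             k@name)
  }
  speciesAll <- unique(unlist(lapply(kinetics, function(k)
    c(names(k@reactants), names(k@products)))))
  unused <- setdiff(names(fixed), speciesAll)
  if (length(unused))
    bgWarn("bgUnusedFixedWarning",
           "fixed species not in any reaction: %s",
           paste(unused, collapse = ", "))
  free <- setdiff(speciesAll, names(fixed))
  rxNames <- vcapply(kinetics, function(k) k@name)
  unknowns <- c(paste0("kappa:", rxNames), paste0("Kq:", free))
  A <- matrix(0, 2 * length(kinetics), length(unknowns),
              dimnames = list(NULL, unknowns))
  b <- numeric(2 * length(kinetics))
  rows <- character(2 * length(kinetics))
  for (j in seq_along(kinetics)) {
    k <- kinetics[[j]]
    for (dir in 1:2) {
      i <- 2 * (j - 1) + dir
      st <- if (dir == 1) k@reactants else k@products
      rate <- if (dir == 1) k@kPlus else k@kMinus
      rows[i] <- paste0(k@name, if (dir == 1) ":+" else ":-")
      A[i, paste0("kappa:", k@name)] <- 1
      rhs <- log(rate)
      for (sp in names(st)) {
        if (sp %in% names(fixed)) rhs <- rhs - st[[sp]] * log(fixed[[sp]])
        else A[i, paste0("Kq:", sp)] <- st[[sp]]
      }
      b[i] <- rhs
    }
  }
  list(A = A, b = b, unknowns = unknowns, fixed = fixed, rows = rows)
}

#' Solve the log-linear system for bond-graph parameters
#'
#' Minimum-norm least squares in log space via singular value
#' decomposition, exponentiated back to kappa and Kq. The residual is the
#' squared norm of the log-space misfit; it is zero (to rounding) exactly
#' when the kinetic scheme satisfies detailed balance, in which case the
#' recovered parameters reproduce every rate constant.
#'
#' @param system output of [buildLogLinearSystem()].
#' @param threshold residual at or below which the scheme is declared
#'   thermodynamically consistent.
#' @return a [ConversionResult-class].
#' @export
solveParameters <- function(system, threshold = 1e-12) {
  A <- system$A
  b <- system$b
  sv <- svd(A)
  svTol <- max(dim(A)) * max(sv$d, 0) * .Machine$double.eps
  pos <- sv$d > svTol
  rank <- sum(pos)
  x <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos])
  x <- as.numeric(x)
  names(x) <- system$unknowns
  residual <- sum((as.vector(A %*% x) - b)^2)
  under <- rank < ncol(A)
  isK <- startsWith(system$unknowns, "kappa:")
  kappa <- exp(x[isK])
  names(kappa) <- sub("^kappa:", "", names(kappa))
  Kq <- exp(x[!isK])
  names(Kq) <- sub("^Kq:", "", names(Kq))
  Kq <- c(Kq, system$fixed[setdiff(names(system$fixed), names(Kq))])
  new("ConversionResult", kappa = kappa, Kq = namedNumeric(Kq),
      residual = residual, consistent = residual <= threshold,
      threshold = threshold, fixed = namedNumeric(system$fixed),
      gaugeUnderdetermined = under)
}

setMethod("show", "ConversionResult", function(object) {
  cat(sprintf(
    "ConversionResult: %d kappa, %d Kq; residual %.3e -> %s%s\n",
    length(object@kappa), length(object@Kq), object@residual,
    if (object@consistent) "thermodynamically consistent"
    else "NOT consistent (detailed balance violated)",
    if (object@gaugeUnderdetermined) " [gauge-underdetermined]" else ""))
})

#' Convert kinetics to bond-graph parameters
#'
#' One-call wrapper around [buildLogLinearSystem()] and
#' [solveParameters()]. The constraint system only determines the
#' parameters up to a gauge (rescalings of the Kq that leave every
#' kPlus/kMinus unchanged); by default that freedom is resolved by the
#' deterministic minimum-norm convention, which never perturbs the misfit.
#' Supplying `fixed` (e.g. shared chemostat potentials) pins constants
#' explicitly instead; note that fixing a species whose constant is
#' identifiable from the constraints at a value inconsistent with them
#' raises the residual. `autoGauge = TRUE` fixes Kq = 1 for one species per
#' connected component of the species-reaction graph, which is safe only
#' when each anchor species genuinely carries gauge freedom.
#'
#' @inheritParams buildLogLinearSystem
#' @inheritParams solveParameters
#' @param autoGauge fix one species per connected component when `fixed` is
#'   empty (off by default; the minimum-norm convention is the gauge).
#' @return a [ConversionResult-class].
#' @export
convertKinetics <- function(kinetics, fixed = numeric(), threshold = 1e-12,
                            autoGauge = FALSE) {
  fixed <- namedNumeric(fixed)
  if (!length(fixed) && autoGauge && length(kinetics)) {
    comp <- speciesComponents_(kinetics)
    anchors <- vcapply(comp, `[[`, 1L)
    fixed <- stats::setNames(rep(1, length(anchors)), anchors)
  }
  solveParameters(buildLogLinearSystem(kinetics, fixed), threshold)
}

# connected components of the species set under "share a reaction";
# tiny union-find
speciesComponents_ <- function(kinetics) {
  speciesAll <- unique(unlist(lapply(kinetics, function(k)
    c(names(k@reactants), names(k@products)))))
  parent <- stats::setNames(seq_along(speciesAll), speciesAll)
  find <- function(i) {
    while (parent[[i]] != i) i <- parent[[i]]
    i
  }
  for (k in kinetics) {
    idx <- match(c(names(k@reactants), names(k@products)), speciesAll)
    r <- find(idx[1])
    for (i in idx[-1]) parent[[find(i)]] <- r
  }
  roots <- vnapply(seq_along(speciesAll), find)
  split(speciesAll, roots)
}

#' Detailed-balance residual of a kinetic scheme
#'
#' Builds and solves the log-linear system and returns the residual only:
#' zero iff a thermodynamically consistent bond-graph parameterisation
#' reproduces the kinetics exactly (Wegscheider loop conditions hold).
#'
#' @inheritParams convertKinetics
#' @return the non-negative residual.
#' @export
detailedBalanceResidual <- function(kinetics, fixed = numeric()) {
  convertKinetics(kinetics, fixed)@residual
}

#' Approximate an irreversible reaction for bond-graph conversion
#'
#' Irreversible reactions are thermodynamically impossible in an
#' energy-based model, so two approximation policies are offered:
#' `"small-kminus"` assigns kMinus = epsilon * kPlus so the reverse flux is
#' negligible (for Michaelis-Menten input, kPlus defaults to Vmax/Km, the
#' low-saturation slope); `"trajectory-fit"` additionally estimates kappa by
#' minimising the squared error between the mass-action approximation's
#' simulated time course and a supplied reference time course, using
#' deterministic bounded scalar minimisation on log10(kappa).
#'
#' @param reaction an irreversible [KineticReaction-class].
#' @param mode `"small-kminus"` or `"trajectory-fit"`.
#' @param epsilon reverse/forward ratio for the small-kMinus policy.
#' @param constants named Kq map for all participants (required to report
#'   kappa; the constraint kPlus = kappa * prod Kr^alpha fixes kappa once
#'   the constants are known).
#' @param data for `"trajectory-fit"`: a data.frame with a `time` column and
#'   one amount column per participating species (the reference time
#'   course); the first row provides the initial state.
#' @param ctx thermodynamic context for the fitted simulation.
#' @param logKappaRange search interval for log10(kappa) in trajectory fit.
#' @return list with `kappa`, `kPlus`, `kMinusEffective`, and (for
#'   trajectory fit) `sse`.
#' @export
approximateIrreversible <- function(reaction,
                                    mode = c("small-kminus", "trajectory-fit"),
                                    epsilon = 1e-6, constants = NULL,
                                    data = NULL, ctx = thermoContext(),
                                    logKappaRange = c(-6, 6)) {
  mode <- match.arg(mode)
  stopifnot(is(reaction, "KineticReaction"))
  if (!reaction@irreversible)
    bgStop("bgUsageError", "reaction '%s' is not irreversible", reaction@name)
  kPlus <- if (!is.na(reaction@kPlus)) reaction@kPlus
    else reaction@Vmax / reaction@Km
  kMinus <- epsilon * kPlus
  kappaFromConstants <- function() {
    if (is.null(constants)) return(NA_real_)
    need <- names(reaction@reactants)
    if (!all(need %in% names(constants)))
      bgStop("bgLookupError", "constants missing for %s",
             paste(setdiff(need, names(constants)), collapse = ", "))
    kPlus / prod(constants[need]^reaction@reactants)
  }
  if (mode == "small-kminus") {
    return(list(kappa = unname(kappaFromConstants()), kPlus = kPlus,
                kMinusEffective = kMinus))
  }
  # trajectory fit
  if (is.null(data))
    bgStop("bgUsageError", "trajectory-fit mode requires reference data")
  if (is.null(constants))
    bgStop("bgUsageError", "trajectory-fit mode requires species constants")
  if (!("time" %in% names(data)))
    bgStop("bgFormatError", "reference data needs a 'time' column")
  participants <- c(names(reaction@reactants), names(reaction@products))
  have <- intersect(participants, names(data))
  if (!length(have))
    bgStop("bgFormatError", "reference data covers no participating species")
  q0 <- stats::setNames(vnapply(participants, function(sp)
    if (sp %in% names(data)) data[[sp]][1] else 0), participants)
  times <- data$time
  simulateCandidate <- function(kappa) {
    comps <- lapply(participants, function(sp)
      speciesComponent(sp, Kq = constants[[sp]], q0 = q0[[sp]]))
    net <- buildNetwork(comps, list(reactionComponent(
      reaction@name, reaction@reactants, reaction@products, kappa = kappa)),
      ctx)
    sys <- assembleODEs(net)
    traj <- simulateODE(sys, times = times, tMax = max(times),
                        keepFluxes = FALSE)
    traj@states
  }
  objective <- function(logKappa) {
    st <- simulateCandidate(10^logKappa)
    sum(vnapply(have, function(sp) sum((st[, sp] - data[[sp]])^2)))
  }
  opt <- stats::optimize(objective, interval = logKappaRange, tol = 1e-8)
  kappa <- 10^opt$minimum
  if (!is.finite(kappa) || kappa <= 0)
    bgStop("bgOptimError", "trajectory fit produced a non-positive kappa")
  list(kappa = kappa, kPlus = kPlus, kMinusEffective = kMinus,
       sse = opt$objective)
}

#' Write a conversion report
#'
#' Per-reaction kappa and per-species Kq as CSV plus a one-line consistency
#' summary.
#'
#' @param result a [ConversionResult-class].
#' @param path output CSV path.
#' @return `path`, invisibly; the summary is printed with `message()`.
#' @export
writeConversionCSV <- function(result, path) {
  df <- rbind(
    data.frame(component = names(result@kappa), field = "kappa",
               value = unname(result@kappa)),
    data.frame(component = names(result@Kq), field = "Kq",
               value = unname(result@Kq)),
    data.frame(component = "(all)", field = "residual",
               value = result@residual))
  utils::write.csv(df, path, row.names = FALSE)
  message(sprintf(
    "conversion residual %.3e: %s", result@residual,
    if (result@consistent) "kinetics are thermodynamically consistent"
    else "kinetics violate detailed balance; least-squares approximation"))
  invisible(path)
}
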