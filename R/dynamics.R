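#' Mass-action flux of a single reaction
#'
#' Evaluates v = kappa * (prod (Kr*qr)^alpha - prod (Kp*qp)^beta), the
#' mass-action form of the Marcelin-de Donder relation
#' v = kappa * (exp(ur/RT) - exp(up/RT)) after substituting the species
#' constitutive relation. Well defined at zero amounts (unlike the
#' potentials themselves).
#'
#' @param reaction a [ReactionComponent-class] with `kappa` set.
#' @param amounts named numeric map species -> amount.
#' @param constants named numeric map species -> Kq.
#' @return the molar flux (scalar).
#' @examples
#' r <- reactionComponent("r", c(A = 1), c(B = 1), kappa = 1)
#' reactionFlux(r, c(A = 3, B = 1), c(A = 2, B = 1))  # 2*3 - 1 = 5
#' @export
reactionFlux <- function(reaction, amounts, constants) {
  stopifnot(is(reaction, "ReactionComponent"))
  participants <- c(names(reaction@reactants), names(reaction@products))
  missingA <- setdiff(participants, names(amounts))
  if (length(missingA))
    bgStop("bgLookupError", "missing amount for %s in reaction '%s'",
           paste(missingA, collapse = ", "), reaction@name)
  missingK <- setdiff(participants, names(constants))
  if (length(missingK))
    bgStop("bgLookupError", "missing Kq for %s in reaction '%s'",
           paste(missingK, collapse = ", "), reaction@name)
  if (is.na(reaction@kappa))
    bgStop("bgParameterError", "reaction '%s' has no kappa", reaction@name)
  fw <- prod((constants[names(reaction@reactants)] *
                amounts[names(reaction@reactants)])^reaction@reactants)
  bw <- prod((constants[names(reaction@products)] *
                amounts[names(reaction@products)])^reaction@products)
  unname(reaction@kappa * (fw - bw))
}

#' Assemble the ODE system of a parameterised network
#'
#' For each non-chemostat species s, dq_s/dt = sum over reactions of
#' (beta_s - alpha_s) * v, the flow balance at its '0:u' junction; chemostat
#' rates are identically zero. Conserved moieties are a basis of the left
#' null space of the stoichiometric matrix restricted to non-chemostat
#' species.
#'
#' @param network a fully parameterised [BondGraphNetwork-class].
#' @return an [ODESystem-class].
#' @aliases assembleODEs
#' @export
setMethod("assembleODEs", "BondGraphNetwork", function(network) {
  sp <- network@species
  rx <- network@reactions
  spNames <- speciesNames(network)
  chem <- vlapply(sp, function(s) s@isChemostat)
  missing <- character()
  for (s in sp) if (is.na(s@Kq) || is.na(s@q0))
    missing <- c(missing, sprintf("species '%s' (%s)", s@name,
      paste(c("Kq", "q0")[c(is.na(s@Kq), is.na(s@q0))], collapse = ", ")))
  for (r in rx) if (is.na(r@kappa))
    missing <- c(missing, sprintf("reaction '%s' (kappa)", r@name))
  if (length(missing))
    bgStop("bgParameterError", "unparameterised components: %s",
           paste(missing, collapse = "; "))

  # order states non-chemostats first
  ord <- order(chem)
  spNames <- spNames[ord]
  chem <- chem[ord]
  Kq <- stats::setNames(vnapply(sp, function(s) s@Kq),
                        vcapply(sp, function(s) s@name))[spNames]
  q0 <- stats::setNames(vnapply(sp, function(s) s@q0),
                        vcapply(sp, function(s) s@name))[spNames]
  rxNames <- reactionNames(network)
  ctx <- network@context

  S <- matrix(0, length(spNames), length(rxNames),
              dimnames = list(spNames, rxNames))
  # precomputed index/exponent tables for fast flux evaluation
  rIdx <- pIdx <- vector("list", length(rx))
  rExp <- pExp <- vector("list", length(rx))
  kappa <- numeric(length(rx))
  for (j in seq_along(rx)) {
    r <- rx[[j]]
    S[names(r@reactants), j] <- S[names(r@reactants), j] - r@reactants
    S[names(r@products), j] <- S[names(r@products), j] + r@products
    rIdx[[j]] <- match(names(r@reactants), spNames)
    pIdx[[j]] <- match(names(r@products), spNames)
    rExp[[j]] <- unname(r@reactants)
    pExp[[j]] <- unname(r@products)
    kappa[j] <- r@kappa
  }
  KqU <- unname(Kq)
  nR <- length(rx)

  fluxFun <- function(state) {
    q <- unname(state[spNames])
    v <- numeric(nR)
    for (j in seq_len(nR)) {
      v[j] <- kappa[j] *
        (prod((KqU[rIdx[[j]]] * q[rIdx[[j]]])^rExp[[j]]) -
         prod((KqU[pIdx[[j]]] * q[pIdx[[j]]])^pExp[[j]]))
    }
    names(v) <- rxNames
    v
  }
  rateFun <- function(state) {
    v <- fluxFun(state)
    r <- as.vector(S %*% v)
    r[chem] <- 0
    names(r) <- spNames
    r
  }
  potFun <- function(state) {
    q <- state[spNames]
    stats::setNames(chemicalPotential(KqU, unname(q), ctx), spNames)
  }

  Snc <- S[!chem, , drop = FALSE]
  moieties <- if (nrow(Snc)) MASS::Null(Snc) else
    matrix(0, 0, 0)
  if (length(moieties)) rownames(moieties) <- spNames[!chem]

  new("ODESystem", stateLabels = spNames, rate = rateFun, flux = fluxFun,
      potentials = potFun, stoichiometry = S, conservedMoieties = moieties,
      chemostats = spNames[chem], q0 = q0)
})

setMethod("show", "ODESystem", function(object) {
  cat(sprintf("ODESystem: %d states (%d chemostats), %d reactions, %d conserved moieties\n",
              length(object@stateLabels), length(object@chemostats),
              ncol(object@stoichiometry),
              if (length(object@conservedMoieties))
                ncol(object@conservedMoieties) else 0))
})

#' Plain-text listing of the rate equations
#'
#' @param system an [ODESystem-class].
#' @return character vector, one equation per species, plus flux definitions.
#' @export
odeListing <- function(system) {
  S <- system@stoichiometry
  lines <- character()
  for (j in colnames(S)) {
    col <- S[, j]
    terms <- col[col != 0]
    lines <- c(lines, sprintf("v_%s : mass-action flux of reaction %s", j, j))
  }
  for (s in rownames(S)) {
    if (s %in% system@chemostats) {
      lines <- c(lines, sprintf("dq_%s/dt = 0   (chemostat)", s))
      next
    }
    col <- stats::setNames(as.vector(S[s, , drop = FALSE]), colnames(S))
    terms <- col[col != 0]
    if (!length(terms)) {
      lines <- c(lines, sprintf("dq_%s/dt = 0", s))
      next
    }
    rhs <- paste(sprintf("%s%s*v_%s",
                         ifelse(terms > 0, "+", "-"),
                         abs(terms), names(terms)), collapse = " ")
    rhs <- sub("^\\+", "", rhs)
    rhs <- gsub("1\\*", "", rhs)
    lines <- c(lines, sprintf("dq_%s/dt = %s", s, rhs))
  }
  lines
}

#' Simulate an ODE system
#'
#' Stiff-capable integration with `deSolve::ode` (lsoda). Chemostat states
#' are carried in the state vector with zero rates, so they stay constant
#' exactly.
#'
#' @param system an [ODESystem-class].
#' @param tMax simulation horizon (s); ignored when `times` is given.
#' @param q0 named initial state; defaults to the network's initial amounts.
#' @param times explicit output times (strictly increasing, starting >= 0).
#' @param rtol,atol solver tolerances.
#' @param keepFluxes record per-reaction fluxes along the trajectory.
#' @return a [Trajectory-class].
#' @aliases simulateODE
#' @export
setMethod("simulateODE", "ODESystem",
function(system, tMax, q0 = NULL, times = NULL,
         rtol = 1e-8, atol = 1e-12, keepFluxes = TRUE) {
  if (is.null(q0)) q0 <- system@q0
  if (any(is.na(q0[system@stateLabels])))
    bgStop("bgParameterError", "initial state contains NA")
  q0 <- q0[system@stateLabels]
  if (is.null(times)) {
    stopifnot(length(tMax) == 1, tMax > 0)
    times <- seq(0, tMax, length.out = 201)
  }
  deriv <- function(t, y, parms) list(unname(system@rate(y)))
  out <- deSolve::ode(y = q0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  diag <- attr(out, "istate")
  if (!is.null(diag) && diag[1] < 0)
    bgStop("bgSolverError", "ODE solver failed (istate = %d)", diag[1])
  states <- unname(out[, -1, drop = FALSE])
  dimnames(states) <- list(NULL, system@stateLabels)
  fluxes <- if (keepFluxes)
    t(apply(states, 1, system@flux))
  else matrix(0, nrow(states), 0)
  if (keepFluxes && ncol(system@stoichiometry) == 1)
    fluxes <- matrix(fluxes, ncol = 1,
                     dimnames = list(NULL, colnames(system@stoichiometry)))
  new("Trajectory", times = out[, 1], states = states, fluxes = fluxes)
})

#' Steady state by long-horizon integration
#'
#' Integrates over doubling time chunks until max |dq/dt| falls below
#' `tol * max(1, max|q|)`. Root finding is avoided deliberately: cascades
#' move on conservation-constrained manifolds where naive Jacobians are
#' singular. Deterministic for fixed inputs.
#'
#' @param system an [ODESystem-class].
#' @param q0 named initial state (defaults to the network's initial amounts).
#' @param tol rate-norm termination tolerance.
#' @param tFirst first integration chunk length (s).
#' @param maxDoublings iteration budget; chunks double each round.
#' @param rtol,atol solver tolerances.
#' @return the named steady state with attributes `time` (total integrated
#'   time) and `rateNorm`.
#' @aliases steadyState
#' @export
setMethod("steadyState", "ODESystem",
function(system, q0 = NULL, tol = 1e-9, tFirst = 10, maxDoublings = 45,
         rtol = 1e-8, atol = 1e-12) {
  if (is.null(q0)) q0 <- system@q0
  state <- q0[system@stateLabels]
  if (any(is.na(state)))
    bgStop("bgParameterError", "initial state contains NA")
  converged <- function(s) {
    rn <- max(abs(system@rate(s)))
    rn < tol * max(1, max(abs(s)))
  }
  if (converged(state)) {
    attr(state, "time") <- 0
    attr(state, "rateNorm") <- max(abs(system@rate(state)))
    return(state)
  }
  deriv <- function(t, y, parms) list(unname(system@rate(y)))
  total <- 0
  chunk <- tFirst
  for (i in seq_len(maxDoublings)) {
    out <- deSolve::ode(y = state, times = c(0, chunk), func = deriv,
                        parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    state <- stats::setNames(as.numeric(out[nrow(out), -1]),
                             system@stateLabels)
    total <- total + chunk
    if (converged(state)) {
      attr(state, "time") <- total
      attr(state, "rateNorm") <- max(abs(system@rate(state)))
      return(state)
    }
    chunk <- chunk * 2
  }
  bgStop("bgConvergenceError",
         "no steady state within budget (final rate norm %.3e after %g s)",
         max(abs(system@rate(state))), total)
})

#' Export a trajectory as CSV
#'
#' Time column plus one column per species (and optionally per-reaction
#' fluxes prefixed "v_").
#'
#' @param trajectory a [Trajectory-class].
#' @param path output file.
#' @param fluxes include flux columns when present.
#' @return `path`, invisibly.
#' @export
writeTrajectoryCSV <- function(trajectory, path, fluxes = FALSE) {
  df <- data.frame(time = trajectory@times, trajectory@states,
                   check.names = FALSE)
  if (fluxes && ncol(trajectory@fluxes)) {
    fx <- trajectory@fluxes
    colnames(fx) <- paste0("v_", colnames(fx))
    df <- cbind(df, fx)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
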