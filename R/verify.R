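#' Normalised root-mean-square error (percent)
#'
#' 100 * sqrt(mean((estimate - reference)^2)) / (max(reference) -
#' min(reference)). The normalising range is taken from the reference
#' series; a constant reference is an error.
#'
#' @param estimate,reference equal-length numeric series (length >= 2).
#' @return NRMSE in percent.
#' @examples
#' nrmse(c(0.5, 1.5, 2.5), c(0, 1, 2))  # 25
#' @export
nrmse <- function(estimate, reference) {
  if (length(estimate) != length(reference) || length(reference) < 2)
    bgStop("bgUsageError", "series must have equal length >= 2")
  rng <- max(reference) - min(reference)
  if (rng == 0)
    bgStop("bgDomainError",
           "reference series is constant; NRMSE undefined (zero range)")
  100 * sqrt(mean((estimate - reference)^2)) / rng
}

#' Clamp an input species and rebuild the ODE system
#'
#' Marks `species` as a chemostat at amount `value`; used by dose-response
#' scans to hold the stimulus fixed.
#'
#' @param network a [BondGraphNetwork-class].
#' @param species species name.
#' @param value clamped amount.
#' @return the modified network.
#' @export
clampSpecies <- function(network, species, value) {
  i <- match(species, speciesNames(network))
  if (is.na(i)) bgStop("bgLookupError", "no species named '%s'", species)
  network@species[[i]]@isChemostat <- TRUE
  network@species[[i]]@q0 <- as.numeric(value)
  network
}

#' Scale a chemostat's amount
#'
#' Clamps an existing chemostat at a fraction of its baseline level (e.g.
#' ATP at 10%); everything else is unchanged. A non-chemostat target is a
#' usage error.
#'
#' @param network a [BondGraphNetwork-class].
#' @param species chemostat name.
#' @param fraction positive multiplier of the baseline amount.
#' @return the modified network.
#' @export
clampChemostat <- function(network, species, fraction) {
  i <- match(species, speciesNames(network))
  if (is.na(i)) bgStop("bgLookupError", "no species named '%s'", species)
  if (!network@species[[i]]@isChemostat)
    bgStop("bgUsageError", "'%s' is not a chemostat", species)
  if (!is.numeric(fraction) || fraction <= 0)
    bgStop("bgUsageError", "fraction must be positive")
  network@species[[i]]@q0 <- network@species[[i]]@q0 * fraction
  network
}

#' Steady-state dose-response scan
#'
#' For each grid value the input species is clamped at that amount, the
#' system is run to steady state, and the observed species are recorded.
#' Curves are additionally normalised to their own maximum. Deterministic.
#'
#' @param network a parameterised [BondGraphNetwork-class].
#' @param inputSpecies name of the stimulus species to clamp.
#' @param grid strictly increasing positive input amounts (use
#'   [logGrid()] for the usual log-spaced scan).
#' @param observed names of species to record.
#' @param ssTol,tFirst,maxDoublings steady-state solver controls, see
#'   [steadyState()].
#' @return a [DoseResponse-class].
#' @export
doseResponse <- function(network, inputSpecies, grid, observed,
                         ssTol = 1e-9, tFirst = 10, maxDoublings = 45) {
  if (!(inputSpecies %in% speciesNames(network)))
    bgStop("bgLookupError", "no species named '%s'", inputSpecies)
  if (any(grid <= 0) || any(diff(grid) <= 0))
    bgStop("bgUsageError", "grid must be positive and strictly increasing")
  missing <- setdiff(observed, speciesNames(network))
  if (length(missing))
    bgStop("bgLookupError", "observed species not in network: %s",
           paste(missing, collapse = ", "))
  out <- matrix(NA_real_, length(grid), length(observed),
                dimnames = list(NULL, observed))
  for (i in seq_along(grid)) {
    net <- clampSpecies(network, inputSpecies, grid[i])
    sys <- assembleODEs(net)
    st <- tryCatch(
      steadyState(sys, tol = ssTol, tFirst = tFirst,
                  maxDoublings = maxDoublings),
      bgnetError = function(e)
        bgStop("bgConvergenceError",
               "steady state failed at grid point %g: %s", grid[i],
               conditionMessage(e)))
    out[i, ] <- st[observed]
  }
  normalised <- apply(out, 2, function(col) {
    m <- max(col)
    if (m > 0) col / m else col
  })
  normalised <- matrix(normalised, nrow = length(grid),
                       dimnames = dimnames(out))
  # clip solver-level noise so normalised values sit in [0, 1]
  normalised[normalised < 0] <- 0
  normalised[normalised > 1] <- 1
  new("DoseResponse", inputs = grid, outputs = out,
      normalised = normalised, inputSpecies = inputSpecies)
}

#' Log-spaced input grid
#'
#' @param from,to positive grid end points.
#' @param points number of points (default 50 across the scan).
#' @return strictly increasing numeric grid.
#' @export
logGrid <- function(from = 1e-8, to = 1, points = 50) {
  if (from <= 0 || to <= from)
    bgStop("bgUsageError", "need 0 < from < to")
  10^seq(log10(from), log10(to), length.out = points)
}

#' Effective concentration at a response fraction
#'
#' Input level at which a normalised dose-response curve crosses `frac`,
#' located by linear interpolation in log-input space (responses kept
#' linear). An exact grid hit returns that grid input.
#'
#' @param dr a [DoseResponse-class].
#' @param species observed species (column of the scan).
#' @param frac target fraction in (0, 1), e.g. 0.1 or 0.9.
#' @return interpolated input level.
#' @export
ecFraction <- function(dr, species, frac) {
  stopifnot(is(dr, "DoseResponse"))
  if (!(species %in% colnames(dr@normalised)))
    bgStop("bgLookupError", "no observed species '%s'", species)
  if (!(frac > 0 && frac < 1))
    bgStop("bgDomainError", "frac must lie strictly between 0 and 1")
  y <- dr@normalised[, species]
  x <- dr@inputs
  hit <- which(y == frac)
  if (length(hit)) return(x[hit[1]])
  cross <- which(y[-length(y)] < frac & y[-1] >= frac)
  if (!length(cross))
    bgStop("bgRangeError",
           "curve for '%s' never reaches fraction %g (max %g)", species,
           frac, max(y))
  i <- cross[1]
  lx <- log(x[i]) + (frac - y[i]) / (y[i + 1] - y[i]) *
    (log(x[i + 1]) - log(x[i]))
  exp(lx)
}

#' Hill coefficient from EC90 and EC10
#'
#' nH = log(81) / log(EC90/EC10); base-invariant (natural log used in both
#' numerator and denominator). An EC90/EC10 ratio of 81 corresponds to a
#' hyperbolic (nH = 1) response; smaller ratios mean ultrasensitivity.
#'
#' @param ec90,ec10 input levels producing 90% and 10% of the maximal
#'   response (ec90 > ec10 > 0).
#' @return the Hill coefficient.
#' @examples
#' hillCoefficient(81, 1)   # 1
#' hillCoefficient(80, 1)   # 1.0028 (printed as 1.002 at EC precision)
#' @export
hillCoefficient <- function(ec90, ec10) {
  if (!(ec10 > 0) || !(ec90 > ec10))
    bgStop("bgDomainError", "need ec90 > ec10 > 0")
  log(81) / log(ec90 / ec10)
}

#' Dose-response summary table
#'
#' EC10, EC90, the input fold-increase EC90/EC10 and the Hill coefficient
#' per observed species, mirroring the usual ultrasensitivity table layout.
#'
#' @param dr a [DoseResponse-class].
#' @return data.frame with one row per observed species.
#' @export
doseResponseSummary <- function(dr) {
  species <- colnames(dr@normalised)
  rows <- lapply(species, function(sp) {
    ec10 <- ecFraction(dr, sp, 0.1)
    ec90 <- ecFraction(dr, sp, 0.9)
    data.frame(species = sp, EC10 = ec10, EC90 = ec90,
               foldIncrease = ec90 / ec10,
               nH = hillCoefficient(ec90, ec10))
  })
  do.call(rbind, rows)
}

#' Export a dose-response scan as CSV
#'
#' @param dr a [DoseResponse-class].
#' @param path output CSV (input column, raw steady states, normalised
#'   columns suffixed ".norm").
#' @return `path`, invisibly.
#' @export
writeDoseResponseCSV <- function(dr, path) {
  norm <- dr@normalised
  colnames(norm) <- paste0(colnames(norm), ".norm")
  df <- data.frame(input = dr@inputs, dr@outputs, norm, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

setMethod("show", "DoseResponse", function(object) {
  cat(sprintf("DoseResponse: %s over [%g, %g] (%d points), observing %s\n",
              object@inputSpecies, min(object@inputs), max(object@inputs),
              length(object@inputs),
              paste(colnames(object@outputs), collapse = ", ")))
})
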