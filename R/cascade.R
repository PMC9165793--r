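#' Default synthetic parameterisation of a MAPK cycle
#'
#' One choice of realistic operating conditions for the cascade, applied
#' identically to every cycle (amounts in uM, time in s). Protein species
#' carry Kq = 100 (activities Kq*q well above unity at uM amounts, as in
#' published thermodynamic parameterisations of kinase cascades, so that a
#' species wired in as an enzyme accelerates its reaction); complexes carry
#' Kq = 1500. With the reaction constants below this yields
#' enzyme-substrate association 1000 uM^-1 s^-1, dissociation 150 s^-1 and
#' kcat = 150 s^-1 against the ATP pool (Kq*q = 1000), hence a Michaelis
#' constant of 0.3 uM. The ATP/ADP/Pi chemostats (activities 1000, 0.1 and
#' 1e-3) supply a hydrolysis drive of RT*ln(1e7), about 41.7 kJ/mol at
#' 310 K, keeping both arms of every cycle far from equilibrium.
#'
#' @return list with `Kq`, `kappa` and chemostat `q0` values keyed by the
#'   cycle template's role names.
#' @export
mapkCycleDefaults <- function() {
  list(
    Kq = c(S = 100, SP = 100, E = 100, F = 100, E_S = 1500, F_SP = 1500,
           ATP = 1, ADP = 1e-2, Pi = 1e-6),
    kappa = c(bind = 0.1, cat = 1e-4, pbind = 0.1, rel = 0.1),
    q0chemostat = c(ATP = 1000, ADP = 10, Pi = 1000))
}

# role -> concrete species names for the five cycles (three layers; layers
# 2 and 3 are dual phosphorylation, hence two cycles each). The linking
# species are the phosphorylated kinases (enzymes of the next layer), the
# shared intermediates of dual phosphorylation, the shared phosphatases and
# the ATP/ADP/Pi pools.
mapkCycleNaming <- function() {
  list(
    cycle1 = c(S = "MKKK", SP = "MKKKP", E = "Ras", F = "MKKKPase",
               E_S = "MKKK_Ras", F_SP = "MKKKP_MKKKPase"),
    cycle2 = c(S = "MKK", SP = "MKKP", E = "MKKKP", F = "MKKPase",
               E_S = "MKK_MKKKP", F_SP = "MKKP_MKKPase"),
    cycle3 = c(S = "MKKP", SP = "MKKPP", E = "MKKKP", F = "MKKPase",
               E_S = "MKKP_MKKKP", F_SP = "MKKPP_MKKPase"),
    cycle4 = c(S = "MK", SP = "MKP", E = "MKKPP", F = "MKPase",
               E_S = "MK_MKKPP", F_SP = "MKP_MKPase"),
    cycle5 = c(S = "MKP", SP = "MKPP", E = "MKKPP", F = "MKPase",
               E_S = "MKP_MKKPP", F_SP = "MKPP_MKPase"))
}

#' Default initial amounts for the cascade (uM)
#'
#' Totals in the classic ultrasensitivity regime: scarce first-layer
#' components (MKKK 3e-3, its phosphatase 3e-4), abundant second/third
#' layer substrates (1.2 each) against Michaelis constants of 0.3, and a
#' small baseline stimulus (Ras 3e-5).
#'
#' @return named numeric vector of initial amounts.
#' @export
mapkCascadeInitial <- function() {
  c(MKKK = 3e-3, MKK = 1.2, MK = 1.2,
    MKKKPase = 3e-4, MKKPase = 3e-4, MKPase = 0.12,
    Ras = 3e-5)
}

#' Build the five annotated cycle modules of the MAPK cascade
#'
#' Instantiates the single cycle template five times with the canonical
#' linking names, parameterised with [mapkCycleDefaults()]. The instances
#' are ready for semantic composition: shared kinases, phosphatases,
#' intermediates and the ATP/ADP/Pi pools carry identical annotation sets
#' across modules.
#'
#' @param initial named initial amounts overriding
#'   [mapkCascadeInitial()] entries.
#' @param defaults cycle parameterisation as from [mapkCycleDefaults()].
#' @return named list of five parameterised [BondGraphNetwork-class]
#'   modules.
#' @export
mapkCascadeModules <- function(initial = NULL, defaults = mapkCycleDefaults()) {
  tpl <- mapkCycleTemplate()
  naming <- mapkCycleNaming()
  q0All <- mapkCascadeInitial()
  if (!is.null(initial)) q0All[names(initial)] <- initial
  modules <- lapply(names(naming), function(cy) {
    nm <- naming[[cy]]
    Kq <- stats::setNames(defaults$Kq, c(nm, ATP = "ATP", ADP = "ADP",
                                         Pi = "Pi")[names(defaults$Kq)])
    q0 <- stats::setNames(rep(0, length(nm)), unname(nm))
    present <- intersect(names(q0All), names(q0))
    q0[present] <- q0All[present]
    q0 <- c(q0, defaults$q0chemostat)
    instantiateTemplate(tpl, names = nm, Kq = Kq, q0 = q0,
                        kappa = defaults$kappa)
  })
  names(modules) <- names(naming)
  modules
}

#' Compose the full MAPK cascade from its five cycle modules
#'
#' Semantic composition of the output of [mapkCascadeModules()]; shared
#' species merge automatically (the phosphorylated kinases linking the
#' layers, the shared phosphatases and the ATP/ADP/Pi trio, which is kept
#' once). Species names in the composed network are module-qualified; use
#' [cascadeSpecies()] to resolve the canonical kinase names.
#'
#' @inheritParams mapkCascadeModules
#' @return list as from [composeNetworks()].
#' @export
mapkCascade <- function(initial = NULL, defaults = mapkCycleDefaults()) {
  mergeNetworks(mapkCascadeModules(initial, defaults))
}

#' Resolve canonical species names in a composed cascade
#'
#' @param network a composed cascade [BondGraphNetwork-class].
#' @param names canonical species names (e.g. "MKPP", "Ras", "ATP").
#' @return the module-qualified names used in the composed network.
#' @export
cascadeSpecies <- function(network, names) {
  full <- speciesNames(network)
  vcapply(names, function(nm) {
    hits <- full[sub("^[^:]+:", "", full) == nm]
    if (length(hits) != 1)
      bgStop("bgLookupError", "species '%s' resolves to %d names", nm,
             length(hits))
    hits
  })
}
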