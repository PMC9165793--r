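---
title: "Energy-based modelling and semantic composition of biochemical networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-based modelling and semantic composition of biochemical networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgnet)
```

## The model

`bgnet` treats a biochemical reaction network as an energy-processing
system. Each species is a nonlinear storage element with constitutive
relation

$$u = RT \ln(K_q\,q),$$

where $u$ (J mol$^{-1}$) is the chemical potential, $q$ the amount, and
$K_q > 0$ a per-species thermodynamic constant that absorbs the standard
free energy of formation. Species held at fixed amount (ATP, ADP, Pi
pools) are chemostats: their potential is constant and they act as energy
sources or sinks. Each reaction is a dissipative element with the
Marcelin–de Donder relation

$$v = \kappa\left(e^{u_r/RT} - e^{u_p/RT}\right),$$

with $u_r$, $u_p$ the total reactant- and product-side potentials
(weighted by stoichiometry). Substituting the storage relation gives the
equivalent mass-action form

$$v = \kappa\left[\prod_i (K_{r_i} q_{r_i})^{\alpha_i} -
                  \prod_j (K_{p_j} q_{p_j})^{\beta_j}\right],$$

which is what the package evaluates (it is well defined at $q = 0$,
unlike the potential). Because every reaction's forward and reverse
coefficients derive from one $\kappa$ and shared species constants, any
parameterisation in this form satisfies detailed balance automatically:
closed loops carry zero flux at equilibrium, and every flux has the sign
of its affinity ($v\,(u_r - u_p) \ge 0$). Both properties are asserted as
tests rather than assumed.

The junction structure is canonical and derived from the reaction list:
one common-potential (`0:u`) junction per species, one `Re` element per
reaction, a common-flow (`1:v`) junction on any reaction side with more
than one participant or a stoichiometry above one, and a transformer
(`TF`) per stoichiometry above one. A network is therefore fully
described by its components plus a symmetric binary *connectivity
matrix* over these elements, which is the package's exchange format for
structural editing and composition (`toConnectivityMatrix()`,
`editMatrix()`, `readConnectivityCSV()`).

## Converting kinetic parameters

Published models usually specify reversible mass action by $k^+$ and
$k^-$. Matching the mass-action bond-graph form requires

$$k^+ = \kappa \prod_i K_{r_i}^{\alpha_i}, \qquad
  k^- = \kappa \prod_j K_{p_j}^{\beta_j},$$

which after taking logarithms is linear in $\ln\kappa$ and $\ln K_q$:
two constraint rows per reaction (`buildLogLinearSystem()`). The system
is solved by least squares in log space (`solveParameters()`); the
squared log-space misfit is the *detailed-balance residual*. It vanishes
exactly when the kinetic scheme satisfies the Wegscheider loop
conditions, and a residual above the consistency threshold
($10^{-12}$ by default, a value chosen as comfortably above
double-precision round-off and far below any genuine inconsistency)
quantifies how thermodynamically inconsistent the source parameters are.

Two numerical choices matter here:

* **Gauge.** The constraints determine the parameters only up to
  rescalings of the $K_q$ that leave every $k^\pm$ unchanged. That
  freedom is the null space of the constraint matrix and follows the
  network's conservation structure — it is *not* simply one degree of
  freedom per connected component. For stoichiometries such as
  $\{A + B \rightleftharpoons C,\; A \rightleftharpoons C\}$ the
  constant of $B$ is fully identified, and pinning it at an arbitrary
  value would corrupt an otherwise exact conversion. The default gauge is
  therefore the deterministic minimum-norm least-squares solution, which
  never perturbs the misfit; callers can instead supply `fixed` constants
  (e.g. chemostat potentials shared with an already-converted module),
  which is the physically meaningful way to pin the gauge.
* **Irreversible reactions.** These are thermodynamically impossible in
  an energy-based model. `approximateIrreversible()` offers the
  small-reverse-constant policy $k^- = \varepsilon k^+$ (default
  $\varepsilon = 10^{-6}$, small enough that the reverse flux is
  negligible at any realistic activity while keeping the model
  reversible) and a trajectory-fit mode that estimates $\kappa$ by
  deterministic bounded scalar minimisation of the squared deviation from
  a supplied reference time course (bracketing on $\log_{10}\kappa$, no
  randomness). For Michaelis–Menten input the forward constant defaults
  to the low-saturation slope $V_{max}/K_m$.

## Automated composition

Modules are composed semantically. Every species carries a set of
annotation identifier strings (property, entity and compartment terms in
the subject–predicate–object style of annotated models); matching is
*exact set equality* — fuzzy matching is out of scope by design, since a
wrong automatic merge is worse than a missed one. The engine
(`mergeNetworks()`, or the individual steps `matchEntities()` →
`checkMergeable()` → `planMerge()` → `resolveConflicts()` →
`composeNetworks()`):

1. extracts annotated entities per module;
2. groups entities with identical annotation sets across modules
   (no matches is a warning, not an error);
3. filters mergeability — species and chemostats merge, scalar context
   parameters such as temperature and whole reactions do not;
4. keeps one representative per group (the entity from the earliest
   module in the caller's argument order — a definite, documented rule),
   deletes the duplicates' rows/columns from the block-diagonal stack of
   per-module connectivity matrices, and inserts a symmetric 1-pair from
   the representative's `0:u` junction to every former bond partner of
   each removed junction;
5. surfaces value conflicts (differing initial amounts or constants
   within a group) and resolves them under an explicit policy
   (`keep-first`, `keep-module`, `override`, or `interactive`; the
   non-interactive policies are the default so that scripted runs never
   hang, and every resolution is logged);
6. emits the composed network and its ODE system.

At a merged junction the flow balance becomes the signed sum of all
adjacent reaction fluxes across modules — composing
$A \rightleftharpoons C$ with $C \rightleftharpoons B$ yields
$\dot q_C = v_1 - v_2$ — and this is verified both symbolically (on the
emitted equation listing) and numerically. Two entities with identical
annotations *inside one* module are an ambiguity error rather than a
guessed tie-break, because no ordering rule could be justified there.
Unit text is carried through but never auto-converted; mismatches are the
user's to resolve.

Templates (`mapkCycleTemplate()`, `egfrTemplate()`, `rasTemplate()`) are
networks with unset parameters plus a signature annotation set;
`selectTemplate()` picks the unique registry template whose signature is
contained in a document's annotations and treats multiple matches as an
error listing the candidates. Parameter values are deliberately not
shipped for the receptor-level templates: they belong to externally
published parameter sets and are read from user-supplied files.

## ODE assembly, simulation and steady states

`assembleODEs()` builds the stoichiometric matrix $S$ and returns
$\dot q = S\,v(q)$ with chemostat rows zeroed; conserved moieties are a
basis of the left null space of $S$ restricted to non-chemostat species
and are monitored as an integration invariant (drift below $10^{-6}$
relative over a trajectory). Integration uses the stiff-capable `lsoda`
solver with defaults `rtol = 1e-8`, `atol = 1e-12` — signalling cascades
mix second-scale binding with hour-scale relaxation, so a stiff solver is
not optional. Steady states are found by integrating over doubling time
chunks until $\max|\dot q| < \mathrm{tol}\cdot\max(1, \max|q|)$
(termination tolerance $10^{-9}$) rather than by root finding: cascade
dynamics live on conservation-constrained manifolds where naive Newton
steps meet singular Jacobians, while relaxation is robust and, for these
gradient-like systems, guaranteed to converge to the equilibrium of the
compatibility class.

## The synthetic cascade and its parameterisation

The cascade builder instantiates one cycle template five times (one
cycle for the first layer, two each for the dual-phosphorylation second
and third layers) and composes them through the shared kinases,
phosphatases and the ATP/ADP/Pi trio, which is kept once. Each cycle
follows the standard bind/catalyse motif — the internal enzyme
intermediates per cycle are not uniquely dictated by the pathway
topology, and one complex per arm (substrate–kinase and
product–phosphatase) is the minimal choice that still sequesters enzyme,
which is what the layered behaviour relies on.

The default parameterisation (amounts in µM, time in s) is chosen once
to sit in the classic ultrasensitivity operating regime of kinase
cascades: association $1000\ \mu M^{-1} s^{-1}$, dissociation
$150\ s^{-1}$, $k_{cat} = 150\ s^{-1}$ (so $K_m = 0.3\ \mu M$), totals
MKKK $3\times10^{-3}$, MKK and MK $1.2$, first/second-layer phosphatases
$3\times10^{-4}$, MK-phosphatase $0.12$, baseline stimulus Ras
$3\times10^{-5}$. The ATP/ADP/Pi chemostat activities ($10^3$, $10^{-1}$,
$10^{-3}$) supply a hydrolysis drive of $RT\ln 10^7 \approx 41.7$ kJ/mol
at 310 K, keeping both arms of every cycle far from equilibrium.

Protein species carry $K_q = 100$ rather than the neutral gauge
$K_q = 1$. The two choices give identical fluxes for any fixed network
(the reaction constants absorb the rescaling exactly), but the scale
matters the moment a species is *wired in* as an enzyme: enzymatic
participation multiplies a flux by the activity $K_q q$, so constants
must place realistic enzyme activities above unity — as published
thermodynamic parameterisations of these cascades do — for catalytic
coupling to accelerate rather than throttle its target. With this
parameterisation the composed cascade reproduces the expected layered
ultrasensitivity (Hill coefficients ordered third > second > first
layer, the first layer hyperbolic), enzymatic negative feedback from the
terminal kinase onto the first layer's dephosphorylation suppresses the
terminal output, and clamping ATP at 10% of baseline lowers every
activated kinase's steady state.

The synthetic-fixture generator (`randomConsistentNetwork()`) draws
$K_q$ and $\kappa$ log-uniformly on $[10^{-2}, 10^2]$, builds random
connected stoichiometries with coefficients in $\{1, 2\}$ (capped at 2
so that hand-checked oracles stay tractable), and *derives* the kinetic
constants from the thermodynamic ones — so its kinetics are
detailed-balance-consistent by construction and form an exact round-trip
oracle for the conversion. What the generator emulates is the
algebraic structure of real kinetic schemes, not their biology: it has
no enzyme saturation hierarchy, no compartments, no units beyond
consistency, and no experimental noise. Passing tests therefore
demonstrate correctness of the machinery (conversion exactness,
conservation, dissipation, composition bookkeeping), not predictive
accuracy for any particular pathway, which always enters through
user-supplied parameter files.

## Verification metrics

* `nrmse()` — root-mean-square error between an estimate and a reference
  series, normalised by the reference's range, in percent; a constant
  reference is rejected rather than silently divided by zero.
* `doseResponse()` — clamp the stimulus species at each point of a
  log-spaced grid (default 50 points across the scan), relax to steady
  state, record the observed species, and normalise each curve to its own
  maximum.
* `ecFraction()` — crossing of a normalised curve with a target
  fraction, interpolated linearly in log-input space (responses kept
  linear); an exact grid hit returns the grid value and a curve whose
  plateau never reaches the fraction is a range error.
* `hillCoefficient()` — $n_H = \log 81 / \log(EC_{90}/EC_{10})$, using
  the natural logarithm in both places (the ratio makes the base
  irrelevant; stating it avoids confusion). A ratio of 81 is exactly
  hyperbolic ($n_H = 1$).

Problem sizes used by the shipped tests and the acceptance script — 50
random fixtures of up to 8 species and 6 reactions, dose-response grids
of 13–33 points over six to eight decades, and the 25-species composed
cascade — were picked as the smallest sizes at which every qualitative
regime (ultrasensitivity ordering, feedback inhibition, energy
limitation) is clearly expressed.

## Known limitations

* Only the biochemical domain is implemented; electrical/mechanical
  bond-graph components are out of scope.
* Annotation matching is exact; harmonising heterogeneous annotation
  vocabularies is upstream work.
* Michaelis–Menten kinetics are approximated by elementary mass action
  (small reverse constant or trajectory fit), not modelled as a dedicated
  reversible Michaelis–Menten element.
* Units are carried as text and checked for nothing; composing modules
  in different unit systems is flagged only through value conflicts.
* Deterministic ODEs only — no stochastic simulation, events or delays.
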