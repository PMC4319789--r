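---
title: "The minimal Cdk network model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The minimal Cdk network model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcncycle)
```

## The model

Fission yeast strains in which a single Cdc13-L-Cdc2 cyclin-Cdk fusion
protein replaces the entire cyclin complement cycle normally, which makes
them the cleanest experimental system for the *quantitative* view of cell
cycle control: one kinase activity (called MPF throughout) triggers DNA
replication when it rises past a low threshold (`theta_s = 0.01`) and
mitosis when it rises past a high one (`theta_m = 0.2`).  `mcncycle`
implements a deterministic and a stochastic version of an ODE model of
this minimal network with nine molecular state variables plus cell mass:

* **MPF / MPF_P** — active and Tyr/Thr-phosphorylated fusion protein.
  The phosphorylated form keeps `alpha = 0.05` of full activity, so the
  effective kinase activity driving every catalytic step is
  `A = MPF + alpha * MPF_P` (divided by `1 + NmPP1` for analog-sensitive
  kinase under inhibitor).
* **Wee1, Cdc25** — the inhibitory kinase (Wee1 and Mik1 are lumped into
  one pool, as their distinction never matters here) and the activating
  phosphatase.  Both are regulated by MPF through zero-order
  ultrasensitive (Goldbeter–Koshland) modules, creating the
  double-negative and positive feedback loops that make G2/M a bistable
  switch.
* **IE, APC:Slp1** — a two-stage ultrasensitive relay from MPF to the
  degradation machinery.  The intermediary enzyme exists to delay the
  negative feedback; without the delay the APC would clamp MPF at an
  intermediate level instead of oscillating.
* **Rum1, Rum1_P, MPF:Rum1** — the stoichiometric inhibitor.  Rum1 binds
  MPF tightly (Michaelis constant `(k_diss + k_irum1)/k_ass` about
  0.02 CU) and is also a distributively two-step-phosphorylated substrate
  of the kinase: slow in-complex mono-phosphorylation (`k_irum1 = 2`/min),
  fast dephosphorylation of the free mono-phosphoform (`k_arum1 = 35`/min),
  and a mass-action second phosphorylation (`k_drum1p = 250` per CU·min)
  that commits Rum1 to immediate degradation.  The doubly phosphorylated
  species is therefore not a state variable.
* **mass** — grows exponentially (`mu = 0.005`/min, so the balanced cycle
  period is `log(2)/mu = 138.6` min) and multiplies the fusion-protein
  synthesis flux `k_smpf * mass`.  This is the only mass-coupled flux:
  growth feeds the cycle solely by raising the effective synthesis rate
  of the kinase.

Two structural choices deserve emphasis because the phenotypes of the
mutant strains hinge on them:

1. **MPF_P is the starter kinase.**  It binds Rum1 only weakly, so it is
   not sequestered, and its mono-phosphorylation of free Rum1 is mass
   action with the dedicated constant `k_i2rum1 = 50` per CU·min acting on
   the `MPF_P * Rum1` product.  The fractional activity `alpha` does not
   multiply this flux: the derivation of the mass-action constant already
   absorbs it (the turnover and Michaelis constant of the weak-binding
   route both scale with `alpha`, which cancels in their ratio).  In the
   wild-type minimal network the fusion protein accumulates mostly as
   MPF_P, which both keeps mitosis off *and* clears Rum1 early - that is
   why G1 is short.  Strains without inhibitory phosphorylation lack the
   starter kinase entirely, their unphosphorylated MPF is trapped by
   Rum1, and G1 lengthens until synthesis titrates the inhibitor away.
2. **CCP is a background activity, not a species.**  The G1/S cyclins
   (Cig1, Cig2, Puc1) enter only as a constant Cdc2 activity `ccp` that
   degrades Rum1 (`k_dx = 1` per CU·min) in all three of its pools - free
   Rum1, Rum1_P, and the MPF:Rum1 complex, the latter releasing active
   MPF.  Degrading the mono-phosphoform as well is our reading of the
   statement that the same terms appear in the free-MPF and Rum1_P
   equations; it makes CCP act uniformly on the inhibitor, which is what
   the lumped "background kinase" idealisation means.  `ccp = 2` encodes
   strains whose CCP complexes additionally escape Wee1 inhibition.

Genotypes are parameter transformations (`apply_genotype()`): loss of
Rum1 zeroes its synthesis; loss of Wee1/Mik1 zeroes the Wee1 total; the
AF (T14A/Y15F) fusion zeroes the inhibitory-phosphorylation flux.  Since
there is no Wee1-independent basal phosphorylation of the fusion protein
in the model, the AF fusion and the Wee1/Mik1 deletion are *identical*
parameterisations at `ccp = 0` - a property the test suite asserts, and
the reason those two rows of the phenotype table coincide.

## Parameter provenance and calibration

Every constant with a stated value is transcribed directly and marked
`transcribed` (or `derived` when forced by a stated relation, as with
`k_ass`, `k_diss` and `mu`) in `inst/extdata/mcn_parameters.yaml`.  The
remaining rates - the four Goldbeter–Koshland module rate pairs, the
degradation constants, the Cdc25/Wee1 catalytic constants and the Rum1
synthesis/turnover rates - are not individually identifiable from the
published material, so they were calibrated *once* (`scripts/calibrate.R`)
against the computed phenotype table: the wild-type minimal-network row
(G1 31.8, S/G2 98.5, M 8.3, re-licensing 27.1 min) anchors the fit, with
the mutant rows, the post-division activity minimum (0.0035) and the
G1-phase total-Rum1 scale (~0.4 CU) constraining the rest.  The result is
frozen in the package defaults and is not revisited; all analyses,
tests and reports run from this one parameter file.

## Events, phases and viability

Division is an event of the model: when the effective activity crosses
`theta_m` downward the cell divides, mass is halved, and every
concentration is left continuous (concentrations are intensive; the
halved cell inherits the mother's composition).  Phase boundaries are
threshold crossings of the same activity: G1 is birth to the upward
`theta_s` crossing, S/G2 runs to the upward `theta_m` crossing, M to the
next division.  The re-licensing time is the total time per cycle with
activity below `theta_s`, because replication origins can only reload
while Cdk activity is essentially absent.  Two rules turn phases into
viability calls (`assess_viability()`):

* no re-licensing window longer than 1 min → death by
  `NO_RELICENSING` (the printed tables report such strains with a
  re-licensing time of exactly 0);
* an S-to-M interval shorter than `t_replication = 20` min (the lower
  edge of the 20–30 min S-phase duration of fission yeast) → mitotic
  catastrophe, `SHORT_S_TO_M`.  The conditional-catastrophe protocol
  (`run_g1_reset()`) produces an S-to-M lag of about 14 min, which is
  exactly why it is lethal under this rule.

Event detection accepts a crossing only if the trajectory stays on the
far side for at least one minute.  This debounce exists for two reasons:
solver ripple near the shallow `theta_s` crossing in the ODE model, and
count shot noise in the stochastic model, where the S threshold
corresponds to only a handful of molecules.

## Numerical choices

The ODE right-hand side exists twice: a readable R implementation
(`cdk_rhs()`), which is the reference, and a C translation used by the
integrators; a test asserts they integrate identically.  Integration
uses `deSolve`'s stiff-capable `lsodar` with relative tolerance 1e-8,
absolute 1e-10, and the division surface located by the solver's own
root finder.  The limit cycle is declared converged when consecutive
division masses agree to 1e-4 (relative); halving either tolerance moves
the reported phase durations by well under 1%, which the suite checks.

Bifurcation analysis freezes mass (the growth equation is removed; all
mass-scaled fluxes keep the frozen value) and uses brute-force
multi-start damped-Newton root finding plus nearest-neighbour grid
continuation rather than pseudo-arclength continuation: the diagram has
at most three coexisting branches, and fold bisection localises
saddle-nodes to 1e-4 in mass, which is far tighter than the 0.005 grid.
Stability comes from central finite-difference Jacobians (relative step
1e-6, validated against a higher-order difference oracle) and their
eigenvalues.  A fold is relabelled SNIC when sustained oscillations start
within 0.01 mass units above it and their period diverges approaching it
(period at fold+0.002 more than twice the period at fold+0.02).
Oscillation detection (amplitude above 1e-3, at least three maxima in the
retained window) rejects solver ripple while keeping the small-amplitude
cycles of the Wee1-less genotype.

## The stochastic version

The Gillespie direct method runs over one reaction per elementary flux
of the deterministic right-hand side - the two term inventories are in
bijection, and the core stochastic test asserts that stoichiometry-
weighted propensities divided by system volume reproduce the ODE
derivatives exactly, for every genotype.  Saturating (Goldbeter–Koshland)
fluxes are single lumped reactions; no elementary-complex expansion is
attempted, so exactness is sacrificed knowingly at that granularity.

The system size `omega = 1000` converts concentrations to molecule
numbers (count = concentration x omega, putting protein counts in the
hundreds), and growth enters the stochastic dynamics exactly as in the
ODE: only through the mass-scaled synthesis flux.  The deterministic
model's concentrations do not dilute with growth, so a volume-scaled
system size would introduce a spurious dilution term; keeping `omega`
fixed avoids that and makes the stoichiometry-weighted propensities
reproduce the ODE drift exactly.  Division is handled on the same
intensive scale: mass is halved and each daughter inherits
binomial(n, 1/2) of the mother's molecules in half the volume, which on
the fixed `omega` scale is the mean-preserving draw `2*binomial(n, 1/2)`
with variance `n` - partition noise without the concentration
discontinuity that raw count-halving would imply (a regression switch
passes counts through unchanged for comparison against the ODE).  The
regulatory-module species (Wee1, Cdc25, IE, APC active fractions, total
concentration 1) receive the same treatment, which preserves the active
fraction in expectation.  Mass grows deterministically between jumps and
propensities are refreshed at every firing, with a 0.5-min cap on silent
advances; at the system sizes used, inter-jump times are orders of
magnitude below `1/mu`, so the jump-adapted approximation is accurate.

Parametric (cell-to-cell) noise multiplies the two synthesis rates by
`1 + sigma * r`, `r` uniform on [-1, 1], redrawn independently at every
birth with `sigma_smpf = 0.1` and `sigma_srum1 = 0.25`.  Populations are
simulated as independent single-daughter lineages, lineage `i` running on
RNG stream `seed + i` so results do not depend on execution order; a
fixed number of early divisions per lineage is discarded as burn-in.

## What the synthetic fixtures do and do not emulate

The toy trajectories (`make_toy_trajectory()`) are closed-form activity
traces - ramp, raised sinusoid, pulse train - whose threshold crossings
are known analytically; they exercise event detection and phase
classification against exact ground truth, not the biology.  The
reference populations (`make_reference_population()`) are normal draws
with the qualitative property that the strain without inhibitory
phosphorylation has the broader size distribution; they stand in for
measured histograms in format-level tests.  Passing tests on these
fixtures validates the machinery; statements about real cells rest on
the model simulations, which in turn inherit all the idealisations
listed above (lumped Wee1/Mik1, constant phosphatases, threshold-based
licensing with no explicit Cdc18/Cdt1 biochemistry, no S-phase
checkpoint, symmetric division, CCP as a constant background).

## Problem sizes used by the shipped analyses

The acceptance script and the test suite run the full deterministic
analysis set (phenotype table over nine genotypes, G1-reset protocol,
bifurcation diagrams at mass step 0.005, Wee1 titration at 5% steps).
The stochastic populations use 100 lineages of 10 retained divisions
each per genotype in the acceptance script (40 lineages of 8 divisions
in the test suite), with the first three divisions of every lineage
discarded as burn-in; these samples comfortably resolve the contrasts
of interest (broader AF size distribution at similar mean; the failure
census of the CCP = 2 AF strain), and larger populations sharpen the
histograms without changing any reported conclusion.

## Known limitations

* The unprinted constants are a calibrated set: they reproduce the
  phenotype table and the bifurcation structure, but individual values
  are not measurements and should not be interpreted as such.
* The stochastic model treats the Goldbeter–Koshland modules as lumped
  reactions, underestimating their intrinsic noise relative to an
  elementary-step expansion.
* Phase durations in the stochastic model use debounced threshold
  crossings; at very small system sizes (`omega` below ~200) the S
  threshold corresponds to so few molecules that the G1/S boundary
  becomes ill-defined.
* The model has no S-phase checkpoint by construction, so it cannot be
  used to study replication-stress responses; the catastrophe calls are
  purely threshold-timing based.
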