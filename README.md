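# mcncycle

Deterministic and stochastic simulation of the **minimal Cdk network**:
the fission yeast cell-cycle control system reduced to a single
cyclin-Cdk fusion protein.  In strains where Cdc13-L-Cdc2 replaces the
entire cyclin complement, one kinase activity (MPF) drives the whole
cycle *quantitatively*: DNA replication starts when activity exceeds a
low threshold (θ_S = 0.01), mitosis when it exceeds a high one
(θ_M = 0.2), and division follows when activity falls back through θ_M.
The package is for systems biologists who want to reproduce, probe or
extend the dynamics of this network - its mutant phenotypes, its
bifurcation structure, and its sensitivity to molecular noise.

## The model

Nine molecular variables plus cell mass `m`:

* active and Tyr-phosphorylated fusion protein (MPF, MPF_P; the
  phosphoform keeps α = 0.05 of full activity, so the effective kinase
  activity is `A = MPF + α·MPF_P`),
* Goldbeter–Koshland ultrasensitive modules for Wee1 (inhibitory kinase,
  Mik1 lumped in), Cdc25 (activating phosphatase), and a delayed
  negative-feedback relay IE → APC:Slp1 that degrades the fusion
  protein at mitotic exit,
* the stoichiometric inhibitor Rum1 with tight MPF binding
  (K_m ≈ 0.02 CU) and distributive two-step phosphorylation
  (k_irum1 = 2 min⁻¹ in complex, k_arum1 = 35 min⁻¹ dephosphorylation,
  k_drum1p = 250 CU⁻¹min⁻¹ second site, then immediate degradation);
  MPF_P is the "starter kinase" that phosphorylates Rum1 without being
  sequestered (k_i2rum1 = 50 CU⁻¹min⁻¹),
* exponential growth `dm/dt = µm` (µ = 0.005 min⁻¹) coupled to the
  network only through the synthesis flux `k_smpf·m`; at division `m`
  is halved and concentrations are continuous.

Mutant strains are parameter switches (`genotype_preset()`): Rum1
deletion, Wee1/Mik1 deletion, the non-phosphorylatable AF fusion, a
background G1/S-cyclin (CCP) activity that degrades Rum1, and the
analog-sensitive kinase whose activity is divided by `1 + [NmPP1]`.
The stochastic version runs Gillespie's direct method over one reaction
per elementary flux at system size Ω = 1000 molecules per concentration
unit, with mean-preserving binomial partition noise at division and
per-birth uniform noise on the two synthesis rates (σ_SMPF = 0.1,
σ_SRUM1 = 0.25).

See `vignettes/minimal-cdk-network.Rmd` for the full account of the
model, the calibration of the unprinted rate constants, and the
numerical choices.

## Worked example

```r
library(mcncycle)

p <- mcn_parameters()

# wild-type minimal network: converge to the limit cycle and classify
cyc <- integrate_to_limit_cycle(p, genotype())
classify_phases(cyc)
#> G1 28.9 | S/G2 101.9 | M 7.9 min; re-licensing 23.5 min
#> mass at division 0.9683; viable

# the same network without Wee1/Mik1: long G1, similar size at division
classify_phases(integrate_to_limit_cycle(p, "mcn-dwee1dmik1"))
#> G1 79.4 | S/G2 51.2 | M 8.0 min; re-licensing 70.0 min
#> mass at division 1.0344; viable

# conditional mitotic catastrophe by inhibitor reset: block in G2,
# reset to G1 with a high dose, release
run_g1_reset(p, genotype(cdc2as = TRUE),
             schedule = list(c(1, 100), c(20, 70)))
#> G1-reset protocol: release at t = 198.8 min, post-release S-to-M lag 13.9 min
```

The phase durations are read off the effective-activity thresholds; the
re-licensing time is the window with activity below θ_S, which the
daughter needs to reload its replication origins.  The post-release lag
of ~14 min is shorter than the ~20 min needed to replicate the genome:
the release drives the cell into mitosis with unreplicated DNA - a
mitotic catastrophe - although the same network cycles indefinitely
when left alone.

Other entry points: `build_phenotype_table()` (phase durations,
re-licensing and relative division size for all genotype presets),
`trace_branches()` / `limit_cycle_envelope()` / `classify_snic()`
(one-parameter bifurcation diagrams over cell mass),
`wee1_titration()` (size at division vs Wee1 activity),
`ssa_lineage()` / `run_population()` / `catastrophe_census()`
(stochastic lineages and population statistics), and a small command
line front end (`inst/scripts/mcncycle`, see `?cli_dispatch`).

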