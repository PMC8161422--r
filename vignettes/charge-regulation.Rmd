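---
title: "Charge regulation and apparent pKa shifts during amyloid fibril formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge regulation and apparent pKa shifts during amyloid fibril formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkashift)
```

## The problem

alpha-Synuclein is a 140-residue intrinsically disordered protein whose
amyloid fibrils are the hallmark of Parkinson's disease. Its last 40
residues — the C-terminal tail — carry 15 acidic groups (14 Asp/Glu
carboxyls plus the C-terminal carboxyl) and stay disordered in the
fibril, protruding from the rigid core (residues 29–100) like a
polyelectrolyte brush. When monomers stack into a fibril, those acidic
tails are forced close together. The electrostatic penalty of crowding
many carboxylates is relieved by *charge regulation*: the sites take up
protons, their apparent pKa values shift up, and — in unbuffered water,
where the protein is the only buffer — the sample pH visibly rises.

`pkashift` quantifies this effect along two independent routes:

1. a **closed-system proton balance** that converts a measured
   monomer-to-fibril pH pair into an apparent average pKa of the
   fibrillar acidic groups, and
2. a **constant-pH coarse-grained Metropolis Monte Carlo** model that
   predicts per-residue protonation changes between the monomeric and
   fibrillar states from electrostatics alone.

A synthetic-data layer generates noisy electrode experiments from the
forward balance model and fibril-like bead geometries, so the whole
pipeline is testable without any external downloads.

## The closed-system proton balance

In water with no buffer, the total proton content of a sealed sample is
fixed. Before fibrillation, it is distributed between protons bound to
the acidic groups and protons free in solution:

$$\mathrm{bound[H^+]_{mono}} = n \, \bar Q(\mathrm{pH_{mono}}) \, C,
  \qquad \mathrm{free[H^+]_{mono}} = 10^{-\mathrm{pH_{mono}}},$$

where $n$ is the number of acidic sites per chain, $C$ the protein
concentration, and $\bar Q$ the mean Henderson–Hasselbalch protonation
degree, $Q = 1/(1 + 10^{\mathrm{pH} - \mathrm{p}K_a})$, over the monomer
pKa assignments. After fibrillation the same total is re-partitioned
between the free pool at the new pH, the residual free monomers, and the
fibrillar acidic groups; mass action on the latter yields a single
apparent dissociation constant:

$$K_a = \frac{\mathrm{free[H^+]_{fib}} \cdot \mathrm{free[P]}}
             {\mathrm{bound[H^+]_{fib}^{fib}}},
  \qquad \mathrm{p}K_a^{\mathrm{ave}} = -\log_{10} K_a .$$

`infer_fibril_pka()` implements this bookkeeping step by step and
reports every intermediate concentration; `forward_ph()` is its exact
inverse (a bracketed root search in pH on (1, 13), tolerance 1e-10) and
drives the synthetic-data generator.

```{r}
wt <- protein_spec("wt")
infer_fibril_pka(ph_experiment(5.6, 6.5, 20e-6), wt)
```

### Parameters that matter

* **Monomer pKa scheme** (`assign_pkas()`): the default
  `croke_regional` scheme uses the NMR-derived monomer values, which are
  regional — tail Asp 4.2 / Glu 4.6, N-terminal/NAC Asp 3.6 / Glu 4.2.
  The C-terminal carboxyl is not listed in that table; it defaults to
  3.6, the terminal α-COOH model-compound value (override via
  `cterm_pka`). The reported averages are insensitive to this choice.
* **Site set** (`site_set`): the bookkeeping can run over the 15
  tail acids (default) or all 25 acidic groups. The tail set embodies
  the structural picture that only the brush-like tails regulate; the
  full set treats the whole chain. Both are computed by
  `analysis/02_proton_balance.R`; they differ by ≲0.15 in the wild-type
  fibril pKa and the difference is reported, not hidden.
* **Residual monomer** (`C_residual_mono`): fibrillation does not
  consume all monomer. The default is 20% of the total, the middle of
  the plausible 10–30% band; stage 2 shows the inferred pKa moves by
  only a few hundredths across that band (and by < 0.03 under the
  frozen-Q convention below).
* **Q-evaluation convention** (`qave_convention`): the residual
  monomers in the fibrillar sample must be assigned a protonation
  degree. The default, `"at_pH_fib"`, evaluates their (unchanged) pKa
  set at the pH the sample actually has — chemical equilibrium demands
  that sites titrate at the prevailing pH. The alternative
  `"at_pH_mono"` freezes the monomeric protonation at its
  pre-fibrillation value; it makes the inference almost perfectly
  insensitive to the residual assumption but caps the inferable proton
  uptake at the free-proton pool (~0.14 protons/monomer at these
  concentrations, an order of magnitude below the uptake both the
  experiment and the simulations indicate). Both conventions are first
  class; stage 2 tabulates both.
* **ΔpKa reference**: the shift is reported against the monomer
  average pKa over *all* acidic groups (4.3 for the wild type, 4.2 for
  5Q under the regional scheme) — the monomer-side average the
  experiment quotes — regardless of the bookkeeping site set
  (`monomer_pka_mean` overrides).
* **Water autoionization** (`autoionization`, `Kw`): including the
  hydroxide term in the conserved proton pool changes the wild-type
  shift by about +0.0006 at Kw = 1e-14 — far below electrode
  reproducibility, which is why the plain bookkeeping is the default.

### Protons per monomer

`protons_per_monomer()` reports the protons a fibril-incorporated
monomer holds in excess of a free monomer, with the free-monomer
reference evaluated per the convention above. Under the default
convention this is the uptake relative to a monomer at the final pH —
the same comparison the constant-pH simulations make — and comes out
near 1.3 for the wild-type configuration (per fibril-incorporated
monomer; `ppm_normalization = "per_total_monomer"` rescales).

## The constant-pH Monte Carlo model

Each residue is one bead. Flexible segments (the whole monomer chain;
residues 1–28 and 101–140 of each fibril chain) are connected by
harmonic bonds; fibril core beads (29–100) are fixed at per-residue mass
centers, either read from a PDB structure (`read_pdb_mass_centers()`,
default range 29–100, mass-weighted over all atoms) or generated as a
synthetic stacked-plane geometry (`synthetic_fibril()`: planar
serpentines at ~3.8 Å bead spacing stacked at the 4.8 Å cross-β
distance). Beads interact through

$$u(r) = 4\varepsilon\left[\left(\tfrac{\sigma}{r}\right)^{12} -
  \left(\tfrac{\sigma}{r}\right)^{6}\right] +
  \lambda_B \, q_i q_j \, \frac{e^{-r/\kappa^{-1}}}{r}$$

in kT units, with Bjerrum length λ_B = 7 Å (water, 300 K) and Debye
length κ⁻¹ = (8π λ_B N_A I)^(−1/2) — about 137 Å at the 0.5 mM fibril
conditions and 25 Å at the 15 mM monomer-validation conditions. Every
titratable group (Asp, Glu, His, Tyr, Lys and both termini, intrinsic
pKa values 4.0/4.4/6.3/10.1/10.4/8.0/3.6) is subject to charge-swap
moves with trial energy

$$\Delta u = \ln 10\,(\mathrm{pH} - \mathrm{p}K_a^0) + \Delta u_{\mathrm{elec}},$$

for protonation (negated chemical term for deprotonation), alongside
single-bead translations, chain pivots and crankshaft rotations at
fixed pH — so any coupling between titrating groups is captured
explicitly. The ln 10 factor is required for the stationary distribution
of an ideal site to be exactly Henderson–Hasselbalch, which the test
suite verifies against exact 2^n-state partition sums and the λ_B = 0
limit.

### Numerical choices

* LJ and bond parameters are not dictated by the physics above; the
  package fixes σ = 7 Å (uniform), ε = 0.05 kT, bond length 4.9 Å and
  spring constant 0.76 kT/Å² (energy k/2 (r−r₀)²) in one
  `energy_params()` block, echoed into every manifest. The asserted
  results are limits, oracles and sign/ordering properties robust to
  these choices.
* Bonded neighbours are excluded from non-bonded interactions;
  electrostatics are truncated at 4 Debye lengths (no truncation when
  unscreened); the screened Coulomb factor is tabulated at 0.05 Å
  resolution, identically for incremental updates and full
  recomputation, so the energy bookkeeping check closes to < 1e-8 kT.
* A spherical hard container (radius 250 Å) confines flexible beads; it
  is far larger than any sampled conformation at these system sizes.
* Initial conformations are clash-free by construction: a serpentine
  for the monomer, self-avoiding walks grafted to the core anchors for
  fibril tails (minimum distance 3.0 Å, with backtracking).
* All randomness flows through R's RNG; a run is bit-reproducible from
  its seed. Per-site standard errors come from 20-block averaging;
  block SEs understate the uncertainty of sites that rarely flip, so
  ideal-limit comparisons floor the tolerance at 0.005.
* Fibril statistics use interior chains only (the two end planes are
  excluded) to avoid edge effects.

### Desk-scale versus production scale

The documented study conditions for tests and the bundled analysis
scripts are 3 planes and 2×10⁴ sweeps (a few minutes on one CPU); the
production-scale setting for the published comparison is 10 planes of
the experimental 2N0A geometry and 10⁶ sweeps. At desk scale the
simulations establish the *mechanistic* claims — every wild-type tail
carboxyl is less negative in the fibril than in the monomer at pH 6.5,
the 5Q tail shifts are several-fold smaller, the fibril is cationic at
pH 4 — while quantitative figures such as the simulated ~2
protons/monomer uptake require the production geometry and run length.

## What the synthetic data do and do not show

The experiment generator perturbs both pH readings with additive
Gaussian noise (default SD 0.05, typical glass-electrode repeatability)
and draws the residual monomer fraction uniformly from 10–30% per
replicate. It emulates electrode noise and residual-monomer uncertainty
— the dominant uncertainties of the real measurement — but not
electrode drift, CO₂ uptake, buffer impurities or kinetic effects
during the slow fibrillation, so passing recovery tests demonstrate the
*inference* is sound, not that real measurements are this well behaved.
The synthetic fibril likewise reproduces bead density and connectivity,
not the true serpentine fold of the deposited structure: per-residue
details of core sites (His50 in particular) should not be over-read at
desk scale.

## Known limitations

* The balance treats activities as concentrations and water as the only
  non-protein proton reservoir (no CO₂/carbonate, no co-solutes).
* A single apparent pKa is assigned to the whole fibrillar acidic set;
  the simulations show the underlying titration curves are stretched,
  so this number is an effective, pH-window-dependent summary.
* The tail net-charge folklore value (−12 at physiological pH) is not
  reproduced by naive summation over residues 101–140 (≈ −14); region
  boundary conventions differ across the literature, and the package
  does not assert it.
* The coarse-grained model has no explicit ions, no desolvation and no
  conformation-dependent dielectric; it isolates the screened-Coulomb
  mechanism of charge regulation.

## Reproducing the analyses

The numbered scripts under `analysis/` run the pipeline end to end
(sites → balance → sensitivity → recovery → monomer MC → fibril MC) and
write their tables under `results/`. `scripts/acceptance.R` recomputes
the headline quantities — the wild-type fibril pKa, the 5Q shift, the
protons per monomer and the autoionization correction — from scratch:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
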