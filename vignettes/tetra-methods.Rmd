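---
title: "Methods: restraints, envelope docking, and stepwise ITC in tetra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: restraints, envelope docking, and stepwise ITC in tetra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetra)
```

`tetra` implements three analysis stages used to characterize the factor
XIII A₂B₂ heterotetramer — cross-link restraint analysis, AFM envelope
docking, and stepwise ITC — together with the synthetic-data generators
that make each stage testable end to end. This vignette documents the
models, their assumptions, the tunable parameters, and the numerical and
design choices, in the package's own terms.

## Cross-link distance restraints

A lysine-reactive cross-linker of known span converts a covalent link
between residues *i* and *j* into a geometric statement about any correct
model: the anchor atoms of those residues must lie within the linker's
reach. For DSS the package uses the conventional residue-level window of
**3 to 24 Å** between **Cβ atoms** (Cα for glycine, which has no Cβ).

* *Anchor rule.* The linker bridges side chains, so Cβ–Cβ is the natural
  residue-level proxy; 24 Å is the standard Cβ cap for DSS. The rule is
  configurable to Cα–Cα (`anchor = "ca"`), which shifts distances by at
  most one bond length and suits backbone-only models.
* *Ambiguity.* In a homodimer, a cross-link to protein P cannot say which
  copy of P it touched. `build_restraints()` therefore expands each link
  over the chain assignment's cross product and groups the expansions
  under one parent; `evaluate_restraints()` scores the group satisfied if
  **any** member is. This mirrors the ambiguous-interaction-restraint
  convention of docking engines, and the exporter renders such groups as
  `or`-joined `assign` statements.
* *Unmappable restraints* (residues absent from the model) are counted
  separately and excluded from the satisfaction fraction rather than
  silently counted as violations; a truncated construct should not be
  penalized for residues it does not contain.

Domain-pair contact matrices use the crystallographic FXIII-A domain
ranges (activation peptide 1–37, β-sandwich 38–183, catalytic core
184–515, β-barrel-1 516–627, β-barrel-2 628–731). FXIII-B sushi-domain
boundaries are *not* hard-coded: the literature gives only approximate
~60-residue modules, so boundaries are user-supplied as a `domain_map`
(the tests use an even 60-residue tiling as a stand-in).

For presenting a homodimer to a bi-molecular docking engine,
`renumber_continuum()` concatenates chains into a single chain with
residue numbers offset by the cumulative maximum of the preceding chains,
and returns the bijective index map needed to translate results back.

## AFM topograph simulation and envelope docking

An AFM topograph is a height field h(x, y) above the substrate plane
z = 0, in nm. The simulator uses hard-sphere tip dilation: after
grounding the model (lowest atom sphere touching the substrate), each
pixel records the lowest point the tip apex can reach above it,

h(x, y) = maxₐ [ zₐ + √((r_atom + r_tip)² − d²) − r_tip ],

with d the lateral pixel–atom distance and imaginary roots contributing
nothing. This captures the dominant artifact of AFM on molecular-scale
objects — lateral broadening by the tip — while ignoring elastic
deformation and adsorption flattening, which is why simulated heights
should not be compared to published instrument heights for the real
complex.

Docking is an exhaustive rigid search: in-plane rotations on a fixed grid
(default step 30°; the adsorbate is assumed flat on the substrate, so
out-of-plane tilt is not searched) crossed with every whole-pixel lateral
translation. Each placement is grounded and scored by the
**favorable-layer count**: atoms within `layer_thickness` below the local
envelope height score, and the pseudo-energy is E = −N_favorable — the
simplest monotone mapping under which the best score is the lowest
energy. Parameters:

* `layer_thickness` (nm, default 1.0). The favorable-layer thickness is
  not standardized; 1.0 nm spans roughly two atomic shells under the
  envelope and is reported with every result. It is a resolution
  parameter: thicker layers are more permissive and less discriminating.
* `clash_tolerance` (nm, default 0.3). The envelope is a physical upper
  bound on matter, so any atom more than this far above it invalidates
  the pose. A soft mode (`soft_penalty = TRUE`) instead subtracts
  protruding atoms from the score, useful when comparing models that
  cannot all fit under a given envelope.
* Ranking is deterministic: energy, then smallest lateral offset (ties
  between equal-energy placements go to the most centered), then
  rotation. No randomness is used anywhere in the search.

Reported statistics follow the envelope-docking convention: minimum
energy, mean energy of the top 10, mean pairwise Cα RMSD of the top 3
placements *without* superposition (superposing would erase exactly the
placement differences the statistic is meant to expose), and the lateral
offset of the best pose's centroid from the grid center.

## Stepwise binding equilibria and ITC

The sequential scheme M + A ⇌ MA ⇌ MA₂ (⇌ MA₃) is parameterized by
stepwise dissociation constants Kd_i and step enthalpies ΔH_i. With
overall association constants βⱼ = Πᵢ≤ⱼ 1/Kd_i, the binding polynomial
Φ(a) = 1 + Σⱼ βⱼ aʲ is the partition function over ligation states, and
the free-ligand mass balance

A_tot = a + M_tot · (Σⱼ j βⱼ aʲ) / Φ(a)

has a unique root because the left side is strictly increasing in a. The
solver brackets on [0, A_tot] by bisection and polishes with Newton steps
(the derivative is ≥ 1, so the iteration cannot overshoot the bracket
badly); convergence is to 1e-12 relative tolerance, far below any
titration-relevant scale. Species follow [MAⱼ] = [M] βⱼ aʲ with [M] fixed
by conservation. The classic one-set-of-sites model is available as a
separate `kind`; a one-step sequential model and one-set with n = 1 are
algebraically identical, and the package's tests hold them to 1e-12.

The injection model is displacement (perfusion) dilution: an injection of
volume v into a cell of working volume V₀ scales prior contents by
(1 − v/V₀) while the injectant accumulates. The differential heat is
qᵢ = Hᵢ − Hᵢ₋₁(1 − vᵢ/V₀), with H the cell's enthalpy content
V₀ Σⱼ (Σᵢ≤ⱼ ΔHᵢ)[MAⱼ], normalized per mole of injected ligand. A
no-displacement mode exists for closed-form cross-checks (the
tight-binding limit Σq = V₀M₀ΣΔH is exact there). Defaults emulate a
MicroCal-class instrument — 200 µL cell, one 0.4 µL priming injection
followed by 19 × 2 µL — because the experiments the package models were
run on such an instrument and no schedule is otherwise published; both
are configurable, and the acceptance analysis uses exactly these
defaults. The first injection is excluded from fitting by default
(standard practice: the priming injection's heat is corrupted by
diffusion across the syringe tip). The heat of dilution enters as a
constant per-injection offset, default 0 for synthetic data. Standard
state is 1 M; ΔG = RT ln(Kd/1 M) with R = 8.314 J/(mol·K), and
−TΔS = ΔG − ΔH, so the decomposition identity holds to machine
precision. Association simulations default to 298.15 K; the calcium
disassembly analysis uses 303.15 K as published.

## Fitting

`fit_isotherm()` minimizes Σ wᵢ (q_obs,i − q_model,i)² by
Levenberg–Marquardt. Choices that matter:

* **log-Kd parameterization.** Kds span nM to mM; optimizing log Kd keeps
  them positive without constrained solvers and makes multiplicative
  perturbations natural. Enthalpies stay linear. Site counts, when free,
  are also log-parameterized.
* **Deterministic multistart** (default 8 starts: the supplied initial
  point plus 7 seeded perturbations, log-normal on Kd, ±30% on ΔH). This
  replaces the iterate-until-stable loop of interactive fitting software
  with a reproducible procedure; the best-RSS start wins.
* **Weights.** Unit by default — the data carry no error model. When an
  isotherm carries noise metadata, 1/σ² weighting is available; with a
  single global σ the two are equivalent up to scale.
* **Fixed parameters** are held exactly (they never enter the optimizer),
  supporting the published protocol of fixing the first calcium-binding
  Kd at 100 µM, a value too weak to be resolved against the two
  neighboring events from one isotherm.
* **Identifiability flags.** The steepness parameter c = [M]₀/Kd governs
  what an isotherm can say about a step: for c > 1000 the transition is a
  near-vertical step whose position fixes stoichiometry but whose slope —
  the only carrier of Kd information — is below noise. Such steps are
  flagged `kd_bounded_flags`; their Kd should be read as an upper bound.
  In noisy recovery tests the package holds Kd medians to a factor of 2
  only for steps with c in [1, 1000], by design.

Uncertainty comes from a residual-resampling bootstrap (percentile
2.5/97.5 intervals, seeded); model choice from small-sample AIC,
AICc = n ln(RSS/n) + 2k + 2k(k+1)/(n−k−1), with k counting free
parameters plus the noise variance.

## Synthetic data: what it emulates, and what it does not

The generators produce data with the *statistical structure* each stage
assumes, not facsimiles of the real system:

* `toy_model()` builds self-avoiding (≥ 2 Å) poly-alanine chains with
  planted glycines (no Cβ) so the anchor fallback is exercised;
* `bipartite_model()` reproduces the qualitative AFM signature of the
  complex — a compact tall core with a thin low-lying filamentous arm —
  as a geometric stand-in, with two height regimes by construction;
* `sample_crosslinks()` plants residue pairs with an exact in-band
  fraction, giving restraint evaluation a known ground truth;
* `noisy_isotherm()` / `noisy_topograph()` add iid zero-mean Gaussian
  noise (heights clipped at the substrate), the simplest model consistent
  with integrated-heat and height-map errors; no error model is published
  for either modality.

Passing tests on these fixtures shows the algorithms are correct under
their stated assumptions. It does not show that real AFM heights (which
include adsorption flattening and scanner drift), real cross-link sets
(which carry identification errors upstream of this package), or real
isotherms (whose noise is correlated across injections) will behave as
well; those effects are explicitly out of scope.

## Problem sizes and numerical conventions

The test and acceptance workloads are sized for a single CPU: titrations
of 20 injections (19 used), sequential models of up to 3 steps, toy
structures of tens of residues, docking grids of order 30 × 30 pixels
with 4–12 rotations, and 20-seed noisy-recovery ensembles. Round-trip
parameter recovery on noise-free data is held to 1% relative; noisy
recovery to 5% on median ΔH and a factor of 2 on median Kd within the
identifiable c-window. Degenerate inputs are handled explicitly: empty
restraint sets evaluate to an undefined (absent) fraction rather than
0/0; a docking search with no clash-free placement returns an empty
result with a diagnostic rather than an arbitrary pose; zero-volume or
non-positive concentrations are rejected at construction.

## Known limitations

* Coordinates are read from fixed-width PDB only; insertion codes are
  rejected rather than renumbered, and mmCIF is not supported.
* The docking search is in-plane (z-axis rotations); molecules adsorbed
  on an edge would need the full rotation grid, at corresponding cost.
* The ITC forward model treats the cell as well-mixed at each injection
  and ignores kinetics; time-resolved effects cannot be represented.
* Thermodynamic values are reported in kJ/mol throughout; conversion to
  kcal/mol is left to the caller.
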