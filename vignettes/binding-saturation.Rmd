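---
title: "Measuring relative lipid-site affinities from equilibrium CG simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring relative lipid-site affinities from equilibrium CG simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satbind)
```

## The model

`satbind` treats lipid binding to a protein site as a reversible
two-state equilibrium observed through trajectory frames.  Its central
quantity is the **site occupancy**: the percentage of frames in which any
bead of the tracked lipid species touches a site residue, averaged over
the site's residues.  Plotted against the **free-ligand concentration**
(unbound cholesterol as a percent of all unbound lipids), occupancy
follows the one-site specific-binding isotherm

$$y = \frac{B_\mathrm{max}\, x}{K_d + x},$$

whose unconstrained nonlinear least-squares fit yields the apparent
dissociation constant $K_d^\mathrm{app}$ (free-cholesterol percent at
half-maximal occupancy) and the plateau $B_\mathrm{max}^\mathrm{app}$.
Sites are then ranked through
$\Delta\Delta G^\mathrm{app} = RT\,\ln(K_{d,A}/K_{d,B})$, in which the
units of $K_d$ cancel.

Assumptions worth keeping in mind:

* **One site, no cooperativity.**  Occupancy of a site is attributed to
  specific binding at that site alone; no Hill coefficient, no
  competitive multi-site model.  Nonspecific background is assessed
  separately (below), not subtracted inside the fit.
* **Equilibrium sampling.**  Occupancies are time averages; they estimate
  equilibrium probabilities only if binding and unbinding occur many
  times per trajectory.  Cholesterol, with its fast exchange kinetics, is
  the intended regime; slow lipids (e.g. cardiolipin) would need far
  longer sampling.
* **Bead-level contacts.**  All distances are minimum-image distances
  between coarse-grained beads; "any bead of the lipid to any bead of the
  residue", never a centre-of-mass shortcut.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| contact lower cutoff | 0.55 | nm | distance below which a contact initiates |
| contact upper cutoff | 1.0 | nm | distance above which a contact ends |
| free-ligand exclusion | 0.8 | nm | lipid farther than this from every protein bead is unbound |
| exposure cutoff | 0.6 | nm | neighbourhood radius for the burial fraction |
| density bin size | 0.1 | nm | voxel edge of the 3D density grid |
| temperature | 310 | K | enters every $RT$; physiological bilayer temperature |
| nonspecific band | [30, 50] | % | occupancy band (at the reference composition) defining baseline residues |
| gas constant | 8.314e-3 | kJ/mol/K | `GAS_CONSTANT_KJ` |

The dual cutoff is a hysteresis filter: brief excursions of a bound lipid
between 0.55 and 1.0 nm do not end the contact, suppressing flicker that
would otherwise fragment residence and bias occupancies downward.  At
frame 1 there is no history, so the state is "in contact" only below the
*lower* cutoff.  This initial-state rule is a package decision (the band
is ambiguous without history); it is conservative — a contact is never
credited before it demonstrably initiated — and collapses to plain
thresholding when the cutoffs coincide.

The **nonspecific band** is treated as a closed interval, and the 0.8 nm
unbound criterion is applied identically to cholesterol and to the
competing phospholipid when forming the free-ligand denominator.  The
free-ligand criterion uses the minimum over *all* lipid beads (not the
molecule centre); with multi-bead lipids this is the stricter reading of
"distance from the protein surface".

## Fitting protocol

Points are paired per replicate — each replicate contributes its own
(free-cholesterol, occupancy) point per composition — so replicate
scatter survives into the analysis.  `fit_saturation()` reports two
errors on $K_d^\mathrm{app}$:

* the **SEM over per-replicate fits** (headline, matching the protocol of
  averaging independent repeats), and
* the **asymptotic standard error of the pooled fit** (a stricter
  diagnostic, usually smaller).

Numerical choices: Gauss–Newton (`stats::nls`) with starting values
$B_{\max,0} = \max y$, $K_{d,0} = \mathrm{median}\,x$, tolerance
$10^{-8}$, up to 1024 iterations (`nls`'s hard cap; the originally
intended $10^4$ is unreachable there).  When Gauss–Newton fails — the
oscillating-step case on noisy two-replicate subsets, or degenerate
all-zero occupancies — a Nelder–Mead minimisation of the residual sum of
squares (with $K_d$ log-parameterised to keep it positive) takes over and
its own convergence status is reported.  A fit with non-positive or
non-finite $K_d$ or $B_\mathrm{max}$ is always flagged unconverged.
Fitting is unconstrained, matching the original protocol.

**Sign conventions.**  We use $\Delta G^\mathrm{app} = RT \ln(K_d/100)$
(mole-fraction reference): a smaller $K_d$ — stronger binding — gives a
more negative $\Delta G$, and
$\Delta G_A - \Delta G_B = RT\ln(K_{d,A}/K_{d,B}) = \Delta\Delta G$,
negative when A is the stronger site.  Absolute $\Delta G^\mathrm{app}$
values depend on the mole-fraction reference state and should not be
compared across methods; $\Delta\Delta G$ is reference-free.

## Density-based free energy

`accumulate_density()` bins selected beads into 0.1 nm voxels after
rigidly aligning every frame's protein onto frame 1 (translation plus
rotation about z only — the membrane normal breaks full rotational
symmetry, and tilting frames out of the bilayer plane would smear leaflet
structure).  Then

$$\Delta G = -RT \ln\left(\bar\rho_\mathrm{site} / \bar\rho_\mathrm{bulk}\right)$$

over masked voxel sets.  The exact masking recipe used in the original
analysis is not publicly specified, so the package's masks are explicit,
configurable stand-ins: a **site mask** is a sphere of voxel centres; the
**bulk mask** is a bilayer z-slab with a protein clearance (default
2.0 nm) and all site spheres excluded.  Two practical notes:

* For quantitative comparisons, erode the site-mask radius by one bin
  below the physical site extent: voxels straddling the site boundary are
  only partially covered by the high-density region and dilute
  $\bar\rho_\mathrm{site}$ (a ~20% density bias is ~0.5 kJ/mol at 310 K).
  The pipeline and acceptance runs do this.
* All cholesterol beads are counted by default; a head-bead-only
  selection is a matter of passing a different `selection`, useful for
  sensitivity checks.  Density-derived $\Delta G$ is known to depend on
  the bulk cholesterol concentration, so the pipeline reports it per
  composition rather than as one number.

## What the synthetic generators do (and do not) emulate

**Kinetic generator** (`kinetic_site_model`,
`generate_saturation_dataset`): a two-state Markov chain per frame with
$p_\mathrm{on} = k_\mathrm{on}[L]$ and $p_\mathrm{off} = k_\mathrm{off}$,
whose stationary occupancy is exactly the Langmuir isotherm with
$K_d^* = k_\mathrm{off}/k_\mathrm{on}$.  Defaults are the stated world of
the validation protocol: the seven-composition series
1, 2.5, 5, 10, 15, 30, 40 %, five replicates, $2\times10^4$ frames per
replicate, $k_\mathrm{off} = 0.1$/frame (a ~10-frame correlation time:
fast-exchange, cholesterol-like when frames are saved every few ns),
emission probability 1 (ground-truth $B_\mathrm{max} = 100\,\%$).  The
chain starts from its stationary distribution so short series are
unbiased.  Seeds derive from the base seed by a counter over
condition × replicate.  What it does **not** emulate: spatial
correlation between residues of a site, x-axis noise (free-ligand
fluctuations), nonspecific background, multi-lipid competition.  A green
recovery test therefore establishes that the occupancy → fit pipeline is
correct and converges at the stated sampling — not that real MD data are
this well-behaved.

**Spatial generator** (`spatial_ensemble_model`,
`simulate_snapshot_ensemble`): i.i.d. snapshots with cholesterol placed
by the Boltzmann weight of a piecewise-constant potential (depth
$\Delta G^*$ inside spherical site wells adjacent to a static protein
cylinder, 0 elsewhere in the two leaflet slabs), the phospholipid
uniform.  Single-bead lipids, no diffusion dynamics, no leaflet
asymmetry: the density estimator and the free-ligand accounting only see
the equilibrium ensemble, which this reproduces exactly, so parameter
recovery here validates the estimator, not any kinetic claim.  Defaults
(10 nm box, 1 nm-radius protein, 0.8 nm site touching the protein
surface, 100+100 lipids, 310 K) were chosen once as a plausible
CG-membrane scale and are not tuned.

## Degenerate inputs and edge rules

* Triclinic boxes are rejected everywhere (GRO, PDB, DCD) — the
  minimum-image arithmetic assumes orthorhombic cells.
* XTC input is rejected with a pointer to DCD/GRO (no XDR decoder is
  available offline; DCD is written and read natively and was validated
  against an independent MD toolkit during development).
* GRO has no chain column: protein chains are inferred by advancing the
  chain label whenever resid fails to increase, which handles multimers
  written as repeated 1..N blocks.  PDB chains are taken as-is.
* A frame with zero unbound lipids is an error (the abscissa is
  undefined); an exposure frame with zero contacts is skipped with a
  message, and only an all-zero set errors.
* Zero site density yields $+\infty$ with a warning (unsampled site);
  zero bulk density is an error.
* Boundary occupancies 30% and 50% are inside the nonspecific band; a
  lipid exactly 0.8 nm from the protein is *bound* (the criterion is
  strictly greater).

## Known limitations

* Ordinary least squares ignores the (small) per-replicate variation of
  the free-cholesterol abscissa.
* Site residue lists are inputs; the community-detection step that
  discovers candidate sites in real trajectories is out of scope.
* Residence-time kinetics ($k_\mathrm{off}$, residence times) are not
  computed — occupancy is a purely equilibrium readout.
* Absolute $\Delta G^\mathrm{app}$ from $K_d^\mathrm{app}$ and from
  densities use different reference states; rank and difference
  comparisons are meaningful, absolute cross-method comparisons are not.
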