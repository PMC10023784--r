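---
title: "Quantitative analysis of TM/JM helix ensembles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative analysis of TM/JM helix ensembles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memjm)
library(dplyr)
```

## The problem

Single-pass innate-immunity receptors such as the Toll-like receptors carry
one transmembrane (TM) helix followed by a cytoplasmic juxtamembrane (JM)
stretch before the globular signalling domain. Solution-NMR studies of
TM+JM constructs in membrane mimetics (bicelles, micelles) deposit
conformer ensembles — typically the 10 best structures — and the questions
asked of those ensembles are quantitative and recurring:

* Does the sequence predict a second, membrane-associated JM helix
  (sliding-window hydropathy; interfacial partitioning propensity)?
* How precise is the ensemble (average pairwise RMSD of the helical
  segments)?
* How is the JM helix oriented relative to the TM helix (interhelical
  angle), and where is the TM helix kinked (local bend profile)?
* Which parts of the construct move as rigid bodies (CA–CA distance
  deviation maps)?
* Which residues face lipid and which face water (NOESY cross-peak
  intensities normalised by diagonal peaks), and how does the environment
  perturb the amide resonances (chemical-shift perturbations)?

`memjm` implements this toolbox end to end, with a synthetic-data module
that builds every input with exact ground truth, so each analysis closes
the loop against its own construction.

## Data model

Everything is a tibble. Ensembles are long atom tables (`model`, `chain`,
`resno`, `resid`, `elety`, `x`, `y`, `z` in Å) validated by
`as_ensemble()`; all analyses operate on the *shared index*, the set of
atoms present in every conformer, because deposited ensembles commonly
differ in terminal atoms. Residue numbering is taken verbatim from the
source file (UniProt convention); nothing is ever renumbered, so published
segment ranges address the data directly.

## Geometry

**Superposition.** `kabsch()` is the closed-form SVD solution with the
determinant corrected to exclude reflections. `pairwise_rmsd()` superposes
every unordered conformer pair on the selected atoms of the selected
segments jointly and reports mean ± sample SD (denominator $M-1$; the
estimator behind published "±" values is rarely stated, and the sample SD
is the conservative choice). "Backbone" means N, CA, C — the convention of
the NMR structure-calculation tools that produce such ensembles; "heavy"
means all non-hydrogen atoms. Published per-construct RMSD tables list one
value per helical segment, so `reference_geometry()` stores per-segment
statistics; joint multi-segment superposition remains available by passing
several segments, and for well-defined ensembles the two conventions agree
to within the quoted SDs.

**Helix axes.** The axis is fitted by least-squares alignment of the
segment's CA atoms onto themselves shifted by one residue: the optimal
rigid transform mapping CA$_{1..n-1}$ onto CA$_{2..n}$ is a screw motion
whose rotation axis is the helix axis. This was a deliberate choice over
the plain principal-component (total-least-squares) line through the CA
cloud: on a finite helix arc whose length is not an integral number of
turns, the PC1 direction is systematically tilted — we measured ≈2° for an
18-residue ideal helix and 10–18° for 5–7-residue windows — which would
swamp both the bend profile and short-segment angles. The screw fit is
exact on ideal helices of any length and, in Monte-Carlo tests
(σ = 0.3 Å per coordinate, 18 residues), recovers the construction axis
with a mean error of ≈0.6°, versus ≈2.3° for PCA. Axes are directed
N→C (sign fixed by the chain displacement), so interhelical angles live in
[0°, 180°] with parallel = 0°.

**Angles and bends.** `interhelix_angle()` averages per-conformer angles
(arithmetic mean ± sample SD; the published TM/JM angles sit far from the
0°/180° wrap, so circular statistics are unnecessary — a documented
limitation near the boundaries). A `mean_axis` method (average the unit
axes first) is exposed because either convention could stand behind a
published single number. `bend_profile()` slides two adjacent axis-fit
windows along the helix; defaults `window = 7`, `offset = 7` (about two
helical turns per window, adjacent windows) are the shortest windows that
keep the local axis stable. The track is anchored at the first residue of
the downstream window, which places a planted kink at exactly its
construction residue.

## Mobility maps

`mobility_map()` computes the sample SD over conformers of every CA–CA
distance, in nm (Å by flag). Distances are rigid-body invariants, so the
map isolates internal flexibility; `rigid_blocks()` extracts maximal
diagonal intervals whose internal deviations all stay below a cutoff
(default 0.1 nm — a display-level choice, configurable, and never asserted
against published values). Frame thinning of trajectory-derived ensembles
is the caller's responsibility; the reader accepts any multi-model PDB.

## NMR-derived tracks

Chemical-shift perturbations combine amide shifts as
$\mathrm{CSP} = \sqrt{\Delta\delta_H^2 + \Delta\delta_N^2/10^2}$, the
15N change scaled down tenfold for the gyromagnetic-ratio difference.
NOE contact profiles divide the lipid-CH$_2$-region (1.25–1.35 ppm) and
water (4.6 ppm) cross-peak intensities by the residue's diagonal-peak
intensity. Residues whose own protons — or those of residue $i-1$ —
resonate within the lipid window (± a margin, default 0.05 ppm, since
"close" is not quantifiable from published material) are excluded from the
lipid track: their intra/sequential NOEs would masquerade as lipid
contacts. Classification cutoffs for surface-style colouring default to
0.05 on both normalised tracks; they are presentation parameters, not
measurements.

## Hydropathy

`window_hydropathy()` computes moving averages over a 4-residue frame by
default — close to one α-helix turn, so amphipathic helical faces do not
alias. The scale behind published hydropathy figures is typically unnamed;
the Kyte–Doolittle index is the shipped default and the Wimley–White
interfacial scale (kcal/mol, charged-form Asp/Glu, neutral His) backs
`interface_propensity()`. Window values anchor at the window's first
residue (keeps the TM-run left edge aligned with the sequence), with
center anchoring by flag; the hydrophobic threshold defaults to 0.0 scale
units. All three choices are configurable because the corresponding
published display conventions are unstated.

## Synthetic data as ground truth

`make_helix()` places CA atoms on a cylinder (rise 1.5 Å, twist 100°,
radius 2.3 Å — textbook α-helix values stored as defaults, not literals in
the code paths). Kinks rotate everything downstream about an axis
perpendicular to the local helix axis, so the inter-axis angle across the
kink is exact by construction. `make_hairpin()` joins two ideal helices at
an exact inter-axis angle with a 3-residue unmodeled numbering gap (a
built loop would blur the axis ground truth). `perturb_ensemble()` adds
i.i.d. Gaussian coordinate noise and optional random rigid transforms —
the negative control every internal-geometry analysis must ignore.
`make_tables()` plants CSPs (realised in the 1H dimension), normalised
contacts, and overlap exclusions exactly.

What the generator does *not* emulate: real side chains (heavy-atom RMSD
statistics on synthetic ensembles reduce to backbone statistics),
correlated structural noise (NMR ensembles are restraint-driven, not
i.i.d.), loop geometry between helices, and chemical-shift physics. Tests
passing on synthetic fixtures therefore demonstrate correctness of the
estimators, not the field behaviour of real depositions — which is why the
package ships `validate_ensembles()`, a one-call comparison of a
user-supplied directory of deposited multi-model PDB files against the
published per-segment RMSDs and interhelical angles in
`reference_geometry()`. Nothing is downloaded at any point.

A note on noise levels: i.i.d. coordinate noise σ relates to the expected
pairwise RMSD as $\sqrt{2}\,\sigma\sqrt{3}\approx 2.45\sigma$ *before*
superposition; the Kabsch fit absorbs six rigid degrees of freedom, so
measured values run a few percent lower. Where the test suite emulates a
deposited ensemble's precision (backbone RMSD ≈ 0.45 Å) it uses
σ ≈ 0.19 Å.

## Numerical choices and degenerate inputs

* Sample SD (ddof = 1) everywhere, for consistency across modules.
* Angles are clamped into [−1, 1] before `acos`; axis signs resolved by
  chain direction; ties in altloc resolution go to `A` after occupancy.
* Collinear point sets are rejected by `kabsch()` and `fit_axis()` (the
  rotation/axis is undetermined); segments must span ≥ 5 residues
  (≈1.4 turns) for an axis fit.
* `rigid_blocks()` ignores the (zero) diagonal, so a cutoff of 0 yields
  singleton blocks rather than nothing.
* Coordinates are Å internally; nm appears only at the mobility-map
  output boundary. PDB output uses the fixed-width three-decimal dialect,
  so round trips are exact to 10⁻³ Å.

## Problem sizes in the shipped tests

The suite closes loops on 18–40-residue helices, ensembles of 2–10
conformers, 20-seed Monte-Carlo repeats for stochastic claims, and 1000
random sequences for the hydropathy brute-force property — sizes chosen so
the whole suite runs in about a minute and a half on one core while every
estimator is exercised above its minimum stable input size.

## Worked example

```{r example}
hp <- make_hairpin(65, seed = 1)
segs <- attr(hp, "segments")
ens <- perturb_ensemble(hp, n_models = 10, sigma = 0.3, seed = 1)

interhelix_angle(ens, segs[1, ], segs[2, ])
pairwise_rmsd(ens, segs)
glance(mobility_map(ens))
```

## Known limitations

* No membrane frame: tilt angles relative to a bilayer normal are out of
  scope (NMR depositions carry no membrane coordinates).
* Angle statistics are linear, not circular; distributions hugging 0° or
  180° will be biased inward.
* The FASTA/PDB/TSV dialects are deliberately narrow (no mmCIF, no binary
  trajectories); convert externally.
* Heavy-atom selections on CA-only synthetic fixtures silently coincide
  with backbone selections — by design, but worth knowing when reading
  test output.
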