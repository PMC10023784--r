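# memjm

Quantitative analysis of transmembrane/juxtamembrane (TM/JM) helix
constructs of single-pass membrane receptors, as studied by solution NMR in
membrane mimetics. The package is aimed at structural biologists who have a
conformer ensemble (a deposited multi-model PDB file, or frames exported
from a simulation), the construct sequence, and per-residue NMR tables, and
who want the standard quantitative read-outs computed reproducibly:

* **Hydropathy profiling** — moving-average hydrophobicity over an
  `f`-residue frame (default 4, about one α-helix turn),
  value<sub>i</sub> = mean of scale values over residues *i..i+f−1*, with
  Kyte–Doolittle and Wimley–White interfacial scales shipped; plus
  hydrophobic/hydrophilic run annotation and interfacial-partitioning
  propensity of a residue range.
* **Ensemble geometry** — Kabsch (SVD) superposition; average pairwise RMSD
  over all M(M−1)/2 conformer pairs on backbone (N, CA, C) or heavy atoms;
  helix-axis fits (the screw axis of the least-squares map of CA₁..ₙ₋₁ onto
  CA₂..ₙ); interhelical angles θ = arccos(û₁·û₂) on N→C directed axes; and
  local bend/kink profiles from adjacent axis-fit windows.
* **Internal mobility maps** — entry (i, j) is the sample SD over
  conformers of the CA<sub>i</sub>–CA<sub>j</sub> distance (nm), a
  rigid-motion-invariant map whose low-deviation diagonal blocks are the
  rigid structural domains (`rigid_blocks()` extracts them).
* **NMR tracks** — chemical-shift perturbations
  CSP = √(Δδ<sub>H</sub>² + Δδ<sub>N</sub>²/10²), and NOE lipid/water
  contact profiles normalised by diagonal-peak intensities with the
  spectral-overlap exclusion rule (residue *i* is dropped from the lipid
  track when a proton of *i* or *i−1* resonates inside the lipid CH₂
  window).
* **Synthetic ground truth** — ideal helices, kinked helices, two-helix
  hairpins at exact inter-axis angles, Gaussian-noise ensembles, and
  shift/peak tables with planted effects, so every estimator closes the
  loop against its own construction.

Everything takes and returns tibbles and chains with the pipe; result
objects have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

A 65° two-helix hairpin, blurred into a 10-conformer ensemble with 0.3 Å
coordinate noise, then re-measured:

```r
library(memjm)

hp   <- make_hairpin(65, seed = 1)          # exact ground truth: 65 deg
segs <- attr(hp, "segments")                # residues 1-18 and 22-39
ens  <- perturb_ensemble(hp, n_models = 10, sigma = 0.3, seed = 1)

interhelix_angle(ens, segs[1, ], segs[2, ])
#> Interhelical angle 1-18 vs 22-39 (per_conformer): 65.1 +/- 0.7 deg

pairwise_rmsd(ens, segs)
#> Pairwise RMSD (backbone atoms, 10 conformers, 45 pairs): 0.75 +/- 0.05 A

glance(mobility_map(ens))
#> # A tibble: 1 × 5
#>   n_residues n_conformers units max_deviation median_deviation
#> 1         36           10 nm           0.0797           0.0419
```

The recovered angle (65.1° ± 0.7°) brackets the construction truth; the
pairwise backbone RMSD sits at the σ√6 ≈ 0.73 Å level expected for
i.i.d. 0.3 Å noise; the mobility map stays below 0.08 nm because i.i.d.
noise creates no coherent inter-domain motion.

Sequence-side, a designed TM + linker + JM architecture shows the
two-patch hydropathy signature:

```r
make_tm_jm_sequence("separated") |>
  window_hydropathy(frame = 4) |>
  annotate_regions(threshold = 0)
#> # A tibble: 5 × 6
#>   start   end res_first res_last n_windows label
#> 1     1     7         1       10         7 hydrophilic
#> 2     8    26         8       29        19 hydrophobic   <- TM run
#> 3    27    32        27       35         6 hydrophilic   <- linker
#> 4    33    44        33       47        12 hydrophobic   <- JM patch
#> 5    45    49        45       52         5 hydrophilic
```

## Validating against deposited ensembles

`validate_ensembles(dir)` takes a directory containing user-downloaded
multi-model PDB files for the TLR TM/JM depositions (8AR0, 8AR1, 8AR2,
8AR3; nothing is downloaded by the package), recomputes per-segment
pairwise RMSDs and TM/JM interhelical angles, and compares them with the
published reference values in `reference_geometry()` (e.g. 80° ± 10° for
the TLR2 construct, backbone RMSD 0.45 ± 0.19 Å for its TM helix). The
same workflow is exercised in the test suite on synthetic stand-in
ensembles built at those geometries.

A thin command-line front end covers the same ground:

```sh
Rscript inst/cli/memjm.R angle --pdb ens.pdb --helix1 586-606 --helix2 615-626
Rscript inst/cli/memjm.R validate --accession-dir ./pdb --out report.tsv
```

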