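---
title: "Methods: dual-target docking selectivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-target docking selectivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockselect)
```

# The procedure

`dockselect` post-processes a dual-target virtual screen: one ligand library
docked with AutoDock Vina (or a fork) against two related receptors, the
motivating pair being acetylcholinesterase (AChE, "target A") and
butyrylcholinesterase (BChE, "target B"). The analysis chain is

1. parse each ligand's multi-model PDBQT output into ranked binding modes
   (energy, RMSD bounds) and the mode-1 atom records;
2. summarize each ligand's modes (first-mode energy, mean, SD, SE, mean RMSD
   bounds);
3. pair ligands across the two screens by identifier and compute the signed
   selectivity `s = E_A − E_B` from the first-mode energies, classifying at
   a strict threshold;
4. summarize the screen (class counts/percentages, per-class |ΔE_A| maxima,
   occurrence histograms) and compare |ΔE_A| samples with a Mann–Whitney U
   test;
5. map residue-proximity densities of the docked poses' polar H, O and N
   atoms under per-element distance cutoffs;
6. filter ligands on structural properties (rotatable bonds, bounding box,
   Lipinski subset).

The package deliberately stops at analysis: it never runs docking, prepares
receptors, or assigns charges. Receptor and ligand files are read as
prepared; in particular, partial charges are taken verbatim from the PDBQT
columns and never recomputed.

# Assumptions

* **First-mode comparison.** Selectivity is judged on the lowest-energy
  binding mode of each ligand–target pair. Mode-energy means sit close to
  the first-mode energies in practice (SDs of a few tenths of a kcal/mol),
  which is what makes the first-mode shortcut defensible; the per-ligand
  statistics let a user check that closeness on their own screen.
* **More negative = stronger.** Binding free energies are in kcal/mol;
  `s < 0` means the ligand is predicted to prefer target A. Positive
  (repulsive) energies are retained — they are scientifically meaningful,
  arising when a large ligand cannot fit one target's active-site gorge, and
  they drive the extreme |ΔE_A| tail.
* **Polar hydrogens only.** Ligand PDBQT files are united-atom: AutoDock
  merges non-polar hydrogens, so every "hydrogen" analysis (proximity
  clouds, donor counts) operates on polar hydrogens (type HD). This is a
  property of the input format, not a package choice.
* **Vina rank convention.** Mode 1 is the energy minimum and energies are
  nondecreasing with rank. Files violating this are accepted with a warning
  and a flag, since third-party outputs may be hand-edited; modes are never
  re-sorted, and tied energies keep file order.

# Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| selectivity threshold `t` | 0.1 | kcal/mol | Vina prints energies at 0.1 kcal/mol resolution; differences at or below one print unit are noise. The inequality is strict: `|s| = 0.1` is nonselective. |
| proximity cutoffs | H 1.5, O 1.5, N 2.5 | Å | the per-element radii used when annotating active-site residues around docked H/O/N atom clouds; S and halogens can be added via `proximity_cutoffs(...)`. |
| histogram bin width | 0.1 | kcal/mol | one print unit; the occurrence histograms then count ligands per resolvable energy difference. |
| histogram cutoff | none (`Inf`) | kcal/mol | set to e.g. 100 to pool the repulsive tail into one overflow bin for display. |
| rotor limit | 18 | bonds | the conventional pre-docking exclusion of overly flexible ligands; the count is the PDBQT `TORSDOF` value, the only rotor count those files carry. |
| SD denominator | sample (n−1) | — | mode counts can be as low as 6, where the sample/population distinction is material; sample SD is the conventional default and a flag switches to population. |

# Numerical choices

* **Cutoff boundary inclusive.** A contact requires `d ≤ cutoff`. Contact
  detection is exact brute force (all atom pairs); no spatial index is used,
  so there are no boundary false negatives by construction.
* **Contact counting.** Each (ligand atom, residue) pair counts once, at the
  minimum atom–atom distance — a large residue is not counted once per
  receptor atom. `per_receptor_atom = TRUE` switches to per-atom counting as
  a sensitivity analysis.
* **Tie-breaks.** Residue rankings break count ties by ascending residue
  number; ligand rankings use a stable sort, so key ties keep input order.
* **Mann–Whitney.** Midranks for ties; tie-corrected variance always on; no
  continuity correction; two-sided p from the normal approximation. With
  0.1-resolution energies ties are ubiquitous, so the correction term is not
  optional. For pooled sizes ≤ 12 an exact p is also computed by full
  enumeration of group assignments. Zero pooled variance (all values
  identical) is reported as a degenerate test with p = 1. The normal
  approximation is a *large-sample* device: for pooled sizes around 10 it
  can disagree with the exact p by far more than 0.05 near the null center
  (the discrete exact p jumps to 1 while the continuous approximation stays
  near 0.9) — use `p_exact` for small samples.
* **Percentage rounding.** Screen percentages are reported rounded to the
  nearest integer, as such summaries are quoted, with full-precision values
  alongside.
* **Histogram edges.** Bin lower edges are multiples of the bin width
  (intervals `[lo, lo + w)`), values beyond the cutoff pool into one
  overflow bin, and counts always sum to the number of records.
* **Energy precision on write.** Vina prints one decimal; fixtures default
  to three so statistical tests are not quantization-dominated
  (`digits = 1` restores Vina-faithful output). Round-trips are exact at the
  written precision.
* **Degenerate inputs.** One binding mode gives SD 0 by convention; a
  missing `TORSDOF` keeps the ligand with a warning and an unknown count;
  an empty contact set yields an empty profile, not an error.

# The synthetic generator

`generate_paired_screen()` emulates the distributional shape of a paired
cholinesterase screen, with planted per-ligand truth:

* class fractions default to 48% A-selective / 46% B-selective / 6%
  nonselective — the split observed in an FDA-approved library screen;
* base first-mode energies are normal around −8.5 kcal/mol (SD 1);
* selective |ΔE_A| magnitudes are `t + guard + Gamma(shape, scale)`, with a
  tighter gamma for the A side (shape 1.2, scale 0.45; observed A-side
  maxima are a few kcal/mol) than the B side (shape 1.3, scale 1.6,
  concentrated roughly over 0.1–10 kcal/mol);
* a small fraction (2%) of B-selective ligands draw instead from a uniform
  100–120 kcal/mol tail, modelling the distinct mechanism of repulsive
  target-A energies — a separate component, not a stretched gamma;
* mode counts are uniform on 6–20 with exponential inter-mode gaps
  (mean 0.25 kcal/mol), and RMSD bounds satisfy `lb ≤ ub` with mode 1 at
  0/0;
* mock atoms cycle C/N/O/HD with charges ~ N(0, 0.2 e) clipped to ±1.

The **guard band** (0.005 kcal/mol) keeps every planted magnitude strictly
away from the threshold by more than one 3-decimal write-precision unit, so
planted labels are recoverable exactly after file round-trips. Each ligand
draws from its own seed-derived RNG substream, so growing the screen never
reshuffles earlier ligands, and the same seed reproduces output directories
byte-identically.

What the generator does **not** emulate: physically realistic poses,
correlated energies between targets beyond the planted difference,
force-field structure in the mode lists, chemically valid ligand topologies.
Passing recovery tests therefore demonstrates that the *analysis chain* is
correct — pairing, classification, counting, contact detection — not that
docking energies themselves are accurate, and conclusions about real screens
still depend on the docking engine's validity.

`generate_proximity_fixture()` places residue anchors 25 Å apart and ligand
atoms at exact planted distances, with all other pairwise distances beyond
any reasonable cutoff, so the planted contact table is the ground truth the
contact stage must recover exactly. Distances within 0.01 Å of a cutoff are
rejected unless boundary testing is requested.

# Open design choices

* **Sign convention.** `s = E_A − E_B` with A-selective meaning `s < −t`;
  self-consistent with the reported magnitudes (e.g. an A-selective ligand
  at −10.8 vs −8.9 kcal/mol has ΔE_A = 1.9).
* **"Volume".** Ligand volume is the product of the three axis-aligned
  bounding-box extents — the printed dimension products match the quoted
  volumes for the reference ligands — not a van der Waals volume, and it is
  orientation-dependent unless `principal_axes = TRUE`.
* **HBD/HBA.** Donors are counted as polar hydrogens and acceptors as N + O
  atoms, the classical structural operationalization; PDBQT carries no bond
  table, so these are approximations and documented as such.
* **Element mapping.** AutoDock types map deterministically to
  {C, N, O, H, S, P, halogen, other}; unknown types become "other" and are
  never dropped.
* **Within-run rank test.** `run_pipeline()` compares the A-selective vs
  B-selective |ΔE_A| samples of the run; comparing two different screens'
  ΔE_A distributions (e.g. two libraries) is done directly with
  `mann_whitney()` on their record tables.
* **Receptor charges.** Prepared receptor files carry whatever charge model
  the preparation tool assigned; the package reads those columns as-is and
  never recomputes charges.

# Problem sizes used in the test suite

The suite exercises: parser round-trips on randomized ligands; mode
statistics against a brute-force oracle on 1,000 random ligands (agreement
to 1e−9); contact detection against an exhaustive all-pairs oracle on 1,000
random geometries including exact-boundary plantings; Mann–Whitney against
full enumeration across all pooled sizes ≤ 10 and against an independent
12,870-assignment enumeration at 8+8; label and fraction recovery on a
5,000-ligand synthetic screen; and a Kolmogorov–Smirnov check of the planted
gamma body at n = 10,000. These sizes give stable statistical power for the
properties being checked while keeping the full suite fast.

# Known limitations

* Only mode-1 poses are analyzed for proximity and property work; the
  parser retains atoms of mode 1 only, matching the first-mode analysis
  convention.
* logP cannot be computed from PDBQT content; the Lipinski logP rule is
  evaluated only when a value is supplied externally.
* Molecular weight from a docked pose omits merged non-polar hydrogens;
  formula-based `molecular_weight()` is exact.
* Residue-proximity results are only as meaningful as the receptor frame:
  ligand poses and receptor must come from the same docking setup.
* The selectivity statistic inherits every limitation of docking scores;
  the package quantifies predicted selectivity, it does not validate it.
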