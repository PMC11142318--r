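---
title: "Scoring predicted protein-ligand complexes with poseval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring predicted protein-ligand complexes with poseval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poseval)
library(dplyr)
```

## What the toolkit measures

Docking and co-folding models output a protein structure together with one
or more placed ligands. Judging such a pose against the crystal reference
involves several distinct questions — is the ligand in the right pocket, in
the right orientation, chemically sane, and does it make the right contacts
with the right residues? `poseval` computes one metric per question:

* **Heavy-atom RMSD** (symmetry-corrected): for a ligand with heavy-atom
  positions $\hat{x}_i$ against reference positions $x_i$,
  $\mathrm{RMSD} = \sqrt{\tfrac1n \sum_i \lVert \hat{x}_{\sigma(i)} - x_i
  \rVert^2}$, minimized over the automorphisms $\sigma$ of the molecular
  graph. Without the correction a benzene rotated by 60° about its
  six-fold axis — a physically identical pose — would score ≈ 1.4 Å
  instead of 0.
* **Centroid distance (cRMSD)**: the Euclidean distance between the
  unweighted heavy-atom centroids. It is a pocket-identification proxy —
  a pose can have terrible internal geometry and still a small cRMSD. The
  field's "cRMSD" name is kept although it is a plain distance.
* **lDDT**: the superposition-free local distance difference test. For
  each reference atom $i$, the neighbor set $N_i$ holds atoms of *other*
  residues within the inclusion radius $R_o = 15$ Å; the score averages,
  over atoms and the thresholds $\Delta_k \in \{0.5, 1, 2, 4\}$ Å, the
  fraction of neighbor distances reproduced to better than $\Delta_k$
  (strict `<`).
* **lDDT-PLI**: the interface variant. Scored atoms range over ligand
  heavy atoms, neighbor sets hold only protein heavy atoms within a
  contact radius of that atom in the reference, and the ligand
  automorphism maximizing the score is used. The generic $R_o$ is defined
  in the literature only for whole-structure lDDT; for the interface
  restriction this package defaults to a 6 Å contact radius and exposes it
  (`lddt_params(pli_radius = )`), since published descriptions of the
  interface variant do not pin it down.
* **PB-Valid**: a PoseBusters-style conjunction of chemical and geometric
  sanity checks (valences, bond lengths within 0.75–1.25 of the
  covalent-radius reference, angles within 0.75–1.25 of the hybridization
  ideal, non-bonded intramolecular pairs ≥ 0.8 of the van der Waals sum,
  aromatic rings and double-bond frames flat to 0.25 Å, no intermolecular
  clashes below 0.75 of the van der Waals sum, stereocenters preserved
  when a reference is available). The original suite's force-field
  energy-ratio inspection is deliberately **not** evaluated — it would make
  the verdict depend on a force-field implementation — and is recorded as
  `NA` rather than silently passed.
* **PLIF-EMD / PLIF-WM**: each complex is reduced to a histogram of
  interaction fingerprints, tuples ⟨ligand code, residue name, interaction
  type⟩ detected by geometric rules. Predicted and native histograms are
  placed on the union of their bins (so hallucinated interaction types are
  penalized), normalized to probability mass, and compared with the 1-D
  Wasserstein distance $\sum_k |\mathrm{CDF}_u(k) - \mathrm{CDF}_v(k)|$
  over unit-spaced bins. Per-method mean distances are min–max normalized
  across a method collection into the matching score
  $\mathrm{WM} = 1 - (\mathrm{EMD} - \mathrm{EMD}_{\min}) /
  (\mathrm{EMD}_{\max} - \mathrm{EMD}_{\min})$, so the collection's best
  method scores 1 and its worst 0.

## The evaluation protocols

`evaluate_primary()` chains the steps a benchmark run needs for a
single-annotated-ligand target: optimal chain mapping → reference pocket
definition (all residues with any heavy atom within 10 Å of any ligand
heavy atom) → pocket-focused superposition of the predicted protein (a
Kabsch fit on pocket Cα atoms, applied to the whole prediction including
its ligands) → extraction of the predicted primary fragment by molecular
graph match → metrics. Any error in this chain (a missing primary
fragment, an unparseable file, a degenerate alignment) marks the target
`excluded` with the reason recorded; scoring failures are data, not
crashes.

`evaluate_multi()` handles complexes with several fragments: the pocket
alignment is done once, predicted fragments are assigned to reference
fragments within each graph-identity class by minimum summed
symmetry-aware RMSD (exhaustive for ≤ 6 per class, Hungarian beyond), each
reference fragment gets its own row, the validity verdict is issued once
per complex, and inter-ligand steric clashes are counted.

`aggregate_runs()` turns per-target rows into per-method summaries. Two
decisions deserve emphasis:

* **Excluded predictions count as unsuccessful.** Benchmark papers state
  that failing predictions are "excluded from the evaluation" yet report
  rates over the full target count; this package resolves the tension by
  using the full count as the rate denominator and dropping excluded
  targets only from mean-metric computations (mean PLIF-EMD, mean
  lDDT-PLI).
* **Rates are averaged per run.** With several independent runs per
  method, per-run success rates are computed first and then summarized as
  mean ± sample standard deviation, rather than pooling poses across runs
  before thresholding.

The min–max normalization of PLIF-WM is applied to per-method dataset
means (one mean EMD per method, normalized across the collection); a
per-complex variant would be possible but couples each complex's score to
every other method's behavior on that complex, which makes summaries
harder to interpret.

## Alignment choices

The pocket superposition fits Cα atoms only. Predicted apo structures
routinely repack side chains; a Cα fit is robust to that, and glycine
needs no special casing. An all-heavy-atom pocket fit is available
(`align_to_pocket(atoms = "heavy")`) since the atom choice in published
pipelines is often unstated. The interactive tool used in such pipelines
performs outlier rejection during superposition; plain Kabsch is the
default here, with optional iterative trimming (drop the worst 10 % of
pairs, up to 5 cycles, `trim_cycles`) for users who want
rejection-style behavior — the exact published behavior is not specified
anywhere, so the deterministic plain fit is the default.

Residue correspondence between predicted and reference chains comes from
global sequence alignment with affine gap penalties; only aligned,
identical residues contribute Cα pairs. Chain bijections are enumerated
exhaustively within sequence-compatible classes (≥ 95 % identity by
default) up to 6 interchangeable chains, greedily beyond, and the
bijection minimizing the pocket fit RMSD wins.

## Fingerprint detection rules

Detection is purely geometric, on heavy atoms, with idealized hydrogens
constructed only where an angle test needs them: for a donor with one
heavy neighbor the hydrogen is placed on the cone at the hybridization
angle around the bond axis, steered toward the acceptor (the optimum for
a rotatable O–H/N–H); for multi-neighbor donors it points away from the
mean neighbor direction. Default thresholds: hydrogen bond ≤ 3.5 Å with
idealized D–H⋯A ≥ 130°; hydrophobic C/S⋯C/S ≤ 4.5 Å; ionic group centers
≤ 4.5 Å; ring-centroid ≤ 5.5 Å with inter-plane angle ≤ 35° (face) or
50–90° (edge); cation–ring ≤ 4.5 Å; halogen bond ≤ 3.5 Å with C–X⋯A ≥
130°; metal–N/O/S ≤ 2.8 Å. Every threshold lives in
`geometric_criteria()`. A generic van der Waals contact rule exists but
is off by default, matching the reference fingerprinting tool's shipped
configuration. Interaction names take the ligand's perspective
(`HBond-donor` = ligand donates; `Ionic-anion` = ligand is the anion;
`CationPi` = ligand cation over a protein ring; `PiCation` = ligand ring
under a protein cation).

Because the tuples are categorical, their 1-D embedding for the
Wasserstein distance depends on bin order; the package fixes a canonical
lexicographic order (ligand code, residue name, interaction type, C
locale) so every result is reproducible. When a method predicts zero
interactions the distance is undefined and raised as a typed condition by
default; a "maximum distance" fallback exists behind
`plif_emd(empty_policy = "max")` but guessing is not the default.

## The synthetic-complex generator

All tests run on synthetic complexes built by `make_toy_complex()`:
idealized residues (GLY, ALA, SER, ARG, ASP, PHE, HIS — enough to plant
every interaction type) placed on a Fibonacci sphere around the origin
with side chains pointing inward, and idealized small molecules (benzene,
ethanol, acetate, methylammonium, imidazole, a bare Mg²⁺ ion) centered in
the cavity. Residue geometry comes from standard internal coordinates
(NeRF placement; aromatic rings are exact regular polygons, so planarity
holds to machine precision). One contact is planted deterministically — an
alanine CB at 4.0 Å from an apolar ligand atom, or an aspartate OD2 at
2.6 Å from a lone metal — so every generated reference complex passes the
validity checks, has a non-empty 10 Å pocket and carries at least one
detectable fingerprint; the generator re-validates these guarantees and
retries with a slightly wider sphere (+2.5, +5 Å) if a seeded side-chain
spin happens to graze a fragment. A single integer seed governs all
randomness through counter-based sub-streams, so outputs are
byte-reproducible and independent of generation order.

`perturb_pose()` provides perturbations with closed-form ground truth:
a translation by $d$ changes RMSD and centroid distance by exactly $d$; a
rotation about the ligand centroid leaves the centroid fixed; relabeling
atoms by a graph automorphism leaves the symmetry-corrected RMSD at
exactly 0; ejection moves the ligand > 10 Å from every residue, emptying
the pocket and the fingerprint histogram.

`make_benchmark()` emulates a method-comparison study: per synthetic
"method" it plants an exact success fraction (successes are 0.5 Å
translations plus optional small Gaussian jitter, failures 6 Å
translations) and hands each prediction to the scorer in a different
global frame — a seeded rigid motion of the whole predicted complex — so
the pocket alignment is genuinely exercised. The protein coordinates are
otherwise exact copies; predicted-apo coordinate error is emulated only
through that frame change, which keeps the planted pose errors exact
after alignment (the realized success rates equal the planted fractions
to the digit). This is the one important respect in which the synthetic
data are easier than real benchmarks: real apo predictions deform the
pocket itself, so real pocket fits have nonzero residuals and the metrics
inherit that noise. Passing tests demonstrate correctness of the scoring
machinery, not robustness to pocket deformation.

The default study conditions used by `scripts/acceptance.R` are 20
targets, three method profiles (planted success fractions 0.9 / 0.5 /
0.2 with per-atom jitter of 0.03 / 0.08 / 0.15 Å on successful poses),
and three runs per method — sizes chosen so the whole pipeline, run
three times over, completes in about a minute on one CPU while still
exercising multi-run aggregation.

## Numerical choices and degenerate inputs

* Kabsch uses an SVD with the determinant sign fixed, so a reflection is
  never returned; rank-deficient (collinear) point sets and fits with
  fewer than 3 pairs raise a typed `degenerate alignment` condition.
* lDDT's step function is strict (`<`), exactly as the formula prints; a
  deviation equal to a threshold fails that threshold. Atoms with empty
  neighbor sets are skipped from the outer average (the conventional
  treatment); with $R_o = 15$ Å this essentially never differs from
  averaging over all atoms.
* Automorphism enumeration is capped at 10⁴ mappings; beyond the cap the
  single canonical-labeling correspondence is used and the result flagged.
  None of the shipped templates comes near the cap.
* Ligand identity ignores stereochemistry: predictions that flip a
  stereocenter must be scored (and fail the stereo check), not rejected
  at fragment-matching time.
* Alternate locations resolve to the highest-occupancy conformer, ties
  broken by altloc label — a deterministic parse.
* Tied assignment costs (e.g. two identical ions equidistant from two
  references) resolve to the first optimal permutation in enumeration
  order, which is fixed by the canonical fragment order.

## Limitations

Covalently bound ligands, nucleic-acid chains, water-mediated
interactions, interaction energies, and the energy-ratio validity check
are out of scope. The fingerprint detector's hydrogen idealization is a
geometric construction, not a protonation-state assignment; histidine is
treated as neutral (donor/acceptor on both ring nitrogens, never
cationic). The symmetry treatment of resonance-equivalent groups (e.g.
the two carboxylate oxygens drawn with different bond orders) follows the
drawn graph, as the validity literature does, rather than a
resonance-aware equivalence.
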