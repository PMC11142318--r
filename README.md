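# poseval

Scoring toolkit for protein–ligand docking and co-folding predictions.

Methods that predict protein–ligand complex structures — classical docking
programs and the newer co-folding models alike — are judged by comparing
each predicted pose against the deposited crystal structure. Doing that
fairly requires more than a naive coordinate difference: the predicted
protein lives in its own frame and must first be superposed onto the
reference *binding pocket*; chemically equivalent atoms (a benzene ring's
six carbons, two identical cofactor copies) must not be penalized for
arbitrary labeling; a pose can be numerically close yet chemically
nonsensical; and a pose can be structurally accurate while making the
wrong contacts with the wrong residues. `poseval` implements the full
scoring stack for benchmark studies of such methods, for structural
bioinformaticians who need reproducible, dependency-light pose evaluation
in R.

## Metrics

For a ligand with predicted heavy-atom positions $\hat x_i$ and reference
positions $x_i$ (both in the pocket-aligned frame):

* symmetry-corrected RMSD
  $\min_{\sigma \in \mathrm{Aut}(G)} \sqrt{\frac1n \sum_i \lVert
  \hat x_{\sigma(i)} - x_i \rVert^2}$, minimized over the automorphisms of
  the molecular graph $G$;
* centroid distance (cRMSD), a binding-pocket-identification proxy;
* lDDT — the superposition-free local distance difference test with
  inclusion radius 15 Å and thresholds 0.5/1/2/4 Å — and its
  protein–ligand interface variant lDDT-PLI;
* PB-Valid, a PoseBusters-style conjunction of chemical and geometric
  sanity checks, plus separate protein–ligand and inter-ligand steric
  clash counts;
* PLIF-EMD, the 1-D Wasserstein distance between predicted and native
  histograms of interaction-fingerprint tuples ⟨ligand, residue,
  interaction type⟩, and PLIF-WM, its min–max normalization across a
  method collection (1 = best, 0 = worst).

Success rates are reported at the standard thresholds RMSD ≤ 2 Å and
cRMSD ≤ 1 Å, aggregated as mean ± sd across independent runs. The methods
vignette (`vignettes/pose-evaluation.Rmd`) derives every formula and
documents each design decision.

## Worked example

Build a toy reference complex (an idealized pocket with an acetate bound
at its center), perturb it into a "prediction", and score it:

```r
library(poseval)

ref  <- make_toy_complex(seed = 7, templates = "acetate")
pred <- ref |>
  perturb_pose("translate", magnitude = 1.4, seed = 2) |>
  perturb_pose("jitter", magnitude = 0.1, seed = 3)

evaluate_primary(pred, ref, target_id = "toy")
#>   target_id status rmsd crmsd lddt_pli pb_valid plif_emd
#> 1       toy scored 1.46  1.46    0.708     TRUE        0
```

The 1.4 Å planted translation (plus 0.1 Å jitter) shows up as an RMSD of
1.46 Å — inside the 2 Å success threshold — with the centroid moved by
the same amount; the interface lDDT of 0.708 reflects the disturbed
protein–ligand distances; the pose is chemically valid; and the
fingerprint distance of 0 says the pose still makes exactly the native
interactions:

```r
detect_plifs(ref)
#> # A tibble: 1 × 4
#>   ligand_code residue_name interaction count
#> 1 ACT         ALA          Hydrophobic     1
```

Batch evaluation reads a manifest CSV of prediction/reference file pairs
(PDB/mmCIF proteins, SDF ligands, optional SMILES sidecars) and
`aggregate_runs()` produces the per-method summary table with success
rates, mean PLIF-EMD and PLIF-WM; `autoplot()` on that table draws the
usual grouped success-rate bars. A thin command-line front end is
installed at `inst/cli/poseval` with `score`, `batch`, `aggregate`,
`plif` and `fixtures` subcommands.

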