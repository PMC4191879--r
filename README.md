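# terpchannel

Mechanism-based reaction-channel prediction for triterpenoid synthases.

## The problem

Triterpenoid synthases (triterpene cyclases) convert squalene or
2,3-oxidosqualene into hundreds of polycyclic products — hopene, lupeol,
lanosterol, cycloartenol and relatives — through cascades of carbocationic
intermediates. Which cascade ("reaction channel") an enzyme follows, and
where along it the cation is finally quenched, determines the product
skeleton. Because single point mutations can redirect the cascade,
sequence similarity alone is a poor predictor of product specificity.

`terpchannel` implements a structure-based alternative: dock *multiple
carbocationic intermediates* along each candidate channel into an enzyme's
active site, and read the channel, the plausible product precursors, and
the ruled-out products off the per-intermediate binding-score profile.
It is aimed at computational enzymologists triaging uncharacterized
cyclase sequences and at protein engineers screening mutations.

## The method

Channels are ordered series of intermediates (channel A: hopene,
A-I1..A-I4; B: lupeol/dammarenyl, B-I1..B-I2; C: lanosterol/protosteryl,
C-I1..C-I9; D: C35, representable but disabled by default). Scores are
MM/GBSA-style binding energies in kcal/mol, more negative = better; an
intermediate for which no constraint-satisfying pose exists is the
distinct state NO_POSE, never a sentinel number.

Given a score table S(enzyme, intermediate), the package provides:

* **Hierarchical channel ranking** (`rank_channels`, `predict_channel`) —
  round 1 orders channels by their first representative intermediate I1;
  channels within a tie threshold (default 1 kcal/mol) of the best are
  re-ordered in round 2 by the second representative I2. NO_POSE ranks
  strictly worse than any number.
* **Intermediate ranking** (`rank_intermediates`) — all scored
  intermediates along the chosen channel, best first.
* **Endpoint prediction** (`predict_endpoint`) — the best downstream
  binder (index ≥ 2) is the putative product precursor; the reaction is
  predicted to terminate just before the first downstream non-binder
  (NO_POSE or score > 0), and the products of everything past that point
  are ruled out.
* **Mutant analysis** (`compare_mutant`) — Δ = S_mut − S_wt per
  intermediate, classified unaffected / destabilized (Δ ≥ 5 kcal/mol) /
  abolished (NO_POSE).
* **Pose geometry** (`read_pose`, `dihedral`, `classify_conformer`,
  `rmsd`, `check_core_restraint`) — minimal mol2/SDF/PDB readers, the
  signed Φ[C16-C17-C18-H18] torsion whose sign separates the A-like
  (Φ > 0) from the B/C-like (Φ < 0) I1 fold, in-place and Kabsch RMSD,
  and the 1.0 Å core-restraint check.
* **Toy constrained docking** (`dock`, `score_pose`) — a desk-scale
  stand-in for induced-fit docking: seeded rigid sampling under an
  anionic-anchor constraint and core restraint, Lennard-Jones + Coulomb
  scoring with ε(r) = 4r, and rigid-body refinement.
* **Sequence similarity networks** (`build_network`,
  `segregation_purity`, `quartile_table`) — all-vs-all local alignment
  (BLOSUM62, affine gaps) with Karlin–Altschul E-values, thresholded
  graphs, components, and channel-segregation purity.
* **Synthetic fixtures** (`gen_profiles`, `gen_sequences`,
  `gen_toy_complex`) — seeded generators planting known channels,
  families and poses, so every stage is testable without downloads.

## Worked example

```r
library(terpchannel)
lib <- default_channel_library()

# representative-intermediate scores for one enzyme (kcal/mol)
tab <- score_table("E1",
  c("A-I1","A-I2","B-I1","B-I2","C-I1","C-I2"),
  c(-60.2, -55.0, -60.0, -50.1, -52.3, -49.0))
rank_channels(tab, "E1", lib)
#> Channel prediction for E1
#>   ranking: A > B > C
#>   round-1 tie group: { A, B }
```

A-I1 and B-I1 differ by 0.2 kcal/mol — inside the 1 kcal/mol tie
threshold — so round 2 compares A-I2 (−55.0) with B-I2 (−50.1) and picks
channel A. C, 7.7 kcal/mol behind in round 1, stays last.

```r
ids <- channel_intermediates(lib, "C")$id
t2 <- score_table("E2", ids, c(-80,-45,-47,-50,-53,-60,-57,NA,-40))
predict_endpoint(t2, "E2", "C", lib)
#> Endpoint prediction for E2, channel C
#>   best intermediate (index >= 2): C-I6
#>   terminate after index 7 (C-I7)
#>   ruled out: cycloartenol, cucurbitadienol
#>   downstream rise check: passed
```

C-I6 is the best downstream binder and C-I8 cannot be docked, so the
cascade is predicted to stop at C-I6/C-I7 (lanosterol precursors);
products quenched from C-I8 and C-I9 (cycloartenol, cucurbitadienol) are
ruled out.

```r
rel <- read_scores_csv(system.file("extdata",
         "shc_mutant_relative_scores.csv", package = "terpchannel"),
         lib, mode = "relative")
compare_mutant(rel, mut_enzyme = "1SQC-L607K", channel = "A", lib = lib)
#>   intermediate wt_score mut_score mut_no_pose delta classification
#> 1         A-I1        0      13.9       FALSE  13.9   destabilized
#> 2         A-I2        0        NA        TRUE    NA      abolished
#> 3         A-I3        0        NA        TRUE    NA      abolished
#> 4         A-I4        0        NA        TRUE    NA      abolished
```

The lysine's positive charge repels every cation past A-I1 — the
electrostatic signature of a mutant that aborts the cascade at its first
intermediate.

A command-line wrapper ships in `exec/terpchannel`
(`predict`, `endpoint`, `mutants`, `ssn`, `toydock`, `fixtures`).

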