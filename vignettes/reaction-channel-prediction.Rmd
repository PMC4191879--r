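---
title: "Multi-intermediate docking for triterpenoid synthase specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-intermediate docking for triterpenoid synthase specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(terpchannel)
```

## The model

Class-II terpenoid synthases protonate squalene or 2,3-oxidosqualene and
steer the resulting carbocation through a cascade of cyclizations and
rearrangements. The cascades group into reaction channels — ordered
series of intermediates leading to products that share a carbon
skeleton. This package encodes four: channel A (hopene; four
intermediates ending in the hopanyl cation A-I4), channel B
(lupeol/dammarenyl; B-I1 and B-I2 in the default library), channel C
(lanosterol/protosteryl; nine intermediates), and channel D (the C35
sesquarterpenoid channel, present but disabled for ranking because its
intermediates are too different in size and shape to score on the same
footing as the C30 channels).

Transition states are outside the reach of molecular-mechanics scoring,
so the working hypothesis is thermodynamic surrogacy: an active site that
stabilizes the intermediates of one channel better than those of the
others is predicted to run that channel, and an active site that cannot
stabilize an intermediate at all cannot produce anything downstream of
it. Two structural facts make this workable. First, the I1 and I2
cations are the stereochemical fork between channels: A-I1 and B-I1 are
chemically identical but folded differently (the sign of the
Φ[C16-C17-C18-H18] torsion distinguishes the folds: positive for the
A-like all-chair fold, negative for the B/C-like folds), and the fold is
transmitted down the cascade. Second, docked poses of successive
intermediates must stay mutually consistent, which the docking stage
enforces with an anchor constraint (the cation head near the catalytic
aspartate) and a core restraint (core atoms within 1.0 Å in-place RMSD
of a reference placement).

Scores are binding-energy estimates in kcal/mol, more negative = better.
A failed docking is the distinct state NO_POSE, kept as a logical flag:
NO_POSE orders strictly worse than any number, and the +100 or −10
kcal/mol values that appear in score-profile figures are display
sentinels only (`display_score()`), never ranking inputs.

## The decision rules

**Channel ranking** (`rank_channels`). Round 1 orders the enabled
channels by their rank-1 representative (I1). Channels whose round-1
score lies within `tie_threshold` (default 1.0 kcal/mol) of the round-1
best form a tie group, re-ordered in round 2 by the rank-2
representative (I2); everything else keeps its round-1 order. The two
rounds are equivalent to one lexicographic sort on (tie-bucket
membership, round-2 score inside the bucket / round-1 score outside),
which is the independent oracle the tests compare against. A tie that
survives round 2 is broken by the better round-1 score, then by summed
representative scores, then by library order, and the prediction is
flagged `ambiguous` — the output stays deterministic but announces that
the data did not decide. If every representative is NO_POSE there is no
best channel.

Directionality is fixed as "higher binding affinity = more negative
score" throughout; tables in relative mode (mutant Δ-scores) are refused
by the ranking functions so sentinel or relative arithmetic can never
leak into a channel call.

**Endpoint prediction** (`predict_endpoint`). Along the chosen channel,
the best-scoring intermediate at index ≥ 2 is the putative product
precursor (I1 is the entry cation). Scanning past it, the first
non-binder — NO_POSE, or score above `binder_threshold` — terminates the
cascade at the preceding index, and the products of all later
intermediates are ruled out. `binder_threshold` defaults to 0.0 kcal/mol
(any net-unfavorable score is a non-binder), with NO_POSE always a
non-binder; the threshold is exposed because "non-binder" can also be
read as "weaker than some soft cutoff". The `rise_check_passed` flag
records whether any intermediate after the putative precursor scores
strictly worse (or fails to dock): a profile that improves monotonically
to the channel end carries no termination signal, and such calls should
be treated as failures of the method rather than predictions.

**Mutant classification** (`compare_mutant`). Per intermediate,
Δ = mutant − wild type. `abolished` iff the mutant has no pose;
`destabilized` iff Δ ≥ `destabilization_threshold`. The default
threshold of 5.0 kcal/mol is the smallest round value separating
ordinary re-docking fluctuation (a few kcal/mol either way, as in the
published Y609X rows for A-I1/A-I2/A-I4) from genuine destabilization
(tens of kcal/mol, as for A-I3); it is a classification aid, not a free
energy.

**Evaluation** (`evaluate_predictions`) tallies correct channel calls
per template cluster and in total, and counts how many enzymes of a
product class place their best downstream binder inside an expected
precursor set (e.g. C-I6/C-I7 for lanosterol, C-I7/C-I8 for
cycloartenol — both sets of two because adjacent cations quench to the
same product).

## Parameters at a glance

| parameter | default | unit | role |
|---|---|---|---|
| `tie_threshold` | 1.0 | kcal/mol | round-1 tie group width |
| `binder_threshold` | 0.0 | kcal/mol | non-binder cutoff in endpoint rule |
| `destabilization_threshold` | 5.0 | kcal/mol | mutant Δ classification |
| core restraint tolerance | 1.0 | Å | pose-consistency check (inclusive) |
| torsion refusal band | 1.0 | degree | \|Φ\| near 0/180 has no usable sign |
| SSN threshold | 1e-60 | E-value | network edge cutoff |
| `anchor_max_dist` | 3.0 | Å | cation head to anchor site |
| dielectric | ε(r) = 4r | — | toy Coulomb screening |

## Geometry

`dihedral()` returns the IUPAC-signed torsion on (−180, 180] via the
atan2 formulation. Its true symmetries — unchanged under atom-order
reversal, negated under mirror reflection, invariant under rigid
motion — are asserted as properties against an independent
projection-based formula. `classify_conformer()` refuses to call a fold
when |Φ| is within 1° of 0 or 180°, where the sign is inside coordinate
noise. `rmsd()` is in-place by default because docked poses and a
crystal ligand share the receptor frame; Kabsch superposition (SVD, with
the determinant sign correction) is available where frames differ, and
is cross-checked against a Horn quaternion oracle. Which atoms enter a
reported pose RMSD is a user-supplied correspondence: published pose
RMSDs do not state whether they cover all heavy atoms or the tetracyclic
core only, so the choice is exposed rather than guessed.

## The toy docking stand-in

Production induced-fit docking with QM-derived charges is out of scope;
`dock()` preserves the protocol's *shape* at desk scale: seeded uniform
rigid sampling (Marsaglia quaternions; translations in a box around the
anchor), hard anchor and core constraints, interaction scoring, and a
rigid-body Nelder-Mead refinement of the best survivor mirroring the
minimization stage of induced-fit protocols. Scoring is Lennard-Jones
12-6 plus Coulomb with the distance-dependent dielectric ε(r) = 4r; no
solvation term is included, so the systems are charge-dominated by
design — which is exactly what makes the flipped-anchor control work:
turning the anchor charge to +1 makes every constraint-satisfying pose
net-repulsive, and the docking reports NO_POSE, reproducing the
electrostatic abolition seen when a lysine replaces the anchor-adjacent
leucine. A pose is counted as "passed" only if it satisfies the
geometric constraints *and* scores below `score_cutoff` (default 0):
energetic feasibility is treated as one of the docking constraints, so
NO_POSE coincides exactly with zero passed placements. Magnitudes are
not comparable to real MM/GBSA scores; signs and orderings are.

## Sequence similarity networks

Pairwise local alignment uses Smith–Waterman (BLOSUM62, gap open 11,
extend 1, `X` scored 0) through Biostrings, with significance converted
by the Karlin–Altschul formula using the published ungapped BLOSUM62
parameters (λ = 0.3176, K = 0.134) and E = m·n·2^(−bit) on raw sequence
lengths. These E-values track BLAST's qualitatively but are not
numerically identical (no length correction, ungapped parameters), so
published cutoffs such as 1e−60 or 1e−300 are treated as regimes —
"family-level" vs "channel-segregating" — rather than reproduction
targets, and the cutoff is always a parameter. Thresholding is done in
log10(E) so that astronomically significant pairs, whose E-value
underflows double precision, are still ordered exactly. Unannotated
(grey) nodes are excluded from segregation purity.

## The synthetic generators

`gen_profiles()` plants a known channel per enzyme: the planted
channel's I1/I2 draw `representative_gap` (default 3) kcal/mol better
than the other channels', and the planted channel's full profile follows
the empirical sterol-channel shape — I1 near −80, I2 penalized near −45,
steady improvement from I3 to a precursor minimum near −62 (default
index 6 on channel C), an 8 kcal/mol-per-step rise past it, and NO_POSE
at stated downstream indices (default C-I8). Noise is independent
Gaussian with σ = `noise` (default 1 kcal/mol) — the simplest testable
error model; nothing is known about the true error structure of docking
rescores, so no correlation structure is invented. Under the default
conditions (gap 3, σ 1) two-round ranking recovers the planted channel
in ≈ 99% of enzymes, and exactly 100% in the noiseless limit.

`gen_sequences()` targets pairwise identities by seeded point mutation
without indels (members mutate a family ancestor at a rate of
1 − sqrt(within/100), ancestors mutate a common root at
1 − sqrt(between/100)), which keeps realized within-family identity
inside about ±2 points of the target. `gen_toy_complex()` builds a
pocket of complementary Lennard-Jones sites around a 4-bead cation and
then relaxes the ligand to the pocket's actual local optimum, so the
planted pose is a genuine score minimum, not merely the construction
origin. All generators are bit-reproducible given their seed.

What passing these tests shows — and does not. Synthetic profiles have
independent noise and a clean planted signal; real docking scores have
systematic, structure-correlated errors, and reported channel-prediction
accuracy on real homology models (on the order of 80%) is far below the
≈ 99% planted-recovery rate. The synthetic results validate
the *decision rules*, not docking accuracy.

## Numerical choices and degenerate inputs

Ties everywhere break toward library (mechanistic) order, keeping every
output deterministic. The core-restraint check is inclusive at its
tolerance. CSV writers print the shortest decimal that reparses to the
identical double, so write/read round-trips are exact and reruns are
byte-identical. Degenerate geometry (coincident or collinear torsion
points), empty sequences, empty correspondences, unknown ids, duplicate
keys and mixed score modes are all hard errors rather than silent
coercions.

## Problem sizes

The shipped tests and the acceptance script use: 10,000 random
representative tables against the ranking oracle; 1,000 simulated
enzymes for planted-channel recovery (plus 200 noiseless); 1,000 random
profiles against the endpoint scan oracle; 1,000 random quadruples for
the torsion oracle at 1e−9°; short-sequence alignment oracles on
lengths ≤ 8; 12-sequence planted families for the network checks; and
12,000 rigid samples for toy-dock recovery. These sizes make the whole
suite run in a few minutes on one core while keeping every statistical
margin wide (the recovery property sits ≈ 4 percentage points above its
95% bound).

## Known limitations

The channel library covers the naturally occurring channels only;
automatic enumeration of all carbocation rearrangements is out of scope.
Channel B beyond B-I2 is configurable through the channel-definition
file rather than shipped, since the canonical intermediate list past the
dammarenyl cation varies by source. Quantitative product distributions
and the final deprotonation/hydration chemistry are explicitly not
modeled; the method's outputs are channel calls, precursor candidates
and exclusions. The product-to-precursor index maps each product to a
single primary precursor (lanosterol to C-I6), with adjacent-precursor
sets used where two cations quench to the same product.
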