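---
title: "Assessing predicted residue-residue contacts: models, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing predicted residue-residue contacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contacteval)
```

## The problem

A contact predictor emits a ranked list of residue pairs it believes to be
spatially close in the folded protein. Whether such a list is good enough
to fold the protein, and which of several lists to trust, are the two
questions this package answers. The first needs a solved native structure;
the second does not.

## Contact model

A *contact* is a residue pair whose representative atoms are closer than a
threshold `d`, with sequence separation `j - i` at least `min_sep`. The
defaults follow the CASP convention — Cβ atoms (Cα for glycine), `d` = 8 Å,
`min_sep` = 6 — and every piece is tunable through `contact_definition()`:
reconstruction studies variously favour Cα at 7 Å or Cβ at 9 Å and more, so
the thresholds are parameters, not constants. The inequality at `d` is
strict: a pair at exactly 8 Å is not a contact. Separation classes default
to short [6, 11], medium [12, 23] and long [24, ∞); only the minimum of 6
and the long-range boundary above 23 are fixed by convention, the interior
split is a configurable default.

`L` is the chain length that scales the selection groups. When a native
structure is supplied, `L` is its residue count; otherwise the length of
the sequence in the RR file; as a last resort (with a warning) the largest
residue index observed.

## Evaluation pipeline

Contacts are sorted by confidence (ties broken by `(i, j)` ascending, which
makes every downstream selection deterministic), filtered to the requested
separation range, and — when a native structure is present — stripped of
pairs touching residues the structure does not resolve, with the removed
count reported. The six conventional selections top-5, L/10, L/5, L/2, L
and 2L are then scored. Fractional group sizes use floor with a minimum of
1: rounding is not fixed by convention, and this choice never yields an
empty selection.

Residue correspondence between an RR file and a structure is decided once,
before filtering: if the RR file carries a sequence identical to the
structure's, RR index k denotes the structure's k-th residue; otherwise RR
indices are read as author residue numbers (a warning is raised when a
supplied sequence disagrees). This is the simplest rule that handles both
full-chain evaluations and CASP-style domain evaluations, where the domain
PDB covers only part of the predicted sequence.

## Measures

*Reduced-list* measures score one selection:

- precision TP/(TP+FP) and coverage TP/N_c, with N_c the native-contact
  count of the evaluated range;
- mean false-positive error, the mean of `d_ij - d` over wrong predictions
  (`d_ij` their native distance). With no false positives it is reported as
  `NA`, never 0 — averaging across proteins must be able to skip it, and 0
  would mean "wrong by zero Å", the opposite of "nothing wrong";
- X_d, a 15-term sum comparing the binned native distances of the predicted
  pairs (PiP) against a reference distribution (PiA) over 4-Å bins spanning
  0–60 Å (distances beyond 60 Å clamp into the last bin; bins are
  half-open `(lo, hi]`), each term weighted by the bin's upper limit
  normalized to 60, times 15;
- spread, the mean Euclidean distance in contact-map index space from each
  native contact to its nearest prediction — 0 exactly when the prediction
  covers every native contact.

*Full-list* measures use the whole filtered list over the candidate-pair
universe (all in-range pairs among resolved residues): MCC with predicted
positives defined by confidence > 0.5 (strictly; a degenerate denominator
factor yields MCC = 0), and ROC / precision–recall curves in which
unlisted universe pairs score 0 — an RR file ranks a subset, and the curve
sweep needs a total order. Tied scores are processed as one threshold
group; ROC area uses the trapezoid rule, PR area holds each threshold's
precision across the recall it gains (so a single positive ranked last in
a universe of ten gives AUC_PR = 0.1).

### The X_d reference distribution

The implemented default builds PiA from the native-contact distances, so
PiA is zero in every bin above 8 Å. Under this convention a *perfect*
prediction scores exactly 0 and imperfect ones score negative — the score
measures departure from the native contact-distance profile. The
historical CASP variant instead takes PiA from *all* candidate pairs,
whose mass sits at large distances; against that reference a good
prediction scores large and positive (tens) and a random one near 0.
`xd_reference = "all_pairs"` in `evaluate_contacts()` selects that
variant; both use the identical 15-term machinery, and the choice is
reported with the results. The default follows the stricter reading of the
contact-distribution reference; users comparing against published CASP
numbers should switch to `"all_pairs"`.

## Similarity without a native structure

Two prediction sets are compared by Jaccard similarity
J = M / (|A| + |B| − M), where M counts shared contacts. With relaxation
N > 0, a pair of A and a pair of B count as the same contact when both
indices differ by at most N (3–15 and 3–16 match at N = 1). Counting
relaxed matches greedily is order-dependent, so M is defined as the size
of a maximum-cardinality bipartite matching on the compatibility graph:
deterministic, symmetric, an upper bound on any greedy count, and equal to
plain set intersection at N = 0. Defining the union as |A|+|B|−M keeps
J ≤ 1 under relaxation. J is monotone non-decreasing in N (the graph only
gains edges). A caution inherited from practice: at N ≥ 2 in helical
proteins, register shifts of two residues can look "similar" while being
structurally wrong; the relaxation level is always printed with the
matrix.

Sets are truncated to a common selection before comparison (top-L/5 of
the chosen range by default, configurable) so that differently sized
submissions are compared on equal footing. Similarity matrices are
clustered by average linkage on 1 − J; merge ties resolve in label order,
which makes heatmap/dendrogram output reproducible.

## Visualization and export

Every plot writes a tab-separated sidecar of its plotted coordinates and
returns the same table invisibly, so tests (and users) can assert on data
rather than pixels. Contact maps draw the native contacts in gray in both
triangles with each prediction overlaid; chord diagrams place residue 1
at angle 0 counter-clockwise, one chord per contact, leaving untouched
arcs visible (a chain segment with no predicted contacts — e.g. a
disordered terminus — shows as a bare arc). Coordination-number profiles
report per-residue contact participation plus totals; the per-set sum is
always twice the contact count (handshake identity).

Chimera scripts emit one `distance` command per contact between the
stored representative atoms, addressed by chain and author residue
number. Correct contacts are drawn first and colored as pseudobonds;
incorrect ones are drawn after the color command, so they keep the
default distance-monitor line and label and the violated distance is
visible in the viewer. Classic Chimera syntax is the default with a
ChimeraX dialect behind a flag. Script generation is deterministic:
identical inputs give byte-identical files.

## Synthetic data: what it emulates and what it does not

The generator produces chains with one representative atom per residue at
3.8 Å consecutive spacing:

- *compact*: a self-avoiding random walk (non-neighbor atoms at least
  3.5 Å apart) confined to a sphere whose radius grows linearly with L
  (calibrated for L between 10 and ~100); generation restarts with
  advancing sub-seeds until the chain closes and, for L ≥ 30, carries at
  least L/2 long-range native contacts — below L = 30 too few pairs reach
  separation 24 for that guarantee to be meaningful;
- *helix*: ideal α-helix geometry (2.3 Å radius, 1.5 Å rise, 100°/residue)
  — short-range contacts only;
- *extended*: a straight chain — no contacts beyond nearest neighbors.

Predictions with planted precision p draw ⌈pn⌉ contacts from the native
set and the rest from non-contact pairs, with confidences Uniform(0.5, 1)
for true contacts and Uniform(0, 0.7) for decoys. The overlap is
deliberate: a separable confidence model would make every ranking metric
trivially perfect and the ROC/PR tests vacuous.

What passing tests on this data shows: the bookkeeping, formulas,
filtering, ranking and file round trips are correct, at the contact
densities and chain lengths stated. What it does not show: behavior on
real protein geometry (no secondary-structure contact patterns, no
side-chain packing, single chain only), on NMR multi-model files beyond
model 1, or on mmCIF input (unsupported).

## Numerical and degenerate-input conventions

- Undefined results are `NA` with a documented meaning, never silent 0:
  mean FP error with no false positives, spread with an empty prediction
  or empty native set, X_d with an empty predicted histogram, Jaccard of
  two empty sets, ROC/PR with a one-class universe.
- Duplicate RR pairs collapse to the higher confidence; (j, i) and (i, j)
  are the same pair.
- Confidences outside [0, 1] are accepted with a warning and used only
  for ranking; the MCC cut stays at 0.5 as printed.
- Alternate-location atoms: highest occupancy wins, ties to the first
  record; residues with no representative atom are dropped (never
  silently given coordinates).
- All randomness flows through explicit integer seeds; regeneration with
  the same seed is bit-identical.

## Problem sizes used in the test suite

The suite exercises chains of L = 30–80 with 100-instance oracle sweeps,
1,000 random set pairs for the similarity properties, and 30-seed
parameter-recovery runs at planted precisions 0.2 / 0.5 / 0.8 (top-L/5
sized sets; the 2L-sized mixed set at p = 0.25 for full-list measures
keeps the planted true contacts within the generator's guaranteed native
budget). The acceptance script's benchmark uses a single L = 80 compact
chain. These sizes were chosen as the smallest at which every property
under test is non-degenerate.

## Known limitations

- Inter-chain contacts and heavy-atom minimum-distance definitions are out
  of scope; one representative atom per residue.
- Insertion-code residues are kept in file order and consume the next
  position; author-number lookup uses the first match, so heavily
  insertion-coded chains are better evaluated via the sequence-matching
  path.
- The relaxed-match definition (maximum matching) can differ from older
  greedy implementations by design; it is the order-independent choice.
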