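# contacteval

Assessment and comparison of predicted protein residue–residue contacts.

Predicted contacts drive contact-guided ab initio structure prediction:
when the top-ranked predicted pairs are truly close in the native fold, model
building recovers the fold. This package is for people who develop or use
contact predictors and need to (a) score a prediction (or several) against
a solved structure, and (b) compare predictions against each other when no
structure exists yet.

## What it computes

A contact follows the CASP convention: residues separated by at least 6
positions whose representative atoms (Cβ; Cα for glycine) are closer than
8 Å, all configurable via `contact_definition()`. Separation classes are
short [6, 11], medium [12, 23], long [24, ∞).

Against a native structure (PDB), for each of the standard selections
top-5, L/10, L/5, L/2, L, 2L of the confidence-sorted, range-filtered,
native-filtered list:

- **precision** = TP / (TP + FP), **coverage** = TP / N_c;
- **mean false-positive error** = (1/FP) Σ (d_ij − d), the mean native
  distance excess of wrong predictions over the threshold d;
- **X_d** = Σ_{i=1..15} (PiP_i − PiA_i) / (d_i · 15): the difference
  between the binned native-distance distribution of the predicted pairs
  (PiP) and a reference distribution (PiA), over 15 four-Å bins spanning
  0–60 Å with d_i the bin's upper limit normalized to 60;
- **spread** = (1/N_c) Σ_T min_P ‖T − P‖: mean contact-map distance from
  each native contact to its nearest prediction;

and on the full list: **MCC** over the candidate-pair universe (positives
= confidence > 0.5), **ROC** and **precision–recall** curves with areas.

Without a structure: per-range contact counts, per-residue coordination
numbers, contact maps, chord diagrams, and the **Jaccard similarity**
J_AB = |A∩B| / |A∪B| between prediction sets, optionally relaxed so pairs
within ±N residues (N = 0..3) count as the same contact (the intersection
is a maximum one-to-one matching, so J is symmetric and ≤ 1). Similarity
matrices come with average-linkage clustering for heatmap/dendrogram
display, and every evaluated selection can be exported as a UCSF Chimera
command script that draws the contacts on the structure, correct and
incorrect ones styled differently.

A synthetic-data generator (`make_structure()`, `make_predictions()`,
`make_instance()`) builds compact / helical / extended chains and
prediction sets with planted precision, so the whole pipeline runs and is
tested without any external data.

## Worked example

```r
library(contacteval)
inst <- make_instance(L = 60, p = c(0.7, 0.3), n_contacts = 30, seed = 11)
ev <- evaluate_contacts(inst$predictions, inst$structure, range = "long")
summary(ev)
```

```
Contact evaluation over 666 candidate pairs (Nc = 129)

    source group   k n_evaluated TP FP precision coverage mean_fp_error      xd spread
 set1_p0.7 top-5   5           5  5  0     1.000    0.039            NA  -4.651  4.574
 set1_p0.7  L/10   6           6  6  0     1.000    0.047            NA  -4.651  3.769
 set1_p0.7   L/5  12          12 10  2     0.833    0.078         2.892  -3.262  2.467
 set1_p0.7   L/2  30          30 21  9     0.700    0.163         4.428  -9.429  1.555
 ...
Full-list measures (positives: confidence > 0.5):
    source   MCC AUC_ROC AUC_PR
 set1_p0.7 0.313   0.574  0.307
 set2_p0.3 0.156   0.517  0.242
```

The 60-residue compact chain has 129 long-range native contacts among 666
candidate pairs. The planted-0.7 set keeps precision 1.0 in its top-5
(its true contacts rank highest), 0.70 over all 30 contacts; its top-5
contains no false positives, so the mean FP error is undefined (`NA`)
there rather than 0. Spread falls as more contacts are selected because
every native contact finds a nearer prediction.

```r
cmp <- compare_contacts(inst$predictions, N = 0:1, L = 60, range = "long", top = "all")
cmp$similarity$N1
#           set1_p0.7 set2_p0.3
# set1_p0.7     1.000     0.154
# set2_p0.3     0.154     1.000
```

`write_report(ev, "report/")` writes the metric tables, curve tables,
plots with data sidecars, and one Chimera script per source and selection
group. A command-line wrapper with `evaluate`, `compare`, `structure` and
`fixtures` modes lives at `system.file("cli", "contacteval.R", package =
"contacteval")`.

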