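---
title: "TCR fingerprinting: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TCR fingerprinting: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrfingerprint)
```

## The problem

Engineered, affinity-enhanced T-cell receptors (TCRs) used in adoptive cell
therapy can recognize self-peptides other than their intended tumor antigen,
with potentially lethal consequences. Given a TCR of interest — the running
example throughout this package is a receptor recognizing the NY-ESO-1
peptide SLLMWITQC presented by HLA-A\*02:01 — the task is to rank all
MHC-binding 9-mer peptides of a proteome by how likely the TCR is to
recognize them, so candidate off-targets can be tested before a clinical
trial rather than discovered during one.

The package implements the replacement-scan ("TCR fingerprint") approach:
measure how every single-residue substitution of the epitope changes TCR
binding, T-cell activation and target killing; summarize those measurements
as position weight matrices; project the matrices onto the peptide universe;
and calibrate a score cutoff against activation outcomes.

## The model

### Fingerprint construction

The scanned epitope is a $k$-mer (default the anchor-optimized 9-mer
SLLMWITQV; position 9 carries valine rather than the wild-type cysteine to
strengthen MHC binding). Anchor positions (P2 and P9 for HLA-A\*02:01) face
the MHC groove, not the TCR; they are held fixed in the scan and excluded
throughout. The replacement library is the epitope plus each of the 19
alternative residues at each of the $|P|$ non-anchor positions —
$19\,|P| + 1$ peptides, i.e. 134 for the 9-mer/2-anchor design.

Each library peptide is measured in up to three assays (binding,
activation, killing) in several replicates, as percent positive cells, each
replicate with a matched no-peptide background. For the variant carrying
residue $a$ at position $i$,

$$W_{a,i} = 100 \cdot \frac{L_{a,i}}{L_{\mathrm{epitope}}},$$

where $L$ is the mean over replicates of the *background-corrected* signal
— the subtraction happens per replicate, before averaging, because the
background is a property of the replicate, not of the assay. Values above
100 are trimmed to 100 and negative values set to 0, so every cell lies on
a 0–100 percent scale; the epitope's own residue at each scored position is
pinned at 100 by construction. `build_pwm()` implements exactly this;
clamping is applied to $W$ after normalization, never to raw replicates.

Anchor columns are not stored in the matrix at all. Since scoring never
consults them, storing them would only invite accidental use.

### Scoring

A query peptide of the same length scores

$$S_{\mathrm{seq}} = \frac{\sum_{i \in P} W_{l_i,\,i}}{100\,|P|},$$

with $l_i$ its residue at position $i$. The denominator is the theoretical
maximum — which equals the epitope's own score because epitope cells are
pinned at 100. We deliberately use the theoretical form rather than the
epitope's realized sum so that alanine-scan matrices, whose construction
also pins the epitope at 100, normalize identically. Scores therefore lie
in $[0, 1]$, the epitope scores exactly 1, and substituting a residue for
one of strictly greater weight can never lower a score.

The overall TCR recognition score of a peptide is the arithmetic mean of
its three per-assay scores (`predict()` on a `tcr_fingerprint`,
`combine_scores()`). Averaging happens on peptide scores, not on the
matrices, matching the order of operations of the screening procedure.
First-order additivity across positions is the central modelling
assumption: no epistasis between substitutions is represented.

### Screening

`enumerate_kmers()` slides a 9-residue window across every protein,
skipping windows with non-canonical letters and deduplicating at the
sequence level (a peptide's score depends only on its sequence); provenance
keeps every source protein, gene and 1-based start. Candidates are then
restricted to predicted MHC binders — IC50 at most 500 nM, boundary
inclusive, from a precomputed affinity table; peptides with no prediction
are excluded rather than assumed to bind, because the screening universe is
defined as the predicted-binder set. Candidates are ranked by combined
score with lexicographic tie-breaks for full determinism. For motif
inspection, `bin_motifs()` splits the scored universe into five groups
(default edges 0.25, 0.40, 0.55, 0.70, 0.85, 1.00; intervals half-open,
last closed) and builds per-position residue frequency matrices over the
full peptide length, anchors included — in the top bin the recognition
motif emerges, in low bins only the binder anchor preference.

### Classification

Activation outcomes are binarized at 75% of the normalized epitope signal
(strict inequality). `roc_curve()` sweeps "positive iff score ≥ threshold"
over realized scores; the AUC is the ties-aware Mann–Whitney concordance.
`select_cutoff()` implements the max-sensitivity policy: among thresholds
with sensitivity 1 (one always exists, at or below the lowest positive
score), pick the most specific, breaking remaining ties toward the largest
threshold. The positive call is boundary-inclusive (`score ≥ cutoff`) so
the sensitivity guarantee is achieved at a realized score. Under label
noise the max-sensitivity cutoff necessarily chases the lowest-scoring
mislabelled peptide — that is a property of the policy, not a defect of the
implementation; the AUC degrades gracefully instead.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `anchors` | 2, 9 | MHC-groove positions excluded from scan and score |
| `ic50_max_nm` | 500 nM | inclusive predicted-binder cutoff |
| `activation_threshold` | 0.75 | activating/non-activating split (strict >) |
| `bin_edges` | 0.25…1.00 | five motif score groups |
| `permissive_threshold` | 0.5 | alanine-scan "successful substitution" level |
| `tpm_threshold` | 10 TPM | tissue counted as expressing a source gene |
| `hamming_reference` | epitope | reference for reported edit distances |

All of these are explicit configuration (`pipeline_config()`), never
hard-coded in logic. Two that deserve comment:

* **`permissive_threshold`** — the alanine-scan adaptation declares a
  position permissive when the alanine variant retains at least this
  fraction of the epitope signal; permissive positions then accept any
  residue at weight 100. No quantitative definition of "successful
  substitution" is standard, so the threshold is an exposed parameter with
  a conservative default of half the epitope signal rather than a buried
  constant.
* **`hamming_reference`** — edit distances are reported against the
  wild-type peptide (SLLMWITQC for NY-ESO-1), which differs from the
  scanned, anchor-optimized epitope (SLLMWITQV). The two are independent
  configuration fields for exactly this reason.

PWM similarity (`pwm_similarity()`) is the plain Pearson correlation over
the flattened 20 × $|P|$ cell vectors. Published PWM-comparison variants
exist that reweight cells; we use the unmodified coefficient because it is
reproducible without auxiliary choices and the quantity is only used
descriptively (inter-assay concordance).

## The synthetic-data generator

`synthetic_scenario()` fixes the study conditions; every generator output
is a pure function of the scenario and its seed (default 20191022).

* **Kernel** (`make_kernel()`): epitope residues at 100; at critical
  positions (default P5 and P8, where the fingerprint of the NY-ESO-1
  receptor concentrates — the tryptophan/glutamine pair) all other
  residues ≤ 10; at tolerant positions residues draw uniformly from
  [10, 100].
* **Measurements** (`simulate_measurements()`): true read-out
  `background + epitope_signal · W/100` with mean-one multiplicative
  lognormal replicate noise. Noise is multiplicative because the read-outs
  are strictly positive percentages with right-skewed error; the default
  10% CV and 3 replicates reflect typical flow-cytometry assay precision,
  and the ~2% background exercises the per-replicate subtraction
  nontrivially. With zero noise, `build_pwm()` inverts the generator
  exactly (a property the tests assert).
* **Proteome** (`simulate_proteome()`): 2,000 uniform-composition proteins
  of 300 residues (~584,000 windows — large enough that decoys dominate by
  four orders of magnitude, small enough to screen in well under a minute);
  10 planted cross-reactive peptides (the epitope plus variants
  substituting 1–3 tolerant positions with residues of kernel weight
  ≥ 90), embedded at recorded positions.
* **Affinity** (`simulate_affinity()`): binders (L/M at P2 and V/L/C at
  P9, the anchor preference of the allele) draw IC50 log-uniformly in
  (1, 500]; everything else in (500, 50000]. Values are assigned in sorted
  peptide order, so the map is invariant to enumeration order. Planted
  peptides never touch anchors and hence always pass the filter.
* **Outcomes** (`simulate_outcomes()`): activation high (0.85–1.2) for
  peptides at or above the true cutoff (default 0.9, inside the gap between
  planted and decoy scores), low (0–0.35) otherwise, with optional label
  flips.

What the generator does *not* emulate: realistic flow-cytometry
distributions, position-dependent amino-acid composition of real proteomes,
length polymorphism (8/10-mers), true HLA binding energetics, or correlated
assay-specific biases between binding, activation and killing (all three
assays share one kernel, differing only in noise). Passing tests therefore
demonstrate that the estimator inverts its own data-generating model and
that the pipeline's plumbing, ordering and thresholds behave as specified —
not that the method's experimental accuracy on real scans is reproduced,
which would require the original raw assay data.

## Numerical and degenerate-input choices

* An epitope whose background-corrected mean is ≤ 0 cannot normalize
  anything; `build_pwm()` raises a degenerate-normalization error rather
  than returning infinities.
* A complete scan covers all 19 substitutions per position; unmeasured
  cells are imputed as 0 (unmeasured ⇒ treated as not recognized) with a
  warning, or rejected outright with `on_missing = "error"`. Imputing 0 is
  conservative for off-target screening: it can only depress scores.
* Peptides containing B/J/O/U/X/Z are never scored; enumeration skips and
  counts them.
* Ranking ties break lexicographically; ROC thresholds are realized scores
  (plus a sentinel), so the selected cutoff is always an achievable score.
* PWM serialization keeps 15 significant digits; round-trips are exact to
  at least 12.

## Worked example

```{r example, eval = FALSE}
sc <- synthetic_scenario()          # the default study conditions
kern <- make_kernel(sc)             # ground-truth recognition kernel
ms <- simulate_measurements(kern, sc)
fp <- tcr_fingerprint(ms, sc$epitope, sc$anchors)
summary(fp)                         # inter-assay PWM concordance

res <- run_pipeline(pipeline_config(scenario = sc), tempdir())
res                                 # stage counts, AUC, selected cutoff
head(res$ranked)                    # planted peptides at the top
```

The default test suite runs the full 2,000 × 300 scenario once; unit tests
use reduced proteomes (120–150 proteins) where the full size adds nothing
to the property under test.

## Known limitations

* First-order additivity: multi-substitution epistasis is not modelled, so
  peptides recognized through compensatory substitution pairs can be
  mis-scored. This is inherent to the PWM representation.
* Only epitope-length peptides are scored; no indel (Levenshtein)
  distances, no 8/10-mer scanning.
* The affinity filter is only as good as the upstream predictor whose
  table is supplied; peptides missing from the table are dropped.
* The max-sensitivity cutoff is calibrated on the peptides actually tested
  for activation; it is not a population-calibrated probability.
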