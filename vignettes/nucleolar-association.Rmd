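---
title: "Classifying degrees of nucleolar association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying degrees of nucleolar association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoclass)
```

## The problem

The nucleolus has no membrane, and much of its proteome is in flux:
proteins cycle between the nucleolus and the nucleoplasm, travel to the
nucleolus for assembly into ribonucleoprotein complexes before returning to
the cytoplasm, or relocate there only under stress. `nucleoclass` models
this fluidity by predicting one of four *degrees* of nucleolar association
— nucleolar-enriched, nucleolar-nucleoplasmic, nucleolar-cytoplasmic, or
non-nucleolar — rather than a binary nucleolar/not label. The four labels
carry a fixed precedence order (`nucleolar_classes()`) used solely for
deterministic tie-breaking.

## The model

Each protein is described by eight discretized feature channels derived
from five data sources, and the channels are combined by a semi-naive
Bayes rule.

**Training.** For every channel, proteins of each class are counted per
bin; a pseudocount $\alpha = 0.1$ is added to every (bin, class) cell, and
the counts in each bin are divided by the pseudocounted bin total over all
four classes. Each bin row therefore holds the *class proportions among
proteins falling in that bin* — a posterior-flavoured quantity, not a
class-conditional likelihood. We implement this normalization literally
rather than "correcting" it to textbook naive Bayes, and the consequences
matter for interpretation: a channel that is constant across all proteins
still contributes each class's corpus frequency once per channel, so the
effective weight of the class imbalance grows with the number of
channels. Pseudocounts guarantee strictly positive entries, hence finite
scores and a finite reliability index.

**Scoring.** The score of class $c$ is the prior $\pi_c$ (defaults
$0.2/0.15/0.15/0.5$) times the product over observed channels of the bin
entry for $c$. Channels whose input is missing (no expression profile, no
annotated interactor) are skipped entirely — the "missing contributes
nothing" policy — instead of occupying an extra bin, so bin counts stay
exactly as published. Scores are accumulated in log space and
exponentiated to avoid underflow; raw products are reported (no
renormalization across classes), which is inconsequential for the label
and for the reliability index since both are scale-invariant.

**Reliability index.** The ratio of the highest to the second-highest
class score; 1 under an exact tie, with ties broken by class precedence.

## The channels and their parameters

* *Amino-acid frequencies* of S, L, I, K: residue count over sequence
  length, 5 bins each (4 for lysine).
* *Targeting motifs*: consumed as upstream predictor outputs
  (signal-peptide flag, TMD count, mitochondrial-peptide flag, maximum
  NoLS score in $[0,1]$). The NoLS score discretizes at 0.8 and 0.9; a
  missing NoLS value means "no predicted NoLS" and maps to 0. The nine
  targeting bins are $3 s_C + s_N$.
* *Co-expression*: mean Pearson correlation with the nucleolar-cytoplasmic
  training group across tissues, the query excluded from its own reference
  set; zero-variance profiles yield a missing channel. Four bins.
* *GO scores*: $g_c = \frac{1}{|T_p|}\sum_{t \in T_p} n_{ct}/n_t$ over the
  protein's biological-process and molecular-function terms pooled into one
  set (the two namespaces are used jointly; nothing in the scoring needs
  them separated). Bin = arg-max class, or bin 3 when every $g_c$ falls
  below the operating threshold 0.003 or the protein has no usable term.
* *NPI*: compartment annotations map to nucleolar proximity distances
  (nucleolus 0.0; nucleoplasm/speckles/pore/envelope 1.2; cytosol,
  cytoplasmic organelles, plasma membrane, extracellular 3.0; bare
  "nuclear" 0.8 — it cannot distinguish nucleolar from non-nucleolar
  nuclear proteins). A partner's proximity is the mean over its
  compartments; the channel is the mean over partners; 5 bins. The
  vocabulary-to-distance table is an editable data frame
  (`localisation_distances()`), since compartment vocabularies are listed
  by example in practice, never exhaustively.

## Binning calibration

Bin thresholds for the continuous channels are not universal constants:
they are operating points chosen on a training corpus. The package
distinguishes two calibration rules, following how each channel's bins are
traditionally defined:

* **Equal-frequency** (`equal_frequency_thresholds()`) for co-expression:
  bins hold roughly (within 20%) the same number of proteins.
* **Balanced class error** (`class_error_thresholds()`) for the amino-acid
  and NPI channels: all combinations of thresholds from a candidate
  quantile grid are scored by the average per-class error of the
  single-channel bin classifier, and the best combination wins. This
  mirrors the practice of manually selecting proximity-score thresholds to
  minimise average class error. The distinction is not cosmetic: under the
  per-bin-proportion scoring rule a 200-protein negative class occupies
  ~72% of every quantile-defined bin, so equal-frequency thresholds make
  most channels vote for the majority class regardless of the query.

`binning_config()` ships thresholds frozen from one calibration on the
default synthetic reference cohort (high separation, seed 42);
`calibrate_binning()` re-derives them for any labelled cohort and is what
`loocv()` uses when no configuration is passed. The GO threshold 0.003 is
an operating point, not a quantile, and is carried through unchanged.

Bins are half-open $[t_i, t_{i+1})$ with the last bin closed above; a
value exactly at a threshold resolves upward.

## Evaluation protocol

`loocv()` holds each labelled protein out in turn and retrains on the
rest. Three reference structures are rebuilt per fold without the held-out
protein: every training protein's interactor set (so a training protein
whose only partner is the test protein has a missing NPI channel in that
fold), the GO class counts, and the co-expression reference group. The
first exclusion is the critical leakage guard — interaction edges are the
one feature that directly ties a test protein to training proteins. The
GO/co-expression hold-out is the conservative reading of the protocol and
is test-pinned.

`evaluate_independent()` scores a disjoint test set against a fitted
model and refuses any overlap with the training manifest.
`multirun_evaluate()` repeats either protocol over negative sets resampled
with per-run seeds, sharing the three nucleolar groups, and reports means
with run-to-run standard deviations ($n-1$ denominator; 0 for a single
run). Metrics with zero denominators are reported as `NA`, never 0, so
they cannot silently deflate or inflate averages.

`reliability_sweep()` re-scores predictions at increasing minimum
reliability indices; coverage is non-increasing by construction. The GO
term census (`term_census()`) uses a strict inequality (RI > 10 by
default) so proteins at exactly the cut-off are excluded; the choice is
exposed via `strict = FALSE`.

## SILAC mapping

Dual abundance ratios (nucleolar/cytoplasmic, nucleoplasmic/cytoplasmic)
are thresholded in log2 space — ratios are multiplicative, so symmetric
enrichment and depletion should be symmetric on the scale — using one
axis-aligned rectangle per class with closed edges; points outside every
rectangle are `UNDEFINED`. Because the original operating thresholds are
a data-set-specific artifact, `calibrate_regions()` documents a
reproducible replacement for the manual step: per class, the bounding box
of the labelled overlap proteins expanded by a 0.5 log2-unit margin, with
overlapping boxes shrunk to the midline between their nearest conflicting
edges (an epsilon of 1e-9 keeps closed edges disjoint). Calibration
proteins are flagged and excluded from downstream agreement scoring, as
are `UNDEFINED` proteins.

## Sequence redundancy

`pairwise_identity()` computes whole-sequence identity as identical
columns over alignment columns of a global alignment (match 1, mismatch 0,
linear gap −1) — the simplest whole-sequence reading; scoring parameters
and the 25% threshold are arguments. Non-standard residues (X, U, B)
count toward alignment length but never as identities.
`redundancy_filter()` applies a greedy keep-first sweep in input order,
which is deterministic and order-documented.

## The synthetic cohort generator

`cohort_spec()` / `simulate_cohort()` draw complete cohorts — sequences,
targeting-predictor outputs, GO annotations, expression, interactions,
localisation annotations, SILAC ratios, orthology — with class-conditional
structure. Class sizes default to 30/22/24/200, the sizes of the curated
training groups plus the standard resampled negative set; expression uses
79 tissues, the size of the canonical normal-tissue panel.

Design choices worth knowing:

* Co-expression is modelled as a per-class template plus independent
  Gaussian noise, which realizes exactly the "correlation with the
  nucleolar-cytoplasmic group" feature: members of that class correlate
  strongly with each other and negligibly with anyone else.
* Localisation labels are drawn from class-typical pools and corrupted at
  rate 0.1, so the NPI channel is informative but imperfect and the
  pseudocounts are genuinely exercised.
* The `separation` preset scales every between-class contrast toward the
  pooled mean (factors 1 / 0.6 / 0.25 for high / medium / low). The
  *high* preset is an idealised, strongly separated regime: disjoint
  per-class GO term pools, amino-acid composition shifts of 2–4 standard
  errors on the tracked residues, dense within-class interactions (edge
  probability 0.30 within vs 0.005 between), distinct NoLS score
  distributions (Beta means 0.85/0.60/0.60 for the nucleolar classes vs
  0.12 for the background) and a background rich in secretory/membrane/
  mitochondrial targeting. It is the regime in which the classifier should
  recover essentially every parameter; *medium* and *low* probe graceful
  degradation.
* SILAC ratios are log-normal in log2 space with class-specific means
  (e.g. nucleolar-enriched proteins high on the nucleolar/cytoplasmic
  axis, low on the nucleoplasmic/cytoplasmic axis) and SD 0.6.

What the generator does **not** emulate: real amino-acid composition of
human proteins (compositions are stylised contrasts), identifier
semantics, the scale and sparsity of real interaction networks, GO's
hierarchical correlation structure among annotations, or batch effects in
expression data. Passing the recovery tests therefore demonstrates that
the implementation is faithful and the pipeline wiring is correct — not
that these accuracies would be attained on real proteomes, where the
corresponding published accuracies are substantially lower.

## Problem sizes

The test suite and the acceptance script run leave-one-out
cross-validation on the three 276-protein reference cohorts (a few seconds
each), oracle comparisons on 200 random instances per formula, ten-run
evaluations on an 86-protein cohort, and bootstrap standard deviations
with 10,000 resamples (the bootstrap depth is an argument; millions of
resamples are reachable when wanted). These sizes were chosen as
desk-scale defaults that keep every check comfortably interactive.

## Known limitations

* The classifier consumes upstream predictor outputs (signal peptides,
  TMDs, mitochondrial peptides, NoLS scores) and curated annotation
  tables as files; it does not run those predictors.
* The per-bin-proportion scoring rule entangles class priors with every
  channel, as discussed above; with many uninformative channels the
  majority class is favoured more strongly than a textbook naive Bayes
  would.
* Whether the original aa/NPI thresholds, GO class counts, or
  co-expression references excluded the held-out protein during
  cross-validation is not fully specified anywhere; our choices (fixed
  thresholds per corpus, hold-out everywhere else) are documented and
  pinned by tests.
* Rectangular SILAC regions cannot represent non-axis-aligned class
  boundaries; they are the simplest shape consistent with per-axis
  thresholds.
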