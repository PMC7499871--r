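---
title: "Methods: paired tumor/metastasis panel CNV and actionability analysis"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`pairedpanel` analyses matched primary-tumor (PT) and bone-metastasis (BM)
biopsies sequenced on a barcoded hybrid-capture panel of cancer genes,
together with a matched normal (blood) sample. The pipeline runs, per
patient:

1. **Molecule processing** — read records are filtered at MAPQ ≥ 20 and
   collapsed to unique molecules on the key (barcode, chromosome, start,
   stop); per-target unique-molecule counts and average depth of coverage
   (DoC) follow.
2. **Normalization** — each sample separately: LOESS regression of depth on
   target GC fraction, applied multiplicatively so relative depths are
   GC-flat while the global mean is preserved, then RPKM scaling
   (`count * 1e9 / (target_length * total_count)`).
3. **Segmentation** — per-target `log2(tumor/normal)` ratios, segmented by
   circular binary segmentation (CBS) within chromosomes.
4. **Gene-level CNV calls** — targets labelled gain when their segment value
   (mean log ratio of the segment) is ≥ 0.35 and loss when ≤ −0.5; genes
   with ≤ 4 targets are filtered; a gene with ≥ 70% gain (loss) targets is
   an amplification (deletion); the observed copy number is
   `2 * 2^(mean log2 ratio)` over all of the gene's targets.
5. **Mutation copy number** — for each somatic SNV/indel with allele
   frequency VAF at purity *p* and tumor locus copy number CN~t~:
   `n_mut = VAF * (1/p) * (p*CN_t + CN_n*(1−p))`, CN~n~ = 2. Fusions carry
   no multiplicity.
6. **Concordance** — the shared somatic fingerprint between PT and BM:
   SNVs/indels shared when both sides have VAF ≥ 3%, amplifications when
   both have CN ≥ 4, deletions when both have CN ≤ 1. A pair with more
   than half of its event union shared is classified `shared_dominant`.
7. **Actionability** — events matched to a bundled drug-knowledge table
   with evidence levels A–D (A/B tier 1, C/D tier 2); gene amplification
   is therapy-relevant only above the strict CN > 5 rule; options whose
   drug differs from the initially administered therapy are alternatives,
   and events absent from the PT but present in the BM are flagged
   BM-exclusive.

Every stage is exposed as a plain function over data frames, so each is
usable and testable standalone; `run_pair()` / `run_cohort()` orchestrate
them, and `pipeline_config()` gathers all constants.

# The model behind the copy-number arithmetic

A biopsy with tumor purity *p* is a cell mixture: a locus with tumor copy
number CN~t~ contributes `p*CN_t + 2*(1−p)` copies per cell on average, so
depth ratios against a diploid normal shrink toward 1 as purity falls.
`purity_adjust_cn()` inverts this mixture (clamping at zero) to recover the
tumor-cell copy number that feeds the n~mut~ equation, while the *observed*
copy number is reported alongside because published per-patient tables
print mixture-scale values. The same dilution applies to allele
frequencies, which is why n~mut~ multiplies VAF by the inverse mixture; the
two relations are exact algebraic inverses of each other, and the test
suite checks the round trip at machine precision.

Thresholds on the log2 scale were chosen by the study we reimplement:
+0.35 corresponds to ≈ 2.55 copies and −0.5 to ≈ 1.41 copies in a pure
diploid-background sample. The asymmetry is taken as printed. Two distinct
amplification constants coexist deliberately: CN ≥ 4 (inclusive) for
*sharing* between biopsies and CN > 5 (strict) for *therapy relevance*.

# Circular binary segmentation

Segmentation maximizes, over all arcs of the (circularized) per-chromosome
profile, the pooled-variance two-sample t-statistic comparing the arc mean
against its complement, with arcs restricted to at least `min_width = 2`
targets on both sides. The split is accepted when its permutation p-value
(default 1000 permutations) falls below `alpha = 0.01`; accepted cuts are
applied and the pieces are re-segmented recursively. Chromosome boundaries
are hard segment boundaries, adjacent segments closer than 0.1 log2 units
are coalesced afterwards, and the permutation stream is seeded so reruns
are byte-identical. The scan and permutation loop are implemented in C++;
a variance floor (1e-12) handles the perfect-separation case so noise-free
step profiles split exactly at the true boundary.

Numerical notes: the maximizing arc is defined up to complementation on
the circle (an arc and its complement induce the same cut set); ties are
broken deterministically by scan order. A constant segment has statistic
zero and is never split. Permutation counts use the add-one estimator
`(1 + exceedances) / (1 + n_perm)`, and the permutation loop stops early
once rejection is certain.

The test suite pins the scan to an exhaustive O(n²) arc search on random
profiles, and the recursive procedure to exact behavior on noise-free
steps.

# The synthetic cohort

No sequencing data is distributed with the study this package reimplements
(raw data are available only on request), so a simulator provides
ground-truth cohorts:

* **Panel**: 457 genes over 22 chromosomes, 4–8 targets per gene of
  120–300 bp, GC drawn uniformly from [0.3, 0.7]. Some genes deliberately
  fall under the 5-target floor so the gene filter is exercised.
* **GC bias**: a smooth unimodal capture-efficiency multiplier peaking at
  GC = 0.45 with range [0.6, 1.0] — strong enough that the LOESS corrector
  has real structure to remove.
* **Depth**: negative-binomial per-target molecule counts around the
  purity-diluted expectation, dispersion 0.05 (variance `mu + 0.05 mu²`,
  i.e. ≈ 23% CV at depth 300), emulating FFPE library variability;
  dispersion 0 falls back to Poisson. The matched normal is diploid.
* **Clonal structure**: a truncal-plus-private two-sample model — a stated
  fraction of variants is truncal (present in both biopsies), the rest
  private to one side; copy-number events (default CN 8 amplifications and
  CN 0 deletions) are shared. Allele counts are binomial around the
  expected VAF.
* All randomness flows from one explicit integer seed; the simulator never
  reads global RNG state, and truth is returned as a separate object so
  the pipeline stays blind.

What the simulator does **not** model: mappability and reference artifacts,
FFPE deamination errors, subclonal copy-number states, correlated noise
along the genome, and panel-of-normals batch structure. Recovery results
on simulated cohorts therefore demonstrate internal consistency of the
pipeline under its stated noise model, not performance on real libraries.

## Recovery characteristics

At the simulated study scale (457 genes, depth 300, purities 0.5 and 0.8,
20 cohorts), gene-level CNV calling recovers planted CN 8 / CN 0 events
with pooled sensitivity around 0.9 and specificity above 0.99. The two
purities behave very differently: at purity 0.8 recovery is essentially
perfect, while at purity 0.5 roughly 15% of 5-target events are lost —
either the permutation test cannot isolate a short arc on a chromosome
carrying several other events, or a mid-gene breakpoint leaves the gain
fraction below 0.7. This is an intrinsic power limit of single-pass CBS at
that noise level, and it is reported as measured.

Mutation copy numbers are recovered essentially unbiased (|bias| < 0.01 at
depth 1000 across purities 0.2–1.0), and shared-fraction scoring recovers
planted truncal fractions of 0.7 within ±0.1 with correct
`shared_dominant` / `divergent` classification.

# Fixtures and the bundled knowledge table

The 17-patient cohort tables are bundled as TSVs: per-patient clinical
records (hotspot-PCR results, histology purities, treatments) and the
treatable-variant table (labels, printed copy-number annotations, drugs,
evidence levels, and whether the option was an alternative to the initial
therapy). Loaders verify pinned checksums. Printed parenthetical numbers
are stored verbatim under neutral names because the source table does not
state whether they are mutation copy numbers or gene copy numbers;
interpretation happens downstream.

Where the printed integer copy number 5 appears alongside an amplification
flag (strict > 5 rule), the bundled table stores synthetic pre-rounding
values (5.3/5.4) consistent with the flag; these cells are marked as such
in the file header. The drug-knowledge table is a small static
transcription of the published drug/level pairs — deliberately not a live
database client, so tests are hermetic. TP53/ATM truncating variants are
matched by a suffix grammar (trailing `X` nonsense, `fs` frameshift); the
published missense exception (TP53 R248W) has its own exact entry.

One matching subtlety: several first-line EGFR TKIs are interchangeable
level-A options for the same driver mutation. When one event matches
several entries and one of them is the administered initial therapy, only
that entry is reported for the event; otherwise all matches are kept.
This reproduces the published per-patient assignments without inventing
per-patient knowledge.

# Design choices on open questions

* **GC-then-RPKM order** follows the upstream description of the assay;
  RPKM operates on GC-corrected molecule counts.
* **Observed vs adjusted CN**: sharing thresholds apply to the observed
  (mixture-scale) copy number, since the published fingerprint figures
  display mixture-scale values; the purity-adjusted value feeds n~mut~.
  Both are always reported.
* **Shared-fraction denominator**: the union of all detected events;
  configurable to a PT-only denominator. The union is threshold-free
  (detection is upstream), which makes the shared fraction monotone in
  the VAF threshold; non-shared matched variants attribute to the
  higher-VAF side.
* **Log base 2** for depth ratios, making the printed thresholds
  correspond to standard copy-number interpretation against a diploid
  control.
* **LOESS**: span 0.3, degree 1, symmetric family with 2 robustness
  iterations — common read-depth defaults, all config-exposed. The
  correction is multiplicative to preserve non-negativity.
* **Problem sizes in tests**: the recovery checks use 20 simulated
  cohorts of the full 457-gene panel and 5 simulated pairs per truncal
  fraction — the smallest sizes at which the recovery bounds are stable
  statements rather than single draws.

# Known limitations

* Purity is an input (histology or an external estimator); the package
  does not estimate purity or ploidy.
* CBS power at 5-target events degrades at purity ≤ 0.5 under the
  simulator's FFPE-like dispersion (see above).
* Variant identity is gene + protein label, matching how panel reports
  present events; genomic-coordinate matching is not attempted.
* The knowledge table is frozen at the published evidence state; it is a
  reproduction fixture, not clinical guidance.
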