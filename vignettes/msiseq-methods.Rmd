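---
title: "MSI-seq scoring: model, assumptions and design choices"
author: "msiseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MSI-seq scoring: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(msiseq)
```

## The model

Replication slippage in microsatellites — tandem repeats with units of
1–6 bp — produces insertions and deletions of whole repeat units. A
functional mismatch repair (MMR) system corrects most of them; when MMR
is deficient, the correction fails asymmetrically: short microsatellite
*deletions* (especially single-unit, often 1-bp events) accumulate
sharply, while microsatellite insertions stay roughly at their normal
rate. `msiseq` turns that asymmetry into a per-sample score.

Writing $n^{ins}_{ms}/n^{ins}$ for the fraction of a sample's insertion
events that fall inside microsatellites (PI), and $n^{del}_{ms}/n^{del}$
for the deletion analogue (PD), the MSI-seq index is

$$\mathrm{index} = \frac{PI}{PD}.$$

PD alone rises under MMR deficiency but varies with sequencing depth and
indel-calling behaviour across samples; PI tracks those nuisance factors
without responding to MMR status, so the ratio cancels them. The index
needs no matched germline control and is a continuous measure of MSI
degree rather than a binary call.

**Classification.** Samples with index below a threshold are labelled
MSI. The default threshold is 0.9, the midpoint region of the
tumor-cohort separation (MSI tumors up to ≈0.81, MSS tumors from ≈0.99);
a threshold of 1.0 is equally consistent with cell-line data and both are
exposed through the `threshold` argument. Samples with fewer than
`min_ins = 20` insertions or `min_del = 20` deletions in total are
labelled `indeterminate`: the index is a ratio of two proportions and is
unstable at tiny denominators. We deliberately use *no* pseudocounts by
default — an undefined ratio is reported as undefined rather than
fabricated (a `pseudocount` argument exists for users who prefer
shrinkage).

**Distributional signature.** Independently of the index, the
length distribution of a sample's microsatellite deletions can be
compared against a pooled control cohort with a two-sample
Kolmogorov–Smirnov test (`ks_length_test`). Pooling concatenates the
control samples' lengths into one reference multiset. Lengths are small
tied integers, so the asymptotic p-value is approximate; we use it as in
common practice and document it as such. Insertion lengths are compared
the same way and are expected *not* to separate groups.

**Group comparisons.** `group_compare` implements the classical Student
two-sample t-test with pooled variance (Welch via `var_equal = FALSE`)
and a paired mode for matched tumor/normal designs. Degenerate inputs
(essentially constant data) are flagged, not errors.

## The microsatellite scanner

The catalogue is built by a deterministic exact-repeat scanner: a
microsatellite is a **maximal perfect tract** of a primitive unit of
1–6 bp, with defaults of at least 3 unit copies and at least 6 bp of
tract. This is a deliberate divergence from alignment-based tandem-repeat
finders, which tolerate interruptions under a similarity model with tool-
and parameter-dependent output; a perfect-repeat definition is fully
reproducible and testable against an exhaustive brute-force oracle (the
test suite does exactly that). Imperfect or interrupted repeats are
therefore *not* detected — catalogues built here are conservative
relative to alignment-based ones.

Conventions worth knowing:

* Coordinates are 0-based half-open everywhere internally (BED-style);
  the 1-based VCF convention appears only at I/O boundaries.
* The reported unit is the lexicographically smallest rotation of the
  primitive motif ("CA" tracts are reported as "AC"); no
  reverse-complement folding is applied because transcript space is
  single-stranded.
* A partial terminal copy counts toward tract length, so copy numbers
  can be fractional (`ACACACA` is 3.5 copies of `AC`).
* Positions containing `N` never participate in a tract.

## Indel ingestion and normalization

Only pure indels are scored: records where one allele is a prefix of the
other. Substitutions, MNPs and complex records are skipped (and counted);
the method counts insertions and deletions only, so decomposing complex
records would invent events. Multi-allelic records are split per ALT.
Every retained call is validated against the reference sequence and
**left-normalized**: shifted to the smallest-coordinate representation
that produces the same edited sequence, keeping a preceding anchor base.
Normalization is what makes slippage indels land at the left edge of
their tract, and it is idempotent (tested against a string-edit oracle
that applies every candidate representation).

Known-variant (dbSNP-style) filtering matches by the normalized
`(sequence, position, ref, alt)` key — both sides pass through the same
normalization, so representation differences cannot cause misses. The
source does not specify whether filtering was by identifier or by
position/allele; allele-level matching was chosen because it is robust to
missing rsID annotation.

**Intersection rules.** A deletion is in a microsatellite when its
deleted interval overlaps the tract; an insertion when its anchor lies in
`[start − 1, end)`. The left-flank position is included deliberately:
left-normalization parks tract-lengthening insertions one base before the
tract, and excluding that position would systematically miss slippage
insertions. When several tracts qualify, the smallest-start (tie:
longest) tract is assigned. Region assignment (5′UTR/CDS/3′UTR/ncRNA)
uses the normalized anchor position, so an indel spanning a region
boundary gets a single label and region proportions remain a partition.
Proportions are computed over microsatellite indel *events* (the same
currency as the PI/PD numerators); the count of distinct *altered tracts*
is reported separately, and `region_proportions(by = "tract")` gives the
tract-level view, since the event/tract distinction is genuinely
ambiguous in how such proportions are usually quoted.

## The synthetic-data generator

The simulator exists so the whole pipeline can be exercised, calibrated
and tested without any external download, with analytic ground truth.

* **Transcriptome** — random ACGT transcripts (default 200 × 2000 bp)
  with 3 planted perfect tracts each (unit 1–6 bp, ≥ 8 bp, integer
  copies), flanked by phase-breaking bases and spaced so tracts never
  merge. Accidental repeats arising in the random background are broken
  by point changes until the scanner's output equals the planted
  catalogue exactly; this self-consistency is what makes planted
  membership an exact truth assignment. ~80% of transcripts receive CDS
  boundaries; the rest are non-coding.
* **Samples** — placement is by *count*, not by a per-base rate: each of
  `n_ins_total` insertions is microsatellite-placed with probability
  `p_ms_ins` (deletions analogously), so the expected PI and PD equal the
  generator parameters exactly and acceptance math is clean.
  Microsatellite events are planted at tract left edges in
  already-normalized form — the pipeline's normalization must leave them
  invariant, which doubles as a normalization test. Background events are
  rejection-sampled so that *after* normalization they do not touch any
  tract (otherwise edge effects would bias PI and PD upward). Lengths:
  microsatellite events remove/add 1–3 whole units, with the 1-unit
  probability `msi_del_1bp_weight` (0.8 for MSI deletions, 0.4
  otherwise) — this is the short-deletion signature; background lengths
  are geometric with mean 2 bp.
* **Defaults as study conditions** — MSI: 300 insertions / 600 deletions,
  `p_ms_ins = 0.3`, `p_ms_del = 0.6` (expected index 0.5); MSS and
  normal: 300/300 at 0.3/0.3 (expected index 1.0). The per-sample totals
  sit in the few-hundred-to-thousand range typical of filtered
  transcriptome indel callsets, and the 2:1 deletion elevation with
  1-bp dominance reproduces the qualitative MSI structure; no
  quantitative per-cell-line rates exist to copy, so these values were
  fixed once as plausible and are not tuned. Insertion 1-unit weight is
  0.4 for every status so that insertion-length distributions do not
  separate groups — matching the observation that only deletion lengths
  carry the MMRD signature.
* **Cohorts** — `simulate_cohort` writes normal/MSS/MSI groups with
  ±10% per-sample count jitter, a truth table, and optionally duplicates
  a fraction of background indels into a synthetic known-variant VCF
  (`known_frac`) to exercise the filtering stage.

**What the simulator does not emulate:** read-level artifacts (coverage,
mappability, alignment errors around repeats), imperfect microsatellites,
genome-space splicing, somatic/germline mixtures, and real indel callers'
error modes. Passing tests on synthetic data therefore demonstrate the
correctness of the scoring logic under the stated statistical structure,
not calling accuracy on real RNA-seq.

## Numerical and edge-case policy

* Zero insertion or deletion totals ⇒ PI or PD undefined ⇒ index
  undefined ⇒ label `indeterminate`; never a division error.
* Zero microsatellite indels ⇒ region proportions flagged undefined
  (all `NA`), not silent zeros.
* Empty length multisets ⇒ KS result flagged undefined.
* Tract assignment ties break deterministically (smallest start, then
  longest tract); scanning, scoring and reporting are fully
  deterministic — all randomness lives in the simulator behind explicit
  seeds.
* No indel length cap is imposed by default (`max_indel_len` is
  available); upstream aligner gap limits are a property of the caller,
  not of this method.

## Problem sizes used in the tests

The test suite validates the scanner against an exhaustive brute-force
search on 200 random sequences (≤ 200 bp), normalization against a
string-edit oracle on 1000 random indels, parameter recovery over 50
simulated replicates at the default generator scale, index separation and
KS signatures on default-scale samples against a 10-sample pooled normal
cohort, and end-to-end determinism on a 9-sample cohort over a reduced
transcriptome (60 × 1 kb). These sizes were chosen so the full suite runs
in about two minutes while keeping every statistical check at its
intended power.

## Known limitations

* The perfect-repeat catalogue misses interrupted microsatellites; real
  catalogues built with alignment-based finders will be larger, which
  shifts PI and PD but largely cancels in their ratio.
* Transcriptome-based scoring only sees expressed microsatellites and
  needs adequate coverage for the upstream caller; regulatory-region
  instability is invisible.
* The asymptotic KS p-value with heavily tied integer lengths is
  approximate; at very small event counts prefer the index over the KS
  signature.
* The default threshold (0.9) is calibrated for transcript-space indel
  callsets comparable to the design conditions; recalibration on a
  control cohort is advisable for substantially different pipelines.
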