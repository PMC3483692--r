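---
title: "Methods: tag-based DGE profiling with tagdge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tag-based DGE profiling with tagdge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagdge)
```

## The measurement model

Tag-based DGE reduces each transcript to a 21-bp signature: cDNA is cut
with NlaIII at its CATG recognition sites, an adaptor carrying an MmeI site
is ligated, and MmeI releases the CATG plus the 17 nt downstream. Because
the protocol works inward from the bead-bound polyA end, the fragment that
is actually sequenced comes from the 3′-most CATG of the sense strand.
Expression of a gene in a library is then the count of its tag among the
library's sequenced tags.

Three consequences shape everything downstream:

* a gene without a full-length `CATG`+17 window is invisible ("untaggable");
* tags are short, so distinct genes can share a tag (ambiguity) and a
  sequencing error can move a tag between genes (hence ≤1-mismatch
  mapping);
* each stage is one library — there are no replicates, so significance
  must come from the counting process itself.

### Reference tag database

`build_db()` indexes **every** `CATG`+17 window on **both** strands, not
only the canonical 3′-most sense site. EST-derived unigene references have
unreliable orientation, so restricting to the annotated sense strand would
silently lose genes assembled backwards; indexing everything costs only
ambiguity that the classifier reports honestly. The canonical flag is kept
as metadata — the simulator uses it, mapping does not. Windows containing
non-ACGT characters are skipped; such a window could never be observed as
a clean tag.

### Cleaning

`filter_raw_tags()` applies, in a fixed order so the counters are
unambiguous: malformed length → adaptor prefix → non-ACGT ("N") →
copy-number-1 (singleton). Singletons are judged on the multiset that
survives the earlier rules. The singleton filter embodies the assumption
that a tag seen once in a multi-hundred-thousand-tag library is more
likely a sequencing error of an abundant tag than a real rare transcript;
it costs sensitivity at the very bottom of the dynamic range, which is
also why the DE filter below carries a TPM floor. The adaptor list is
empty by default (adaptor sequences are platform-specific and belong in
the run configuration).

### Mapping

Exact hits take precedence over 1-mismatch hits: if a tag matches the
database verbatim, its 63 single-substitution variants are never
consulted. The alternative (pooling distances 0 and 1) inflates ambiguity
for every tag that happens to neighbour a paralog. Ties at distance 1
across several genes are ambiguous — there is no scoring tie-break,
because the unambiguous class is defined as "identifies exactly one
gene". Multiple matched sites *within* one gene still count as one gene.

### Quantification

TPM is computed per million **clean** tags, not per million mapped tags.
The two denominators differ by the unknown-tag fraction (often half the
library in cross-species EST references); clean-tag normalization keeps
TPM comparable across libraries with different unknown rates, at the cost
of making per-gene TPMs sum to less than 10⁶.

Ambiguous tags matching 2–20 genes are distributed in a single
proportional pass: each gene receives the tag's count times its share of
the candidates' unambiguous counts (equal shares if all candidates have
zero unambiguous evidence); tags matching more than 20 genes are
discarded and accounted. One pass, not EM — iterating the proportional
split changes results only in heavily shared neighbourhoods, where the
honest answer is "ambiguous" anyway. Distributed counts are fractional;
TPM uses the fraction, while the count-based test below rounds half-up to
the nearest integer.

## Differential expression

With one library per stage, the only usable null is the counting noise.
For a tag observed `x` times among `N1` clean tags and `y` among `N2`,
the Audic–Claverie posterior of the second count given the first (Poisson
rate with a flat prior integrated out) is negative binomial with size
`x+1` and success probability `N1/(N1+N2)`. Tail masses are evaluated with
`pnbinom()` (incomplete-beta routines), never naive summation; the upper
tail uses `lower.tail = FALSE` because `1 - F` loses all precision when
`F` is within machine epsilon of 1.

The two-sided p doubles the smaller of the two **complementary** tails:

> p = min(1, 2·min(P(Y ≤ y), P(Y > y)))

Splitting at the observed point this way makes the test exactly symmetric
— `count_test_p(x, y, N1, N2) == count_test_p(y, x, N2, N1)` to machine
precision — so a comparison's calls cannot depend on which stage was
written first. The more common inclusive/inclusive convention is
asymmetric by exactly the observed point's mass. At the boundaries the
conventions agree: p(0,0) = 1 and p(10,0) = 2/2048 ≈ 9.8 × 10⁻⁴ under
equal depths either way.

A gene is called DE iff all four filters pass:

| filter | default | rationale |
|---|---|---|
| TPM ≥ 20 in ≥1 stage | 20 | below ~20 TPM the singleton filter and counting noise dominate |
| p ≤ 0.001 | 0.001 | raw significance of the count test |
| &#124;log₂ ratio&#124; ≥ 1 | 1 | two-fold effect floor |
| BH q < 0.05 | 0.05 | FDR over the TPM-filtered genes of this comparison |

Both the raw-p and the q threshold are applied jointly (the strictest
reading of "P ≤ 0.001 … based on FDR < 0.05"). The BH family is the genes
passing the TPM filter *within one comparison*: each pairwise comparison
is reported as its own figure, so pooling families across comparisons
would make any one comparison's calls depend on how many comparisons were
run. For the log₂ ratio, a zero TPM is floored at the TPM equivalent of a
single tag (10⁶/cleanTags) — a detection-limit floor that keeps on/off
genes finite and large rather than infinite.

## Trajectory analysis

Consecutive-stage comparisons (0h→6h, …, TE→CE) are the default design:
the three biological processes — dedifferentiation (0h→NEC), the NEC→EC
transition, and embryo development (EC→CE) — are windows over consecutive
stages, so consecutive comparisons let every DE call attribute to exactly
one process. A gene belongs to a process iff it is DE in at least one of
that window's comparisons; `process_venn()` reports all seven regions.

### Clustering

Profiles are `log2(TPM + 1)`, standardized per gene. On standardized rows
the squared Euclidean distance equals `2(m−1)(1 − r)`, so Lloyd's k-means
in the standardized space minimizes exactly the Pearson-distance
objective the profiles call for, while retaining k-means' guaranteed
monotone descent (the per-iteration objective trace is kept and asserted
in the tests). Restarts (default 10) keep the best objective; empty
clusters are reseeded with the worst-fit point; a zero-variance profile
standardizes to the zero vector, which sits at distance 1 − r = 1 from
everything — the neutral "no correlation" convention.

The number of profile types is chosen by leave-one-stage-out figure of
merit: cluster on all stages but one, and score the root-mean-square
deviation of the held-out stage from its cluster means, scaled by
`sqrt(n/(n−k))` to remove the trivial advantage of more clusters; sum
over held-out stages. The knee is the smallest k whose next increment
improves the FOM by less than 10%. The same rule, over k = 2..4, splits
each type into sub-clusters (types with fewer than 8 genes are not
split). When k is given (default 5, the typical number of trajectory
archetypes in staged embryogenesis series), the FOM step is skipped.

## qRT-PCR cross-validation

`relative_expression()` is plain 2^(−ΔΔCt) with amplification efficiency
fixed at 2 (no dilution-series correction): replicate-averaged
ΔCt = Ct(target) − Ct(reference), differenced against the first sampled
stage. The sequencing side of the comparison (`rnaseq_ratios()`) is
log₂(TPM ratio versus the same baseline stage) with the single-tag floor,
so both platforms express the same quantity — fold change relative to the
experiment's origin. `platform_correlation()` reports Pearson r and R² on
the paired log₂ ratios, overall or per stage, skipping groups with fewer
than 3 pairs.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes, at desk scale:

| parameter | default | what it models |
|---|---|---|
| `n_genes` | 2000 | reference size (real unigene sets: ~20k) |
| `library_depth` | 2 × 10⁵ | clean tags per library (real: ~3.5 M) |
| `taggable_fraction` | 0.94 | genes with a usable CATG site (~94% observed in plant unigene sets) |
| `base_error_rate` | 10⁻³ /base | typical short-read substitution rate |
| `offref_fraction` | 0.30 | share of the tag stream from transcripts absent from the reference |
| `adaptor/n/singleton_fraction` | 0.005/0.005/0.01 | the three contaminant classes the cleaner removes |
| `archetype_mix` | 5 × 5% + 75% flat | five trajectory shapes (monotone up, monotone down, up-then-down, down-then-up, oscillating) plus stably expressed genes |
| `de_log2fc` | 2 | trajectory amplitude in log₂ units |

Baseline abundances are log-normal (sdlog 1.8), spanning roughly five
orders of magnitude; stage profiles multiply the baseline by the
archetype trajectory with small per-gene shape jitter; per-stage
abundances are renormalized to sum to one, and true DE status for any
stage pair is recomputable from the abundance table as |log₂ ratio| ≥ 1.
Only the canonical 3′-most sense tag is ever "sequenced" — non-canonical
sites exist in the reference DB but not in the libraries, which
deliberately reproduces the real asymmetry between what mapping must
consider and what the protocol emits. Off-reference transcripts form a
stage-shared pool with Zipf-like abundances so that most survive the
singleton filter, and they displace reference draws, making
`offref_fraction` the expected unknown share of the clean stream.

What the generator does **not** model: read-level quality scores, PCR
duplicates, GC or position bias, library-preparation batch effects,
isoforms sharing 3′ ends, and any real biological covariance between
genes. Passing the simulation benchmarks therefore demonstrates that the
pipeline's bookkeeping, test calibration and recovery behave as designed
under the stated noise model — not that real libraries meet that model.

## Numerical and scale choices

* Printed-table percentages round half-up to two decimals
  (`format_pct()`), matching how accounting tables are conventionally
  printed (64.4996 → "64.50"); the "Average" row rounds half-up to
  integers.
* Fractional distributed counts are rounded half-up only for the count
  test; TPM keeps the fraction.
* Saturation curves subsample without replacement, average over
  replicates, and enforce monotonicity by cumulative maximum across the
  fraction grid.
* Test-suite and benchmark problem sizes — 2,000 genes at depth 3 × 10⁵
  with 200 null pairs for test calibration; 200 planted four-fold effects
  at the 100 ↔ 400 TPM level for sensitivity/FDP; 60 genes over 8 stages
  for figure-of-merit recovery; full pipelines at 60–500 genes and depths
  5 × 10³–5 × 10⁴ — were chosen so every property is measured with
  comfortable statistical margin while the whole suite stays interactive.
  The planted effects sit at the 100 ↔ 400 TPM level because the
  replicate-free count test simply does not have 90% power at p ≤ 0.001
  for a 100 → 25 TPM drop at these depths (counts 30 vs 7.5; power ≈ 0.7)
  — an honest limitation of single-library designs, not of the
  implementation.

## Known limitations

* No replicate-aware dispersion modelling: with one library per stage the
  count test measures sampling noise only, and its small p-values must
  not be read as biological certainty.
* No between-library normalization beyond TPM (no TMM/quantile); strongly
  asymmetric transcriptome remodelling between stages will bias ratios.
* Mapping is tag-to-tagDB, not alignment: no positional information, no
  splice awareness, and a reference without a gene's 3′ end simply cannot
  see that gene.
* The multi-read split is evidence-proportional, not an estimator with
  guarantees; genes whose only signal is shared tags remain uncertain.
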