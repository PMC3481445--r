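---
title: "Comparative CNV merging and concordance: methods and design"
author: "ccnvtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative CNV merging and concordance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(ccnvtools))
```

# The model

Read-depth CNV callers assign a copy-number value to genomic segments;
everything outside a called segment is implicitly at baseline ploidy.
`ccnvtools` treats one caller *configuration* (e.g. one normalization
choice) as a `CNVCallSet`: a sorted, disjoint set of valued intervals on a
fixed genome layout, with the neutral value (default 2) never stored
explicitly. This "variants only, neutral implicit" convention matches how
read-depth callers report their output and makes the per-base copy-number
function of a configuration total: every base has a value, either called
or neutral.

## Merging into comparative CNV regions

Given *k* configurations on one genome, the merge proceeds in three steps:

1. **Fragmentation.** Every call longer than `maxFragment` bases (default
   10 000, i.e. 10 kb) is cut into abutting fragments anchored at the
   *segment start* (`start + j·maxFragment`; the last fragment may be
   shorter). Read-depth callers can emit multi-megabase segments, and
   without this step a single long call would extend a merged region far
   beyond the short calls it overlaps in other configurations. Anchoring
   at the segment start rather than at absolute genome coordinates keeps
   the cut pattern a property of the call, not of its position; either
   convention leaves all per-base quantities unchanged, so the choice is
   cosmetic and we fixed it once.
2. **Breakpoint extraction and vector assignment.** The union of all
   segment start/end positions defines elementary intervals; each receives
   one copy-number value per configuration (neutral where uncalled).
   Intervals neutral in every configuration are not represented.
3. **Coalescing.** Consecutive elementary intervals with identical value
   vectors are merged. This makes the merge idempotent (merging the
   extracted per-configuration call sets again reproduces the result
   exactly) and means fragmentation has no effect on any per-base or
   per-region quantity — it only bounds the granularity of the *reported*
   segments. We note a latent tension in the usual description of such
   merges: "no breakpoint inside a merged segment" and "coalesce equal
   vectors" conflict exactly at fragmentation cut points. We follow the
   coalescing reading because idempotence is the more useful algebraic
   property and no downstream statistic can tell the difference.

A **cCNV region** is a maximal run of abutting merged segments: the base
before its start and the base at its end are all-neutral or a chromosome
boundary. Since all-neutral intervals are dropped before grouping, every
base of a region is variant in at least one configuration. Each region
carries two fractions in [0, 1]: the share of its bases covered by the
genic track and by the validated track. Where a finer grouping of merged
segments into regions might be wanted (e.g. splitting runs at changes of
which configurations are variant), maximal contiguity is the only rule
that needs no extra parameter, and it is the one we implement.

## Concordance statistics

For a configuration and a stratum (`all`, `genic`, `nongenic` = layout
complement of the genic track, `validated`), the *base set* is the set of
bases where the configuration's merged value differs from neutral,
intersected with the stratum. Genic and non-genic base sets partition the
all-stratum set exactly, mirroring the exact partition
`Genic + NonGenic = total` of the overlap base counts.

The **Jaccard index** of two base sets is intersection over union in
bases. Two empty sets give 0, not NaN: an empty configuration shares no
variant signal, and a NaN would poison across-genome means; report tables
flag this case in a `bothEmpty` column.

**Bin profiles** partition a configuration's variant bases by value:
deletions (v < 2), moderate amplifications (2 < v ≤ 6), high
amplifications (v > 6). The boundary value 2 is the neutral ploidy and is
excluded by construction, so reading "2 to 6 copies" as the half-open
interval (2, 6] loses nothing; values are not required to be integers
(relative-ratio callers produce fractional estimates). **Fraction change**
is `(alternative − reference)/reference` per bin — the reference is the
configuration the others are compared against (in the default simulated
contrast, the GC-like profile). A −0.70 in the deletion bin means 70% of
the reference's deletion bases are gone. An empty reference bin yields NA
with a warning rather than an infinity.

The **rank-sum test** compares genic vs non-genic Jaccard values. For
pooled sample sizes n + m ≤ 20 the two-sided p-value is computed by full
enumeration of all `choose(n+m, n)` rank assignments, as
`P(|W − E[W]| ≥ |w − E[W]|)` with midranks for ties; beyond that, a normal
approximation with the standard tie correction of the variance (and no
continuity correction) is used. All-tied input is degenerate and returns
p = 1 with a warning; samples of fewer than two observations are an
error. `stats::wilcox.test` is used in the test suite as an independent
cross-check, never as the implementation.

Across genomes, summaries report the arithmetic mean and the sample
standard deviation (n − 1); one genome yields sd = NA rather than 0.

# The synthetic-data generator

The generator is first-class, tested code. It emulates the statistical
structure the analysis assumes, not sequencing itself:

- a toy layout (default 2 chromosomes × 5 Mb);
- a truth landscape of non-overlapping, non-abutting CNVs (default 150)
  with log-uniform lengths (default 2–20 kb — the scale at which
  read-depth callers with kilobase windows resolve events), deletion
  values {0, 1} and gain values {3..8} with equal deletion/gain balance;
- a genic track accumulating random gene-body-sized intervals (5–50 kb,
  log-uniform) until it covers the requested fraction of the layout
  (default 0.35, a gene-body-like share; adding one interval at a time
  bounds the overshoot by a single interval, well within ±2% at 10 Mb);
- a validated track spawning, with probability 0.3 by default, an
  interval overlapping each truth CNV extended by up to 5 kb per side —
  a catalogue enriched at true variant sites, as an externally validated
  CNV set would be;
- per-configuration distortion profiles: detection probability, Gaussian
  boundary jitter (rounded to integer bases, clipped to the layout,
  minimum segment length 1; post-jitter overlaps resolved by truncating
  both segments at the midpoint of the overlap, which preserves call-set
  validity without rejection sampling), Poisson false calls (values drawn
  uniformly from the deletion and gain pools; a false call colliding with
  a retained segment is re-drawn up to 20 times, then skipped), and
  deletion suppression — the extra probability that a detected deletion
  is dropped.

The three default profiles encode the qualitative contrast between
read-count normalization strategies that motivates the package: a
GC-content-like reference reporting the full landscape; a
mappability-like profile with deletion suppression 0.70 (mappability
filtering removes read-count artifacts that mimic deletions), detection
0.9 and mild jitter; and a control-genome-like profile with lower
detection, stronger jitter and ten expected extra calls. These defaults
were fixed once, from the qualitative behaviour the contrast is meant to
reproduce, and are deliberately not tuned per analysis.

Everything is deterministic given `(seed, config)`; each operation draws
from its own seeded stream and restores the caller's RNG state.

**What passing tests do and do not show.** The generator produces clean
rectangular segments with independent distortions. Real call sets have
correlated errors (shared mappability artifacts hit all configurations),
length-dependent detection, and breakpoint uncertainty that is not
Gaussian. Recovery of a simulated 70% deletion suppression therefore
validates the *statistics* (the pipeline measures what was put in), not
the biological accuracy of any particular caller.

# Numerical and interface choices

- **Coordinates** are 0-based half-open (BED convention) in all tabular
  input/output and 1-based closed inside `GRanges`, converted exactly at
  the boundary; all base counting is integer-exact.
- **Validation** unions overlapping or adjacent *equal-valued* input
  segments (the per-base function is unchanged) and hard-errors on
  overlapping *conflicting* values, naming the locus. Zero-length rows —
  the artifacts of duplicate breakpoints — are dropped silently.
- **Per-configuration overlap shares** (`overlapSummary(...,
  configuration = )`) are computed on the bases where that configuration
  is variant, with fractions recomputed on those sub-segments; the
  whole-region mode applies the length-times-fraction formulas to entire
  cCNV regions. Both readings are exposed because summary tables in the
  literature do not always say which one they use.
- **Jaccard strata** use merged (cCNV) bases, i.e. the padded extents
  produced by the merge, not the raw pre-merge calls — concordance is a
  property of the comparative representation.
- **FREEC-style input** is assumed 1-based inclusive (`oneBased = FALSE`
  overrides); the numeric copy number is authoritative when the gain/loss
  status column disagrees. **CNV-seq-style input** is converted by joining
  runs of ≥ 6 contiguous windows with p below 1e-4 (both exposed as
  parameters; the stringent defaults follow common practice of tightening
  the caller's defaults) into one segment valued `2·2^mean(log2)` rounded
  to 2 decimals.
- The CLI collapses an `annotate` step into `merge`/`concord` output: the
  overlap fractions are columns of the merged table, so a separate
  subcommand would re-read and re-write the same file.

# Problem sizes used in the test suite

The oracle-backed tests run against flat per-base arrays: 100 random
three-configuration instances on a 2 × 500 kb layout for the merge and
conservation checks, 100 random interval pairs for the Jaccard oracle, 30
instances for partition and binning oracles, 20 replicates × 200 deletion
CNVs on 2 × 5 Mb for suppression recovery (pooled estimate checked
against the 99% binomial interval around −0.70), and 20 replicates per
grid point for the jitter {0, 500, 5000 bases} and false-call {0, 10, 50}
monotonicity checks. These sizes give the per-base oracles full coverage
of every code path while keeping the suite comfortably reproducible on a
single CPU.

# Known limitations

- Merging assumes one shared neutral value; mixed-ploidy designs (e.g.
  sex chromosomes analysed jointly with autosomes) must be split into
  separate analyses — `keepChromosomes()` exists for exactly this.
- cCNV regions are maximal contiguous runs; no pruning of padded ends is
  implemented (a more conservative variant would shrink regions to the
  overlap cores).
- The rank-sum enumeration is exact but O(choose(n+m, n)); it is capped
  at n + m ≤ 20 by design.
- The generator does not simulate reads, GC/mappability fields on
  sequence, or caller internals; external callers are consumed through
  their output tables only.
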