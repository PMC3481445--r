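# ccnvtools

Comparative copy-number variant (CNV) merging and concordance analysis for R
(Bioconductor-style, built on GenomicRanges / SummarizedExperiment).

## The problem

Read-depth CNV callers expose normalization choices — GC-content correction,
mappability filtering, control-genome scaling — and the same sequencing run
can yield very different CNV calls under different choices. Low-mappability
regions accumulate fewer reads and mimic deletions, so mappability-style
filtering characteristically removes a large share of deletion calls;
control-genome normalization instead reshuffles moderate-amplification
calls. Quantifying this disagreement requires putting all configurations
onto a common segmentation first.

`ccnvtools` implements the comparative-CNV (cCNV) representation: the call
sets of *k* configurations are fragmented to at most 10 kb per segment
(so a single multi-megabase call cannot "pad" a merged region far beyond
the short calls it overlaps elsewhere), every unique segment start/end
becomes a breakpoint, and each elementary interval between adjacent
breakpoints carries a vector of *k* copy-number values — the neutral value
(ploidy, 2) filled in where a configuration made no call. Maximal runs of
abutting merged segments form cCNV regions, annotated with their fractional
overlap with a genic track and a validated-CNV track.

On top of the merged representation the package computes:

- **base-pair Jaccard indices** between configuration pairs,
  `JI(A, B) = |A ∩ B| / |A ∪ B|` counted in single bases, stratified into
  all / genic / non-genic / validated regions;
- **overlap base counts** per the length-times-fraction formulas
  `Genic = Σ_c len(c)·f_genic(c)`, `NonGenic = Σ_c len(c) − Genic`,
  `Validated = Σ_c len(c)·f_validated(c)` (exact integer partition);
- **copy-number bin profiles** (below 2 / 2–6 / above 6 copies) and per-bin
  **fraction changes** `(alt − ref)/ref` between configurations;
- a **two-sample Wilcoxon rank-sum test** (exact enumeration for
  n + m ≤ 20, tie-corrected normal approximation otherwise) for comparing
  genic vs non-genic concordance;
- a **synthetic call-set generator** (toy genome, truth CNV landscape,
  annotation tracks, per-configuration detection/jitter/false-call/deletion-
  suppression distortions) so the whole pipeline is testable with no
  external data;
- readers for BED4, FREEC-style and CNV-seq-style call tables, a `.fai`
  layout reader, and a small CLI (`inst/scripts/ccnv.R`) with
  `simulate | merge | concord | report` subcommands.

## Worked example

```r
library(ccnvtools)

cfg <- simulationConfig(seed = 42, nCnvs = 80)   # 2 x 5 Mb toy genome
study <- simulateStudy(cfg)   # truth + gc/mappability/control call sets
study$merged
#> CCNVExperiment: 325 merged segments x 3 configurations (gc, mappability, control)
#>   neutral value 2; 87 cCNV regions

rep <- concordanceReport(study$merged, genic = study$genic,
                         validated = study$validated)
subset(summarizeConcordance(rep)$jaccard,
       configA == "gc" & configB == "mappability")
#>  configA     configB   stratum      mean sd n
#>       gc mappability       all 0.5196108 NA 1
#>       gc mappability     genic 0.6134119 NA 1
#>       gc mappability  nongenic 0.4789093 NA 1
#>       gc mappability validated 0.6015112 NA 1

subset(fractionChangeTable(rep),
       configuration == "mappability" & stratum == "all")
#>  genome configuration stratum      bin fractionChange
#>     sim   mappability     all   below2    -0.76712601
#>     sim   mappability     all from2to6    -0.06182155
#>     sim   mappability     all   above6    -0.18701897
```

Reading: merging the three simulated configurations gives 325 granular
segments grouped into 87 cCNV regions. The mappability-like configuration
agrees with the GC-like reference on ~52% of variant bases (Jaccard), more
in genic than non-genic territory, and its deletion bin has lost ~77% of
the reference's deletion bases — the generator's deletion suppression
(70%) plus its 10% missed-detection rate, recovered by the fraction-change
statistic.

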