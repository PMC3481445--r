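setOldClass("data.frame")

#' CNVCallSet: one caller configuration's copy-number calls on a genome
#'
#' A \code{CNVCallSet} holds the non-overlapping, copy-number-valued genomic
#' segments emitted by a single caller configuration (for example a read-depth
#' caller run with GC-content, mappability or control-genome normalization)
#' for one genome. Coordinates are stored as a \linkS4class{GRanges} on a
#' fixed genome layout (\link[GenomeInfoDb]{Seqinfo}); the numeric
#' \code{value} metadata column is the estimated absolute copy number.
#' Regions without a call are implicitly at the neutral copy number
#' (baseline ploidy, 2 by default): the call set stores variant segments
#' only, never neutral ones.
#'
#' @slot calls \code{GRanges} with numeric metadata column \code{value};
#'   sorted, disjoint within each chromosome, all values \code{>= 0} and
#'   none equal to \code{neutralValue}.
#' @slot genomeLabel single string naming the genome/sample.
#' @slot configLabel single string naming the caller configuration.
#' @slot neutralValue baseline (ploidy) copy number, default 2.
#'
#' @seealso \code{\link{CNVCallSet}} (validating constructor),
#'   \code{\link{fragmentSegments}}, \code{\link{mergeCallSets}}
#' @exportClass CNVCallSet
setClass("CNVCallSet",
  slots = c(
    calls = "GRanges",
    genomeLabel = "character",
    configLabel = "character",
    neutralValue = "numeric"
  )
)

setValidity("CNVCallSet", function(object) {
  gr <- object@calls
  msg <- character()
  if (length(object@genomeLabel) != 1L || is.na(object@genomeLabel))
    msg <- c(msg, "'genomeLabel' must be a single string")
  if (length(object@configLabel) != 1L || is.na(object@configLabel))
    msg <- c(msg, "'configLabel' must be a single string")
  if (length(object@neutralValue) != 1L || !is.finite(object@neutralValue))
    msg <- c(msg, "'neutralValue' must be a single finite number")
  if (is.null(mcols(gr)$value))
    return(c(msg, "calls must carry a numeric 'value' metadata column"))
  v <- mcols(gr)$value
  if (!is.numeric(v) || anyNA(v))
    msg <- c(msg, "'value' column must be numeric without NA")
  else {
    if (any(v < 0))
      msg <- c(msg, "copy-number values must be >= 0")
    if (any(v == object@neutralValue))
      msg <- c(msg, "neutral-valued segments must not be stored explicitly")
  }
  if (any(is.na(seqlengths(seqinfo(gr)))))
    msg <- c(msg, "all chromosomes must have known lengths in the layout")
  else if (length(gr) && any(end(gr) > seqlengths(seqinfo(gr))[as.character(seqnames(gr))]))
    msg <- c(msg, "segment ends exceed chromosome lengths")
  if (length(gr) > 1L) {
    if (is.unsorted(order(as.integer(seqnames(gr)), start(gr))) ||
        !identical(order(as.integer(seqnames(gr)), start(gr)), seq_along(gr)))
      msg <- c(msg, "segments must be sorted by (chrom, start)")
    else {
      same <- as.character(seqnames(gr))[-length(gr)] ==
        as.character(seqnames(gr))[-1L]
      if (any(same & end(gr)[-length(gr)] >= start(gr)[-1L]))
        msg <- c(msg, "segments overlap within a chromosome")
    }
  }
  if (length(msg)) msg else TRUE
})

#' RegionTrack: a disjoint union of annotation intervals
#'
#' An annotation track (genic regions, externally validated CNV regions, ...)
#' stored as the sorted disjoint union of its input intervals: overlapping or
#' abutting inputs are merged on construction, so covered-base counts are
#' invariant under permutation and duplication of the inputs.
#'
#' @slot ranges reduced (sorted, disjoint, strand-free) \code{GRanges}.
#' @slot label single string naming the track (e.g. \code{"genic"}).
#'
#' @seealso \code{\link{RegionTrack}}, \code{\link{readTrack}}
#' @exportClass RegionTrack
setClass("RegionTrack",
  slots = c(ranges = "GRanges", label = "character")
)

setValidity("RegionTrack", function(object) {
  gr <- object@ranges
  msg <- character()
  if (length(object@label) != 1L || is.na(object@label))
    msg <- c(msg, "'label' must be a single string")
  if (!identical(gr, reduce(gr)))
    msg <- c(msg, "track ranges must be a sorted disjoint (reduced) union")
  if (any(is.na(seqlengths(seqinfo(gr)))))
    msg <- c(msg, "all chromosomes must have known lengths in the layout")
  else if (length(gr) && any(end(gr) > seqlengths(seqinfo(gr))[as.character(seqnames(gr))]))
    msg <- c(msg, "intervals exceed chromosome lengths")
  if (length(msg)) msg else TRUE
})

#' CCNVExperiment: merged comparative CNV segments
#'
#' Container for the output of \code{\link{mergeCallSets}}: a
#' \linkS4class{RangedSummarizedExperiment} whose rows are granular merged
#' segments (elementary intervals between breakpoints pooled from all input
#' call sets, coalesced where the per-configuration value vector is
#' constant) and whose columns are the input caller configurations. The
#' single assay, \code{"copyNumber"}, holds one copy-number value per
#' segment and configuration, with the neutral value filled in where a
#' configuration made no call. Every row is variant (non-neutral) in at
#' least one configuration. The neutral value is kept in
#' \code{metadata(x)$neutralValue}.
#'
#' Maximal runs of abutting rows form comparative CNV (cCNV) regions; see
#' \code{\link{ccnvRegions}}.
#'
#' @seealso \code{\link{mergeCallSets}}, \code{\link{copyNumbers}},
#'   \code{\link{ccnvRegions}}, \code{\link{baseSet}}
#' @exportClass CCNVExperiment
setClass("CCNVExperiment",
  contains = "RangedSummarizedExperiment"
)

setValidity("CCNVExperiment", function(object) {
  msg <- character()
  if (!"copyNumber" %in% names(assays(object)))
    return("assay 'copyNumber' is required")
  nv <- metadata(object)$neutralValue
  if (is.null(nv) || length(nv) != 1L || !is.finite(nv))
    msg <- c(msg, "metadata(x)$neutralValue must be a single finite number")
  m <- assay(object, "copyNumber")
  if (!is.numeric(m) || anyNA(m))
    msg <- c(msg, "copyNumber assay must be numeric without NA")
  else if (!is.null(nv) && length(nv) == 1L && is.finite(nv) &&
           nrow(m) && any(rowSums(m != nv) == 0L))
    msg <- c(msg, "every merged segment must be variant in >= 1 configuration")
  if (length(msg)) msg else TRUE
})

#' ConcordanceReport: pairwise concordance metrics across genomes
#'
#' Result container produced by \code{\link{concordanceReport}}. Holds long-
#' format tables of pairwise base-pair Jaccard indices per stratum, per-
#' configuration copy-number bin profiles, and per-bin fraction changes of an
#' alternative configuration relative to a reference configuration, for one
#' or more genomes.
#'
#' @slot jaccard data.frame: genome, configA, configB, stratum, jaccard,
#'   bothEmpty.
#' @slot bins data.frame: genome, configuration, stratum, bin, bases.
#' @slot fractionChange data.frame: genome, configuration, stratum, bin,
#'   fractionChange (NA where the reference bin is empty).
#' @slot reference label of the reference configuration used for fraction
#'   changes.
#'
#' @seealso \code{\link{concordanceReport}},
#'   \code{\link{summarizeConcordance}}, \code{\link{genicNongenicTest}}
#' @exportClass ConcordanceReport
setClass("ConcordanceReport",
  slots = c(
    jaccard = "data.frame",
    bins = "data.frame",
    fractionChange = "data.frame",
    reference = "character"
  )
)
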