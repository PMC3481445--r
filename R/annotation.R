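#' Base-count overlap summary of comparative CNV regions
#'
#' Summarises how many bases of the comparative CNV regions fall in genic,
#' non-genic and validated territory. Writing \code{length(c)} for a
#' region's size and \code{f_genic(c)} for its fractional genic overlap, the
#' genic base count is \code{sum over regions of length(c) * f_genic(c)};
#' non-genic bases are the complement \code{total - genic}; validated bases
#' use the validated track's fraction the same way. Because the fractions
#' are covered-base counts divided by region length, the partition
#' \code{genic + nongenic == total} is exact in integer bases.
#'
#' With \code{configuration} set, the sums run only over the bases where
#' that configuration is variant (its merged value differs from neutral),
#' with overlap fractions recomputed on those sub-segments — the
#' per-configuration reading used for genic/validated share tables.
#'
#' @param x a \linkS4class{CCNVExperiment}, or a \code{GRanges} of regions
#'   from \code{\link{ccnvRegions}} carrying \code{genicOverlap} /
#'   \code{validatedOverlap} metadata columns.
#' @param genic,validated \linkS4class{RegionTrack}s (or \code{GRanges});
#'   optional for the \code{GRanges} method, where stored fractions are
#'   used. A missing track yields \code{NA} for its base count.
#' @param configuration optional configuration label or index
#'   (\code{CCNVExperiment} method only).
#' @return A one-row data.frame with columns \code{genicBases},
#'   \code{nongenicBases}, \code{validatedBases}, \code{totalBases},
#'   \code{genicShare}, \code{validatedShare}.
#' @examples
#' lay <- genomeLayout("chr1", 1e6)
#' a <- CNVCallSet(data.frame(chrom = "chr1", start = 0, end = 1000,
#'                            value = 3), lay, "g", "gc")
#' b <- CNVCallSet(data.frame(chrom = "chr1", start = 500, end = 1500,
#'                            value = 1), lay, "g", "map")
#' gen <- RegionTrack(data.frame(chrom = "chr1", start = 500, end = 2500),
#'                    lay, "genic")
#' overlapSummary(mergeCallSets(list(a, b)), genic = gen)
#' @export
setMethod("overlapSummary", "CCNVExperiment",
          function(x, genic = NULL, validated = NULL, configuration = NULL) {
  if (is.null(configuration)) {
    base <- reduce(rowRanges(x))
  } else {
    v <- copyNumbers(x)[, configuration]
    base <- reduce(rowRanges(x)[v != neutralValue(x)])
  }
  .overlapSummaryRanges(base, genic, validated)
})

#' @rdname overlapSummary-CCNVExperiment-method
#' @export
setMethod("overlapSummary", "GRanges",
          function(x, genic = NULL, validated = NULL, configuration = NULL) {
  if (!is.null(configuration))
    stop("'configuration' applies only to CCNVExperiment input")
  if (is.null(genic) && is.null(validated) &&
      all(c("genicOverlap", "validatedOverlap") %in% names(mcols(x)))) {
    w <- as.numeric(width(x))
    total <- sum(w)
    genicBases <- sum(w * mcols(x)$genicOverlap)
    validatedBases <- sum(w * mcols(x)$validatedOverlap)
    return(.summaryRow(genicBases, validatedBases, total))
  }
  .overlapSummaryRanges(reduce(x), genic, validated)
})

.overlapSummaryRanges <- function(base, genic, validated) {
  total <- sum(as.numeric(width(base)))
  trackBases <- function(track) {
    if (is.null(track)) return(NA_real_)
    tr <- if (is(track, "RegionTrack")) trackRanges(track) else reduce(track)
    sum(.overlapBases(base, tr))
  }
  .summaryRow(trackBases(genic), trackBases(validated), total)
}

.summaryRow <- function(genicBases, validatedBases, total) {
  data.frame(
    genicBases = genicBases,
    nongenicBases = total - genicBases,
    validatedBases = validatedBases,
    totalBases = total,
    genicShare = if (total > 0) genicBases / total else NA_real_,
    validatedShare = if (total > 0) validatedBases / total else NA_real_
  )
}
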