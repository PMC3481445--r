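#' Fragment long call segments
#'
#' Pre-processing step of the cCNV merge: every call segment longer than
#' \code{maxFragment} bases is cut into abutting fragments of at most
#' \code{maxFragment} bases carrying the original value. Cut points are
#' anchored at the segment start (\code{start + k * maxFragment}); the last
#' fragment may be shorter. The per-base copy-number function and the total
#' variant base count are unchanged. Read-depth callers tend to emit
#' multi-megabase segments; without fragmentation a single long segment
#' would "pad" a merged comparative region far beyond the extent of the
#' short calls it overlaps in other configurations.
#'
#' @param x a \linkS4class{CNVCallSet}.
#' @param maxFragment maximum fragment length in bases (default 10000).
#' @return A \linkS4class{CNVCallSet} with all segments of length
#'   \code{<= maxFragment}.
#' @export
setMethod("fragmentSegments", "CNVCallSet",
          function(x, maxFragment = 10000L) {
  maxFragment <- as.numeric(maxFragment)
  if (length(maxFragment) != 1L || is.na(maxFragment) || maxFragment <= 0)
    stop("'maxFragment' must be a single positive number of bases")
  gr <- x@calls
  if (length(gr) == 0L || all(width(gr) <= maxFragment)) return(x)
  n <- ceiling(width(gr) / maxFragment)
  idx <- rep(seq_along(gr), n)
  off <- (sequence(n) - 1L) * maxFragment
  s <- start(gr)[idx] + off
  e <- pmin(s + maxFragment - 1L, end(gr)[idx])
  out <- GRanges(seqnames(gr)[idx], IRanges(s, e), seqinfo = seqinfo(gr))
  mcols(out)$value <- mcols(gr)$value[idx]
  .newCallSet(out, x)
})

#' Merge CNV call sets into a comparative CNV experiment
#'
#' Core merge of the comparative-CNV (cCNV) representation. All input call
#' sets (one per caller configuration, same genome layout and neutral
#' convention) are first fragmented with \code{\link{fragmentSegments}};
#' then every unique segment start and end position across configurations
#' becomes a breakpoint, and each elementary interval between adjacent
#' breakpoints receives a vector of copy-number values — one per
#' configuration, read from that configuration's call where present and the
#' neutral value where not. Intervals that are neutral in every
#' configuration are not represented; consecutive intervals with identical
#' value vectors are coalesced (so the merge is idempotent). The per-base
#' copy-number function of every input configuration is reproduced exactly
#' by the output.
#'
#' @param callsets list of \code{>= 2} \linkS4class{CNVCallSet}s on the same
#'   layout with the same neutral value and distinct configuration labels.
#' @param maxFragment fragmentation length applied to every input before
#'   merging (bases, default 10000); \code{Inf} disables fragmentation.
#' @param coalesce logical; coalesce consecutive elementary intervals with
#'   identical value vectors (default \code{TRUE}).
#' @return A \linkS4class{CCNVExperiment}: rows are merged segments, columns
#'   configurations, assay \code{"copyNumber"} the value matrix.
#' @examples
#' lay <- genomeLayout("chr1", 1e6)
#' a <- CNVCallSet(data.frame(chrom = "chr1", start = 100, end = 300,
#'                            value = 3), lay, "g", "gc")
#' b <- CNVCallSet(data.frame(chrom = "chr1", start = 200, end = 400,
#'                            value = 1), lay, "g", "mappability")
#' mergeCallSets(list(a, b))
#' @export
mergeCallSets <- function(callsets, maxFragment = 10000L, coalesce = TRUE) {
  if (!is.list(callsets) || length(callsets) < 2L ||
      !all(vapply(callsets, is, logical(1), "CNVCallSet")))
    stop("'callsets' must be a list of >= 2 CNVCallSet objects")
  layouts <- lapply(callsets, function(cs) seqinfo(cs@calls))
  if (!all(vapply(layouts[-1L], identical, logical(1), layouts[[1L]])))
    stop("all call sets must share one genome layout")
  nv <- unique(vapply(callsets, function(cs) cs@neutralValue, numeric(1)))
  if (length(nv) != 1L)
    stop("all call sets must share one neutral value")
  labels <- vapply(callsets, function(cs) cs@configLabel, character(1))
  if (anyDuplicated(labels))
    stop("configuration labels must be distinct")
  genomes <- vapply(callsets, function(cs) cs@genomeLabel, character(1))

  frag <- lapply(callsets, function(cs)
    if (is.finite(maxFragment)) fragmentSegments(cs, maxFragment) else cs)
  grl <- lapply(frag, function(cs) cs@calls)
  pooled <- unlist(GRangesList(lapply(grl, function(g) {
    mcols(g) <- NULL
    g
  })), use.names = FALSE)
  k <- length(callsets)
  if (length(pooled) == 0L) {
    dj <- GRanges(seqinfo = layouts[[1L]])
    m <- matrix(numeric(0), nrow = 0L, ncol = k)
  } else {
    dj <- disjoin(pooled)
    m <- matrix(nv, nrow = length(dj), ncol = k)
    for (i in seq_len(k)) {
      hits <- findOverlaps(dj, grl[[i]])
      m[queryHits(hits), i] <- mcols(grl[[i]])$value[subjectHits(hits)]
    }
    keep <- rowSums(m != nv) > 0L
    dj <- dj[keep]
    m <- m[keep, , drop = FALSE]
    if (coalesce && length(dj) > 1L) {
      n <- length(dj)
      sameVec <- rowSums(m[-1L, , drop = FALSE] ==
                         m[-n, , drop = FALSE]) == k
      abut <- as.character(seqnames(dj))[-1L] ==
                as.character(seqnames(dj))[-n] &
              start(dj)[-1L] == end(dj)[-n] + 1L
      isFirst <- c(TRUE, !(sameVec & abut))
      isLast <- c(isFirst[-1L], TRUE)
      dj <- GRanges(seqnames(dj)[isFirst],
                    IRanges(start(dj)[isFirst], end(dj)[isLast]),
                    seqinfo = seqinfo(dj))
      m <- m[isFirst, , drop = FALSE]
    }
  }
  colnames(m) <- labels
  se <- SummarizedExperiment(
    assays = list(copyNumber = m),
    rowRanges = dj,
    colData = DataFrame(configuration = labels, genome = genomes,
                        row.names = labels),
    metadata = list(neutralValue = nv, maxFragment = maxFragment)
  )
  new("CCNVExperiment", se)
}

#' @describeIn CCNVExperiment-class the segment-by-configuration copy-number
#'   matrix (assay \code{"copyNumber"}).
#' @param x a \code{CCNVExperiment}.
#' @export
setMethod("copyNumbers", "CCNVExperiment",
          function(x) assay(x, "copyNumber"))

#' @describeIn CCNVExperiment-class configuration labels in vector order.
#' @export
setMethod("configurationLabels", "CCNVExperiment",
          function(x) colnames(assay(x, "copyNumber")))

#' @describeIn CCNVExperiment-class the neutral (baseline ploidy) value.
#' @export
setMethod("neutralValue", "CCNVExperiment",
          function(x) metadata(x)$neutralValue)

#' @describeIn CCNVExperiment-class total variant bases of one configuration
#'   (bases where its value differs from neutral).
#' @param configuration configuration label or column index.
#' @param ... unused.
#' @export
setMethod("variantBases", "CCNVExperiment",
          function(x, configuration, ...) {
  v <- copyNumbers(x)[, configuration]
  sum(as.numeric(width(rowRanges(x)))[v != neutralValue(x)])
})

#' Reconstruct one configuration's call set from a merged experiment
#'
#' Inverse of \code{\link{mergeCallSets}} for a single configuration: the
#' merged segments where the configuration is non-neutral, coalesced back
#' into a validated \linkS4class{CNVCallSet}. Round-tripping reproduces the
#' input call set's per-base copy-number function exactly.
#'
#' @param x a \linkS4class{CCNVExperiment}.
#' @param configuration configuration label or column index.
#' @return A \linkS4class{CNVCallSet}.
#' @export
configurationCalls <- function(x, configuration) {
  stopifnot(is(x, "CCNVExperiment"))
  v <- copyNumbers(x)[, configuration]
  keep <- v != neutralValue(x)
  gr <- rowRanges(x)[keep]
  mcols(gr) <- NULL
  mcols(gr)$value <- v[keep]
  lab <- if (is.character(configuration)) configuration
         else configurationLabels(x)[configuration]
  CNVCallSet(gr, seqinfo(rowRanges(x)),
             genomeLabel = colData(x)[lab, "genome"],
             configLabel = lab, neutralValue = neutralValue(x))
}

#' @describeIn CCNVExperiment-class merged segments as a 0-based half-open
#'   data.frame: chrom, start, end, one value column per configuration.
#' @export
setMethod("segmentTable", "CCNVExperiment", function(x, ...) {
  df <- .tableFromGr(rowRanges(x))
  cbind(df, as.data.frame(copyNumbers(x)))
})

#' Group merged segments into comparative CNV regions
#'
#' A comparative CNV (cCNV) region is a maximal run of abutting merged
#' segments: the base before its start and the base at its end are neutral
#' in every configuration (or a chromosome boundary). Each region is
#' annotated with its fractional overlap with the genic and validated
#' annotation tracks — 0 for no overlap, 1 for full containment, and the
#' covered-base fraction in between.
#'
#' @param x a \linkS4class{CCNVExperiment} from \code{\link{mergeCallSets}}.
#' @param genic,validated optional \linkS4class{RegionTrack}s (or
#'   \code{GRanges}); when omitted the corresponding fraction is \code{NA}.
#' @return A \code{GRanges} of regions with metadata columns
#'   \code{nSegments}, \code{genicOverlap} and \code{validatedOverlap}.
#' @export
setMethod("ccnvRegions", "CCNVExperiment",
          function(x, genic = NULL, validated = NULL) {
  regions <- reduce(rowRanges(x))
  mcols(regions)$nSegments <- countOverlaps(regions, rowRanges(x))
  w <- as.numeric(width(regions))
  frac <- function(track) {
    if (is.null(track)) return(rep(NA_real_, length(regions)))
    tr <- if (is(track, "RegionTrack")) trackRanges(track) else reduce(track)
    .overlapBases(regions, tr) / w
  }
  mcols(regions)$genicOverlap <- frac(genic)
  mcols(regions)$validatedOverlap <- frac(validated)
  regions
})

setMethod("show", "CCNVExperiment", function(object) {
  cat("CCNVExperiment: ", nrow(object), " merged segments x ",
      ncol(object), " configurations (",
      paste(configurationLabels(object), collapse = ", "), ")\n", sep = "")
  cat("  neutral value ", neutralValue(object), "; ",
      length(reduce(rowRanges(object))), " cCNV regions\n", sep = "")
})
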