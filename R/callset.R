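#' Build a validated CNV call set
#'
#' Validates and normalises the raw segment list of one caller configuration
#' into a \linkS4class{CNVCallSet}:
#' \itemize{
#'   \item coordinates are checked against the layout (0-based half-open in
#'     tabular input; BED convention);
#'   \item segments at the neutral copy number are dropped — neutral
#'     stretches are implicit, the call set records variants only;
#'   \item overlapping or adjacent segments with equal values are unioned
#'     (coalesced), which leaves the per-base copy-number function of the
#'     input unchanged;
#'   \item overlapping segments with conflicting values are a hard error
#'     naming the offending locus;
#'   \item zero-length rows are dropped silently.
#' }
#'
#' @param segments either a data.frame with columns \code{chrom},
#'   \code{start}, \code{end} (0-based half-open) and \code{value}, or a
#'   \code{GRanges} (1-based closed, the usual R convention) with a numeric
#'   \code{value} metadata column.
#' @param layout \link[GenomeInfoDb]{Seqinfo} genome layout.
#' @param genomeLabel,configLabel labels identifying the genome and the
#'   caller configuration.
#' @param neutralValue baseline copy number (ploidy); default 2.
#' @return A \linkS4class{CNVCallSet}.
#' @examples
#' lay <- genomeLayout("chr1", 1e6)
#' CNVCallSet(data.frame(chrom = "chr1", start = c(0, 100), end = c(100, 200),
#'                       value = 1),
#'            lay, "g1", "gc")  # coalesces to one chr1:0-200 segment
#' @export
CNVCallSet <- function(segments, layout, genomeLabel = "genome",
                       configLabel = "config", neutralValue = 2) {
  layout <- .asLayout(layout)
  if (is.data.frame(segments)) {
    need <- c("chrom", "start", "end", "value")
    if (!all(need %in% names(segments)))
      stop("segment table needs columns: ", paste(need, collapse = ", "))
    gr <- .grFromTable(segments$chrom, segments$start, segments$end, layout,
                       value = segments$value)
  } else if (is(segments, "GRanges")) {
    if (is.null(mcols(segments)$value))
      stop("GRanges input needs a numeric 'value' metadata column")
    gr <- GRanges(seqnames(segments), ranges(segments), seqinfo = layout)
    mcols(gr)$value <- as.numeric(mcols(segments)$value)
    gr <- gr[width(gr) > 0L]
  } else {
    stop("'segments' must be a data.frame or GRanges")
  }
  if (anyNA(mcols(gr)$value))
    stop("NA copy-number value in input segments")
  if (any(mcols(gr)$value < 0))
    stop("negative copy-number value in input segments")
  gr <- gr[mcols(gr)$value != neutralValue]
  gr <- .coalesceValued(gr)
  new("CNVCallSet", calls = gr, genomeLabel = as.character(genomeLabel),
      configLabel = as.character(configLabel),
      neutralValue = as.numeric(neutralValue))
}

# single sorted pass: union equal-valued overlapping/abutting segments,
# hard error on overlapping conflicting values
.coalesceValued <- function(gr) {
  if (length(gr) == 0L) {
    mcols(gr)$value <- numeric(0)
    return(gr)
  }
  o <- order(as.integer(seqnames(gr)), start(gr), end(gr))
  ch <- as.character(seqnames(gr))[o]
  s <- start(gr)[o]
  e <- end(gr)[o]
  v <- mcols(gr)$value[o]
  n <- length(s)
  oc <- character(n); os <- integer(n); oe <- integer(n); ov <- numeric(n)
  j <- 1L
  oc[1L] <- ch[1L]; os[1L] <- s[1L]; oe[1L] <- e[1L]; ov[1L] <- v[1L]
  for (i in seq_len(n)[-1L]) {
    if (ch[i] == oc[j] && s[i] <= oe[j] + 1L) {
      if (s[i] <= oe[j] && v[i] != ov[j])
        stop("overlapping segments with conflicting values; overlap at ",
             .fmtLocus(ch[i], s[i] - 1L, min(e[i], oe[j])))
      if (v[i] == ov[j]) {
        oe[j] <- max(oe[j], e[i])
        next
      }
    }
    j <- j + 1L
    oc[j] <- ch[i]; os[j] <- s[i]; oe[j] <- e[i]; ov[j] <- v[i]
  }
  keep <- seq_len(j)
  out <- GRanges(factor(oc[keep], levels = seqlevels(gr)),
                 IRanges(os[keep], oe[keep]), seqinfo = seqinfo(gr))
  mcols(out)$value <- ov[keep]
  out
}

# internal: wrap an already-validated GRanges without coalescing (used by
# fragmentSegments, whose abutting equal-valued fragments are intentional)
.newCallSet <- function(gr, template) {
  new("CNVCallSet", calls = gr, genomeLabel = template@genomeLabel,
      configLabel = template@configLabel,
      neutralValue = template@neutralValue)
}

#' @describeIn CNVCallSet-class the call segments as a \code{GRanges} with a
#'   \code{value} metadata column.
#' @param x a \code{CNVCallSet}.
#' @param ... unused.
#' @export
setMethod("cnvSegments", "CNVCallSet", function(x, ...) x@calls)

#' @describeIn CNVCallSet-class genome label.
#' @export
setMethod("genomeLabel", "CNVCallSet", function(x) x@genomeLabel)

#' @describeIn CNVCallSet-class configuration label.
#' @export
setMethod("configLabel", "CNVCallSet", function(x) x@configLabel)

#' @describeIn CNVCallSet-class neutral (baseline ploidy) copy number.
#' @export
setMethod("neutralValue", "CNVCallSet", function(x) x@neutralValue)

#' @describeIn CNVCallSet-class total variant bases in the call set.
#' @export
setMethod("variantBases", "CNVCallSet",
          function(x, ...) sum(as.numeric(width(x@calls))))

#' @describeIn CNVCallSet-class number of segments.
#' @export
setMethod("length", "CNVCallSet", function(x) length(x@calls))

#' @describeIn CNVCallSet-class segments as a 0-based half-open data.frame
#'   (BED-like; columns chrom, start, end, value).
#' @export
setMethod("segmentTable", "CNVCallSet", function(x, ...) .tableFromGr(x@calls))

setMethod("show", "CNVCallSet", function(object) {
  cat("CNVCallSet:", object@genomeLabel, "/", object@configLabel, "\n")
  cat("  ", length(object@calls), " segments, ",
      format(sum(as.numeric(width(object@calls))), big.mark = ","),
      " variant bases (neutral value ", object@neutralValue, ")\n", sep = "")
  cat("  layout:", paste(seqnames(seqinfo(object@calls)), collapse = ", "),
      "\n")
})
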