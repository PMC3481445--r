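#' Build an annotation track as a disjoint interval union
#'
#' Unions arbitrary (possibly overlapping, unsorted, duplicated) input
#' intervals into a sorted disjoint \linkS4class{RegionTrack}. The covered
#' base count is therefore invariant under permutation and duplication of
#' the inputs.
#'
#' @param intervals data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open, BED convention) or a \code{GRanges}
#'   (1-based closed). May be empty.
#' @param layout \link[GenomeInfoDb]{Seqinfo} genome layout; coordinates
#'   outside it are a hard error.
#' @param label track name, e.g. \code{"genic"} or \code{"validated"}.
#' @return A \linkS4class{RegionTrack}.
#' @examples
#' lay <- genomeLayout("chr1", 1e6)
#' RegionTrack(data.frame(chrom = "chr1", start = c(0, 50), end = c(100, 150)),
#'             lay, "genic")  # one interval chr1:0-150
#' @export
RegionTrack <- function(intervals, layout, label = "track") {
  layout <- .asLayout(layout)
  if (is.data.frame(intervals)) {
    if (nrow(intervals) == 0L) {
      gr <- GRanges(seqinfo = layout)
    } else {
      need <- c("chrom", "start", "end")
      if (!all(need %in% names(intervals)))
        stop("interval table needs columns: ", paste(need, collapse = ", "))
      gr <- .grFromTable(intervals$chrom, intervals$start, intervals$end,
                         layout)
    }
  } else if (is(intervals, "GRanges")) {
    gr <- GRanges(seqnames(intervals), ranges(intervals), seqinfo = layout)
    if (length(gr) &&
        any(end(gr) > seqlengths(layout)[as.character(seqnames(gr))]))
      stop("interval end exceeds chromosome length")
  } else {
    stop("'intervals' must be a data.frame or GRanges")
  }
  new("RegionTrack", ranges = reduce(sort(gr)), label = as.character(label))
}

#' @describeIn RegionTrack-class track label.
#' @param x a \code{RegionTrack}.
#' @export
setMethod("trackLabel", "RegionTrack", function(x) x@label)

#' @describeIn RegionTrack-class the disjoint intervals as a \code{GRanges}.
#' @export
setMethod("trackRanges", "RegionTrack", function(x) x@ranges)

#' @describeIn RegionTrack-class total bases covered by the track.
#' @export
setMethod("coveredBases", "RegionTrack",
          function(x) sum(as.numeric(width(x@ranges))))

#' @describeIn RegionTrack-class number of disjoint intervals.
#' @export
setMethod("length", "RegionTrack", function(x) length(x@ranges))

#' @describeIn RegionTrack-class intervals as a 0-based half-open data.frame.
#' @param ... unused.
#' @export
setMethod("segmentTable", "RegionTrack", function(x, ...) .tableFromGr(x@ranges))

setMethod("show", "RegionTrack", function(object) {
  cat("RegionTrack '", object@label, "': ", length(object@ranges),
      " intervals, ", format(sum(as.numeric(width(object@ranges))),
                             big.mark = ","), " bases\n", sep = "")
})

#' Read an annotation track from a BED3 file
#'
#' @param path BED file (first three columns used; 0-based half-open).
#' @param layout \link[GenomeInfoDb]{Seqinfo} genome layout.
#' @param label track label; defaults to the file name without extension.
#' @return A \linkS4class{RegionTrack} (inputs unioned).
#' @export
readTrack <- function(path, layout,
                      label = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("track file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("malformed BED file '", path, "': ",
                                          conditionMessage(e)))
  mcols(gr) <- NULL
  strand(gr) <- "*"
  RegionTrack(gr, layout, label)
}
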