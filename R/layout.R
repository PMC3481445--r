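#' Construct a genome layout
#'
#' A genome layout is the coordinate universe for all base counting: an
#' ordered set of chromosomes with known lengths, represented as a
#' \link[GenomeInfoDb]{Seqinfo} object. All call sets, tracks and merged
#' results in an analysis must share one layout.
#'
#' @param chromosomes character vector of unique, non-empty chromosome names.
#' @param lengths integer vector of positive chromosome lengths in bases.
#' @return A \link[GenomeInfoDb]{Seqinfo}.
#' @examples
#' genomeLayout(c("chr1", "chr2"), c(500000, 500000))
#' @export
genomeLayout <- function(chromosomes, lengths) {
  chromosomes <- as.character(chromosomes)
  lengths <- as.numeric(lengths)
  if (length(chromosomes) != length(lengths))
    stop("'chromosomes' and 'lengths' must have equal length")
  if (anyNA(chromosomes) || any(!nzchar(chromosomes)))
    stop("chromosome names must be non-empty")
  if (anyDuplicated(chromosomes))
    stop("chromosome names must be unique")
  if (anyNA(lengths) || any(lengths <= 0) || any(lengths != round(lengths)))
    stop("chromosome lengths must be positive integers")
  Seqinfo(seqnames = chromosomes, seqlengths = as.integer(lengths))
}

#' Read a genome layout from a two-column TSV or FASTA index
#'
#' Accepts a headerless tab-separated file whose first two columns are
#' chromosome name and length — the shape of a FASTA index (\code{.fai}),
#' which is accepted directly (extra columns are ignored).
#'
#' @param path file path.
#' @return A \link[GenomeInfoDb]{Seqinfo}.
#' @export
readGenomeLayout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L)
    stop("layout file must have >= 2 tab-separated columns (name, length)")
  genomeLayout(df[[1L]], df[[2L]])
}

#' Restrict an object to a named chromosome set
#'
#' Drops all chromosomes outside \code{chromosomes} from a layout, call set,
#' track or merged experiment. The default set is the human autosomes
#' \code{chr1}-\code{chr22}, the usual restriction when sex chromosomes
#' (whose baseline ploidy differs) are excluded from copy-number
#' concordance analysis.
#'
#' @param x a \code{Seqinfo}, \linkS4class{CNVCallSet},
#'   \linkS4class{RegionTrack} or \linkS4class{CCNVExperiment}.
#' @param chromosomes chromosome names to keep; must all be present in the
#'   layout of \code{x}.
#' @return An object of the same class restricted to \code{chromosomes}.
#' @export
keepChromosomes <- function(x, chromosomes = paste0("chr", 1:22)) {
  if (is(x, "Seqinfo")) {
    miss <- base::setdiff(chromosomes, seqnames(x))
    if (length(miss))
      stop("chromosome(s) not in layout: ", paste(miss, collapse = ", "))
    return(x[chromosomes])
  }
  if (is(x, "CNVCallSet")) {
    gr <- keepSeqlevels(x@calls, chromosomes, pruning.mode = "coarse")
    return(new("CNVCallSet", calls = gr, genomeLabel = x@genomeLabel,
               configLabel = x@configLabel, neutralValue = x@neutralValue))
  }
  if (is(x, "RegionTrack")) {
    gr <- keepSeqlevels(x@ranges, chromosomes, pruning.mode = "coarse")
    return(new("RegionTrack", ranges = gr, label = x@label))
  }
  if (is(x, "CCNVExperiment")) {
    keep <- as.character(seqnames(rowRanges(x))) %in% chromosomes
    out <- x[keep, ]
    rowRanges(out) <- keepSeqlevels(rowRanges(out), chromosomes,
                                    pruning.mode = "coarse")
    return(out)
  }
  stop("cannot restrict object of class ", class(x)[1L])
}
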