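# internal helpers shared across modules

# coerce a layout argument to Seqinfo; all lengths must be known
.asLayout <- function(layout) {
  if (!is(layout, "Seqinfo"))
    stop("'layout' must be a Seqinfo object (see genomeLayout())")
  if (length(seqnames(layout)) == 0L)
    stop("'layout' has no chromosomes")
  if (any(is.na(seqlengths(layout))))
    stop("'layout' has chromosomes of unknown length")
  layout
}

# 0-based half-open table -> GRanges on layout (1-based closed internally).
# Zero-length rows (start == end) are dropped silently; start > end and
# out-of-bounds coordinates are hard errors.
.grFromTable <- function(chrom, start, end, layout, value = NULL) {
  layout <- .asLayout(layout)
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (anyNA(chrom) || anyNA(start) || anyNA(end))
    stop("NA in interval coordinates")
  bad <- !(chrom %in% seqnames(layout))
  if (any(bad))
    stop("unknown chromosome(s): ", paste(unique(chrom[bad]), collapse = ", "))
  if (any(start < 0))
    stop("negative start coordinate")
  if (any(start > end))
    stop("start > end in input intervals")
  keep <- start < end
  chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]
  if (!is.null(value)) value <- value[keep]
  lens <- seqlengths(layout)[chrom]
  if (length(end) && any(end > lens))
    stop("interval end exceeds chromosome length at ",
         paste0(chrom[end > lens][1L], ":", start[end > lens][1L], "-",
                end[end > lens][1L]))
  gr <- GRanges(chrom, IRanges(start + 1L, end), seqinfo = layout)
  if (!is.null(value)) mcols(gr)$value <- as.numeric(value)
  gr
}

# GRanges -> 0-based half-open data.frame
.tableFromGr <- function(gr) {
  df <- data.frame(
    chrom = as.character(seqnames(gr)),
    start = start(gr) - 1L,
    end = end(gr),
    stringsAsFactors = FALSE
  )
  if (!is.null(mcols(gr)$value)) df$value <- mcols(gr)$value
  df
}

# total bases of `query` covered by (reduced) `subject`
.overlapBases <- function(query, subject) {
  if (length(query) == 0L || length(subject) == 0L)
    return(numeric(length(query)))
  hits <- findOverlaps(query, subject)
  w <- width(pintersect(query[queryHits(hits)], subject[subjectHits(hits)]))
  out <- numeric(length(query))
  if (length(hits)) {
    s <- tapply(w, queryHits(hits), sum)
    out[as.integer(names(s))] <- as.numeric(s)
  }
  out
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# log-uniform integer lengths in [minLen, maxLen]
.logUniformLengths <- function(n, minLen, maxLen) {
  if (minLen >= maxLen) stop("length range must satisfy min < max")
  pmax(1L, as.integer(round(exp(runif(n, log(minLen), log(maxLen))))))
}

.fmtLocus <- function(chrom, start0, end0) {
  paste0(chrom, ":", format(start0, scientific = FALSE, trim = TRUE), "-",
         format(end0, scientific = FALSE, trim = TRUE))
}
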