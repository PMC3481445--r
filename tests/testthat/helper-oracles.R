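# Independent brute-force oracles: every genomic quantity is recomputed on
# flat per-base vectors (one slot per base of the layout), never through the
# package's interval arithmetic.

toyLayout <- function(nChrom = 2, len = 5e5)
  genomeLayout(paste0("chr", seq_len(nChrom)), rep(len, nChrom))

chromOffsets <- function(layout) {
  lens <- GenomeInfoDb::seqlengths(layout)
  stats::setNames(c(0, cumsum(as.numeric(lens)))[seq_along(lens)],
                  names(lens))
}

totalBasesOf <- function(layout)
  sum(as.numeric(GenomeInfoDb::seqlengths(layout)))

# per-base copy-number vector of a 0-based half-open segment table
baseValuesFromTable <- function(df, layout, neutral = 2) {
  off <- chromOffsets(layout)
  v <- rep(neutral, totalBasesOf(layout))
  for (i in seq_len(nrow(df))) {
    idx <- (off[[df$chrom[i]]] + df$start[i] + 1):(off[[df$chrom[i]]] + df$end[i])
    v[idx] <- df$value[i]
  }
  v
}

baseValuesFromCallSet <- function(cs, layout = NULL) {
  if (is.null(layout)) layout <- GenomeInfoDb::seqinfo(cnvSegments(cs))
  baseValuesFromTable(segmentTable(cs), layout, neutralValue(cs))
}

# per-configuration per-base vectors reconstructed from a merged experiment
baseValuesFromMerged <- function(x) {
  layout <- GenomeInfoDb::seqinfo(SummarizedExperiment::rowRanges(x))
  df <- segmentTable(x)
  labs <- configurationLabels(x)
  lapply(stats::setNames(labs, labs), function(cf) {
    d <- df[c("chrom", "start", "end")]
    d$value <- df[[cf]]
    baseValuesFromTable(d, layout, neutralValue(x))
  })
}

# per-base coverage indicator of a GRanges / RegionTrack
baseCover <- function(x, layout) {
  gr <- if (is(x, "RegionTrack")) trackRanges(x) else x
  off <- chromOffsets(layout)
  v <- logical(totalBasesOf(layout))
  if (length(gr))
    for (i in seq_along(gr)) {
      chrom <- as.character(GenomeInfoDb::seqnames(gr))[i]
      idx <- (off[[chrom]] + BiocGenerics::start(gr)[i]):
             (off[[chrom]] + BiocGenerics::end(gr)[i])
      v[idx] <- TRUE
    }
  v
}

jaccardOracle <- function(a, b, layout) {
  av <- baseCover(a, layout)
  bv <- baseCover(b, layout)
  u <- sum(av | bv)
  if (u == 0) 0 else sum(av & bv) / u
}

# random non-overlapping valued segment table, written independently of the
# package's simulator (pure rejection sampling on a flat coordinate system)
randomSegmentTable <- function(layout, n, seed,
                               values = c(0, 1, 3, 4, 5, 8),
                               lenRange = c(200, 30000)) {
  set.seed(seed)
  lens <- GenomeInfoDb::seqlengths(layout)
  chroms <- names(lens)
  placed <- lapply(stats::setNames(chroms, chroms),
                   function(.) matrix(numeric(0), ncol = 2))
  rows <- list()
  tries <- 0
  while (length(rows) < n && tries < 200 * n) {
    tries <- tries + 1
    chrom <- sample(chroms, 1)
    len <- sample(lenRange[1]:lenRange[2], 1)
    if (len >= lens[[chrom]]) next
    s <- sample(0:(lens[[chrom]] - len), 1)
    e <- s + len
    p <- placed[[chrom]]
    if (nrow(p) && any(s <= p[, 2] + 1 & e >= p[, 1] - 1)) next
    placed[[chrom]] <- rbind(p, c(s, e))
    rows[[length(rows) + 1]] <-
      data.frame(chrom = chrom, start = s, end = e,
                 value = sample(values, 1))
  }
  if (length(rows) < n) stop("helper could not place segments")
  do.call(rbind, rows)
}

randomCallSet <- function(layout, n, seed, config = "cfg", ...) {
  CNVCallSet(randomSegmentTable(layout, n, seed, ...), layout,
             genomeLabel = "toy", configLabel = config)
}

# independent full-enumeration two-sided rank-sum p-value
rankSumEnumerationOracle <- function(x, y) {
  n <- length(x)
  N <- n + length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n)])
  mu <- n * (N + 1) / 2
  picks <- utils::combn(N, n)
  sums <- apply(picks, 2, function(ix) sum(r[ix]))
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-10)
}
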