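mkPair <- function(lay, rowsA, rowsB) {
  list(CNVCallSet(rowsA, lay, "g", "A"), CNVCallSet(rowsB, lay, "g", "B"))
}

test_that("stratified base sets restrict variant bases correctly", {
  lay <- genomeLayout("chr1", 1e6)
  m <- mergeCallSets(mkPair(lay,
    data.frame(chrom = "chr1", start = 0, end = 100, value = 3),
    data.frame(chrom = "chr1", start = 600, end = 700, value = 1)))
  genic <- RegionTrack(data.frame(chrom = "chr1", start = 50, end = 150),
                       lay, "genic")
  g <- baseSet(m, "A", "genic", genic = genic)
  expect_identical(BiocGenerics::start(g) - 1L, 50L)
  expect_identical(BiocGenerics::end(g), 100L)
  ng <- baseSet(m, "A", "nongenic", genic = genic)
  expect_identical(sum(BiocGenerics::width(ng)), 50L)
  expect_error(baseSet(m, "A", "weird", genic = genic), "arg")
  expect_error(baseSet(m, "A", "validated"), "validated track")
})

test_that("genic and non-genic base sets partition the all stratum", {
  lay <- toyLayout(2, 5e4)
  for (seed in 1:10) {
    csets <- lapply(1:2, function(k)
      randomCallSet(lay, 8, seed * 31 + k, config = paste0("c", k),
                    lenRange = c(50, 8000)))
    set.seed(seed)
    tdf <- data.frame(chrom = sample(c("chr1", "chr2"), 8, replace = TRUE),
                      start = sample(0:40000, 8))
    tdf$end <- pmin(5e4, tdf$start + sample(100:9000, 8, replace = TRUE))
    genic <- RegionTrack(tdf, lay, "genic")
    m <- mergeCallSets(csets)
    for (cf in c("c1", "c2")) {
      allS <- baseSet(m, cf, "all")
      g <- baseSet(m, cf, "genic", genic = genic)
      ng <- baseSet(m, cf, "nongenic", genic = genic)
      wa <- sum(as.numeric(BiocGenerics::width(allS)))
      expect_identical(sum(as.numeric(BiocGenerics::width(g))) +
                         sum(as.numeric(BiocGenerics::width(ng))), wa)
      # disjoint partition per base
      expect_identical(baseCover(allS, lay),
                       baseCover(g, lay) | baseCover(ng, lay))
      expect_false(any(baseCover(g, lay) & baseCover(ng, lay)))
    }
  }
  # empty configuration yields empty sets in every stratum
  e <- mergeCallSets(mkPair(lay,
    data.frame(chrom = "chr1", start = 0, end = 100, value = 3),
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               value = numeric())))
  genic <- RegionTrack(data.frame(chrom = "chr1", start = 0, end = 5e4),
                       lay, "genic")
  for (s in c("all", "genic", "nongenic", "validated"))
    expect_identical(
      length(baseSet(e, "B", s, genic = genic, validated = genic)), 0L)
})

test_that("jaccard index matches the per-base oracle and its axioms", {
  lay <- genomeLayout("chr1", 1e6)
  a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100),
                              seqinfo = lay)
  b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150),
                              seqinfo = lay)
  expect_equal(jaccardIndex(a, b), 50 / 150)
  expect_identical(jaccardIndex(a, a), 1)
  disj <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500, 600),
                                 seqinfo = lay)
  expect_identical(jaccardIndex(a, disj), 0)
  none <- GenomicRanges::GRanges(seqinfo = lay)
  expect_identical(jaccardIndex(none, none), 0)

  small <- toyLayout(2, 3e4)
  for (seed in 1:30) {
    set.seed(seed)
    rgr <- function(s) {
      n <- sample(1:6, 1)
      chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
      st <- sample(0:25000, n)
      en <- pmin(3e4, st + sample(100:6000, n, replace = TRUE))
      GenomicRanges::GRanges(chrom, IRanges::IRanges(st + 1, en),
                             seqinfo = small)
    }
    a <- rgr(); b <- rgr()
    ji <- jaccardIndex(a, b)
    expect_equal(ji, jaccardOracle(a, b, small))
    expect_identical(ji, jaccardIndex(b, a))
    expect_true(ji >= 0 && ji <= 1)
  }
})

test_that("bin profiles partition variant bases by copy-number value", {
  lay <- genomeLayout("chr1", 1e6)
  m <- mergeCallSets(mkPair(lay,
    data.frame(chrom = "chr1", start = c(0, 100, 300),
               end = c(100, 300, 350), value = c(1, 4, 8)),
    data.frame(chrom = "chr1", start = 5000, end = 5100, value = 1)))
  expect_identical(binProfile(m, "A"),
                   c(below2 = 100, from2to6 = 200, above6 = 50))
  # all-deletion call set populates only the deletion bin
  expect_identical(binProfile(m, "B"),
                   c(below2 = 100, from2to6 = 0, above6 = 0))
  # empty configuration
  e <- mergeCallSets(mkPair(lay,
    data.frame(chrom = "chr1", start = 0, end = 100, value = 3),
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               value = numeric())))
  expect_identical(binProfile(e, "B"),
                   c(below2 = 0, from2to6 = 0, above6 = 0))
  # bins sum to the stratum's variant total, including genic restriction
  genic <- RegionTrack(data.frame(chrom = "chr1", start = 50, end = 320),
                       lay, "genic")
  bp <- binProfile(m, "A", "genic", genic = genic)
  expect_identical(sum(bp),
    sum(as.numeric(BiocGenerics::width(baseSet(m, "A", "genic",
                                               genic = genic)))))
})

test_that("fraction change is (alternative - reference) / reference per bin", {
  ref <- c(below2 = 1000, from2to6 = 400, above6 = 100)
  alt <- c(below2 = 300, from2to6 = 400, above6 = 150)
  fc <- fractionChange(ref, alt)
  expect_equal(unname(fc), c(-0.70, 0, 0.5))
  expect_identical(fractionChange(ref, ref),
                   c(below2 = 0, from2to6 = 0, above6 = 0))
  expect_warning(
    fc0 <- fractionChange(c(below2 = 0, from2to6 = 10, above6 = 10),
                          c(below2 = 500, from2to6 = 10, above6 = 10)),
    "undefined")
  expect_true(is.na(fc0[["below2"]]))
  expect_error(fractionChange(ref, c(a = 1, b = 2, c = 3)), "names")
})

test_that("across-genome summaries report mean and sample sd", {
  lay <- genomeLayout("chr1", 1e6)
  genic <- RegionTrack(data.frame(chrom = "chr1", start = 0, end = 5e5),
                       lay, "genic")
  mk <- function(shift) mergeCallSets(mkPair(lay,
    data.frame(chrom = "chr1", start = shift, end = shift + 1000,
               value = 3),
    data.frame(chrom = "chr1", start = shift + 500, end = shift + 1500,
               value = 1)))
  rep1 <- concordanceReport(mk(0), genic = genic, validated = genic)
  s1 <- summarizeConcordance(rep1)
  expect_true(all(is.na(s1$jaccard$sd)))
  expect_identical(unique(s1$jaccard$n), 1L)
  rep3 <- concordanceReport(list(mk(0), mk(2000), mk(4000)),
                            genic = genic, validated = genic)
  s3 <- summarizeConcordance(rep3)
  # identical geometry in every genome: sd is exactly 0
  expect_true(all(s3$jaccard$sd == 0))

  # genomes with distinct overlap geometry: JI = (L - off) / (L + off)
  mk2 <- function(off) mergeCallSets(mkPair(lay,
    data.frame(chrom = "chr1", start = 0, end = 1000, value = 3),
    data.frame(chrom = "chr1", start = off, end = off + 1000, value = 1)))
  repd <- concordanceReport(list(mk2(0), mk2(250), mk2(500)),
                            genic = genic, validated = genic)
  want <- c(1, 750 / 1250, 500 / 1500)
  agg <- summarizeConcordance(repd)$jaccard
  agg <- agg[agg$stratum == "all", ]
  expect_equal(agg$mean, sum(want) / 3)
  expect_equal(agg$sd, sqrt(sum((want - mean(want))^2) / 2))
  expect_identical(agg$n, 3L)
})
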