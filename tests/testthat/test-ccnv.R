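test_that("long segments fragment at fixed cut points from the segment start", {
  lay <- genomeLayout("chr1", 1e6)
  cs <- CNVCallSet(data.frame(chrom = "chr1", start = 0, end = 25000,
                              value = 3), lay)
  fr <- fragmentSegments(cs, 10000)
  expect_identical(segmentTable(fr),
                   data.frame(chrom = "chr1",
                              start = c(0L, 10000L, 20000L),
                              end = c(10000L, 20000L, 25000L),
                              value = 3))
  short <- CNVCallSet(data.frame(chrom = "chr1", start = 0, end = 9999,
                                 value = 1), lay)
  expect_identical(segmentTable(fragmentSegments(short, 10000)),
                   segmentTable(short))
  expect_error(fragmentSegments(cs, 0), "positive")
  expect_error(fragmentSegments(cs, -5), "positive")
})

test_that("fragmentation conserves variant bases and per-base values", {
  lay <- toyLayout(2, 1e5)
  for (seed in 1:15) {
    cs <- randomCallSet(lay, 10, seed, lenRange = c(100, 40000))
    fr <- fragmentSegments(cs, 7000)
    expect_true(all(BiocGenerics::width(cnvSegments(fr)) <= 7000))
    expect_identical(variantBases(fr), variantBases(cs))
    expect_identical(baseValuesFromCallSet(fr), baseValuesFromCallSet(cs))
  }
})

test_that("merging reproduces the worked two-configuration example", {
  lay <- genomeLayout("chr1", 1e6)
  a <- CNVCallSet(data.frame(chrom = "chr1", start = 100, end = 300,
                             value = 3), lay, "g", "A")
  b <- CNVCallSet(data.frame(chrom = "chr1", start = 200, end = 400,
                             value = 1), lay, "g", "B")
  m <- mergeCallSets(list(a, b))
  expect_identical(
    segmentTable(m),
    data.frame(chrom = rep("chr1", 3),
               start = c(100L, 200L, 300L), end = c(200L, 300L, 400L),
               A = c(3, 3, 2), B = c(2, 1, 1)))
  expect_identical(configurationLabels(m), c("A", "B"))
  expect_identical(neutralValue(m), 2)
})

test_that("merging handles identical, empty and single-sided call sets", {
  lay <- genomeLayout("chr1", 1e6)
  a <- CNVCallSet(data.frame(chrom = "chr1", start = 100, end = 300,
                             value = 3), lay, "g", "A")
  a2 <- CNVCallSet(data.frame(chrom = "chr1", start = 100, end = 300,
                              value = 3), lay, "g", "B")
  m <- mergeCallSets(list(a, a2))
  expect_identical(nrow(m), 1L)
  expect_identical(unname(copyNumbers(m)[1, ]), c(3, 3))

  emptyB <- CNVCallSet(data.frame(chrom = character(), start = numeric(),
                                  end = numeric(), value = numeric()),
                       lay, "g", "B")
  m2 <- mergeCallSets(list(a, emptyB))
  expect_identical(unname(copyNumbers(m2)[1, ]), c(3, 2))

  expect_error(mergeCallSets(list(a)), ">= 2")
  expect_error(mergeCallSets(list(a, a)), "distinct")
  other <- CNVCallSet(data.frame(chrom = "chrZ", start = 0, end = 10,
                                 value = 1),
                      genomeLayout("chrZ", 100), "g", "B")
  expect_error(mergeCallSets(list(a, other)), "layout")
})

test_that("merged vectors reproduce every configuration per base", {
  lay <- toyLayout(2, 1e5)
  for (seed in 1:25) {
    csets <- lapply(1:3, function(k)
      randomCallSet(lay, 8, seed * 10 + k, config = paste0("c", k),
                    lenRange = c(100, 25000)))
    m <- mergeCallSets(csets, maxFragment = 10000)
    rebuilt <- baseValuesFromMerged(m)
    for (k in 1:3)
      expect_identical(rebuilt[[paste0("c", k)]],
                       baseValuesFromCallSet(csets[[k]]))
    # conservation: non-neutral merged bases equal the input variant bases
    for (k in 1:3)
      expect_identical(variantBases(m, paste0("c", k)),
                       variantBases(csets[[k]]))
  }
})

test_that("merging is idempotent and insensitive to fragmentation", {
  lay <- toyLayout(2, 1e5)
  for (seed in c(3, 11, 27)) {
    csets <- lapply(1:3, function(k)
      randomCallSet(lay, 8, seed * 10 + k, config = paste0("c", k),
                    lenRange = c(100, 25000)))
    m <- mergeCallSets(csets)
    again <- mergeCallSets(lapply(configurationLabels(m), function(cf)
      configurationCalls(m, cf)))
    expect_identical(segmentTable(again), segmentTable(m))
    # per-base vectors do not depend on the fragmentation length
    mInf <- mergeCallSets(csets, maxFragment = Inf)
    expect_identical(baseValuesFromMerged(mInf), baseValuesFromMerged(m))
  }
})

test_that("cCNV regions are maximal runs with base-exact overlap fractions", {
  lay <- genomeLayout("chr1", 1e6)
  mk <- function(rows, cfg) CNVCallSet(rows, lay, "g", cfg)
  a <- mk(data.frame(chrom = "chr1", start = c(100, 500),
                     end = c(200, 600), value = 3), "A")
  b <- mk(data.frame(chrom = "chr1", start = 200, end = 300, value = 1), "B")
  m <- mergeCallSets(list(a, b))
  reg <- ccnvRegions(m)
  # gap between 300 and 500 splits the runs into two regions
  expect_identical(BiocGenerics::start(reg) - 1L, c(100L, 500L))
  expect_identical(BiocGenerics::end(reg), c(300L, 600L))

  genic <- RegionTrack(data.frame(chrom = "chr1", start = 500, end = 1500),
                       lay, "genic")
  big <- mergeCallSets(list(
    mk(data.frame(chrom = "chr1", start = 0, end = 1000, value = 3), "A"),
    mk(data.frame(chrom = "chr1", start = 0, end = 400, value = 1), "B")))
  reg2 <- ccnvRegions(big, genic = genic, validated = genic)
  expect_identical(S4Vectors::mcols(reg2)$genicOverlap, 0.5)
  expect_identical(S4Vectors::mcols(reg2)$validatedOverlap, 0.5)
  # region fully inside a validated interval
  inner <- mergeCallSets(list(
    mk(data.frame(chrom = "chr1", start = 600, end = 900, value = 3), "A"),
    mk(data.frame(chrom = "chr1", start = 700, end = 800, value = 1), "B")))
  expect_identical(
    S4Vectors::mcols(ccnvRegions(inner, validated = genic))$validatedOverlap,
    1)
})

test_that("region overlap fractions match the per-base oracle", {
  lay <- toyLayout(2, 5e4)
  for (seed in 1:10) {
    csets <- lapply(1:2, function(k)
      randomCallSet(lay, 8, seed * 7 + k, config = paste0("c", k),
                    lenRange = c(50, 8000)))
    set.seed(seed + 500)
    tdf <- data.frame(chrom = sample(c("chr1", "chr2"), 10, replace = TRUE),
                      start = sample(0:45000, 10))
    tdf$end <- pmin(5e4, tdf$start + sample(500:8000, 10, replace = TRUE))
    track <- RegionTrack(tdf, lay, "genic")
    m <- mergeCallSets(csets)
    reg <- ccnvRegions(m, genic = track)
    cv <- baseCover(track, lay)
    for (i in seq_along(reg)) {
      rv <- baseCover(reg[i], lay)
      expect_equal(S4Vectors::mcols(reg)$genicOverlap[i],
                   sum(cv & rv) / sum(rv))
    }
  }
})
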