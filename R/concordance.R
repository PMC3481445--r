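#' Variant base set of a configuration within a stratum
#'
#' Extracts the set of bases (as sorted disjoint intervals) where one
#' configuration of a merged experiment is variant, restricted to a
#' stratum: \code{"all"} (no restriction), \code{"genic"} (intersection
#' with the genic track), \code{"nongenic"} (complement of the genic track
#' within the layout), or \code{"validated"} (intersection with the
#' validated track). Genic and non-genic base sets partition the
#' all-stratum set exactly.
#'
#' @param x a \linkS4class{CCNVExperiment}.
#' @param configuration configuration label or column index.
#' @param stratum one of \code{"all"}, \code{"genic"}, \code{"nongenic"},
#'   \code{"validated"}.
#' @param genic,validated \linkS4class{RegionTrack}s (or \code{GRanges});
#'   required for the corresponding strata.
#' @return A reduced \code{GRanges}.
#' @export
baseSet <- function(x, configuration,
                    stratum = c("all", "genic", "nongenic", "validated"),
                    genic = NULL, validated = NULL) {
  stopifnot(is(x, "CCNVExperiment"))
  stratum <- match.arg(stratum)
  v <- copyNumbers(x)[, configuration]
  variant <- reduce(rowRanges(x)[v != neutralValue(x)])
  .restrictToStratum(variant, stratum, genic, validated)
}

.trackGR <- function(track, what) {
  if (is.null(track)) stop("stratum requires the ", what, " track")
  if (is(track, "RegionTrack")) trackRanges(track) else reduce(track)
}

.restrictToStratum <- function(gr, stratum, genic, validated) {
  switch(stratum,
    all = gr,
    genic = GenomicRanges::intersect(gr, .trackGR(genic, "genic")),
    nongenic = GenomicRanges::setdiff(gr, .trackGR(genic, "genic")),
    validated = GenomicRanges::intersect(gr, .trackGR(validated, "validated"))
  )
}

#' Base-pair Jaccard index of two interval sets
#'
#' Concordance of two variant base sets at single-base resolution: the
#' number of bases in their intersection divided by the number of bases in
#' their union. Symmetric, in \code{[0, 1]}, and equal to 1 exactly when
#' the two sets cover the same bases (and are non-empty). When both sets
#' are empty the index is reported as 0 (there is no shared variant signal
#' to credit); downstream report tables flag this case.
#'
#' @param a,b \code{GRanges} (reduced internally), e.g. from
#'   \code{\link{baseSet}}.
#' @return A single number in \code{[0, 1]}.
#' @examples
#' lay <- genomeLayout("chr1", 1e6)
#' a <- GRanges("chr1", IRanges(1, 100), seqinfo = lay)
#' b <- GRanges("chr1", IRanges(51, 150), seqinfo = lay)
#' jaccardIndex(a, b)  # 50 / 150
#' @export
jaccardIndex <- function(a, b) {
  a <- reduce(a)
  b <- reduce(b)
  uni <- sum(as.numeric(width(GenomicRanges::union(a, b))))
  if (uni == 0) return(0)
  inter <- sum(as.numeric(width(GenomicRanges::intersect(a, b))))
  inter / uni
}

#' Copy-number bin profile of a configuration
#'
#' Partitions one configuration's variant bases (within a stratum) into
#' three copy-number bins: deletions (\code{value < 2}), moderate
#' amplifications (\code{2 < value <= 6}) and high amplifications
#' (\code{value > 6}). The neutral value is excluded by construction, so
#' the three bins sum to the configuration's variant base total in the
#' stratum.
#'
#' @inheritParams baseSet
#' @return Named numeric vector \code{c(below2, from2to6, above6)} of base
#'   counts.
#' @export
binProfile <- function(x, configuration,
                       stratum = c("all", "genic", "nongenic", "validated"),
                       genic = NULL, validated = NULL) {
  stopifnot(is(x, "CCNVExperiment"))
  stratum <- match.arg(stratum)
  v <- copyNumbers(x)[, configuration]
  keep <- v != neutralValue(x)
  gr <- rowRanges(x)[keep]
  v <- v[keep]
  if (any(v < 0)) stop("negative copy-number values")
  w <- if (stratum == "all") {
    as.numeric(width(gr))
  } else if (stratum == "nongenic") {
    as.numeric(width(gr)) - .overlapBases(gr, .trackGR(genic, "genic"))
  } else if (stratum == "genic") {
    .overlapBases(gr, .trackGR(genic, "genic"))
  } else {
    .overlapBases(gr, .trackGR(validated, "validated"))
  }
  c(below2 = sum(w[v < 2]),
    from2to6 = sum(w[v > 2 & v <= 6]),
    above6 = sum(w[v > 6]))
}

#' Per-bin fraction change between two bin profiles
#'
#' Relative change of an alternative configuration's binned base counts with
#' respect to a reference configuration:
#' \code{(alternative - reference) / reference} per bin. A value of
#' \code{-0.70} in the deletion bin means 70 percent of the reference's
#' deletion bases are absent from the alternative. Bins empty in the
#' reference yield \code{NA} with a warning.
#'
#' @param reference,alternative named numeric bin profiles from
#'   \code{\link{binProfile}} (matching names).
#' @return Named numeric vector of per-bin fraction changes.
#' @export
fractionChange <- function(reference, alternative) {
  if (!identical(names(reference), names(alternative)))
    stop("bin profiles must have identical bin names")
  out <- (alternative - reference) / reference
  zero <- reference == 0
  if (any(zero)) {
    out[zero] <- NA_real_
    warning("reference bin(s) empty; fraction change undefined for: ",
            paste(names(reference)[zero], collapse = ", "))
  }
  out
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided two-sample rank-sum test on the rank sum of \code{x} within
#' the pooled sample (midranks for ties). For small samples
#' (\code{n + m <= 20}) the p-value is computed by exact enumeration of all
#' \code{choose(n + m, n)} rank assignments, as the probability of a rank
#' sum at least as far from its null expectation as observed; otherwise a
#' normal approximation with the usual tie correction of the variance is
#' used. Degenerate all-tied input yields \code{p = 1} with a warning.
#'
#' @param x,y numeric vectors, each of length \code{>= 2}.
#' @return An object of class \code{"htest"} with components
#'   \code{statistic} (rank sum of \code{x}), \code{p.value} and
#'   \code{method}.
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6))$p.value  # exact two-sided 0.1
#' @export
rankSumTest <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample must contain >= 2 observations")
  if (anyNA(x) || anyNA(y)) stop("NA in input samples")
  n <- length(x)
  m <- length(y)
  N <- n + m
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n)])
  mu <- n * (N + 1) / 2
  ties <- table(r)
  allTied <- length(ties) == 1L
  if (allTied) {
    warning("all observations tied; rank-sum test degenerate, p = 1")
    p <- 1
    method <- "Wilcoxon rank-sum test (degenerate)"
  } else if (N <= 20L) {
    sums <- colSums(matrix(r[combn(N, n)], nrow = n))
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-10)
    method <- "Exact Wilcoxon rank-sum test (full enumeration)"
  } else {
    tieAdj <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tieAdj)
    z <- (w - mu) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "Wilcoxon rank-sum test (normal approximation, tie-corrected)"
  }
  structure(
    list(statistic = c(W = w), p.value = p, method = method,
         alternative = "two.sided",
         data.name = paste(deparse1(substitute(x)), "and",
                           deparse1(substitute(y)))),
    class = "htest"
  )
}
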