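#' Pairwise concordance report across genomes
#'
#' Computes, for one or more genomes, the full concordance summary of a set
#' of merged caller configurations: base-pair Jaccard indices for every
#' configuration pair in every stratum (all / genic / non-genic /
#' validated), copy-number bin profiles per configuration and stratum, and
#' per-bin fraction changes of every non-reference configuration relative
#' to the reference configuration.
#'
#' @param experiments a single \linkS4class{CCNVExperiment} or a list of
#'   them (one per genome; all with the same configuration labels). Genome
#'   names are taken from each experiment's column data.
#' @param genic,validated \linkS4class{RegionTrack}s shared by all genomes,
#'   or lists of tracks parallel to \code{experiments}.
#' @param reference configuration label (or index) serving as the fraction-
#'   change reference; default the first configuration.
#' @return A \linkS4class{ConcordanceReport}.
#' @seealso \code{\link{summarizeConcordance}},
#'   \code{\link{genicNongenicTest}}
#' @export
concordanceReport <- function(experiments, genic, validated, reference = 1L) {
  if (is(experiments, "CCNVExperiment")) experiments <- list(experiments)
  if (!length(experiments) ||
      !all(vapply(experiments, is, logical(1), "CCNVExperiment")))
    stop("'experiments' must be CCNVExperiment object(s)")
  labels <- configurationLabels(experiments[[1L]])
  if (!all(vapply(experiments, function(e)
        identical(configurationLabels(e), labels), logical(1))))
    stop("all experiments must share one configuration-label set")
  refLabel <- if (is.character(reference)) reference else labels[reference]
  if (!refLabel %in% labels)
    stop("unknown reference configuration: ", refLabel)
  nG <- length(experiments)
  trackFor <- function(tr, i) if (is.list(tr)) tr[[i]] else tr
  genomes <- vapply(experiments, function(e)
    unique(colData(e)$genome)[1L], character(1))
  if (anyDuplicated(genomes))
    genomes <- make.unique(genomes)
  strata <- c("all", "genic", "nongenic", "validated")
  bins <- c("below2", "from2to6", "above6")

  ji <- list(); bp <- list(); fc <- list()
  for (i in seq_len(nG)) {
    ex <- experiments[[i]]
    g <- trackFor(genic, i)
    va <- trackFor(validated, i)
    sets <- lapply(setNames(strata, strata), function(s)
      lapply(setNames(labels, labels), function(cf)
        baseSet(ex, cf, s, genic = g, validated = va)))
    profs <- lapply(setNames(strata, strata), function(s)
      lapply(setNames(labels, labels), function(cf)
        binProfile(ex, cf, s, genic = g, validated = va)))
    pairs <- combn(labels, 2L)
    for (s in strata) {
      for (p in seq_len(ncol(pairs))) {
        a <- sets[[s]][[pairs[1L, p]]]
        b <- sets[[s]][[pairs[2L, p]]]
        ji[[length(ji) + 1L]] <- data.frame(
          genome = genomes[i], configA = pairs[1L, p],
          configB = pairs[2L, p], stratum = s,
          jaccard = jaccardIndex(a, b),
          bothEmpty = length(a) == 0L && length(b) == 0L
        )
      }
      for (cf in labels) {
        bp[[length(bp) + 1L]] <- data.frame(
          genome = genomes[i], configuration = cf, stratum = s,
          bin = bins, bases = as.numeric(profs[[s]][[cf]])
        )
        if (cf != refLabel) {
          f <- suppressWarnings(
            fractionChange(profs[[s]][[refLabel]], profs[[s]][[cf]]))
          fc[[length(fc) + 1L]] <- data.frame(
            genome = genomes[i], configuration = cf, stratum = s,
            bin = bins, fractionChange = as.numeric(f)
          )
        }
      }
    }
  }
  new("ConcordanceReport",
      jaccard = do.call(rbind, ji),
      bins = do.call(rbind, bp),
      fractionChange = if (length(fc)) do.call(rbind, fc) else
        data.frame(genome = character(), configuration = character(),
                   stratum = character(), bin = character(),
                   fractionChange = numeric()),
      reference = refLabel)
}

#' @describeIn concordanceReport long-format Jaccard table.
#' @param x a \linkS4class{ConcordanceReport}.
#' @export
jaccardTable <- function(x) {
  stopifnot(is(x, "ConcordanceReport"))
  x@jaccard
}

#' @describeIn concordanceReport long-format bin-profile table.
#' @export
binTable <- function(x) {
  stopifnot(is(x, "ConcordanceReport"))
  x@bins
}

#' @describeIn concordanceReport long-format fraction-change table (relative
#'   to the reference configuration).
#' @export
fractionChangeTable <- function(x) {
  stopifnot(is(x, "ConcordanceReport"))
  x@fractionChange
}

#' Across-genome summary of a concordance report
#'
#' Arithmetic mean and sample standard deviation (\code{n - 1} denominator)
#' of every Jaccard index and fraction-change entry across genomes. With a
#' single genome the standard deviation is reported as \code{NA}.
#'
#' @param x a \linkS4class{ConcordanceReport}.
#' @return A list of two data.frames, \code{jaccard} (configA, configB,
#'   stratum, mean, sd, n) and \code{fractionChange} (configuration,
#'   stratum, bin, mean, sd, n).
#' @export
summarizeConcordance <- function(x) {
  stopifnot(is(x, "ConcordanceReport"))
  agg <- function(df, value, keys) {
    if (!nrow(df))
      return(cbind(df[keys], mean = numeric(0), sd = numeric(0),
                   n = integer(0)))
    sp <- split(df, df[keys], drop = TRUE)
    out <- do.call(rbind, lapply(sp, function(d) {
      v <- d[[value]]
      v <- v[!is.na(v)]
      cbind(d[1L, keys, drop = FALSE],
            data.frame(mean = if (length(v)) mean(v) else NA_real_,
                       sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
                       n = length(v)))
    }))
    rownames(out) <- NULL
    out
  }
  list(
    jaccard = agg(x@jaccard, "jaccard",
                  c("configA", "configB", "stratum")),
    fractionChange = agg(x@fractionChange, "fractionChange",
                         c("configuration", "stratum", "bin"))
  )
}

#' Rank-sum comparison of genic vs non-genic concordance
#'
#' Tests whether Jaccard indices differ between genic and non-genic strata,
#' pooling all genomes and configuration pairs, with the two-sample
#' \code{\link{rankSumTest}}.
#'
#' @param x a \linkS4class{ConcordanceReport}.
#' @return An \code{"htest"} object.
#' @export
genicNongenicTest <- function(x) {
  stopifnot(is(x, "ConcordanceReport"))
  g <- x@jaccard$jaccard[x@jaccard$stratum == "genic"]
  ng <- x@jaccard$jaccard[x@jaccard$stratum == "nongenic"]
  rankSumTest(g, ng)
}

setMethod("show", "ConcordanceReport", function(object) {
  nG <- length(unique(object@jaccard$genome))
  cat("ConcordanceReport: ", nG, " genome(s), reference configuration '",
      object@reference, "'\n", sep = "")
  s <- summarizeConcordance(object)$jaccard
  s <- s[s$stratum == "all", , drop = FALSE]
  for (i in seq_len(nrow(s)))
    cat(sprintf("  JI(%s, %s) all-stratum: mean %.3f (sd %s, n=%d)\n",
                s$configA[i], s$configB[i], s$mean[i],
                ifelse(is.na(s$sd[i]), "NA", sprintf("%.3f", s$sd[i])),
                s$n[i]))
})
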