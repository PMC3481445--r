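#' Describe one simulated caller configuration
#'
#' A configuration profile captures how one caller configuration distorts
#' the shared truth CNV landscape: incomplete detection, boundary jitter,
#' spurious calls, and configuration-specific suppression of deletion
#' calls (the signature behaviour of mappability-style filtering, where
#' low-mappability read-count artifacts that mimic deletions are removed).
#'
#' @param label configuration label.
#' @param detectionProbability probability that a truth segment is called.
#' @param boundaryJitterSd standard deviation (bases) of the Gaussian
#'   perturbation applied to each retained boundary; rounded to integers.
#' @param falseCallRate expected number (Poisson) of spurious calls per
#'   genome.
#' @param deletionSuppression additional probability that a truth deletion
#'   (value below 2) is dropped even when detected.
#' @return A list of class \code{"ConfigurationProfile"}.
#' @export
configurationProfile <- function(label,
                                 detectionProbability = 1,
                                 boundaryJitterSd = 0,
                                 falseCallRate = 0,
                                 deletionSuppression = 0) {
  p <- list(label = as.character(label),
            detectionProbability = detectionProbability,
            boundaryJitterSd = boundaryJitterSd,
            falseCallRate = falseCallRate,
            deletionSuppression = deletionSuppression)
  for (f in c("detectionProbability", "deletionSuppression"))
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || p[[f]] < 0 ||
        p[[f]] > 1)
      stop("'", f, "' must be a probability in [0, 1]")
  if (p$boundaryJitterSd < 0) stop("'boundaryJitterSd' must be >= 0")
  if (p$falseCallRate < 0) stop("'falseCallRate' must be >= 0")
  structure(p, class = "ConfigurationProfile")
}

#' Simulation configuration for synthetic multi-configuration call sets
#'
#' Defines a toy genome, a shared truth CNV landscape, annotation tracks
#' and a set of caller-configuration profiles. The default profiles mirror
#' the qualitative contrast between read-count normalization strategies
#' that motivates the concordance framework: a GC-content-like reference
#' that reports the full landscape, a mappability-like configuration that
#' suppresses 70 percent of deletion calls, and a control-genome-like
#' configuration that adds extra moderate-copy-number calls.
#'
#' @param seed integer RNG seed; every simulation operation is
#'   deterministic given \code{(seed, config)}.
#' @param nChrom,chromLength number of chromosomes and length of each, in
#'   bases.
#' @param nCnvs number of truth CNV segments to place (non-overlapping,
#'   separated by at least one base).
#' @param cnvLengthRange (min, max) truth segment lengths in bases,
#'   log-uniform.
#' @param deletionFraction probability a truth segment is a deletion.
#' @param deletionValues,gainValues copy-number values drawn for deletions
#'   and gains (baseline ploidy 2 excluded by construction).
#' @param profiles list of \code{\link{configurationProfile}}s.
#' @param genicCoverageFraction target fraction of the genome covered by
#'   the simulated genic track.
#' @param validatedOverlapProbability probability that a truth CNV spawns
#'   an overlapping interval in the validated track.
#' @param neutralValue baseline copy number.
#' @return A list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(seed = 1L,
                             nChrom = 2L,
                             chromLength = 5e6,
                             nCnvs = 150L,
                             cnvLengthRange = c(2000L, 20000L),
                             deletionFraction = 0.5,
                             deletionValues = c(0, 1),
                             gainValues = 3:8,
                             profiles = list(
                               configurationProfile("gc"),
                               configurationProfile("mappability",
                                 detectionProbability = 0.9,
                                 boundaryJitterSd = 300,
                                 falseCallRate = 2,
                                 deletionSuppression = 0.7),
                               configurationProfile("control",
                                 detectionProbability = 0.85,
                                 boundaryJitterSd = 500,
                                 falseCallRate = 10)
                             ),
                             genicCoverageFraction = 0.35,
                             validatedOverlapProbability = 0.3,
                             neutralValue = 2) {
  cfg <- list(seed = as.integer(seed), nChrom = as.integer(nChrom),
              chromLength = as.numeric(chromLength),
              nCnvs = as.integer(nCnvs),
              cnvLengthRange = as.numeric(cnvLengthRange),
              deletionFraction = deletionFraction,
              deletionValues = as.numeric(deletionValues),
              gainValues = as.numeric(gainValues),
              profiles = profiles,
              genicCoverageFraction = genicCoverageFraction,
              validatedOverlapProbability = validatedOverlapProbability,
              neutralValue = as.numeric(neutralValue))
  if (cfg$nChrom < 1L || cfg$chromLength < 1)
    stop("layout must have >= 1 chromosome of positive length")
  if (length(cfg$cnvLengthRange) != 2L ||
      cfg$cnvLengthRange[1L] >= cfg$cnvLengthRange[2L])
    stop("'cnvLengthRange' must be (min, max) with min < max")
  for (f in c("deletionFraction", "genicCoverageFraction",
              "validatedOverlapProbability"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("'", f, "' must be in [0, 1]")
  if (any(cfg$deletionValues >= cfg$neutralValue))
    stop("'deletionValues' must lie below the neutral value")
  if (any(cfg$gainValues <= cfg$neutralValue))
    stop("'gainValues' must lie above the neutral value")
  if (cfg$nCnvs * (cfg$cnvLengthRange[2L] + 1) >
      0.8 * cfg$nChrom * cfg$chromLength)
    stop("truth CNVs cannot plausibly be placed without overlap: ",
         "nCnvs * max length exceeds 80% of the genome")
  if (!length(profiles) ||
      !all(vapply(profiles, inherits, logical(1), "ConfigurationProfile")))
    stop("'profiles' must be a list of configurationProfile() objects")
  labs <- vapply(profiles, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop("profile labels must be distinct")
  structure(cfg, class = "SimulationConfig")
}

#' @describeIn simulationConfig the toy genome layout implied by a
#'   configuration (chromosomes \code{chr1..chrN}).
#' @param config a \code{SimulationConfig}.
#' @export
simulateLayout <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  genomeLayout(paste0("chr", seq_len(config$nChrom)),
               rep(config$chromLength, config$nChrom))
}

#' Simulate a truth CNV landscape
#'
#' Places \code{nCnvs} non-overlapping, non-abutting CNV segments on the
#' toy layout. Lengths are log-uniform in \code{cnvLengthRange}; each
#' segment is a deletion with probability \code{deletionFraction} (value
#' drawn uniformly from \code{deletionValues}) and otherwise a gain (value
#' from \code{gainValues}). Deterministic given the config seed.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return A \linkS4class{CNVCallSet} labelled \code{"truth"}.
#' @export
simulateTruth <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  layout <- simulateLayout(config)
  if (config$nCnvs == 0L)
    return(CNVCallSet(data.frame(chrom = character(), start = numeric(),
                                 end = numeric(), value = numeric()),
                      layout, "sim", "truth", config$neutralValue))
  .withSeed(config$seed, {
    chroms <- as.character(seqnames(layout))
    placedS <- lapply(chroms, function(.) numeric(0))
    placedE <- lapply(chroms, function(.) numeric(0))
    names(placedS) <- names(placedE) <- chroms
    segs <- vector("list", config$nCnvs)
    tries <- 0L
    maxTries <- 200L * config$nCnvs
    i <- 1L
    while (i <= config$nCnvs) {
      if (tries >= maxTries)
        stop("could not place ", config$nCnvs,
             " non-overlapping truth CNVs after ", maxTries, " attempts")
      tries <- tries + 1L
      len <- .logUniformLengths(1L, config$cnvLengthRange[1L],
                                config$cnvLengthRange[2L])
      chrom <- sample(chroms, 1L)
      maxStart <- config$chromLength - len
      if (maxStart < 0) next
      s <- floor(runif(1L, 0, maxStart + 1))  # 0-based
      e <- s + len
      # require a gap of >= 1 base to already-placed segments
      ps <- placedS[[chrom]]; pe <- placedE[[chrom]]
      if (length(ps) && any(s <= pe + 1 & e >= ps - 1)) next
      placedS[[chrom]] <- c(ps, s)
      placedE[[chrom]] <- c(pe, e)
      isDel <- runif(1L) < config$deletionFraction
      val <- if (isDel) sample(config$deletionValues, 1L)
             else sample(config$gainValues, 1L)
      segs[[i]] <- data.frame(chrom = chrom, start = s, end = e,
                              value = val)
      i <- i + 1L
    }
    CNVCallSet(do.call(rbind, segs), layout, "sim", "truth",
               config$neutralValue)
  })
}

#' Simulate one caller configuration's call set from truth
#'
#' Applies a \code{\link{configurationProfile}} to a truth call set: each
#' truth segment is retained with \code{detectionProbability} (deletions
#' are additionally dropped with probability \code{deletionSuppression});
#' retained boundaries are perturbed by rounded Gaussian jitter, clipped to
#' the layout with a minimum length of one base; segments overlapping
#' after jitter are truncated at the midpoint of the overlap; and a
#' Poisson number of false calls with random loci and values is added (a
#' false call colliding with a retained segment is re-drawn a bounded
#' number of times, then skipped).
#'
#' @param truth a \linkS4class{CNVCallSet}, typically from
#'   \code{\link{simulateTruth}}.
#' @param profile a \code{\link{configurationProfile}}.
#' @param seed integer seed for this configuration's randomness.
#' @param config optional \code{\link{simulationConfig}} supplying false-
#'   call lengths and values; defaults match \code{simulationConfig()}.
#' @return A validated \linkS4class{CNVCallSet} labelled with the profile.
#' @export
simulateConfiguration <- function(truth, profile, seed, config = NULL) {
  stopifnot(is(truth, "CNVCallSet"),
            inherits(profile, "ConfigurationProfile"))
  lenRange <- if (is.null(config)) c(2000, 20000) else config$cnvLengthRange
  valPool <- if (is.null(config)) c(0, 1, 3:8)
             else c(config$deletionValues, config$gainValues)
  layout <- seqinfo(cnvSegments(truth))
  nv <- neutralValue(truth)
  .withSeed(seed, {
    df <- segmentTable(truth)
    if (nrow(df)) {
      keep <- runif(nrow(df)) < profile$detectionProbability
      isDel <- df$value < nv
      keep <- keep & !(isDel & runif(nrow(df)) < profile$deletionSuppression)
      df <- df[keep, , drop = FALSE]
    }
    if (nrow(df) && profile$boundaryJitterSd > 0) {
      lens <- seqlengths(layout)[df$chrom]
      df$start <- df$start + round(rnorm(nrow(df), 0,
                                         profile$boundaryJitterSd))
      df$end <- df$end + round(rnorm(nrow(df), 0, profile$boundaryJitterSd))
      df$start <- pmax(0, pmin(df$start, lens - 1))
      df$end <- pmax(df$start + 1, pmin(df$end, lens))
      df <- .resolveOverlapsMidpoint(df)
    }
    nFalse <- rpois(1L, profile$falseCallRate)
    if (nFalse > 0L) {
      fc <- vector("list", nFalse)
      for (j in seq_len(nFalse)) {
        for (attempt in seq_len(20L)) {
          len <- .logUniformLengths(1L, lenRange[1L], lenRange[2L])
          chrom <- sample(as.character(seqnames(layout)), 1L)
          maxStart <- seqlengths(layout)[chrom] - len
          if (maxStart < 0) next
          s <- floor(runif(1L, 0, maxStart + 1))
          e <- s + len
          here <- df$chrom == chrom
          if (!any(here & df$start < e & df$end > s)) {
            row <- data.frame(chrom = chrom, start = s, end = e,
                              value = sample(valPool, 1L))
            fc[[j]] <- row
            df <- rbind(df, row)
            break
          }
        }
      }
    }
    CNVCallSet(df, layout, genomeLabel(truth), profile$label, nv)
  })
}

# truncate overlapping jittered segments at the midpoint of the overlap;
# segments emptied by truncation are dropped
.resolveOverlapsMidpoint <- function(df) {
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  drop <- logical(nrow(df))
  for (i in seq_len(nrow(df))[-1L]) {
    prev <- i - 1L
    while (prev >= 1L && drop[prev]) prev <- prev - 1L
    if (prev < 1L) next
    if (df$chrom[i] == df$chrom[prev] && df$start[i] < df$end[prev]) {
      mid <- floor((df$start[i] + df$end[prev]) / 2)
      df$end[prev] <- mid
      df$start[i] <- mid
      if (df$start[i] >= df$end[i]) drop[i] <- TRUE
      if (df$start[prev] >= df$end[prev]) drop[prev] <- TRUE
    }
  }
  df[!drop, , drop = FALSE]
}

#' Simulate genic and validated annotation tracks
#'
#' The genic track accumulates random gene-sized intervals (log-uniform
#' 5-50 kb) until their union covers at least
#' \code{genicCoverageFraction} of the layout, emulating a RefGene-like
#' gene-body track. The validated track gives each truth CNV, with
#' probability \code{validatedOverlapProbability}, an overlapping interval
#' extended by up to 5 kb on each side, emulating an externally validated
#' CNV catalogue enriched at true variant sites.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param truth a \linkS4class{CNVCallSet} of truth segments.
#' @return A list with elements \code{genic} and \code{validated}, both
#'   \linkS4class{RegionTrack}s.
#' @export
simulateTracks <- function(config, truth) {
  stopifnot(inherits(config, "SimulationConfig"), is(truth, "CNVCallSet"))
  layout <- simulateLayout(config)
  total <- sum(as.numeric(seqlengths(layout)))
  .withSeed(config$seed + 101L, {
    genic <- GRanges(seqinfo = layout)
    target <- config$genicCoverageFraction * total
    if (target > 0) {
      # add gene-sized intervals one at a time so the realized coverage
      # overshoots the target by at most one interval
      while (sum(as.numeric(width(genic))) < target) {
        len <- .logUniformLengths(1L, 5e3, 5e4)
        chrom <- sample(as.character(seqnames(layout)), 1L)
        maxStart <- max(0, seqlengths(layout)[chrom] - len)
        s <- floor(runif(1L, 0, maxStart + 1))
        cand <- GRanges(chrom, IRanges(s + 1, min(s + len, seqlengths(layout)[chrom])),
                        seqinfo = layout)
        genic <- reduce(c(genic, cand))
      }
    }
    genicTrack <- RegionTrack(genic, layout, "genic")

    df <- segmentTable(truth)
    valid <- GRanges(seqinfo = layout)
    if (nrow(df)) {
      hit <- runif(nrow(df)) < config$validatedOverlapProbability
      df <- df[hit, , drop = FALSE]
      if (nrow(df)) {
        lens <- seqlengths(layout)[df$chrom]
        s <- pmax(0, df$start - floor(runif(nrow(df), 0, 5000)))
        e <- pmin(lens, df$end + floor(runif(nrow(df), 0, 5000)))
        valid <- GRanges(df$chrom, IRanges(s + 1, e), seqinfo = layout)
      }
    }
    list(genic = genicTrack,
         validated = RegionTrack(valid, layout, "validated"))
  })
}

#' Run a full synthetic study
#'
#' Convenience driver: simulates the layout, truth landscape, annotation
#' tracks and one call set per configured profile (each from its own
#' deterministic sub-seed), and merges the call sets into a
#' \linkS4class{CCNVExperiment}.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param maxFragment fragmentation length for the merge (bases).
#' @return A list: \code{layout}, \code{truth}, \code{genic},
#'   \code{validated}, \code{callsets} (named list of
#'   \linkS4class{CNVCallSet}s) and \code{merged}
#'   (\linkS4class{CCNVExperiment}).
#' @export
simulateStudy <- function(config, maxFragment = 10000L) {
  stopifnot(inherits(config, "SimulationConfig"))
  truth <- simulateTruth(config)
  tracks <- simulateTracks(config, truth)
  labs <- vapply(config$profiles, `[[`, character(1), "label")
  callsets <- lapply(seq_along(config$profiles), function(i)
    simulateConfiguration(truth, config$profiles[[i]],
                          seed = config$seed + 1000L + i, config = config))
  names(callsets) <- labs
  merged <- mergeCallSets(callsets, maxFragment = maxFragment)
  list(layout = simulateLayout(config), truth = truth,
       genic = tracks$genic, validated = tracks$validated,
       callsets = callsets, merged = merged)
}
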