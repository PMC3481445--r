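#' Read a CNV call table in a caller-output dialect
#'
#' Supported dialects:
#' \describe{
#'   \item{\code{bed4}}{headerless BED-like TSV: chrom, start, end, copy
#'     number; 0-based half-open.}
#'   \item{\code{freec}}{headerless TSV as written by FREEC-style callers:
#'     chrom, start, end, copy number, status; 1-based inclusive
#'     coordinates (converted on ingest; override with \code{oneBased}).
#'     The numeric copy number is authoritative; the gain/loss status
#'     column is ignored. A missing \code{chr} prefix is added when the
#'     layout uses one.}
#'   \item{\code{cnvseq}}{header TSV of windowed log2 ratios as written by
#'     CNV-seq-style callers: columns \code{chrom} (or
#'     \code{chromosome}), \code{start}, \code{end}, \code{log2},
#'     \code{p.value}; 1-based inclusive windows. Runs of at least
#'     \code{minWindows} contiguous windows with \code{p.value} below
#'     \code{pThreshold} become one segment whose value is
#'     \code{2 * 2^mean(log2)} rounded to 2 decimals.}
#' }
#'
#' @param path input file.
#' @param dialect one of \code{"bed4"}, \code{"freec"}, \code{"cnvseq"}.
#' @param layout \link[GenomeInfoDb]{Seqinfo} genome layout.
#' @param genomeLabel,configLabel labels for the resulting call set.
#' @param neutralValue baseline copy number (default 2).
#' @param pThreshold,minWindows cnvseq dialect: significance threshold
#'   (default \code{1e-4}) and minimum run length (default 6 windows).
#' @param oneBased freec dialect: set \code{FALSE} if the file is already
#'   0-based half-open.
#' @return A validated \linkS4class{CNVCallSet}.
#' @export
readCallSet <- function(path, dialect = c("bed4", "freec", "cnvseq"),
                        layout, genomeLabel = "genome",
                        configLabel = "config", neutralValue = 2,
                        pThreshold = 1e-4, minWindows = 6L,
                        oneBased = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("call-set file not found: ", path)
  layout <- .asLayout(layout)
  df <- switch(dialect,
    bed4 = .readBed4(path),
    freec = .readFreec(path, layout, oneBased),
    cnvseq = .readCnvseq(path, pThreshold, minWindows)
  )
  CNVCallSet(df, layout, genomeLabel, configLabel, neutralValue)
}

.splitLines <- function(path, skipHeader = FALSE) {
  lines <- readLines(path, warn = FALSE)
  idx <- seq_along(lines)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#") &
    !startsWith(lines, "track")
  lines <- lines[keep]
  idx <- idx[keep]
  if (skipHeader && length(lines)) {
    lines <- lines[-1L]
    idx <- idx[-1L]
  }
  list(fields = strsplit(lines, "[\t ]+"), lineno = idx)
}

.numField <- function(fields, lineno, col, path, what) {
  v <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), col)))
  bad <- which(is.na(v))
  if (length(bad))
    stop("malformed ", what, " at line ", lineno[bad[1L]], " of ", path)
  v
}

.readBed4 <- function(path) {
  sl <- .splitLines(path)
  if (!length(sl$fields))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric()))
  short <- lengths(sl$fields) < 4L
  if (any(short))
    stop("malformed row (need 4 columns) at line ",
         sl$lineno[which(short)[1L]], " of ", path)
  data.frame(
    chrom = vapply(sl$fields, `[`, character(1), 1L),
    start = .numField(sl$fields, sl$lineno, 2L, path, "start"),
    end = .numField(sl$fields, sl$lineno, 3L, path, "end"),
    value = .numField(sl$fields, sl$lineno, 4L, path, "value")
  )
}

.readFreec <- function(path, layout, oneBased) {
  sl <- .splitLines(path)
  if (!length(sl$fields))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric()))
  # tolerate a header line on the first row
  if (is.na(suppressWarnings(as.numeric(sl$fields[[1L]][2L])))) {
    sl$fields <- sl$fields[-1L]
    sl$lineno <- sl$lineno[-1L]
  }
  short <- lengths(sl$fields) < 4L
  if (any(short))
    stop("malformed row (need >= 4 columns) at line ",
         sl$lineno[which(short)[1L]], " of ", path)
  chrom <- vapply(sl$fields, `[`, character(1), 1L)
  known <- seqnames(layout)
  fix <- !(chrom %in% known) & paste0("chr", chrom) %in% known
  chrom[fix] <- paste0("chr", chrom[fix])
  start <- .numField(sl$fields, sl$lineno, 2L, path, "start")
  end <- .numField(sl$fields, sl$lineno, 3L, path, "end")
  data.frame(
    chrom = chrom,
    start = if (oneBased) start - 1 else start,
    end = end,
    value = .numField(sl$fields, sl$lineno, 4L, path, "copy number")
  )
}

.readCnvseq <- function(path, pThreshold, minWindows) {
  df <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) stop("malformed cnvseq table '", path, "': ",
                             conditionMessage(e)))
  names(df) <- sub("^chromosome$", "chrom", names(df))
  names(df)[names(df) %in% c("p.value", "pvalue", "p_value")] <- "p.value"
  need <- c("chrom", "start", "end", "log2", "p.value")
  if (!all(need %in% names(df)))
    stop("cnvseq table needs columns: ", paste(need, collapse = ", "))
  for (cc in c("start", "end", "log2", "p.value")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v) && !all(is.na(df[[cc]]) == is.na(v)))
      stop("malformed numeric column '", cc, "' in ", path)
    df[[cc]] <- v
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  sig <- !is.na(df$p.value) & df$p.value < pThreshold & !is.na(df$log2)
  if (!any(sig))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric()))
  n <- nrow(df)
  contiguousPrev <- c(FALSE, df$chrom[-1L] == df$chrom[-n] &
                        df$start[-1L] == df$end[-n] + 1)
  newRun <- sig & !(c(FALSE, sig[-n]) & contiguousPrev)
  runId <- cumsum(newRun)
  runId[!sig] <- NA
  runs <- split(which(sig), runId[sig])
  segs <- lapply(runs, function(ix) {
    if (length(ix) < minWindows) return(NULL)
    data.frame(chrom = df$chrom[ix[1L]],
               start = df$start[ix[1L]] - 1,  # 1-based -> 0-based
               end = df$end[ix[length(ix)]],
               value = round(2 * 2^mean(df$log2[ix]), 2))
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (!length(segs))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric()))
  do.call(rbind, segs)
}

#' Write a call set to disk
#'
#' \code{bed4} writes the 0-based half-open chrom/start/end/value table
#' (round-trips exactly through \code{\link{readCallSet}}); \code{freec}
#' writes 1-based inclusive coordinates with a gain/loss status column.
#'
#' @param x a \linkS4class{CNVCallSet}.
#' @param path output file.
#' @param format \code{"bed4"} or \code{"freec"}.
#' @return \code{path}, invisibly.
#' @export
writeCallSet <- function(x, path, format = c("bed4", "freec")) {
  stopifnot(is(x, "CNVCallSet"))
  format <- match.arg(format)
  df <- segmentTable(x)
  if (format == "freec") {
    df <- data.frame(chrom = df$chrom, start = df$start + 1, end = df$end,
                     value = df$value,
                     status = ifelse(df$value > neutralValue(x),
                                     "gain", "loss"))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write merged comparative CNV segments as TSV
#'
#' One row per merged segment: chrom, start, end (0-based half-open), one
#' copy-number column per configuration, the id of the cCNV region the
#' segment belongs to, and that region's genic / validated overlap
#' fractions (NA when a track is not supplied).
#'
#' @param x a \linkS4class{CCNVExperiment}.
#' @param path output file.
#' @param genic,validated optional \linkS4class{RegionTrack}s.
#' @return \code{path}, invisibly.
#' @export
writeCCNVTable <- function(x, path, genic = NULL, validated = NULL) {
  stopifnot(is(x, "CCNVExperiment"))
  df <- segmentTable(x)
  regions <- ccnvRegions(x, genic = genic, validated = validated)
  hits <- findOverlaps(rowRanges(x), regions)
  reg <- integer(nrow(df))
  reg[queryHits(hits)] <- subjectHits(hits)
  df$region <- reg
  df$genic_overlap <- mcols(regions)$genicOverlap[reg]
  df$validated_overlap <- mcols(regions)$validatedOverlap[reg]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
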