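#' @export
setGeneric("cnvSegments", function(x, ...) standardGeneric("cnvSegments"))

#' @export
setGeneric("genomeLabel", function(x) standardGeneric("genomeLabel"))

#' @export
setGeneric("configLabel", function(x) standardGeneric("configLabel"))

#' @export
setGeneric("neutralValue", function(x) standardGeneric("neutralValue"))

#' @export
setGeneric("variantBases", function(x, ...) standardGeneric("variantBases"))

#' @export
setGeneric("trackLabel", function(x) standardGeneric("trackLabel"))

#' @export
setGeneric("trackRanges", function(x) standardGeneric("trackRanges"))

#' @export
setGeneric("coveredBases", function(x) standardGeneric("coveredBases"))

#' @export
setGeneric("fragmentSegments",
  function(x, maxFragment = 10000L) standardGeneric("fragmentSegments"))

#' @export
setGeneric("copyNumbers", function(x) standardGeneric("copyNumbers"))

#' @export
setGeneric("configurationLabels",
  function(x) standardGeneric("configurationLabels"))

#' @export
setGeneric("ccnvRegions",
  function(x, genic = NULL, validated = NULL)
    standardGeneric("ccnvRegions"))

#' @export
setGeneric("overlapSummary",
  function(x, genic = NULL, validated = NULL, configuration = NULL)
    standardGeneric("overlapSummary"))

#' @export
setGeneric("segmentTable", function(x, ...) standardGeneric("segmentTable"))
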