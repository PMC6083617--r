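#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setGeneric("effectAllele", function(x) standardGeneric("effectAllele"))

#' @export
setGeneric("otherAllele", function(x) standardGeneric("otherAllele"))

#' @export
setGeneric("effectWeights", function(x) standardGeneric("effectWeights"))

#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @export
setGeneric("effectAF", function(x) standardGeneric("effectAF"))

#' @export
setGeneric("allele1", function(x) standardGeneric("allele1"))

#' @export
setGeneric("allele2", function(x) standardGeneric("allele2"))

#' @export
setGeneric("alleleFrequency", function(x, ...) standardGeneric("alleleFrequency"))

#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @export
setGeneric("hardCalls", function(x) standardGeneric("hardCalls"))

#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @export
setGeneric("rawSums", function(x) standardGeneric("rawSums"))

#' @export
setGeneric("snpCounts", function(x) standardGeneric("snpCounts"))

#' @export
setGeneric("avgScores", function(x) standardGeneric("avgScores"))

#' @export
setGeneric("scoredSnps", function(x, ...) standardGeneric("scoredSnps"))

#' @export
setGeneric("discardedSnps", function(x) standardGeneric("discardedSnps"))
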