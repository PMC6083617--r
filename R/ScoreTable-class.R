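#' Samples x thresholds polygenic-score table
#'
#' Holds, for every sample and every p-value threshold, the raw weighted
#' dosage sum, the number of SNPs that contributed (non-missing genotype and
#' discovery p-value at or below the threshold), and -- derived -- the
#' averaged score `raw / count`. SNP counts are per sample because
#' missingness varies across participants; the average is undefined (`NA`)
#' when no SNP contributed, never coerced to zero.
#'
#' @slot sample_ids character, cohort order.
#' @slot thresholds numeric, strictly increasing, in (0, 1].
#' @slot raw numeric samples x thresholds matrix of weighted dosage sums.
#' @slot counts integer samples x thresholds matrix of contributing SNPs.
#'
#' @seealso [scorePanel()], [writeScores()], [avgScores()]
#' @export
setClass("ScoreTable",
         representation(sample_ids = "character", thresholds = "numeric",
                        raw = "matrix", counts = "matrix"))

.check_thresholds <- function(th) {
  if (!length(th)) return("thresholds must be non-empty")
  if (any(!is.finite(th) | th <= 0 | th > 1))
    return("thresholds must lie in (0, 1]")
  if (is.unsorted(th, strictly = TRUE))
    return("thresholds must be strictly increasing")
  TRUE
}

setValidity("ScoreTable", function(object) {
  msg <- character()
  tchk <- .check_thresholds(object@thresholds)
  if (!isTRUE(tchk)) msg <- c(msg, tchk)
  dims <- c(length(object@sample_ids), length(object@thresholds))
  if (!all(dim(object@raw) == dims) || !all(dim(object@counts) == dims))
    msg <- c(msg, "raw and counts must be samples x thresholds")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(object@thresholds) > 1L &&
      any(apply(object@counts, 1L, function(r) any(diff(r) < 0))))
    msg <- c(msg, "counts must be non-decreasing in threshold")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

ScoreTable <- function(sample_ids, thresholds, raw, counts) {
  dimnames(raw) <- dimnames(counts) <-
    list(sample_ids, sprintf("%g", thresholds))
  new("ScoreTable", sample_ids = sample_ids, thresholds = thresholds,
      raw = raw, counts = matrix(as.integer(counts), nrow(counts),
                                 ncol(counts), dimnames = dimnames(counts)))
}

#' @describeIn ScoreTable-class cohort sample ids.
#' @param x a `ScoreTable`.
#' @export
setMethod("sampleIds", "ScoreTable", function(x) x@sample_ids)

#' @describeIn ScoreTable-class p-value thresholds.
#' @export
setMethod("thresholds", "ScoreTable", function(x) x@thresholds)

#' @describeIn ScoreTable-class raw weighted dosage sums.
#' @export
setMethod("rawSums", "ScoreTable", function(x) x@raw)

#' @describeIn ScoreTable-class per-sample contributing-SNP counts.
#' @export
setMethod("snpCounts", "ScoreTable", function(x) x@counts)

#' @describeIn ScoreTable-class averaged scores, `NA` where the count is 0.
#' @export
setMethod("avgScores", "ScoreTable", function(x) {
  avg <- x@raw / x@counts
  avg[x@counts == 0L] <- NA_real_
  avg
})

setMethod("show", "ScoreTable", function(object) {
  cat(sprintf("ScoreTable: %d samples x %d thresholds (%s)\n",
              length(object@sample_ids), length(object@thresholds),
              paste(sprintf("%g", object@thresholds), collapse = ", ")))
  cat(sprintf("  SNP counts at max threshold: %d-%d\n",
              min(object@counts[, ncol(object@counts)]),
              max(object@counts[, ncol(object@counts)])))
  invisible(NULL)
})
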