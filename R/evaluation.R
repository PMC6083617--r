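#' Regress a phenotype on the PRS at one threshold
#'
#' Ordinary least squares of the phenotype on the averaged score at the
#' given threshold. Samples with an undefined score or a missing phenotype
#' are dropped pairwise. Reports unadjusted R-squared, the F statistic on
#' (1, n-2) degrees of freedom, its two-sided p-value and the slope sign.
#'
#' @param scores a [ScoreTable-class].
#' @param phenotype data frame with columns `sample_id` and `phenotype`
#'   (any second column name is accepted).
#' @param threshold one of `thresholds(scores)`.
#' @return One-row data frame: `threshold`, `n`, `r_squared`, `f_stat`,
#'   `p_value`, `slope_sign`, `zero_variance`. A zero-variance PRS flags the
#'   fit as undefined (`r_squared = NA`, `zero_variance = TRUE`).
#' @export
fitPrsPhenotype <- function(scores, phenotype, threshold) {
  j <- match(threshold, thresholds(scores))
  if (is.na(j)) stop("threshold ", threshold, " not in the score table")
  if (!"sample_id" %in% colnames(phenotype))
    stop("phenotype table needs a sample_id column")
  y_col <- setdiff(colnames(phenotype), "sample_id")[1L]
  x <- avgScores(scores)[, j]
  y <- phenotype[[y_col]][match(sampleIds(scores), phenotype$sample_id)]
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L)
    stop("fewer than 3 complete (score, phenotype) pairs at threshold ",
         threshold)
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0) {
    return(data.frame(threshold = threshold, n = n, r_squared = NA_real_,
                      f_stat = NA_real_, p_value = NA_real_,
                      slope_sign = 0L, zero_variance = TRUE))
  }
  fit <- lm(y ~ x)
  s <- summary(fit)
  r2 <- s$r.squared
  fstat <- if (r2 >= 1) Inf else (n - 2) * r2 / (1 - r2)
  p <- if (is.infinite(fstat)) 0 else pf(fstat, 1, n - 2, lower.tail = FALSE)
  data.frame(threshold = threshold, n = n, r_squared = r2, f_stat = fstat,
             p_value = max(p, .Machine$double.xmin),
             slope_sign = as.integer(sign(coef(fit)[["x"]])),
             zero_variance = FALSE)
}

#' Fit the phenotype at every threshold of a score table
#'
#' @inheritParams fitPrsPhenotype
#' @return Data frame of [fitPrsPhenotype()] rows, one per threshold, with a
#'   logical `best` column marking the best fit.
#' @export
fitThresholds <- function(scores, phenotype) {
  fits <- do.call(rbind, lapply(thresholds(scores), function(t)
    fitPrsPhenotype(scores, phenotype, t)))
  fits$best <- FALSE
  fits$best[.best_row(fits)] <- TRUE
  fits
}

.best_row <- function(fits) {
  ok <- which(!is.na(fits$r_squared))
  if (!length(ok)) stop("no defined fit to select from")
  # max R^2; ties go to the smaller threshold (more parsimonious score)
  ok[order(-fits$r_squared[ok], fits$threshold[ok])][1L]
}

#' Select the best-fitting threshold
#'
#' @param fits data frame of fit rows from [fitThresholds()] or repeated
#'   [fitPrsPhenotype()] calls.
#' @return The single best row: maximal R-squared, ties broken toward the
#'   smaller threshold.
#' @export
bestFit <- function(fits) {
  if (!nrow(fits)) stop("no fits supplied")
  fits[.best_row(fits), , drop = FALSE]
}

#' Read a two-column phenotype table
#'
#' @param path delimited text with a header; first column sample id, second
#'   the phenotype value.
#' @return Data frame with columns `sample_id`, `phenotype`.
#' @export
readPhenotype <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("phenotype file needs two columns: ", path)
  data.frame(sample_id = as.character(tab[[1L]]),
             phenotype = as.numeric(tab[[2L]]))
}
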