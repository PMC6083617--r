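#' Discovery GWAS summary statistics
#'
#' A `GwasStats` holds one row per discovery SNP: the effect allele, the other
#' allele (optionally absent), the per-allele weight on the natural-log
#' odds-ratio / beta scale, the association p-value, and optionally the
#' effect-allele frequency in the discovery cohort. It extends
#' [S4Vectors::DataFrame] so the usual subsetting and column access work; the
#' columns are fixed and validated.
#'
#' @slot .Data,rownames,nrows inherited from `DFrame`.
#'
#' @section Columns:
#' \describe{
#'   \item{snp_id}{character, unique rsIDs.}
#'   \item{effect_allele}{character, one of A/C/G/T.}
#'   \item{other_allele}{character, one of A/C/G/T or `NA`.}
#'   \item{weight}{numeric, finite; `ln(OR)` for odds-ratio inputs, the beta
#'     itself otherwise.}
#'   \item{p_value}{numeric in (0, 1].}
#'   \item{effect_af}{numeric strictly in (0, 1), or `NA` when the discovery
#'     file reports no frequency.}
#' }
#'
#' @seealso [readSummaryStats()], [dedupStats()]
#' @export
setClass("GwasStats", contains = "DFrame")

.GWAS_COLS <- c("snp_id", "effect_allele", "other_allele",
                "weight", "p_value", "effect_af")

setValidity("GwasStats", function(object) {
  msg <- character()
  missing_cols <- setdiff(.GWAS_COLS, colnames(object))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  ea <- object$effect_allele
  oa <- object$other_allele
  if (!all(ea %in% c("A", "C", "G", "T")))
    msg <- c(msg, "effect_allele must be one of A/C/G/T")
  if (!all(is.na(oa) | oa %in% c("A", "C", "G", "T")))
    msg <- c(msg, "other_allele must be A/C/G/T or NA")
  if (any(!is.na(oa) & oa == ea))
    msg <- c(msg, "effect_allele must differ from other_allele")
  if (!all(is.finite(object$weight)))
    msg <- c(msg, "weights must be finite")
  p <- object$p_value
  if (!all(is.finite(p) & p > 0 & p <= 1))
    msg <- c(msg, "p_value must lie in (0, 1]")
  af <- object$effect_af
  if (!all(is.na(af) | (af > 0 & af < 1)))
    msg <- c(msg, "effect_af must lie strictly in (0, 1) when present")
  if (anyDuplicated(object$snp_id))
    msg <- c(msg, "snp_id must be unique (run dedupStats)")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a GwasStats table
#'
#' @param snp_id character rsIDs, unique.
#' @param effect_allele,other_allele single-base alleles; `other_allele` may
#'   be `NA`.
#' @param weight numeric per-SNP weights (log odds ratio or beta).
#' @param p_value numeric association p-values in (0, 1].
#' @param effect_af optional effect-allele frequency in the discovery cohort,
#'   strictly in (0, 1); `NA` where unknown.
#' @return A [GwasStats-class] object.
#' @examples
#' GwasStats(snp_id = c("rs1", "rs2"),
#'           effect_allele = c("A", "C"), other_allele = c("G", "T"),
#'           weight = c(0.1, -0.2), p_value = c(0.01, 0.3),
#'           effect_af = c(0.25, NA))
#' @export
GwasStats <- function(snp_id, effect_allele, other_allele = NA_character_,
                      weight, p_value, effect_af = NA_real_) {
  n <- length(snp_id)
  df <- DataFrame(
    snp_id = as.character(snp_id),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(rep_len(as.character(other_allele), n)),
    weight = as.numeric(weight),
    p_value = as.numeric(p_value),
    effect_af = rep_len(as.numeric(effect_af), n))
  rownames(df) <- df$snp_id
  new("GwasStats", df)
}

#' @describeIn GwasStats-class SNP identifiers.
#' @param x a `GwasStats`.
#' @export
setMethod("snpIds", "GwasStats", function(x) x$snp_id)

#' @describeIn GwasStats-class effect alleles.
#' @export
setMethod("effectAllele", "GwasStats", function(x) x$effect_allele)

#' @describeIn GwasStats-class other (non-effect) alleles, `NA` when absent.
#' @export
setMethod("otherAllele", "GwasStats", function(x) x$other_allele)

#' @describeIn GwasStats-class per-SNP weights on the log-odds / beta scale.
#' @export
setMethod("effectWeights", "GwasStats", function(x) x$weight)

#' @describeIn GwasStats-class association p-values.
#' @export
setMethod("pValues", "GwasStats", function(x) x$p_value)

#' @describeIn GwasStats-class discovery effect-allele frequencies.
#' @export
setMethod("effectAF", "GwasStats", function(x) x$effect_af)

setMethod("show", "GwasStats", function(object) {
  cat(sprintf("GwasStats with %d SNPs\n", nrow(object)))
  cat(sprintf("  weights: [%.4g, %.4g]  p-values: [%.3g, %.3g]\n",
              suppressWarnings(min(object$weight)),
              suppressWarnings(max(object$weight)),
              suppressWarnings(min(object$p_value)),
              suppressWarnings(max(object$p_value))))
  cat(sprintf("  effect_af present for %d/%d SNPs\n",
              sum(!is.na(object$effect_af)), nrow(object)))
  rej <- metadata(object)$rejected
  if (!is.null(rej) && nrow(rej))
    cat(sprintf("  %d input rows rejected (metadata(x)$rejected)\n", nrow(rej)))
  invisible(NULL)
})
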