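#' Default column mapping for summary-statistics files
#'
#' GWAS summary files have no fixed schema, so the mapping from logical field
#' to header name is explicit user configuration. The defaults match the
#' header style of Psychiatric Genomics Consortium releases.
#'
#' @param snp,a1,a2,effect,p,af header names for the SNP id, effect allele,
#'   other allele, effect size, p-value and effect-allele frequency columns.
#'   `a2` and `af` may be `NA` when the file lacks them.
#' @return Named character vector suitable for the `column_map` argument of
#'   [readSummaryStats()].
#' @export
sumstatsColumns <- function(snp = "SNP", a1 = "A1", a2 = "A2",
                            effect = "OR", p = "P", af = "FRQ_A") {
  c(snp = snp, a1 = a1, a2 = a2, effect = effect, p = p, af = af)
}

#' Read discovery GWAS summary statistics
#'
#' Parses a delimited summary-statistics file (tab or whitespace separated,
#' optionally gzipped) into a [GwasStats-class] table of per-SNP weights.
#' Odds ratios are converted to weights by the natural logarithm; betas pass
#' through unchanged. Rows that cannot yield a valid record are dropped, not
#' fixed: unparseable or non-positive effect/p values, alleles outside
#' A/C/G/T (indels, multi-base), and missing ids. Dropped rows are kept with
#' a reason in `metadata(x)$rejected`.
#'
#' @param path file path (plain or `.gz`).
#' @param column_map named character vector from [sumstatsColumns()]. Entries
#'   `a2` and `af` may be `NA` to declare the column absent.
#' @param effect_is_or if `TRUE` the effect column holds odds ratios and the
#'   weight is `ln(OR)`; if `FALSE` it holds betas used as-is.
#' @return A [GwasStats-class]; `metadata()` carries `rejected` (a
#'   `DataFrame` of snp_id/reason) and `n_input`.
#' @export
readSummaryStats <- function(path, column_map = sumstatsColumns(),
                             effect_is_or = TRUE) {
  if (!file.exists(path))
    stop("summary-statistics file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  need <- c("snp", "a1", "effect", "p")
  opt <- c("a2", "af")
  use <- column_map[!is.na(column_map)]
  missing_req <- need[!(need %in% names(use))]
  if (length(missing_req))
    stop("column_map lacks required entries: ",
         paste(missing_req, collapse = ", "))
  absent <- setdiff(use, colnames(tab))
  if (length(absent))
    stop("mapped column(s) not in header of ", path, ": ",
         paste(absent, collapse = ", "))

  get_col <- function(key) {
    if (key %in% names(use)) tab[[use[[key]]]] else rep(NA_character_, nrow(tab))
  }
  snp <- trimws(get_col("snp"))
  a1 <- toupper(trimws(get_col("a1")))
  a2 <- toupper(trimws(get_col("a2")))
  eff <- suppressWarnings(as.numeric(get_col("effect")))
  p <- suppressWarnings(as.numeric(get_col("p")))
  af <- suppressWarnings(as.numeric(get_col("af")))

  bases <- c("A", "C", "G", "T")
  reason <- rep(NA_character_, nrow(tab))
  flag <- function(bad, why) reason[bad & is.na(reason)] <<- why
  flag(is.na(snp) | snp == "", "missing snp id")
  flag(!(a1 %in% bases), "non-SNP allele")
  flag(!is.na(a2) & a2 != "" & !(a2 %in% bases), "non-SNP allele")
  flag(!is.na(a2) & a2 == a1, "identical alleles")
  flag(!is.finite(eff), "unparseable effect")
  if (effect_is_or) flag(is.finite(eff) & eff <= 0, "OR <= 0")
  flag(!is.finite(p) | p <= 0 | p > 1, "invalid p-value")
  flag(!is.na(af) & (af <= 0 | af >= 1), "invalid allele frequency")

  keep <- is.na(reason)
  rejected <- DataFrame(snp_id = snp[!keep], reason = reason[!keep])
  a2[!is.na(a2) & a2 == ""] <- NA_character_

  stats <- GwasStats(
    snp_id = snp[keep],
    effect_allele = a1[keep],
    other_allele = a2[keep],
    weight = if (effect_is_or) log(eff[keep]) else eff[keep],
    p_value = p[keep],
    effect_af = af[keep])
  metadata(stats)$rejected <- rejected
  metadata(stats)$n_input <- nrow(tab)
  stats
}

#' Remove SNPs with duplicated identifiers
#'
#' A duplicated rsID leaves the weight ambiguous, so every copy of a
#' duplicated id is dropped rather than keeping the first: a wrong weight is
#' worse than a missing SNP.
#'
#' @param stats a [GwasStats-class] (or any object with a `snp_id` column),
#'   possibly carrying duplicates before construction; also accepts a plain
#'   `DataFrame`/`data.frame`.
#' @return List with `stats` (duplicates removed) and `removed` (character
#'   vector of the duplicated ids).
#' @export
dedupStats <- function(stats) {
  ids <- stats$snp_id
  dup_ids <- unique(ids[duplicated(ids)])
  keep <- !(ids %in% dup_ids)
  list(stats = stats[keep, , drop = FALSE], removed = dup_ids)
}

#' Write a GwasStats table back to delimited text
#'
#' Emits a tab-delimited file readable by [readSummaryStats()] with the
#' identity `column_map` (`sumstatsColumns()` names), preserving weights on
#' the input scale.
#'
#' @param stats a [GwasStats-class].
#' @param path output path.
#' @param effect_is_or write `exp(weight)` as an OR column if `TRUE`,
#'   otherwise the weight itself as a beta column.
#' @return `path`, invisibly.
#' @export
writeSummaryStats <- function(stats, path, effect_is_or = TRUE) {
  eff <- if (effect_is_or) exp(stats$weight) else stats$weight
  out <- data.frame(
    SNP = stats$snp_id,
    A1 = stats$effect_allele,
    A2 = ifelse(is.na(stats$other_allele), "NA", stats$other_allele),
    OR = sprintf("%.17g", eff),
    P = sprintf("%.17g", stats$p_value),
    FRQ_A = ifelse(is.na(stats$effect_af), "NA",
                   sprintf("%.17g", stats$effect_af)),
    stringsAsFactors = FALSE)
  if (!effect_is_or) colnames(out)[4] <- "BETA"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
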