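#' Per-threshold SNP log with discard reasons
#'
#' Records which SNPs enter the score at each p-value threshold and via
#' which target allele (`A1`/`A2`), plus the SNPs discarded during allele
#' reconciliation with their reason. The per-threshold lists are nested by
#' construction: a SNP qualifying at threshold `T` qualifies at every larger
#' threshold. A scored SNP whose p-value exceeds the largest threshold
#' appears in no per-threshold list but is still counted (`n_above_max`)
#' so that scored + discarded + above-max equals the matched total.
#'
#' @slot thresholds numeric, strictly increasing.
#' @slot scored `DataFrame` of scored SNPs: `snp_id`, `scored_allele`,
#'   `p_value`.
#' @slot discard `DataFrame` of discarded SNPs: `snp_id`, `reason`.
#'
#' @seealso [buildSnpLog()], [writeSnpLog()], [readSnpLog()]
#' @export
setClass("SnpLog",
         representation(thresholds = "numeric", scored = "DFrame",
                        discard = "DFrame"))

setValidity("SnpLog", function(object) {
  msg <- character()
  tchk <- .check_thresholds(object@thresholds)
  if (!isTRUE(tchk)) msg <- c(msg, tchk)
  if (!all(c("snp_id", "scored_allele", "p_value") %in%
           colnames(object@scored)))
    msg <- c(msg, "scored needs snp_id, scored_allele, p_value")
  if (!all(c("snp_id", "reason") %in% colnames(object@discard)))
    msg <- c(msg, "discard needs snp_id, reason")
  if (length(intersect(object@scored$snp_id, object@discard$snp_id)))
    msg <- c(msg, "a SNP cannot be both scored and discarded")
  if (nrow(object@scored) &&
      !all(object@scored$scored_allele %in% c("A1", "A2")))
    msg <- c(msg, "scored_allele must be A1 or A2")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Build the SNP log from match decisions
#'
#' @param decisions match table from [matchPanel()] (needs `snp_id`,
#'   `action`, `scored_allele`, `reason`, `p_value`).
#' @param thresholds strictly increasing p-value thresholds.
#' @return A [SnpLog-class].
#' @export
buildSnpLog <- function(decisions, thresholds) {
  is_scored <- decisions$action != "DISCARD"
  scored <- DataFrame(
    snp_id = decisions$snp_id[is_scored],
    scored_allele = decisions$scored_allele[is_scored],
    p_value = decisions$p_value[is_scored])
  discard <- DataFrame(
    snp_id = decisions$snp_id[!is_scored],
    reason = decisions$reason[!is_scored])
  new("SnpLog", thresholds = as.numeric(thresholds),
      scored = scored, discard = discard)
}

#' @describeIn SnpLog-class thresholds the log was built for.
#' @param x a `SnpLog`.
#' @export
setMethod("thresholds", "SnpLog", function(x) x@thresholds)

#' @describeIn SnpLog-class scored SNPs. With `threshold` given, only those
#'   whose p-value qualifies (`p <= threshold`); otherwise every scored SNP
#'   including those above the largest threshold.
#' @param threshold optional single threshold to filter on.
#' @export
setMethod("scoredSnps", "SnpLog", function(x, threshold = NULL) {
  sc <- x@scored
  if (is.null(threshold)) return(sc)
  sc[sc$p_value <= threshold, , drop = FALSE]
})

#' @describeIn SnpLog-class discarded SNPs with reasons.
#' @export
setMethod("discardedSnps", "SnpLog", function(x) x@discard)

setMethod("show", "SnpLog", function(object) {
  cat(sprintf("SnpLog over thresholds %s\n",
              paste(sprintf("%g", object@thresholds), collapse = ", ")))
  for (t in object@thresholds)
    cat(sprintf("  p <= %g: %d SNPs\n", t,
                nrow(scoredSnps(object, t))))
  n_above <- sum(object@scored$p_value > max(object@thresholds))
  cat(sprintf("  scored above max threshold: %d; discarded: %d\n",
              n_above, nrow(object@discard)))
  invisible(NULL)
})

#' Write the SNP log in columnar form
#'
#' Tab-delimited with, for each threshold `T`, a `PRS_<T>` column of SNP ids
#' and a `PRS_<T>_flag` column saying whether target allele 1 or 2 was
#' scored, then `Discard` and `Discard_reason` columns. Columns are padded
#' with blanks to equal length.
#'
#' @param log a [SnpLog-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSnpLog <- function(log, path) {
  cols <- list()
  for (t in thresholds(log)) {
    sc <- scoredSnps(log, t)
    tn <- sprintf("%g", t)
    cols[[paste0("PRS_", tn)]] <- sc$snp_id
    cols[[paste0("PRS_", tn, "_flag")]] <- sc$scored_allele
  }
  dc <- discardedSnps(log)
  cols[["Discard"]] <- dc$snp_id
  cols[["Discard_reason"]] <- dc$reason
  depth <- max(c(0L, lengths(cols)))
  padded <- lapply(cols, function(v) c(v, rep("", depth - length(v))))
  out <- as.data.frame(padded, optional = TRUE, stringsAsFactors = FALSE)
  if (depth == 0L) {
    writeLines(paste(names(cols), collapse = "\t"), path)
  } else {
    colnames(out) <- names(cols)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a SNP log written by [writeSnpLog()]
#'
#' Reconstructs the per-threshold lists and the discard list. P-values are
#' not stored in the file, so each scored SNP is assigned the smallest
#' threshold it appears under (sufficient to reproduce every per-threshold
#' list exactly); SNPs above the largest threshold are not representable in
#' the file and are absent from the round trip.
#'
#' @param path path to the log file.
#' @return A [SnpLog-class].
#' @export
readSnpLog <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  prs_cols <- grep("^PRS_", colnames(tab), value = TRUE)
  prs_cols <- prs_cols[!grepl("_flag$", prs_cols)]
  th <- sort(as.numeric(sub("^PRS_", "", prs_cols)))
  seen <- character(); allele <- character(); pv <- numeric()
  for (t in th) {
    tn <- sprintf("%g", t)
    ids <- tab[[paste0("PRS_", tn)]]
    fl <- tab[[paste0("PRS_", tn, "_flag")]]
    keep <- nzchar(ids) & !(ids %in% seen)
    seen <- c(seen, ids[keep])
    allele <- c(allele, fl[keep])
    pv <- c(pv, rep(t, sum(keep)))
  }
  disc <- nzchar(tab[["Discard"]])
  new("SnpLog", thresholds = th,
      scored = DataFrame(snp_id = seen, scored_allele = allele, p_value = pv),
      discard = DataFrame(snp_id = tab[["Discard"]][disc],
                          reason = tab[["Discard_reason"]][disc]))
}
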