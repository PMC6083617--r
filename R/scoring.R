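#' Expected effect-allele dosage from a probability triple
#'
#' The expected count of the scored allele given the genotype posterior:
#' `2*p11 + p12` when target allele 1 carries the effect, `2*p22 + p12` when
#' allele 2 does. With degenerate (hard-call) triples this reduces to the
#' plain allele count 0/1/2.
#'
#' @param p11,p12,p22 numeric vectors or matrices of genotype probabilities.
#' @param scored `"A1"` or `"A2"`, which target allele is scored (recycled).
#' @return Numeric dosage in `[0, 2]`, same shape as the inputs.
#' @examples
#' effectDosage(0.25, 0.5, 0.25, "A1")  # 1
#' effectDosage(0.1, 0.2, 0.7, "A2")    # 1.6
#' @export
effectDosage <- function(p11, p12, p22, scored) {
  out <- ifelse(rep_len(scored == "A1", length(p11)),
                2 * p11 + p12, 2 * p22 + p12)
  if (!is.null(dim(p11))) dim(out) <- dim(p11)
  out
}

# bucket index: smallest threshold T with p <= T; length(th) + 1 when p > max
.bucket_of <- function(p, th) findInterval(p, th, left.open = TRUE) + 1L

#' Accumulate polygenic scores at every threshold in one pass
#'
#' Streams over the scored SNPs once: each SNP's weighted dosage is added to
#' the bucket of its smallest qualifying threshold, and the buckets are
#' cumulatively summed at the end, giving the score at every threshold
#' without re-reading the genotypes. Missing genotypes contribute nothing
#' and are not counted for that sample. SNPs whose p-value exceeds the
#' largest threshold are ignored here (they remain visible to the SNP log).
#'
#' `chunk_size` processes the SNP stream in bounded-size pieces and merges
#' the partial tables; results are invariant to the chunking (within
#' floating-point reassociation), which is what makes the scorer safe to run
#' over partitioned input.
#'
#' @param gwas a [GwasStats-class].
#' @param geno a [GenotypeProbs-class].
#' @param decisions match table from [matchPanel()]; computed with its
#'   defaults when omitted. Only `SCORE_A1`/`SCORE_A2` rows contribute.
#' @param thresholds strictly increasing p-value thresholds in (0, 1].
#' @param chunk_size SNPs per processing chunk; `Inf` for a single chunk.
#' @return A [ScoreTable-class].
#' @export
scorePanel <- function(gwas, geno, decisions = NULL,
                       thresholds = c(0.1, 0.2, 0.3, 0.4, 0.5),
                       chunk_size = Inf) {
  tchk <- .check_thresholds(thresholds)
  if (!isTRUE(tchk)) stop(tchk)
  if (is.null(decisions)) decisions <- matchPanel(gwas, geno)
  scored <- decisions[decisions$action != "DISCARD", , drop = FALSE]
  if (anyDuplicated(scored$snp_id))
    stop("duplicate SNP in scoring stream; deduplicate summary statistics first")

  samples <- sampleIds(geno)
  n_th <- length(thresholds)
  raw <- matrix(0, length(samples), n_th)
  counts <- matrix(0L, length(samples), n_th)

  n <- nrow(scored)
  if (n > 0L) {
    starts <- seq(1L, n, by = if (is.finite(chunk_size)) chunk_size else n)
    for (s in starts) {
      idx <- s:min(s + chunk_size - 1L, n)
      part <- .score_chunk(scored[idx, , drop = FALSE], geno, thresholds)
      raw <- raw + part$raw
      counts <- counts + part$counts
    }
  }
  ScoreTable(samples, thresholds, raw, counts)
}

.score_chunk <- function(scored, geno, thresholds) {
  rows <- scored$geno_row
  p11 <- assay(geno, "p11")[rows, , drop = FALSE]
  p12 <- assay(geno, "p12")[rows, , drop = FALSE]
  p22 <- assay(geno, "p22")[rows, , drop = FALSE]
  miss <- (p11 + p12 + p22) < .MISSING_TOL
  dose <- ifelse(matrix(scored$scored_allele == "A1", nrow(p11), ncol(p11)),
                 2 * p11 + p12, 2 * p22 + p12)
  contrib <- scored$weight * dose
  contrib[miss] <- 0

  bucket <- .bucket_of(scored$p_value, thresholds)
  n_th <- length(thresholds)
  in_range <- bucket <= n_th
  raw_b <- matrix(0, n_th, ncol(contrib))
  cnt_b <- matrix(0, n_th, ncol(contrib))
  if (any(in_range)) {
    g <- bucket[in_range]
    rs <- rowsum(contrib[in_range, , drop = FALSE], g)
    cs <- rowsum((!miss[in_range, , drop = FALSE]) + 0, g)
    lev <- as.integer(rownames(rs))
    raw_b[lev, ] <- rs
    cnt_b[lev, ] <- cs
  }
  # cumulative over thresholds, then back to samples x thresholds
  cum_t <- function(m) {
    cm <- apply(m, 2L, cumsum)
    if (is.null(dim(cm))) cm <- matrix(cm, nrow = 1L)
    t(cm)
  }
  list(raw = cum_t(raw_b), counts = cum_t(cnt_b))
}

#' Write a score table as delimited text
#'
#' One row per sample: `sample_id`, then per threshold the averaged score
#' (`PRS_<T>`) and the contributing-SNP count (`COUNT_<T>`). Undefined
#' averages (count zero) are written as `NA`. Numbers carry 10 significant
#' digits.
#'
#' @param scores a [ScoreTable-class].
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
writeScores <- function(scores, path, sep = "\t") {
  th <- sprintf("%g", thresholds(scores))
  avg <- avgScores(scores)
  cnt <- snpCounts(scores)
  out <- data.frame(sample_id = sampleIds(scores), stringsAsFactors = FALSE)
  for (j in seq_along(th)) {
    out[[paste0("PRS_", th[j])]] <-
      ifelse(is.na(avg[, j]), "NA", sprintf("%.10g", avg[, j]))
    out[[paste0("COUNT_", th[j])]] <- cnt[, j]
  }
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score table written by [writeScores()]
#'
#' @param path path to the score file.
#' @param sep field separator.
#' @return A [ScoreTable-class] with raw sums reconstructed as
#'   `avg * count`.
#' @export
readScores <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  prs_cols <- grep("^PRS_", colnames(tab), value = TRUE)
  th <- as.numeric(sub("^PRS_", "", prs_cols))
  ord <- order(th)
  avg <- as.matrix(tab[, prs_cols[ord], drop = FALSE])
  cnt <- as.matrix(tab[, sub("^PRS_", "COUNT_", prs_cols[ord]), drop = FALSE])
  raw <- avg * cnt
  raw[cnt == 0] <- 0
  ScoreTable(as.character(tab$sample_id), th[ord], raw, cnt)
}
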