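#' Per-SNP genotype probability matrix for a cohort
#'
#' `GenotypeProbs` extends [SummarizedExperiment::SummarizedExperiment] with
#' three SNP x sample assays, `p11`, `p12` and `p22`: the probabilities of
#' the homozygous-allele1, heterozygous and homozygous-allele2 genotypes.
#' Hard-called data are the degenerate special case where one component of
#' each triple is 1. A triple summing to (numerically) zero marks a missing
#' genotype for that sample; triples are never renormalised, since genuine
#' imputation output can carry probability mass below 1.
#'
#' Row metadata holds `snp_id`, `chrom`, `pos`, `allele1`, `allele2`;
#' `colnames` are the cohort sample ids in cohort order.
#'
#' @seealso [readGen()], [readGenotypeVcf()], [alleleFrequency()],
#'   [hardCalls()]
#' @export
setClass("GenotypeProbs", contains = "SummarizedExperiment")

.MISSING_TOL <- 1e-9
.SUM_TOL <- 1e-6

setValidity("GenotypeProbs", function(object) {
  msg <- character()
  if (!all(c("p11", "p12", "p22") %in% names(assays(object))))
    return("assays p11, p12, p22 are required")
  rd <- rowData(object)
  need <- c("snp_id", "allele1", "allele2")
  if (!all(need %in% colnames(rd)))
    return(paste("rowData must contain", paste(need, collapse = ", ")))
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  if (ncol(object) < 1L)
    msg <- c(msg, "cohort must be non-empty")
  for (a in c("p11", "p12", "p22")) {
    v <- assay(object, a)
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      msg <- c(msg, sprintf("assay %s must lie in [0, 1]", a))
  }
  s <- assay(object, "p11") + assay(object, "p12") + assay(object, "p22")
  if (any(s > 1 + .SUM_TOL))
    msg <- c(msg, "probability triples must sum to at most 1")
  ok_allele <- function(a) all(a %in% c("A", "C", "G", "T"))
  if (!ok_allele(rd$allele1) || !ok_allele(rd$allele2))
    msg <- c(msg, "alleles must be single bases A/C/G/T")
  if (any(rd$allele1 == rd$allele2))
    msg <- c(msg, "allele1 and allele2 must differ")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a GenotypeProbs object
#'
#' @param snp_id character SNP identifiers (used as rownames; duplicates are
#'   allowed here and resolved when joining against summary statistics).
#' @param allele1,allele2 single-base target alleles, in file order.
#' @param p11,p12,p22 numeric SNP x sample matrices of genotype
#'   probabilities (hom-allele1, het, hom-allele2).
#' @param sample_ids cohort sample identifiers, one per column.
#' @param chrom,pos optional chromosome labels and 1-based positions.
#' @return A [GenotypeProbs-class] object.
#' @export
GenotypeProbs <- function(snp_id, allele1, allele2, p11, p12, p22,
                          sample_ids, chrom = NA_character_, pos = NA_integer_) {
  p11 <- as.matrix(p11); p12 <- as.matrix(p12); p22 <- as.matrix(p22)
  n <- length(snp_id)
  rd <- DataFrame(
    snp_id = as.character(snp_id),
    chrom = rep_len(as.character(chrom), n),
    pos = rep_len(as.integer(pos), n),
    allele1 = toupper(as.character(allele1)),
    allele2 = toupper(as.character(allele2)))
  dimnames(p11) <- dimnames(p12) <- dimnames(p22) <-
    list(rd$snp_id, as.character(sample_ids))
  se <- SummarizedExperiment(
    assays = list(p11 = p11, p12 = p12, p22 = p22), rowData = rd)
  new("GenotypeProbs", se)
}

#' @describeIn GenotypeProbs-class SNP identifiers.
#' @param x a `GenotypeProbs`.
#' @export
setMethod("snpIds", "GenotypeProbs", function(x) rowData(x)$snp_id)

#' @describeIn GenotypeProbs-class cohort sample ids, in cohort order.
#' @export
setMethod("sampleIds", "GenotypeProbs", function(x) colnames(x))

#' @describeIn GenotypeProbs-class first target allele per SNP.
#' @export
setMethod("allele1", "GenotypeProbs", function(x) rowData(x)$allele1)

#' @describeIn GenotypeProbs-class second target allele per SNP.
#' @export
setMethod("allele2", "GenotypeProbs", function(x) rowData(x)$allele2)

#' @describeIn GenotypeProbs-class logical SNP x sample matrix, `TRUE` where
#'   the probability triple sums to numerical zero (missing genotype).
#' @export
setMethod("missingMask", "GenotypeProbs", function(x) {
  (assay(x, "p11") + assay(x, "p12") + assay(x, "p22")) < .MISSING_TOL
})

#' Target allele-1 frequency from expected dosage
#'
#' For each SNP, the frequency of `allele1` estimated as the mean over
#' non-missing samples of half the expected allele-1 dosage,
#' `(2*p11 + p12) / 2`. `NA` when every sample is missing; that `NA`
#' propagates downstream as a discard reason for ambiguous SNPs.
#'
#' @param x a [GenotypeProbs-class].
#' @param ... unused.
#' @return Named numeric vector in `[0, 1]`, one entry per SNP.
#' @export
setMethod("alleleFrequency", "GenotypeProbs", function(x, ...) {
  dose1 <- 2 * assay(x, "p11") + assay(x, "p12")
  miss <- missingMask(x)
  dose1[miss] <- NA_real_
  n_obs <- rowSums(!miss)
  af <- rowSums(dose1 / 2, na.rm = TRUE) / n_obs
  af[n_obs == 0L] <- NA_real_
  setNames(af, rowData(x)$snp_id)
})

#' Convert probability triples to hard calls
#'
#' Replaces each non-missing triple with a degenerate 0/1 triple at its
#' argmax, ties broken toward the heterozygote (the common "best guess"
#' convention). Missing triples stay missing.
#'
#' @param x a [GenotypeProbs-class].
#' @return A [GenotypeProbs-class] with degenerate triples.
#' @export
setMethod("hardCalls", "GenotypeProbs", function(x) {
  p11 <- assay(x, "p11"); p12 <- assay(x, "p12"); p22 <- assay(x, "p22")
  miss <- missingMask(x)
  # het wins ties: it is picked whenever neither homozygote strictly exceeds it
  pick_het <- p12 >= p11 & p12 >= p22
  pick_hom1 <- !pick_het & p11 >= p22
  h11 <- matrix(0, nrow(p11), ncol(p11), dimnames = dimnames(p11))
  h12 <- h11; h22 <- h11
  h12[pick_het] <- 1
  h11[pick_hom1] <- 1
  h22[!pick_het & !pick_hom1] <- 1
  h11[miss] <- 0; h12[miss] <- 0; h22[miss] <- 0
  assays(x) <- S4Vectors::SimpleList(p11 = h11, p12 = h12, p22 = h22)
  x
})

setMethod("show", "GenotypeProbs", function(object) {
  cat(sprintf("GenotypeProbs: %d SNPs x %d samples\n",
              nrow(object), ncol(object)))
  n_miss <- sum(missingMask(object))
  cat(sprintf("  missing genotypes: %d (%.2f%%)\n", n_miss,
              100 * n_miss / max(1, nrow(object) * ncol(object))))
  degenerate <- all(assay(object, "p11") %in% c(0, 1)) &&
    all(assay(object, "p12") %in% c(0, 1))
  cat(sprintf("  triples: %s\n",
              if (degenerate) "hard calls (degenerate)" else "posterior probabilities"))
  invisible(NULL)
})
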