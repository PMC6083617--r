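.open_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con)
}

#' Read an Oxford SAMPLE file
#'
#' The SAMPLE format carries two header rows (column names, then type codes);
#' the first column of the remaining rows is the sample id.
#'
#' @param path path to a `.sample` file (plain or gzipped).
#' @return Character vector of unique sample ids, in cohort order.
#' @export
readSampleFile <- function(path) {
  if (!file.exists(path)) stop("SAMPLE file not found: ", path)
  lines <- .open_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L)
    stop("SAMPLE file ", path, " has no sample rows")
  ids <- vapply(strsplit(trimws(lines[-(1:2)]), "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate sample ids in ", path)
  ids
}

#' Read Oxford GEN/SAMPLE genotype probabilities
#'
#' Parses a GEN file (plain or gzipped) into a [GenotypeProbs-class]. Each
#' row carries leading identity fields then three probabilities per sample,
#' in cohort order: hom-allele1, het, hom-allele2. Two leading-field dialects
#' exist -- 5 fields (snp id, rsID, position, allele1, allele2) or 6 with a
#' chromosome column in front -- and the dialect is detected from the first
#' row against the SAMPLE-file cohort size, then enforced on every row.
#' Triples are kept exactly as printed (no renormalisation); an all-zero
#' triple is a missing genotype.
#'
#' @param gen_path path to the GEN file.
#' @param sample_path path to the companion SAMPLE file.
#' @return A [GenotypeProbs-class]; `metadata()` records the detected
#'   `gen_dialect`.
#' @export
readGen <- function(gen_path, sample_path) {
  if (!file.exists(gen_path)) stop("GEN file not found: ", gen_path)
  samples <- readSampleFile(sample_path)
  n <- length(samples)
  lines <- .open_lines(gen_path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("GEN file ", gen_path, " is empty")

  fields <- strsplit(trimws(lines), "\\s+")
  lead <- length(fields[[1L]]) - 3L * n
  if (!(lead %in% c(5L, 6L)))
    stop(sprintf(
      "malformed GEN row at line 1 of %s: %d fields cannot be %d or %d leading fields plus 3 x %d samples",
      gen_path, length(fields[[1L]]), 5L, 6L, n))
  message(sprintf("GEN dialect: %d leading fields (%s chromosome column)",
                  lead, if (lead == 6L) "with" else "no"))

  len <- lengths(fields)
  bad <- which(len != lead + 3L * n)
  if (length(bad))
    stop(sprintf("malformed GEN row at line %d of %s: %d fields, expected %d",
                 bad[1L], gen_path, len[bad[1L]], lead + 3L * n))

  m <- matrix(unlist(fields, use.names = FALSE), nrow = length(fields),
              byrow = TRUE)
  off <- lead - 5L  # 0 or 1
  chrom <- if (lead == 6L) m[, 1L] else NA_character_
  snp_id <- m[, off + 2L]
  pos <- suppressWarnings(as.integer(m[, off + 3L]))
  a1 <- toupper(m[, off + 4L])
  a2 <- toupper(m[, off + 5L])
  probs <- suppressWarnings(
    matrix(as.numeric(m[, (lead + 1L):ncol(m), drop = FALSE]),
           nrow = nrow(m)))
  if (any(!is.finite(probs)))
    stop("non-numeric genotype probability in ", gen_path)
  idx <- seq_len(n)
  GenotypeProbs(
    snp_id = snp_id, chrom = chrom, pos = pos, allele1 = a1, allele2 = a2,
    p11 = probs[, 3L * idx - 2L, drop = FALSE],
    p12 = probs[, 3L * idx - 1L, drop = FALSE],
    p22 = probs[, 3L * idx, drop = FALSE],
    sample_ids = samples)
}

#' Read genotypes from a VCF into probability triples
#'
#' Reads biallelic SNP records from a VCF (plain or gzipped) via
#' \pkg{vcfR} and converts them to [GenotypeProbs-class] triples with
#' `allele1 = REF`, `allele2 = ALT`. With `prob_source = "GP"` the
#' three-value genotype posterior field is passed through unchanged (VCF
#' order REF/REF, REF/ALT, ALT/ALT); with `"GT"` diploid hard calls become
#' degenerate triples. Missing calls (`./.` or a missing field) become the
#' all-zero triple. Multi-allelic and non-SNP (indel) records are skipped
#' and counted in `metadata()$skipped`.
#'
#' @param vcf_path path to a `.vcf` or `.vcf.gz`.
#' @param prob_source `"GP"` (genotype posterior probabilities) or `"GT"`
#'   (hard calls).
#' @return A [GenotypeProbs-class].
#' @export
readGenotypeVcf <- function(vcf_path, prob_source = c("GP", "GT")) {
  prob_source <- match.arg(prob_source)
  if (!file.exists(vcf_path)) stop("VCF file not found: ", vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  bases <- c("A", "C", "G", "T")
  multi <- grepl(",", alt, fixed = TRUE)
  non_snp <- !multi & (!(ref %in% bases) | !(alt %in% bases))
  keep <- !multi & !non_snp
  if (any(multi))
    message(sum(multi), " multi-allelic VCF record(s) skipped")
  if (any(non_snp))
    message(sum(non_snp), " non-SNP VCF record(s) skipped")
  if (!any(keep))
    stop("no biallelic SNP records in ", vcf_path)

  fmt <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)))
  if (!(prob_source %in% fmt))
    stop("requested FORMAT field absent from VCF: ", prob_source)

  n_snp <- sum(keep)
  if (prob_source == "GP") {
    gp <- vcfR::extract.gt(vcf, element = "GP")[keep, , drop = FALSE]
    samples <- colnames(gp)
    parse_gp <- function(cell) {
      if (is.na(cell) || cell == ".") return(c(0, 0, 0))
      v <- suppressWarnings(as.numeric(strsplit(cell, ",", fixed = TRUE)[[1L]]))
      if (length(v) != 3L || any(!is.finite(v)))
        stop("malformed GP value: ", cell)
      v
    }
    trip <- vapply(gp, parse_gp, numeric(3L))
    p11 <- matrix(trip[1L, ], n_snp)
    p12 <- matrix(trip[2L, ], n_snp)
    p22 <- matrix(trip[3L, ], n_snp)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
    samples <- colnames(gt)
    alleles <- gsub("\\|", "/", gt)
    code <- function(target) {
      out <- matrix(0, n_snp, ncol(gt))
      out[!is.na(alleles) & (alleles == target[1L] | alleles == target[2L])] <- 1
      out
    }
    p11 <- code(c("0/0", "0/0"))
    p12 <- code(c("0/1", "1/0"))
    p22 <- code(c("1/1", "1/1"))
    unknown <- !is.na(alleles) &
      !(alleles %in% c("0/0", "0/1", "1/0", "1/1", "./."))
    if (any(unknown))
      stop("unsupported GT value(s): ",
           paste(unique(alleles[unknown]), collapse = ", "))
  }
  out <- GenotypeProbs(
    snp_id = fix[keep, "ID"], chrom = fix[keep, "CHROM"],
    pos = suppressWarnings(as.integer(fix[keep, "POS"])),
    allele1 = ref[keep], allele2 = alt[keep],
    p11 = p11, p12 = p12, p22 = p22, sample_ids = samples)
  metadata(out)$skipped <- c(multi_allelic = sum(multi), non_snp = sum(non_snp))
  out
}
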