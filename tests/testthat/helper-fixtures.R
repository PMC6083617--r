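# Shared fixture builders. Everything is generated in code at test time;
# nothing binary is stored.

DEFAULT_THRESHOLDS <- c(0.1, 0.2, 0.3, 0.4, 0.5)

# a tiny in-memory panel with every feature switched on
mixed_panel <- function(seed = 7, ...) {
  simulatePanel(n_samples = 20, n_snps = 40, prop_ambiguous = 0.3,
                imputation_noise = 0.2, strand_flip_rate = 0.2,
                seed = seed, ...)
}

# hand-build a GenotypeProbs from a list of triples (one SNP, many samples)
snp_from_triples <- function(triples, allele1 = "A", allele2 = "G",
                             snp_id = "rs1") {
  m <- do.call(rbind, triples)  # samples x 3
  GenotypeProbs(snp_id = snp_id, allele1 = allele1, allele2 = allele2,
                p11 = matrix(m[, 1], 1), p12 = matrix(m[, 2], 1),
                p22 = matrix(m[, 3], 1),
                sample_ids = sprintf("S%d", seq_len(nrow(m))))
}

# scale-tolerant comparison used for oracle equivalence: absolute error
# bounded by tol relative to the larger of 1 and the reference magnitude
expect_scores_match <- function(got, ref, tol = 1e-12) {
  expect_identical(snpCounts(got), snpCounts(ref))
  scale <- max(1, max(abs(rawSums(ref))))
  expect_lt(max(abs(rawSums(got) - rawSums(ref))), tol * scale)
}
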