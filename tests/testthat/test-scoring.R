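# build a small panel directly from explicit pieces
toy_panel <- function(weights, p_values, triples_by_snp,
                      alleles = NULL, scored = NULL) {
  n_snp <- length(weights)
  ids <- sprintf("rs%d", seq_len(n_snp))
  if (is.null(alleles)) alleles <- list(rep("A", n_snp), rep("G", n_snp))
  n_smp <- nrow(triples_by_snp[[1]])
  p11 <- do.call(rbind, lapply(triples_by_snp, function(m) m[, 1]))
  p12 <- do.call(rbind, lapply(triples_by_snp, function(m) m[, 2]))
  p22 <- do.call(rbind, lapply(triples_by_snp, function(m) m[, 3]))
  geno <- GenotypeProbs(ids, alleles[[1]], alleles[[2]], p11, p12, p22,
                        sample_ids = sprintf("S%d", seq_len(n_smp)))
  gwas <- GwasStats(ids, alleles[[1]], alleles[[2]], weights, p_values)
  list(gwas = gwas, geno = geno)
}

test_that("effect dosage is the expected scored-allele count", {
  expect_identical(effectDosage(1, 0, 0, "A1"), 2)
  expect_identical(effectDosage(0.25, 0.5, 0.25, "A1"), 1)
  expect_equal(effectDosage(0.1, 0.2, 0.7, "A2"), 1.6, tolerance = 1e-12)
  expect_equal(effectDosage(0.1, 0.2, 0.7, "A1"), 0.4, tolerance = 1e-12)
  # vectorised over triples with recycled allele labels
  expect_equal(effectDosage(c(1, 0), c(0, 1), c(0, 0), "A1"), c(2, 1))
})

test_that("single-pass accumulation reproduces hand-computed scores", {
  # one SNP, weight ln(2), one het hard call
  tp <- toy_panel(log(2), 0.3, list(matrix(c(0, 1, 0), 1)))
  st <- scorePanel(tp$gwas, tp$geno, thresholds = 0.5)
  expect_equal(rawSums(st)[1, 1], log(2))
  expect_identical(snpCounts(st)[1, 1], 1L)
  expect_equal(avgScores(st)[1, 1], log(2))

  # p = 0.15 joins the 0.2 bucket only
  tp2 <- toy_panel(1, 0.15, list(matrix(c(0, 1, 0), 1)))
  st2 <- scorePanel(tp2$gwas, tp2$geno, thresholds = c(0.1, 0.2))
  expect_identical(unname(snpCounts(st2)[1, ]), c(0L, 1L))
  expect_true(is.na(avgScores(st2)[1, 1]))

  # missing genotype at the only SNP: count 0, average undefined
  tp3 <- toy_panel(1, 0.05, list(matrix(c(0, 0, 0), 1)))
  st3 <- scorePanel(tp3$gwas, tp3$geno, thresholds = 0.5)
  expect_identical(snpCounts(st3)[1, 1], 0L)
  expect_true(is.na(avgScores(st3)[1, 1]))
  expect_identical(rawSums(st3)[1, 1], 0)

  # two SNPs: 0.1 * 2 + (-0.3) * 1 = -0.1, averaged over 2 SNPs
  tp4 <- toy_panel(c(0.1, -0.3), c(0.2, 0.2),
                   list(matrix(c(1, 0, 0), 1), matrix(c(0, 1, 0), 1)))
  st4 <- scorePanel(tp4$gwas, tp4$geno, thresholds = 0.5)
  expect_equal(rawSums(st4)[1, 1], -0.1)
  expect_equal(avgScores(st4)[1, 1], -0.05)
})

test_that("a SNP with p exactly at a threshold is included there", {
  tp <- toy_panel(1, 0.5, list(matrix(c(1, 0, 0), 1)))
  st <- scorePanel(tp$gwas, tp$geno, thresholds = c(0.1, 0.5))
  expect_identical(unname(snpCounts(st)[1, ]), c(0L, 1L))
})

test_that("accumulation matches the naive oracle on random panels", {
  for (seed in 1:10) {
    p <- mixed_panel(seed = 100 + seed)
    got <- scorePanel(p$gwas, p$geno, thresholds = DEFAULT_THRESHOLDS)
    ref <- referencePrs(p, DEFAULT_THRESHOLDS)
    expect_scores_match(got, ref)
  }
})

test_that("chunked streaming gives the same table as one pass", {
  p <- mixed_panel(seed = 31)
  whole <- scorePanel(p$gwas, p$geno, thresholds = DEFAULT_THRESHOLDS)
  for (cs in c(1, 7)) {
    part <- scorePanel(p$gwas, p$geno, thresholds = DEFAULT_THRESHOLDS,
                       chunk_size = cs)
    expect_identical(snpCounts(part), snpCounts(whole))
    expect_lt(max(abs(rawSums(part) - rawSums(whole))), 1e-12)
  }
})

test_that("hard-call panels score identically via probabilities or counts", {
  p <- simulatePanel(n_samples = 25, n_snps = 30, imputation_noise = 0,
                     prop_ambiguous = 0.2, seed = 77)
  pp <- scorePanel(p$gwas, p$geno, thresholds = DEFAULT_THRESHOLDS)
  hc <- scorePanel(p$gwas, hardCalls(p$geno),
                   thresholds = DEFAULT_THRESHOLDS)
  expect_identical(rawSums(pp), rawSums(hc))
  expect_identical(snpCounts(pp), snpCounts(hc))
})

test_that("counts never decrease with the threshold", {
  for (seed in c(2, 9)) {
    p <- mixed_panel(seed = seed)
    cnt <- snpCounts(scorePanel(p$gwas, p$geno,
                                thresholds = DEFAULT_THRESHOLDS))
    expect_true(all(apply(cnt, 1, function(r) all(diff(r) >= 0))))
  }
})

test_that("scores respond affinely to a weight rescaling", {
  p <- mixed_panel(seed = 55)
  base <- scorePanel(p$gwas, p$geno, thresholds = DEFAULT_THRESHOLDS)
  scaled_gwas <- GwasStats(snpIds(p$gwas), effectAllele(p$gwas),
                           otherAllele(p$gwas), 3 * effectWeights(p$gwas),
                           pValues(p$gwas), effectAF(p$gwas))
  scaled <- scorePanel(scaled_gwas, p$geno, thresholds = DEFAULT_THRESHOLDS)
  expect_equal(rawSums(scaled), 3 * rawSums(base), tolerance = 1e-12)
  expect_identical(snpCounts(scaled), snpCounts(base))
})

test_that("score files round-trip and encode undefined averages as NA", {
  tp <- toy_panel(c(0.2, -0.1), c(0.05, 0.3),
                  list(matrix(c(0, 1, 0, 0, 0, 0), 2, byrow = TRUE),
                       matrix(c(1, 0, 0, 0, 0, 0), 2, byrow = TRUE)))
  st <- scorePanel(tp$gwas, tp$geno, thresholds = c(0.1, 0.5))
  path <- tempfile(fileext = ".txt")
  writeScores(st, path)
  txt <- readLines(path)
  expect_match(txt[1], "^sample_id\tPRS_0.1\tCOUNT_0.1\tPRS_0.5\tCOUNT_0.5$")
  expect_match(txt[3], "NA")  # sample 2 is missing everywhere
  back <- readScores(path)
  expect_identical(snpCounts(back), snpCounts(st))
  expect_equal(avgScores(back), avgScores(st), tolerance = 1e-9)
})

test_that("duplicate SNPs in the scoring stream are fatal", {
  tp <- toy_panel(c(0.1, 0.2), c(0.2, 0.3),
                  list(matrix(c(1, 0, 0), 1), matrix(c(1, 0, 0), 1)))
  dec <- matchPanel(tp$gwas, tp$geno)
  dec$snp_id <- c("rs1", "rs1")
  expect_error(scorePanel(tp$gwas, tp$geno, dec, thresholds = 0.5),
               "duplicate")
})
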