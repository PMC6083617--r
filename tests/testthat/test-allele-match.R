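test_that("strand ambiguity and reverse complement behave as defined", {
  expect_true(isStrandAmbiguous("A", "T"))
  expect_true(isStrandAmbiguous("C", "G"))
  expect_true(isStrandAmbiguous("G", "C"))
  expect_false(isStrandAmbiguous("A", "G"))
  expect_false(isStrandAmbiguous("C", "T"))
  for (b in c("A", "C", "G", "T"))
    expect_identical(reverseComplementAllele(reverseComplementAllele(b)), b)
  expect_identical(reverseComplementAllele(c("A", "C")), c("T", "G"))
})

dec <- function(...) matchAlleles("rs", ...)

test_that("non-ambiguous pairs match directly or via the reverse strand", {
  d <- dec("A", "G", "A", "G", NA, NA)
  expect_identical(d$action, "SCORE_A1")
  expect_identical(d$reason, "OK")
  expect_identical(dec("A", "G", "G", "A", NA, NA)$action, "SCORE_A2")
  # reverse-complement strand: discovery A/G reported as T/C in the target
  expect_identical(dec("A", "G", "T", "C", NA, NA)$action, "SCORE_A1")
  expect_identical(dec("A", "G", "C", "T", NA, NA)$action, "SCORE_A2")
  # inconsistent pair
  d2 <- dec("A", "G", "A", "C", NA, NA)
  expect_identical(d2$action, "DISCARD")
  expect_identical(d2$reason, "ALLELE_MISMATCH")
  # absent other allele weakens the check but still matches on the effect
  expect_identical(dec("A", NA, "A", "C", NA, NA)$action, "SCORE_A1")
})

test_that("ambiguous SNPs follow the allele-frequency rule", {
  expect_identical(dec("A", "T", "A", "T", 0.30, 0.30)$action, "SCORE_A1")
  expect_identical(dec("A", "T", "A", "T", 0.70, 0.70)$action, "SCORE_A1")
  expect_identical(dec("A", "T", "A", "T", 0.30, 0.70)$action, "SCORE_A2")
  expect_identical(dec("A", "T", "A", "T", 0.70, 0.30)$action, "SCORE_A2")
  z <- dec("A", "T", "A", "T", 0.50, 0.30)
  expect_identical(z$reason, "AMBIGUOUS_AF_ZONE")
  expect_identical(dec("A", "T", "A", "T", 0.30, 0.50)$reason,
                   "AMBIGUOUS_AF_ZONE")
  # effect allele written as target allele 2: mirrored frequencies/outcomes
  expect_identical(dec("T", "A", "A", "T", 0.30, 0.70)$action, "SCORE_A2")
  expect_identical(dec("T", "A", "A", "T", 0.30, 0.30)$action, "SCORE_A1")
  # missing frequency on either side discards
  expect_identical(dec("A", "T", "A", "T", NA, 0.3)$reason, "MISSING_AF")
  expect_identical(dec("A", "T", "A", "T", 0.3, NA)$reason, "MISSING_AF")
  # effect letter not in the ambiguous pair
  expect_identical(dec("C", "G", "A", "T", 0.3, 0.3)$reason,
                   "ALLELE_MISMATCH")
})

test_that("zone boundaries 0.4 and 0.6 are closed on both sides", {
  for (b in c(0.4, 0.6)) {
    expect_identical(dec("A", "T", "A", "T", b, 0.3)$reason,
                     "AMBIGUOUS_AF_ZONE")
    expect_identical(dec("A", "T", "A", "T", 0.3, b)$reason,
                     "AMBIGUOUS_AF_ZONE")
  }
  expect_identical(dec("A", "T", "A", "T", 0.39999, 0.39999)$action,
                   "SCORE_A1")
  expect_identical(dec("A", "T", "A", "T", 0.60001, 0.60001)$action,
                   "SCORE_A1")
})

test_that("disabling frequency matching discards every ambiguous SNP", {
  for (t in seq(0, 1, by = 0.1)) {
    d <- dec("A", "T", "A", "T", 0.2, t, use_af_matching = FALSE)
    expect_identical(d$action, "DISCARD")
    expect_identical(d$reason, "AMBIGUOUS_DISABLED")
  }
  # non-ambiguous SNPs are unaffected by the switch
  expect_identical(
    dec("A", "G", "A", "G", 0.2, 0.2, use_af_matching = FALSE)$action,
    "SCORE_A1")
})

test_that("every allele pair and frequency yields a decision", {
  bases <- c("A", "C", "G", "T")
  afs <- c(seq(0.05, 0.95, by = 0.1), 0.4, 0.6, NA)
  violations <- 0L
  for (a1 in bases) for (a2 in bases) for (e in bases) {
    for (d in afs) for (t in afs) {
      out <- matchAlleles("rs", e, NA, a1, a2, d, t)
      ok <- out$action %in% c("SCORE_A1", "SCORE_A2", "DISCARD") &&
        identical(out$action == "DISCARD", out$reason != "OK") &&
        identical(out$action == "DISCARD", is.na(out$scored_allele))
      if (!ok) violations <- violations + 1L
    }
  }
  expect_identical(violations, 0L)
})

test_that("swapping target alleles mirrors the decision", {
  set.seed(5)
  bases <- c("A", "C", "G", "T")
  flip <- c(SCORE_A1 = "SCORE_A2", SCORE_A2 = "SCORE_A1",
            DISCARD = "DISCARD")
  for (i in 1:300) {
    e <- sample(bases, 1)
    o <- sample(c(setdiff(bases, e), NA), 1)
    a1 <- sample(bases, 1)
    a2 <- sample(setdiff(bases, a1), 1)
    d <- sample(c(runif(1), NA), 1)
    t <- sample(c(runif(1), NA), 1)
    fwd <- matchAlleles("rs", e, o, a1, a2, d, t)
    rev <- matchAlleles("rs", e, o, a2, a1, d, if (is.na(t)) NA else 1 - t)
    mirrored <- identical(unname(flip[fwd$action]), rev$action) &&
      identical(fwd$reason, rev$reason)
    if (!mirrored)
      fail(sprintf("asymmetric decision for %s/%s on (%s,%s)", e, o, a1, a2))
  }
  succeed()
})

test_that("matchPanel joins on rsID and records decisions per SNP", {
  p <- mixed_panel(seed = 23)
  d <- matchPanel(p$gwas, p$geno)
  expect_identical(sort(d$snp_id), sort(p$truth$snp_id))
  m <- match(d$snp_id, p$truth$snp_id)
  expect_identical(d$action, p$truth$exp_action[m])
  expect_identical(d$reason, p$truth$exp_reason[m])
  expect_identical(S4Vectors::metadata(d)$n_matched, nrow(p$truth))
})
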