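#' Simulate a discovery + target panel with known ground truth
#'
#' Generates a matched pair of inputs -- a discovery summary-statistics
#' table and a target genotype-probability panel -- plus the ground truth
#' needed to check every downstream step: the correct scored allele per SNP
#' and (via [referencePrs()]) exact per-sample scores from a naive loop.
#'
#' Per SNP: a strand-ambiguous (A/T or C/G) allele pair with probability
#' `prop_ambiguous`, otherwise a non-complementary pair; a discovery
#' effect-allele frequency drawn uniformly from `maf_range` and flipped to
#' the major side with probability 1/2; a weight from N(0, 0.1); a p-value
#' from U(0, 1). Target allele order is randomised (so both `A1` and `A2`
#' are exercised), genotypes are Binomial(2, f) draws, a `missing_rate`
#' fraction of calls is blanked, and with probability `imputation_noise`
#' a call's unit probability mass is replaced by a Dirichlet draw
#' concentrated on the true genotype (mode preserved), emulating imputation
#' uncertainty. Finally a `strand_flip_rate` fraction of the
#' *non-ambiguous* SNPs has its target allele letters reverse-complemented
#' -- a pure relabelling applied last, so the returned `geno` and
#' `geno_unflipped` share every genotype draw and must score identically.
#'
#' @param n_samples cohort size (default 264, a community-cohort scale).
#' @param n_snps number of discovery SNPs.
#' @param maf_range range the minor-side frequency is drawn from.
#' @param prop_ambiguous expected fraction of strand-ambiguous SNPs
#'   (about 1/6 of real SNP pairs are A/T or C/G).
#' @param imputation_noise per-call probability of replacing the hard
#'   genotype with a mode-preserving Dirichlet triple.
#' @param strand_flip_rate fraction of non-ambiguous SNPs whose target
#'   alleles are written on the opposite strand.
#' @param missing_rate per-call missingness probability.
#' @param seed RNG seed; identical seeds give identical panels and files.
#' @param dir when non-`NULL`, fixture files are written there
#'   (`sumstats.txt`, `panel.gen`, `panel.sample`, `panel.vcf`) and their
#'   paths returned.
#' @param gen_chrom_column write the GEN file with the 6-field leading
#'   layout (explicit chromosome column) instead of 5.
#' @return List: `gwas` ([GwasStats-class]), `geno` ([GenotypeProbs-class],
#'   with flips applied), `geno_unflipped`, `truth` (per-SNP data frame with
#'   the expected match decision), `flipped_ids`, `paths` (or `NULL`),
#'   `config`.
#' @export
simulatePanel <- function(n_samples = 264, n_snps = 100,
                          maf_range = c(0.05, 0.5), prop_ambiguous = 0.15,
                          imputation_noise = 0.1, strand_flip_rate = 0,
                          missing_rate = 0.02, seed = 1, dir = NULL,
                          gen_chrom_column = FALSE) {
  stopifnot(n_samples >= 1, n_snps >= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            prop_ambiguous >= 0, prop_ambiguous <= 1,
            imputation_noise >= 0, strand_flip_rate >= 0,
            strand_flip_rate <= 1, missing_rate >= 0, missing_rate < 1)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  snp_id <- sprintf("rs%06d", sample.int(999999L, n_snps))
  ambiguous <- runif(n_snps) < prop_ambiguous
  effect <- sample(bases, n_snps, replace = TRUE)
  other <- ifelse(ambiguous, comp[effect],
                  vapply(effect, function(e)
                    sample(setdiff(bases, c(e, comp[[e]])), 1L), ""))
  f_minor <- runif(n_snps, maf_range[1], maf_range[2])
  f <- ifelse(runif(n_snps) < 0.5, 1 - f_minor, f_minor)
  weight <- rnorm(n_snps, 0, 0.1)
  p_value <- runif(n_snps)
  a1_is_effect <- runif(n_snps) < 0.5
  a1 <- ifelse(a1_is_effect, effect, other)
  a2 <- ifelse(a1_is_effect, other, effect)

  # effect-allele counts, then triples in target (a1/a2) orientation
  cnt <- matrix(rbinom(n_snps * n_samples, 2L, rep(f, n_samples)),
                n_snps, n_samples)
  a1_cnt <- ifelse(matrix(a1_is_effect, n_snps, n_samples), cnt, 2L - cnt)
  p11 <- (a1_cnt == 2L) + 0
  p12 <- (a1_cnt == 1L) + 0
  p22 <- (a1_cnt == 0L) + 0

  if (imputation_noise > 0) {
    noisy <- which(matrix(runif(n_snps * n_samples) <
                            min(1, imputation_noise), n_snps, n_samples))
    if (length(noisy)) {
      g1 <- rgamma(length(noisy), 1 + 8 * p11[noisy])
      g2 <- rgamma(length(noisy), 1 + 8 * p12[noisy])
      g3 <- rgamma(length(noisy), 1 + 8 * p22[noisy])
      tot <- g1 + g2 + g3
      p11[noisy] <- g1 / tot
      p12[noisy] <- g2 / tot
      p22[noisy] <- g3 / tot
    }
  }
  miss <- matrix(runif(n_snps * n_samples) < missing_rate,
                 n_snps, n_samples)
  p11[miss] <- 0; p12[miss] <- 0; p22[miss] <- 0

  flipped <- !ambiguous & runif(n_snps) < strand_flip_rate
  a1_out <- ifelse(flipped, comp[a1], a1)
  a2_out <- ifelse(flipped, comp[a2], a2)

  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  pos <- seq_len(n_snps) * 1000L
  geno <- GenotypeProbs(snp_id, a1_out, a2_out, p11, p12, p22,
                        sample_ids, chrom = "1", pos = pos)
  geno_unflipped <- GenotypeProbs(snp_id, a1, a2, p11, p12, p22,
                                  sample_ids, chrom = "1", pos = pos)
  gwas <- GwasStats(snp_id, effect, other, weight, p_value, effect_af = f)

  truth <- data.frame(
    snp_id = snp_id, effect_allele = effect, other_allele = unname(other),
    effect_af = f, weight = weight, p_value = p_value,
    ambiguous = ambiguous, a1_is_effect = a1_is_effect, flipped = flipped,
    a1 = unname(a1_out), a2 = unname(a2_out),
    target_af1 = unname(alleleFrequency(geno)),
    stringsAsFactors = FALSE)
  dec <- .truth_decision(truth)
  truth$exp_action <- dec$action
  truth$exp_reason <- dec$reason

  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      sumstats = file.path(dir, "sumstats.txt"),
      gen = file.path(dir, "panel.gen"),
      sample = file.path(dir, "panel.sample"),
      vcf = file.path(dir, "panel.vcf"),
      pheno = NULL)
    writeSummaryStats(gwas, paths$sumstats)
    writeGenFixture(geno, paths$gen, paths$sample,
                    chrom_column = gen_chrom_column)
    writeVcfFixture(geno, paths$vcf)
  }
  list(gwas = gwas, geno = geno, geno_unflipped = geno_unflipped,
       truth = truth, flipped_ids = snp_id[flipped], paths = paths,
       config = list(n_samples = n_samples, n_snps = n_snps,
                     maf_range = maf_range, prop_ambiguous = prop_ambiguous,
                     imputation_noise = imputation_noise,
                     strand_flip_rate = strand_flip_rate,
                     missing_rate = missing_rate, seed = seed))
}

# expected decision per SNP, written as plain scalar rules straight from the
# matching contract -- deliberately independent of matchAlleles()
.truth_decision <- function(truth) {
  n <- nrow(truth)
  action <- character(n); reason <- character(n)
  zone <- function(x) !is.na(x) && x >= 0.4 && x <= 0.6
  for (i in seq_len(n)) {
    if (truth$ambiguous[i]) {
      d <- truth$effect_af[i]
      t <- if (truth$a1_is_effect[i]) truth$target_af1[i] else
        1 - truth$target_af1[i]
      if (is.na(d) || is.na(t)) {
        action[i] <- "DISCARD"; reason[i] <- "MISSING_AF"
      } else if (zone(d) || zone(t)) {
        action[i] <- "DISCARD"; reason[i] <- "AMBIGUOUS_AF_ZONE"
      } else if ((d < 0.4) == (t < 0.4)) {
        # frequencies agree: the effect letter is where the generator put it
        action[i] <- if (truth$a1_is_effect[i]) "SCORE_A1" else "SCORE_A2"
        reason[i] <- "OK"
      } else {
        # frequencies disagree: the rule assigns the opposite allele
        action[i] <- if (truth$a1_is_effect[i]) "SCORE_A2" else "SCORE_A1"
        reason[i] <- "OK"
      }
    } else {
      action[i] <- if (truth$a1_is_effect[i]) "SCORE_A1" else "SCORE_A2"
      reason[i] <- "OK"
    }
  }
  list(action = action, reason = reason)
}

#' Naive reference polygenic scores from a simulated panel
#'
#' Triple loop over samples, thresholds and SNPs, applying the scoring
#' definitions one number at a time -- the brute-force oracle against which
#' the single-pass scorer is checked. Uses the expected match decision in
#' the truth record, the stored probability triples, and the same missing
#' rule (triple sum below tolerance).
#'
#' @param panel a list from [simulatePanel()].
#' @param thresholds strictly increasing p-value thresholds.
#' @return A [ScoreTable-class].
#' @export
referencePrs <- function(panel, thresholds = c(0.1, 0.2, 0.3, 0.4, 0.5)) {
  geno <- panel$geno
  truth <- panel$truth
  samples <- sampleIds(geno)
  p11 <- assay(geno, "p11"); p12 <- assay(geno, "p12")
  p22 <- assay(geno, "p22")
  raw <- matrix(0, length(samples), length(thresholds))
  counts <- matrix(0L, length(samples), length(thresholds))
  for (s in seq_along(samples)) {
    for (k in seq_along(thresholds)) {
      acc <- 0; m <- 0L
      for (i in seq_len(nrow(truth))) {
        if (truth$exp_action[i] == "DISCARD") next
        if (truth$p_value[i] > thresholds[k]) next
        tr <- c(p11[i, s], p12[i, s], p22[i, s])
        if (sum(tr) < .MISSING_TOL) next
        dose <- if (truth$exp_action[i] == "SCORE_A1")
          2 * tr[1L] + tr[2L] else 2 * tr[3L] + tr[2L]
        acc <- acc + truth$weight[i] * dose
        m <- m + 1L
      }
      raw[s, k] <- acc
      counts[s, k] <- m
    }
  }
  ScoreTable(samples, thresholds, raw, counts)
}

#' Simulate a phenotype with a target variance explained
#'
#' Builds `phenotype = score + noise` from the averaged score at one
#' threshold, with the noise variance set so the population R-squared of the
#' score--phenotype regression equals `r2_target`. Samples with an
#' undefined score are omitted.
#'
#' @param scores a [ScoreTable-class].
#' @param threshold generating threshold (one of `thresholds(scores)`).
#' @param r2_target population variance explained, in (0, 1).
#' @param seed RNG seed.
#' @return Data frame with `sample_id` and `phenotype`.
#' @export
simulatePhenotype <- function(scores, threshold, r2_target, seed = 1) {
  stopifnot(r2_target > 0, r2_target < 1)
  j <- match(threshold, thresholds(scores))
  if (is.na(j)) stop("threshold ", threshold, " not in the score table")
  s <- avgScores(scores)[, j]
  ok <- !is.na(s)
  s <- s[ok]
  if (var(s) == 0) stop("score has zero variance; cannot target an R^2")
  set.seed(seed)
  noise_sd <- sqrt(var(s) * (1 - r2_target) / r2_target)
  data.frame(sample_id = sampleIds(scores)[ok],
             phenotype = s + rnorm(length(s), 0, noise_sd))
}

#' Write a GenotypeProbs panel as GEN + SAMPLE fixture files
#'
#' Probabilities are printed with \%.17g so parsed values round-trip
#' exactly; missing genotypes are the all-zero triple.
#'
#' @param geno a [GenotypeProbs-class].
#' @param gen_path,sample_path output paths.
#' @param chrom_column write the 6-leading-field dialect (chromosome first)
#'   instead of the 5-field one.
#' @return `gen_path`, invisibly.
#' @export
writeGenFixture <- function(geno, gen_path, sample_path,
                            chrom_column = FALSE) {
  ids <- sampleIds(geno)
  writeLines(c("ID_1 ID_2 missing", "0 0 0",
               paste(ids, ids, "0")), sample_path)
  p11 <- assay(geno, "p11"); p12 <- assay(geno, "p12")
  p22 <- assay(geno, "p22")
  rd <- rowData(geno)
  chrom <- ifelse(is.na(rd$chrom), "1", rd$chrom)
  lines <- vapply(seq_len(nrow(geno)), function(i) {
    probs <- as.vector(rbind(p11[i, ], p12[i, ], p22[i, ]))
    lead <- if (chrom_column)
      c(chrom[i], paste0("SNP", i), rd$snp_id[i], rd$pos[i],
        rd$allele1[i], rd$allele2[i])
    else
      c(chrom[i], rd$snp_id[i], rd$pos[i], rd$allele1[i], rd$allele2[i])
    paste(c(lead, sprintf("%.17g", probs)), collapse = " ")
  }, "")
  writeLines(lines, gen_path)
  invisible(gen_path)
}

#' Write a GenotypeProbs panel as a VCF fixture with GT and GP fields
#'
#' `REF = allele1`, `ALT = allele2`; GT is the hard call (triple argmax,
#' ties to the heterozygote) and GP the probability triple printed with
#' \%.17g. Missing genotypes become `./.` with GP `.`.
#'
#' @param geno a [GenotypeProbs-class].
#' @param vcf_path output path.
#' @return `vcf_path`, invisibly.
#' @export
writeVcfFixture <- function(geno, vcf_path) {
  ids <- sampleIds(geno)
  p11 <- assay(geno, "p11"); p12 <- assay(geno, "p12")
  p22 <- assay(geno, "p22")
  miss <- missingMask(geno)
  rd <- rowData(geno)
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste0('##FORMAT=<ID=GP,Number=G,Type=Float,',
           'Description="Genotype posterior probabilities">'),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"))
  rows <- vapply(seq_len(nrow(geno)), function(i) {
    cells <- vapply(seq_along(ids), function(s) {
      if (miss[i, s]) return("./.:.")
      tr <- c(p11[i, s], p12[i, s], p22[i, s])
      gt <- if (tr[2L] >= tr[1L] && tr[2L] >= tr[3L]) "0/1"
            else if (tr[1L] >= tr[3L]) "0/0" else "1/1"
      paste0(gt, ":", paste(sprintf("%.17g", tr), collapse = ","))
    }, "")
    paste(c(ifelse(is.na(rd$chrom[i]), "1", rd$chrom[i]),
            ifelse(is.na(rd$pos[i]), i * 1000L, rd$pos[i]),
            rd$snp_id[i], rd$allele1[i], rd$allele2[i], ".", "PASS", ".",
            "GT:GP", cells), collapse = "\t")
  }, "")
  writeLines(c(header, rows), vcf_path)
  invisible(vcf_path)
}

#' Write a phenotype fixture file
#'
#' @param phenotype data frame from [simulatePhenotype()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePhenotypeFixture <- function(phenotype, path) {
  write.table(
    data.frame(sample_id = phenotype$sample_id,
               phenotype = sprintf("%.17g", phenotype$phenotype)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
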