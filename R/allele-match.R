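#' Match-decision vocabulary
#'
#' Actions and reasons a SNP can receive during effect-allele
#' reconciliation. `AF_CONFLICT` is reserved in the vocabulary but no
#' current rule emits it: every ambiguous frequency combination falls into
#' the zone, same-side or opposite-side branch.
#'
#' @name matchVocabulary
#' @keywords internal
NULL

MATCH_ACTIONS <- c("SCORE_A1", "SCORE_A2", "DISCARD")
MATCH_REASONS <- c("OK", "AMBIGUOUS_AF_ZONE", "AMBIGUOUS_DISABLED",
                   "ALLELE_MISMATCH", "MISSING_AF", "AF_CONFLICT", "NON_SNP")

# closed uncertainty zone for the ambiguous-SNP frequency rule
.AF_ZONE <- c(0.4, 0.6)

#' Is an allele pair strand-ambiguous?
#'
#' A SNP whose two alleles are reverse complements of each other (A/T or
#' C/G) reads the same on both strands, so strand cannot be inferred from
#' the alleles alone.
#'
#' @param allele1,allele2 single bases in A/C/G/T (vectorised).
#' @return Logical vector.
#' @examples
#' isStrandAmbiguous("A", "T")  # TRUE
#' isStrandAmbiguous("A", "G")  # FALSE
#' @export
isStrandAmbiguous <- function(allele1, allele2) {
  reverseComplementAllele(allele1) == allele2
}

#' Reverse complement of a single allele
#'
#' @param allele character vector of single bases in A/C/G/T.
#' @return The complementary base(s): A<->T, C<->G.
#' @export
reverseComplementAllele <- function(allele) {
  chartr("ACGT", "TGCA", toupper(allele))
}

.in_zone <- function(f) f >= .AF_ZONE[1L] & f <= .AF_ZONE[2L]

.decision <- function(snp_id, action, reason) {
  list(snp_id = snp_id, action = action,
       scored_allele = switch(action, SCORE_A1 = "A1", SCORE_A2 = "A2", NA_character_),
       reason = reason)
}

# frequency rule for an ambiguous SNP once the effect allele has been
# oriented onto target allele1 (t = target frequency of the oriented allele)
.af_rule <- function(snp_id, d, t, flip) {
  if (is.na(d) || is.na(t))
    return(.decision(snp_id, "DISCARD", "MISSING_AF"))
  if (.in_zone(d) || .in_zone(t))
    return(.decision(snp_id, "DISCARD", "AMBIGUOUS_AF_ZONE"))
  same_side <- (d < .AF_ZONE[1L] && t < .AF_ZONE[1L]) ||
               (d > .AF_ZONE[2L] && t > .AF_ZONE[2L])
  action <- if (same_side) "SCORE_A1" else "SCORE_A2"
  if (flip) action <- if (action == "SCORE_A1") "SCORE_A2" else "SCORE_A1"
  .decision(snp_id, action, "OK")
}

#' Decide which target allele carries the discovery weight
#'
#' For a non-ambiguous target pair, the effect allele is matched against the
#' target alleles directly and, failing that, against their reverse
#' complements (the target may be reported on the opposite strand); when the
#' discovery file names the other allele it must agree too. A
#' strand-ambiguous pair is its own reverse complement, so letters cannot
#' settle orientation; instead, when `use_af_matching` is on, the discovery
#' effect-allele frequency is compared with the target allele-1 frequency:
#' both on the same side of the 0.4--0.6 zone means allele 1 carries the
#' effect, opposite sides means allele 2 does, and any frequency inside the
#' closed zone (on either side) discards the SNP because assignment would be
#' guesswork. Frequencies are interpreted for the allele the effect letter
#' maps onto, so an effect allele written as target allele 2 uses `1 -
#' target_af1` with the outcomes mirrored.
#'
#' @param snp_id SNP identifier carried into the decision.
#' @param effect_allele,other_allele discovery alleles (`other_allele` may be
#'   `NA`, weakening the consistency check).
#' @param allele1,allele2 target alleles.
#' @param effect_af discovery effect-allele frequency, `NA` when absent.
#' @param target_af1 target allele-1 frequency from [alleleFrequency()];
#'   `NA` when undefined (all samples missing).
#' @param use_af_matching enable the ambiguous-SNP frequency rescue; when
#'   `FALSE` every ambiguous SNP is discarded.
#' @return A list with `snp_id`, `action` (`SCORE_A1`/`SCORE_A2`/`DISCARD`),
#'   `scored_allele` (`"A1"`/`"A2"` or `NA`), `reason` (`"OK"` or a discard
#'   reason). Every input yields a decision; no error paths.
#' @examples
#' matchAlleles("rs1", "A", "G", "A", "G", NA, NA)          # SCORE_A1
#' matchAlleles("rs1", "A", "G", "T", "C", NA, NA)          # SCORE_A1, reverse strand
#' matchAlleles("rs2", "A", "T", "A", "T", 0.3, 0.7)        # SCORE_A2
#' matchAlleles("rs2", "A", "T", "A", "T", 0.5, 0.3)        # DISCARD, AF zone
#' @export
matchAlleles <- function(snp_id, effect_allele, other_allele,
                         allele1, allele2, effect_af, target_af1,
                         use_af_matching = TRUE) {
  bases <- c("A", "C", "G", "T")
  if (!(effect_allele %in% bases) ||
      (!is.na(other_allele) && !(other_allele %in% bases)) ||
      !(allele1 %in% bases) || !(allele2 %in% bases) || allele1 == allele2)
    return(.decision(snp_id, "DISCARD", "NON_SNP"))

  if (isStrandAmbiguous(allele1, allele2)) {
    if (!is.na(other_allele) &&
        !setequal(c(effect_allele, other_allele), c(allele1, allele2)))
      return(.decision(snp_id, "DISCARD", "ALLELE_MISMATCH"))
    if (effect_allele == allele1) {
      orient <- FALSE
    } else if (effect_allele == allele2) {
      orient <- TRUE
    } else {
      return(.decision(snp_id, "DISCARD", "ALLELE_MISMATCH"))
    }
    if (!use_af_matching)
      return(.decision(snp_id, "DISCARD", "AMBIGUOUS_DISABLED"))
    t <- if (orient) 1 - target_af1 else target_af1
    return(.af_rule(snp_id, effect_af, t, flip = orient))
  }

  consistent <- function(eff, oth) {
    if (effect_allele == eff && (is.na(other_allele) || other_allele == oth))
      "SCORE_A1"
    else if (effect_allele == oth && (is.na(other_allele) || other_allele == eff))
      "SCORE_A2"
    else NA_character_
  }
  act <- consistent(allele1, allele2)
  if (is.na(act))  # reverse-strand retry on the whole target pair
    act <- consistent(reverseComplementAllele(allele1),
                      reverseComplementAllele(allele2))
  if (is.na(act))
    return(.decision(snp_id, "DISCARD", "ALLELE_MISMATCH"))
  .decision(snp_id, act, "OK")
}

#' Reconcile a whole panel of SNPs
#'
#' Joins summary statistics and target genotypes on rsID and runs
#' [matchAlleles()] for every SNP present in both, using
#' [alleleFrequency()] for the target side of the ambiguous-SNP rule.
#' Target SNPs whose id is duplicated in the genotype data cannot be joined
#' unambiguously and are dropped with a message (counted in `metadata()`).
#'
#' @param gwas a [GwasStats-class].
#' @param geno a [GenotypeProbs-class].
#' @param use_af_matching see [matchAlleles()].
#' @return A [S4Vectors::DataFrame] with one row per matched SNP: `snp_id`,
#'   `action`, `scored_allele`, `reason`, `p_value`, `weight`, and the row
#'   index `geno_row` into `geno`. `metadata()` records counts of SNPs only
#'   in one input.
#' @export
matchPanel <- function(gwas, geno, use_af_matching = TRUE) {
  gids <- snpIds(geno)
  dup <- unique(gids[duplicated(gids)])
  if (length(dup)) {
    message(length(dup), " duplicated target SNP id(s) dropped")
  }
  usable <- !(gids %in% dup)
  common <- intersect(snpIds(gwas), gids[usable])
  gw_idx <- match(common, snpIds(gwas))
  ge_idx <- match(common, gids)
  af1 <- alleleFrequency(geno)

  n <- length(common)
  action <- character(n); scored <- character(n); reason <- character(n)
  ea <- effectAllele(gwas); oa <- otherAllele(gwas); daf <- effectAF(gwas)
  a1 <- allele1(geno); a2 <- allele2(geno)
  for (k in seq_len(n)) {
    i <- gw_idx[k]; j <- ge_idx[k]
    d <- matchAlleles(common[k], ea[i], oa[i], a1[j], a2[j],
                      daf[i], af1[j], use_af_matching = use_af_matching)
    action[k] <- d$action
    scored[k] <- d$scored_allele
    reason[k] <- d$reason
  }
  out <- DataFrame(
    snp_id = common, action = action, scored_allele = scored,
    reason = reason, p_value = pValues(gwas)[gw_idx],
    weight = effectWeights(gwas)[gw_idx], geno_row = ge_idx)
  metadata(out) <- list(
    n_sumstats = nrow(gwas), n_target = length(gids),
    n_target_dup = length(dup), n_matched = n,
    n_sumstats_only = nrow(gwas) - n,
    n_target_only = sum(usable) - n)
  out
}
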