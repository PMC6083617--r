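---
title: "Polygenic scoring from genotype probabilities: model and methods"
author: "polyscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic scoring from genotype probabilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyscore)
```

## The model

A polygenic risk score (PRS) summarises the additive contribution of many
common variants to a trait. Given a discovery GWAS that reports, for each
SNP $i$, an effect allele, a weight $\beta_i$ (the natural logarithm of the
odds ratio for binary traits, or the regression beta for continuous ones)
and an association p-value $p_i$, the score of a target individual is

$$\mathrm{PRS} = \sum_{i\,:\,p_i \le P_T} \beta_i \, G_i,$$

where $G_i$ is the individual's count of the effect allele and $P_T$ is a
p-value threshold selecting how much of the discovery signal enters the
score. Imputed genotypes are not certain counts but posterior probabilities
over the three diploid genotypes; `polyscore` therefore scores the
*expected* dosage

$$G_i = 2\,p(AA_i) + p(AB_i) \in [0, 2],$$

with $p(AA_i)$ and $p(AB_i)$ the posterior probabilities of carrying two
and one copies of the effect allele. With hard-called data the triples are
degenerate and this reduces exactly to the allele count, so a single code
path serves array data, hard calls and posterior probabilities — one of the
invariants the test suite asserts.

Because imputation quality varies, the number of SNPs with a non-missing
genotype varies across individuals. The reported score is therefore the
weighted **average**, the raw sum divided by that individual's own SNP
count at that threshold; an individual with no scorable SNP gets a missing
value, never a zero — a zero is a real score. The per-sample counts are
part of the output.

All requested thresholds are computed in a single pass over the genotype
stream: each SNP is binned at its smallest qualifying threshold (inclusion
is $p \le P_T$, closed, so a SNP with $p$ exactly 0.5 enters $P_T = 0.5$)
and the per-bin partial sums are cumulated at the end.

## Effect-allele reconciliation

The discovery and target data may report a SNP on opposite strands, and
the discovery effect allele can sit in either target allele column. For a
**non-ambiguous** allele pair the letters decide: the effect (and, when
present, the other) allele is matched against the target pair directly,
then against its reverse complement; failure on both is an
`ALLELE_MISMATCH` discard.

A **strand-ambiguous** SNP (A/T or C/G) is its own reverse complement, so
letters cannot decide, and most tools simply drop these SNPs — up to about
a sixth of a typical panel. `polyscore` instead rescues them by comparing
allele *frequencies*: let $d$ be the discovery effect-allele frequency and
$t$ the target frequency of the allele the effect letter names. If both
fall on the same side of the uncertainty zone $[0.4, 0.6]$ (both below
0.4, or both above 0.6) that allele carries the weight; if they fall on
opposite sides the *other* target allele does; if **either** frequency
lies inside the closed zone the SNP is discarded (`AMBIGUOUS_AF_ZONE`),
because near 0.5 the two alleles are statistically indistinguishable and a
misassigned weight enters the score with the wrong sign. The target
frequency is estimated from the expected dosage over non-missing samples,
consistent with how scoring treats the same probabilities.

Design points the data do not decide, fixed here once:

* The zone test is applied to **both** frequencies, closed at both
  boundaries (a value of exactly 0.4 or 0.6 discards). Testing only one
  side would score SNPs where the other cohort is uninformative.
* An ambiguous SNP with no discovery frequency (or an all-missing target
  SNP) is discarded (`MISSING_AF`) rather than scored by letters alone —
  conservative, since the letters carry no strand information.
* The rescue can be disabled (`use_af_matching = FALSE`), e.g. when the
  discovery and target cohorts differ in ancestry and frequencies are not
  comparable; every ambiguous SNP is then discarded
  (`AMBIGUOUS_DISABLED`). The rule assumes comparable population
  structure; it is not a substitute for strand alignment against a
  reference.
* The decision vocabulary reserves an `AF_CONFLICT` reason, but the rule
  as specified covers every frequency combination with the zone /
  same-side / opposite-side branches, so no code path emits it.
* Duplicated rsIDs in the summary statistics drop **all** copies (a wrong
  weight is worse than a missing SNP); duplicated target ids are dropped
  from the join and counted.

Every decision is recorded: the SNP log lists, per threshold, the SNPs
scored and via which target allele column (`A1`/`A2`), and the discarded
SNPs with verbatim reasons. On every panel the log satisfies a
conservation identity — scored at the largest threshold, plus scored SNPs
above it, plus discards, equals the matched total — which the tests assert
on randomised fixtures.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `thresholds` | 0.1, 0.2, 0.3, 0.4, 0.5 | p-value thresholds $P_T$ (unitless probabilities, strictly increasing, closed inclusion) |
| `effect_is_or` | `TRUE` | effect column is an odds ratio; weights become $\ln(\mathrm{OR})$ |
| `use_af_matching` | `TRUE` | ambiguous-SNP frequency rescue on/off |
| `column_map` | PGC-style (`SNP`, `A1`, `A2`, `OR`, `P`, `FRQ_A`) | summary-statistics header names |
| `prob_source` | `GP` | VCF field to read: posteriors (`GP`) or hard calls (`GT`) |
| `chunk_size` | all SNPs | stream chunking; results are chunking-invariant |

The 0.4–0.6 zone is part of the method definition rather than a tuning
knob and is deliberately not exposed as an argument.

## Numerical choices

* Probability triples are **never renormalised**: sub-unit mass is
  legitimate imputation output and the dosage formula uses the raw values.
  Mass above $1 + 10^{-6}$ is a malformed input. A triple summing to below
  $10^{-9}$ is a missing genotype (the GEN all-zero convention).
* Hard-call conversion takes the triple's argmax, ties broken toward the
  heterozygote (the common "best guess" practice).
* Accumulation follows SNP stream order; merging chunked partial tables
  only reassociates additions, so chunked and unchunked runs agree to
  floating-point reassociation error (asserted below $10^{-12}$).
* Score files print 10 significant digits with `NA` for undefined
  averages; fixture writers print probabilities at full precision (17
  significant digits) so files round-trip exactly.
* Model fits are ordinary least squares; reported $R^2$ is unadjusted, the
  F statistic has $(1, n-2)$ degrees of freedom, and the best threshold is
  the largest $R^2$ with ties to the **smaller** threshold (fewer SNPs,
  more parsimonious). A zero-variance score flags the fit as undefined
  rather than reporting $R^2 = 0$.

## The synthetic panel generator

`simulatePanel()` produces matched summary-statistics, GEN/SAMPLE and VCF
fixtures with a known ground truth, so every pipeline stage can be tested
without any external download. Genotypes are Binomial(2, $f$) draws at a
SNP-specific frequency; weights are N(0, 0.1); p-values uniform. Defaults
are fixed to a plausible community-cohort setting: 264 samples, minor-side
frequency uniform on (0.05, 0.5) with random major/minor orientation, 15%
strand-ambiguous SNPs (roughly the genome-wide share of A/T and C/G
pairs), 2% missing calls, and a 10% imputation-noise rate under which a
call's unit mass is replaced by a Dirichlet draw with concentration
$1 + 8e$ centred on the true genotype — mode-preserving, so hard calls
remain recoverable, yet enough to separate probability scoring from
hard-call scoring. Strand flips are applied last as a pure relabelling, so
a flipped panel and its unflipped twin share every genotype draw and must
score identically — the property the strand-flip tests exploit.

The generator emulates none of linkage disequilibrium, population
stratification, genotyping batch effects or realistic chromosomal
coordinates. Passing tests therefore demonstrate the *arithmetic and
bookkeeping* of scoring — allele reconciliation, thresholding, missing
handling, averaging — not robustness to the correlation structure of real
cohorts; with real data the discovery file should be LD-clumped upstream,
and frequency-based rescue should only be used across cohorts of
comparable ancestry.

`referencePrs()` is the deliberate opposite of the production scorer: a
triple loop over samples, thresholds and SNPs applying the definitions one
number at a time. It exists to be obviously correct and serves as the
oracle in the validation suite; agreement is required to $10^{-12}$
relative.

## Validation problem sizes

The shipped checks use panels of up to 50 SNPs by 20 samples (200
randomised panels across GEN/VCF and GP/GT input modes) for oracle
equivalence, a 0.05-step frequency grid over all allele pairs for the
matching rule, and 100 replicates of 2000 samples by 100 SNPs for
phenotype recovery at target $R^2$ of 0.05 and 0.2, where the mean
recovered $R^2$ must fall within three Monte-Carlo standard errors of the
target and the generating threshold must be selected in the majority of
replicates. These sizes keep the whole suite at a few minutes on one core
while leaving each property statistically sharp.

## Known limitations

* rsID is the join key; positional joining and liftover are out of scope.
* No LD clumping, covariate-adjusted models, BGEN/PLINK-format input or
  dosage (`DS`) VCF fields.
* The frequency rescue cannot recover ambiguous SNPs whose frequency is
  genuinely near 0.5 — they are discarded by design, and that is the
  method's stated trade-off between inclusiveness and certainty.

## A minimal run

```{r example, eval = FALSE}
panel <- simulatePanel(n_samples = 50, n_snps = 60, seed = 1,
                       dir = tempdir())
res <- runPrs(panel$paths$sumstats, panel$paths$gen,
              out = file.path(tempdir(), "demo"),
              sample = panel$paths$sample, format = "gen",
              snp_log = TRUE)
res$scores
head(avgScores(res$scores))
```
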