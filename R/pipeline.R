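.atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not move temporary output into place: ", path)
  invisible(path)
}

#' Run the full polygenic-scoring pipeline
#'
#' Reads discovery summary statistics and target genotypes, reconciles
#' effect alleles (with the ambiguous-SNP allele-frequency rescue unless
#' disabled), scores every sample at every threshold in one pass, and
#' writes the score table plus an optional SNP log and a run summary. All
#' outputs are written atomically (temporary file, then rename), so a
#' failed run leaves no partial score file. The pipeline is deterministic:
#' identical inputs and configuration give byte-identical outputs.
#'
#' @param sumstats path to the discovery summary-statistics file.
#' @param geno path to the target genotypes (GEN or VCF).
#' @param out output prefix; writes `<out>.score.txt`,
#'   `<out>.summary.txt`, and optionally `<out>.snplog.txt`,
#'   `<out>.fits.txt`.
#' @param sample path to the SAMPLE file (GEN format only).
#' @param format `"gen"` or `"vcf"`.
#' @param prob_source `"GP"` or `"GT"` (VCF only).
#' @param thresholds strictly increasing p-value thresholds in (0, 1].
#' @param effect_is_or whether the effect column holds odds ratios
#'   (weights become `ln(OR)`) or betas.
#' @param use_af_matching enable the ambiguous-SNP frequency rescue.
#' @param snp_log also write the per-threshold SNP log.
#' @param pheno optional phenotype file; when given, per-threshold
#'   regression fits are computed and written.
#' @param column_map summary-statistics header mapping, see
#'   [sumstatsColumns()].
#' @return Invisibly, a list with `scores` ([ScoreTable-class]), `log`
#'   ([SnpLog-class] or `NULL`), `fits` (data frame or `NULL`),
#'   `summary` (named list of counts), and `paths`.
#' @export
runPrs <- function(sumstats, geno, out,
                   sample = NULL, format = c("gen", "vcf"),
                   prob_source = c("GP", "GT"),
                   thresholds = c(0.1, 0.2, 0.3, 0.4, 0.5),
                   effect_is_or = TRUE, use_af_matching = TRUE,
                   snp_log = FALSE, pheno = NULL,
                   column_map = sumstatsColumns()) {
  format <- match.arg(format)
  prob_source <- match.arg(prob_source)
  tchk <- .check_thresholds(thresholds)
  if (!isTRUE(tchk)) stop(tchk)
  if (format == "gen" && is.null(sample))
    stop("GEN input requires a SAMPLE file")

  stats <- readSummaryStats(sumstats, column_map = column_map,
                            effect_is_or = effect_is_or)
  dd <- dedupStats(stats)
  stats <- dd$stats
  gt <- if (format == "gen") readGen(geno, sample)
        else readGenotypeVcf(geno, prob_source = prob_source)

  decisions <- matchPanel(stats, gt, use_af_matching = use_af_matching)
  scores <- scorePanel(stats, gt, decisions, thresholds = thresholds)
  log <- buildSnpLog(decisions, thresholds)

  fits <- NULL
  if (!is.null(pheno)) {
    phenotype <- readPhenotype(pheno)
    fits <- fitThresholds(scores, phenotype)
  }

  reason_counts <- table(factor(
    decisions$reason[decisions$action == "DISCARD"], levels = MATCH_REASONS))
  per_thr <- vapply(thresholds, function(t)
    nrow(scoredSnps(log, t)), integer(1))
  summary_kv <- c(
    list(
      n_sumstats_input = metadata(stats)$n_input,
      n_sumstats_rejected = nrow(metadata(stats)$rejected),
      n_sumstats_dedup_removed = length(dd$removed),
      n_sumstats = nrow(stats),
      n_target = length(snpIds(gt)),
      n_matched = metadata(decisions)$n_matched,
      n_scored = sum(decisions$action != "DISCARD"),
      n_discarded = sum(decisions$action == "DISCARD"),
      n_sumstats_unmatched = metadata(decisions)$n_sumstats_only,
      n_target_unmatched = metadata(decisions)$n_target_only),
    setNames(as.list(as.integer(reason_counts[MATCH_REASONS != "OK"])),
             paste0("discard_", MATCH_REASONS[MATCH_REASONS != "OK"])),
    setNames(as.list(per_thr),
             sprintf("snps_at_%g", thresholds)))

  paths <- list(score = paste0(out, ".score.txt"),
                summary = paste0(out, ".summary.txt"))
  .atomic_write(paths$score, function(p) writeScores(scores, p))
  if (snp_log) {
    paths$snplog <- paste0(out, ".snplog.txt")
    .atomic_write(paths$snplog, function(p) writeSnpLog(log, p))
  }
  if (!is.null(fits)) {
    paths$fits <- paste0(out, ".fits.txt")
    .atomic_write(paths$fits, function(p)
      write.table(fits, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }
  .atomic_write(paths$summary, function(p)
    writeLines(paste(names(summary_kv), unlist(summary_kv), sep = "="), p))

  message(sprintf(
    "scored %d/%d matched SNPs (%d discarded) for %d samples at %d thresholds",
    summary_kv$n_scored, summary_kv$n_matched, summary_kv$n_discarded,
    length(sampleIds(scores)), length(thresholds)))
  invisible(list(scores = scores, log = log, fits = fits,
                 summary = summary_kv, paths = paths))
}

#' Parse command-line flags for the scoring tool
#'
#' Thin option parser used by the `polyscore.R` script in
#' `inst/scripts/`; exported so the flag surface is testable. Returns the
#' argument list for [runPrs()].
#'
#' @param args character vector of command-line arguments.
#' @return Named list of [runPrs()] arguments.
#' @export
parsePrsArgs <- function(args) {
  if (!requireNamespace("optparse", quietly = TRUE))
    stop("the command-line interface needs the optparse package")
  ol <- list(
    optparse::make_option("--sumstats", type = "character"),
    optparse::make_option("--geno", type = "character"),
    optparse::make_option("--sample", type = "character", default = NULL),
    optparse::make_option("--format", type = "character", default = "gen"),
    optparse::make_option("--prob-source", type = "character",
                          default = "gp", dest = "prob_source"),
    optparse::make_option("--thresholds", type = "character",
                          default = "0.1,0.2,0.3,0.4,0.5"),
    optparse::make_option("--effect-or", action = "store_true",
                          default = TRUE, dest = "effect_is_or"),
    optparse::make_option("--effect-beta", action = "store_false",
                          dest = "effect_is_or"),
    optparse::make_option("--af-matching", action = "store_true",
                          default = TRUE, dest = "use_af_matching"),
    optparse::make_option("--no-af-matching", action = "store_false",
                          dest = "use_af_matching"),
    optparse::make_option("--snp-log", action = "store_true",
                          default = FALSE, dest = "snp_log"),
    optparse::make_option("--pheno", type = "character", default = NULL),
    optparse::make_option("--out", type = "character"),
    optparse::make_option("--snp-col", type = "character", default = "SNP",
                          dest = "snp_col"),
    optparse::make_option("--a1-col", type = "character", default = "A1",
                          dest = "a1_col"),
    optparse::make_option("--a2-col", type = "character", default = "A2",
                          dest = "a2_col"),
    optparse::make_option("--effect-col", type = "character",
                          default = "OR", dest = "effect_col"),
    optparse::make_option("--p-col", type = "character", default = "P",
                          dest = "p_col"),
    optparse::make_option("--af-col", type = "character", default = "FRQ_A",
                          dest = "af_col"),
    optparse::make_option("--log-level", type = "character",
                          default = "info", dest = "log_level"))
  opt <- optparse::parse_args(optparse::OptionParser(option_list = ol),
                              args = args)
  for (req in c("sumstats", "geno", "out"))
    if (is.null(opt[[req]])) stop("missing required flag: --", req)
  list(
    sumstats = opt$sumstats, geno = opt$geno, out = opt$out,
    sample = opt$sample, format = tolower(opt$format),
    prob_source = toupper(opt$prob_source),
    thresholds = sort(as.numeric(strsplit(opt$thresholds, ",")[[1]])),
    effect_is_or = opt$effect_is_or,
    use_af_matching = opt$use_af_matching,
    snp_log = opt$snp_log, pheno = opt$pheno,
    column_map = sumstatsColumns(
      snp = opt$snp_col, a1 = opt$a1_col, a2 = opt$a2_col,
      effect = opt$effect_col, p = opt$p_col, af = opt$af_col))
}
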