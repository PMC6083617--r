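write_gen_fixture <- function(gen_lines, sample_ids) {
  gen <- tempfile(fileext = ".gen")
  smp <- tempfile(fileext = ".sample")
  writeLines(gen_lines, gen)
  writeLines(c("ID_1 ID_2 missing", "0 0 0",
               paste(sample_ids, sample_ids, "0")), smp)
  list(gen = gen, sample = smp)
}

test_that("GEN rows parse into exact, unrenormalised triples", {
  fx <- write_gen_fixture(c("1 rs1 1000 A G 1 0 0",
                            "1 rs2 2000 C T 0 0 0",
                            "1 rs3 3000 G T 0.1 0.8 0.1"), "S1")
  g <- suppressMessages(readGen(fx$gen, fx$sample))
  expect_s4_class(g, "GenotypeProbs")
  expect_identical(sampleIds(g), "S1")
  expect_identical(as.vector(SummarizedExperiment::assay(g, "p11")),
                   c(1, 0, 0.1))
  expect_identical(as.vector(SummarizedExperiment::assay(g, "p12")),
                   c(0, 0, 0.8))
  # all-zero triple is the missing convention
  expect_identical(as.vector(missingMask(g)), c(FALSE, TRUE, FALSE))
  expect_identical(allele1(g), c("A", "C", "G"))
})

test_that("both GEN leading-field dialects are detected from the cohort size", {
  five <- write_gen_fixture("1 rs1 1000 A G 1 0 0 0 1 0", c("S1", "S2"))
  expect_message(g5 <- readGen(five$gen, five$sample), "5 leading")
  six <- write_gen_fixture("1 SNP1 rs1 1000 A G 1 0 0 0 1 0", c("S1", "S2"))
  expect_message(g6 <- readGen(six$gen, six$sample), "6 leading")
  expect_identical(snpIds(g5), snpIds(g6))
  expect_identical(SummarizedExperiment::assay(g5, "p12"),
                   SummarizedExperiment::assay(g6, "p12"))
})

test_that("malformed GEN rows fail naming the line", {
  fx <- write_gen_fixture(c("1 rs1 1000 A G 1 0 0 0 1 0",
                            "1 rs2 2000 C T 1 0 0"), c("S1", "S2"))
  expect_error(suppressMessages(readGen(fx$gen, fx$sample)), "line 2")
  short <- write_gen_fixture("1 rs1 1000 A G 1 0", "S1")
  expect_error(readGen(short$gen, short$sample), "line 1")
})

test_that("VCF GT hard calls and GP posteriors both map to triples", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
    '##FORMAT=<ID=GP,Number=G,Type=Float,Description="p">',
    paste(c("#CHROM","POS","ID","REF","ALT","QUAL","FILTER","INFO",
            "FORMAT","S1","S2"), collapse = "\t"),
    paste(c("1","100","rs1","A","G",".",".",".","GT:GP",
            "0/1:0.1,0.8,0.1", "1/1:0,0.2,0.8"), collapse = "\t"),
    paste(c("1","200","rs2","C","T",".",".",".","GT:GP",
            "./.:.", "0/0:0.9,0.1,0.0"), collapse = "\t"),
    paste(c("1","300","rs3","C","T,G",".",".",".","GT:GP",
            "0/1:.", "0/0:."), collapse = "\t")), vcf)

  gt <- suppressMessages(readGenotypeVcf(vcf, prob_source = "GT"))
  expect_identical(snpIds(gt), c("rs1", "rs2"))  # multi-allelic skipped
  expect_identical(as.vector(SummarizedExperiment::assay(gt, "p12")[1, ]),
                   c(1, 0))
  expect_identical(as.vector(SummarizedExperiment::assay(gt, "p22")[1, ]),
                   c(0, 1))
  expect_identical(as.vector(missingMask(gt)[2, ]), c(TRUE, FALSE))

  gp <- suppressMessages(readGenotypeVcf(vcf, prob_source = "GP"))
  expect_identical(as.vector(SummarizedExperiment::assay(gp, "p11")[2, ]),
                   c(0, 0.9))
  expect_identical(as.vector(SummarizedExperiment::assay(gp, "p12")[1, ]),
                   c(0.8, 0.2))

  vcf2 <- tempfile(fileext = ".vcf")
  writeLines(c(readLines(vcf)[1:4],
               paste(c("1","100","rs1","A","G",".",".",".","GT",
                       "0/1","1/1"), collapse = "\t")), vcf2)
  expect_error(readGenotypeVcf(vcf2, prob_source = "GP"), "GP")
})

test_that("target allele-1 frequency is the halved mean expected dosage", {
  g <- snp_from_triples(list(c(1, 0, 0), c(1, 0, 0)))
  expect_identical(unname(alleleFrequency(g)), 1)
  g2 <- snp_from_triples(list(c(1, 0, 0), c(0, 0, 1)))
  expect_identical(unname(alleleFrequency(g2)), 0.5)
  g3 <- snp_from_triples(list(c(0.5, 0.5, 0), c(0, 1, 0)))
  expect_identical(unname(alleleFrequency(g3)), 0.625)
  # missing samples are excluded; all-missing is undefined
  g4 <- snp_from_triples(list(c(1, 0, 0), c(0, 0, 0)))
  expect_identical(unname(alleleFrequency(g4)), 1)
  g5 <- snp_from_triples(list(c(0, 0, 0)))
  expect_true(is.na(alleleFrequency(g5)))
})

test_that("allele-1 and swapped allele-2 frequencies are complementary", {
  set.seed(3)
  for (rep in 1:10) {
    n <- 15
    tr <- lapply(seq_len(n), function(i) {
      x <- rgamma(3, 1); x / sum(x)
    })
    g <- snp_from_triples(tr)
    swapped <- snp_from_triples(lapply(tr, rev), allele1 = "G", allele2 = "A")
    expect_equal(unname(alleleFrequency(g) + alleleFrequency(swapped)), 1,
                 tolerance = 1e-12)
  }
})

test_that("GEN and VCF files encoding the same panel parse identically", {
  p <- mixed_panel(seed = 19)
  d <- tempfile(); dir.create(d)
  writeGenFixture(p$geno, file.path(d, "x.gen"), file.path(d, "x.sample"))
  writeVcfFixture(p$geno, file.path(d, "x.vcf"))
  from_gen <- suppressMessages(readGen(file.path(d, "x.gen"),
                                       file.path(d, "x.sample")))
  from_vcf <- suppressMessages(readGenotypeVcf(file.path(d, "x.vcf"), "GP"))
  expect_identical(snpIds(from_gen), snpIds(from_vcf))
  expect_identical(sampleIds(from_gen), sampleIds(from_vcf))
  for (a in c("p11", "p12", "p22"))
    expect_identical(SummarizedExperiment::assay(from_gen, a),
                     SummarizedExperiment::assay(from_vcf, a))
})

test_that("probability triples above unit mass are rejected", {
  expect_error(snp_from_triples(list(c(0.9, 0.9, 0.9))), "sum")
  # sub-unit mass is legitimate imputation output, kept as-is
  g <- snp_from_triples(list(c(0.3, 0.3, 0.3)))
  expect_identical(as.vector(SummarizedExperiment::assay(g, "p11")), 0.3)
})
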