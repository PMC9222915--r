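test_that("the two-contig / at-most-one-singleton filter is exact", {
  expect_true(filterSample(fakeAssembly(2, 0))$pass)
  expect_true(filterSample(fakeAssembly(2, 1))$pass)
  f1 <- filterSample(fakeAssembly(2, 2))
  expect_false(f1$pass)
  expect_equal(f1$reason, "singleton_count")
  f2 <- filterSample(fakeAssembly(3, 0))
  expect_false(f2$pass)
  expect_equal(f2$reason, "contig_count")
  f3 <- filterSample(fakeAssembly(1, 0))
  expect_false(f3$pass)
  expect_equal(f3$reason, "contig_count")
})

test_that("diploid genotypes are called from two valid contigs", {
  peps <- referencePeptides()
  a9 <- peps[["Allele_9"]]; a2 <- peps[["Allele_2"]]
  asm <- fakeAssembly(2, 0)
  asm@contigs <- Biostrings::DNAStringSet(c(
    contig_1 = embedPeptide(a9, seed = 1),
    contig_2 = embedPeptide(a2, seed = 2)))
  g <- callGenotype("s1", "buckfast", asm)
  expect_equal(g$status, "ok")
  expect_equal(sort(c(g$genotype$allele_a, g$genotype$allele_b)),
               sort(c(a9, a2)))
  expect_false(g$genotype$homozygous)
  expect_equal(g$genotype$allele_a, min(a9, a2))  # canonical order
})

test_that("truncated or invalid contigs reject the sample", {
  peps <- referencePeptides()
  asm <- fakeAssembly(2, 0)
  good <- embedPeptide(peps[["Allele_5"]], seed = 3)
  bad <- embedPeptide(peps[["Allele_7"]], seed = 4)
  substr(bad, 60 + 22, 60 + 24) <- "TGA"    # stop inside the span
  asm@contigs <- Biostrings::DNAStringSet(c(contig_1 = good,
                                            contig_2 = bad))
  g <- callGenotype("s1", "ligustica", asm)
  expect_equal(g$status, "rejected")
  expect_equal(g$reason, "one_allele_truncated")

  asm@contigs <- Biostrings::DNAStringSet(c(
    contig_1 = randomDnaStr(200, seed = 5),
    contig_2 = randomDnaStr(200, seed = 6)))
  g2 <- callGenotype("s1", "ligustica", asm)
  expect_equal(g2$reason, "both_invalid")

  expect_error(callGenotype("s1", "ligustica", fakeAssembly(3, 0)),
               "filterSample")
})

test_that("identical peptides are retained with a homozygous flag", {
  peps <- referencePeptides()
  a <- peps[["Allele_11"]]
  asm <- fakeAssembly(2, 0)
  asm@contigs <- Biostrings::DNAStringSet(c(
    contig_1 = embedPeptide(a, seed = 8),
    contig_2 = embedPeptide(a, seed = 9)))
  g <- callGenotype("s1", "sicula", asm)
  expect_equal(g$status, "ok")
  expect_true(g$genotype$homozygous)
  expect_equal(g$genotype$allele_a, g$genotype$allele_b)
})

test_that("funnel counts are exact on enumerable outcome sets", {
  z <- funnelReport(list())
  expect_true(all(unlist(z) == 0))

  out <- list(
    list(pass = TRUE, nValid = 2, called = TRUE),
    list(pass = TRUE, nValid = 1, called = FALSE),
    list(pass = FALSE, nValid = 0, called = FALSE))
  f <- funnelReport(out)
  expect_equal(f$n_samples_in, 3)
  expect_equal(f$n_pass_assembly_filter, 2)
  expect_equal(f$n_contigs_translated, 4)
  expect_equal(f$n_peptides_valid, 3)
  expect_equal(f$n_samples_both_alleles, 1)
  expect_equal(f$n_sequences_final, 2)
})

test_that("a small synthetic cohort is genotyped almost perfectly", {
  cfg <- simConfig(nSamples = 12, depth = 20, errorRate = 0.001,
                   seed = 404)
  cohort <- generateCohort(cfg)
  bundle <- runPipeline(cohort$sampleSheet, reads = cohort$reads,
                        config = pipelineConfig(buildTree = FALSE))
  f <- bundle$funnel
  # monotone funnel chain and the evenness identity
  expect_lte(f$n_pass_assembly_filter, f$n_samples_in)
  expect_lte(f$n_samples_both_alleles, f$n_pass_assembly_filter)
  expect_lte(f$n_peptides_valid, f$n_contigs_translated)
  expect_equal(f$n_sequences_final, 2 * f$n_samples_both_alleles)
  expect_equal(f$n_sequences_final %% 2, 0)
  # near-perfect exact recovery at this depth and error rate
  got <- bundle$genotypes
  hits <- sum(vapply(seq_len(nrow(cohort$truth)), function(i) {
    tr <- cohort$truth[i, ]
    any(got$sample_id == tr$sample_id &
        got$allele_a == tr$allele_a_seq &
        got$allele_b == tr$allele_b_seq)
  }, TRUE))
  expect_gte(hits, nrow(cohort$truth) - 1)
})
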