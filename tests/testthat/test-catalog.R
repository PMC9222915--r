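makeGenotypes <- function(pairs, subspecies) {
  do.call(rbind, lapply(seq_along(pairs), function(i) {
    p <- sort(pairs[[i]])
    data.frame(sample_id = paste0("s", i), subspecies = subspecies[i],
               allele_a = p[1], allele_b = p[2],
               homozygous = p[1] == p[2], stringsAsFactors = FALSE)
  }))
}

test_that("identity clustering counts copies and orders allele ids", {
  g <- makeGenotypes(list(c("SSLSAAIEQI", "SSLSCCIEQI"),
                          c("SSLSAAIEQI", "SSLSDDIEQI")),
                     c("ligustica", "buckfast"))
  cat1 <- clusterAlleles(g)
  rec <- alleleRecords(cat1)
  expect_equal(totalSequences(cat1), 4L)
  expect_equal(rec$copies[rec$aa_seq == "SSLSAAIEQI"], 2L)
  expect_equal(rec$allele_id[rec$aa_seq == "SSLSAAIEQI"], 1L)  # most copies
  expect_equal(sum(rec$copies), 4L)
  expect_equal(unname(subspeciesTotals(cat1)[c("ligustica", "buckfast")]),
               c(2L, 2L))
})

test_that("permutations move ids only among equal-copy ties", {
  peps <- referencePeptides()
  set.seed(3)
  pairs <- replicate(10, sample(peps, 2), simplify = FALSE)
  subs <- sample(subspeciesLevels(), 10, replace = TRUE)
  g <- makeGenotypes(pairs, subs)
  c1 <- clusterAlleles(g)
  o <- sample(nrow(g))
  c2 <- clusterAlleles(g[o, ])
  m1 <- alleleRecords(c1)[order(alleleRecords(c1)$aa_seq),
                          c("aa_seq", "copies")]
  m2 <- alleleRecords(c2)[order(alleleRecords(c2)$aa_seq),
                          c("aa_seq", "copies")]
  rownames(m1) <- rownames(m2) <- NULL
  expect_identical(m1, m2)
  # ids still rank by descending copies
  expect_true(all(diff(alleleRecords(c2)$copies) <= 0))
})

test_that("frequency arithmetic matches the published values", {
  cat1 <- hvrReferenceCatalog()
  rec <- alleleRecords(cat1)
  expect_equal(rec$pop_freq_pct[rec$copies == 5], 3.62)   # 5 of 138
  expect_equal(rec$freq_buckfast_pct[rec$allele_id == 9], 9.52)  # 4 of 42
  expect_equal(sum(rec$pop_freq_raw), 1, tolerance = 1e-12)
  expect_equal(sum(rec$copies), 138L)
  expect_error(alleleFrequencies(clusterAlleles(NULL)), "no sequences")
})

test_that("a single shared allele reaches 100 percent", {
  g <- makeGenotypes(list(c("SSLSAAIEQI", "SSLSAAIEQI")), "carnica")
  rec <- alleleRecords(alleleFrequencies(clusterAlleles(g)))
  expect_equal(rec$pop_freq_pct, 100)
})

test_that("sharing classes partition the reference catalogue as published", {
  cat1 <- hvrReferenceCatalog()
  sh <- sharingClasses(cat1)
  expect_length(sh$private, 70)
  expect_length(sh$shared2, 16)
  expect_equal(sort(sh$shared3plus), c(13L, 16L))
  expect_equal(sort(sh$shared2),
               c(2L, 4L, 7L, 8L, 9L, 17L, 18L, 19L, 21L, 22L, 24L, 26L,
                 27L, 28L, 29L, 31L))
  expect_equal(length(sh$private) + length(sh$shared2) +
                 length(sh$shared3plus), nrow(alleleRecords(cat1)))

  single <- makeGenotypes(list(c("SSLSAAIEQI", "SSLSCCIEQI")), "sicula")
  sh1 <- sharingClasses(clusterAlleles(single))
  expect_length(sh1$private, 2)
  expect_length(sh1$shared2, 0)
})

test_that("diversity ratio reports under the documented rounding modes", {
  cat1 <- hvrReferenceCatalog()
  expect_equal(diversityRatio(cat1), 0.63)                 # truncated
  expect_equal(diversityRatio(cat1, raw = TRUE), 88 / 138)
  expect_equal(diversityRatio(cat1, rounding = "half_up"), 0.64)
  # 20 alleles in 30 sequences: truncation 0.66, half-up 0.67
  g <- makeGenotypes(c(
    lapply(1:10, function(i) sprintf("SSLSAA%02dAAAAAAAAAAAAIEQI", c(i, i + 10))),
    lapply(1:5, function(i) sprintf("SSLSAA%02dAAAAAAAAAAAAIEQI", c(i, i + 10)))),
    rep("ligustica", 15))
  cat2 <- clusterAlleles(g)
  expect_equal(nrow(alleleRecords(cat2)), 20)
  expect_equal(totalSequences(cat2), 30L)
  expect_equal(diversityRatio(cat2), 0.66)
  expect_equal(diversityRatio(cat2, rounding = "half_up"), 0.67)

  all2 <- makeGenotypes(list(c("SSLSAAIEQI", "SSLSCCIEQI")), "sicula")
  expect_equal(diversityRatio(clusterAlleles(all2)), 1.00)
})

test_that("known-allele matching is strict full-length identity", {
  meta <- hvrReferenceMeta()
  a3 <- meta$aa_seq[meta$allele_id == 3]
  expect_true("CCF23480.1" %in% matchKnown(a3))
  a1 <- meta$aa_seq[meta$allele_id == 1]     # novel allele
  expect_length(matchKnown(a1), 0)
  mut <- a3
  substr(mut, 6, 6) <- "A"
  expect_length(matchKnown(mut), 0)
  expect_length(matchKnown(tolower(a3)), length(matchKnown(a3)))
})

test_that("the reference catalogue splits 68 known / 20 novel alleles", {
  cat1 <- annotateKnown(hvrReferenceCatalog())
  rec <- alleleRecords(cat1)
  expect_equal(sum(rec$known_match_ids != ""), 68)
  expect_equal(sum(rec$known_match_ids == ""), 20)
  # novelty flag from the publication agrees with local strict matching
  expect_identical(rec$known_match_ids == "", rec$novel)
  expect_equal(range(rec$length), c(27L, 50L))
})
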