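test_that("findBestOverlap handles identity, dovetail and threshold cases", {
  set.seed(5)
  x <- randomDnaStr(60)
  hit <- findBestOverlap(x, x)
  expect_equal(hit$length, 60)
  expect_equal(hit$identity, 1.0)

  # two 60-mers sharing a 45-base dovetail with 2 mismatches: suffix of a
  # equals prefix of b except at two interior positions
  core <- randomDnaStr(45)
  core2 <- core
  flip <- c(A = "C", C = "G", G = "T", T = "A")
  substr(core2, 10, 10) <- flip[[substr(core2, 10, 10)]]
  substr(core2, 30, 30) <- flip[[substr(core2, 30, 30)]]
  a <- paste0(randomDnaStr(15), core)
  b <- paste0(core2, randomDnaStr(15))
  hit <- findBestOverlap(a, b)
  expect_equal(hit$length, 45)
  expect_equal(hit$matches, 43)
  expect_equal(hit$identity, 43 / 45, tolerance = 1e-12)
  expect_true(hit$identity >= 0.90)

  # 39-base exact dovetail is below the minimum overlap length
  core39 <- randomDnaStr(39)
  a39 <- paste0(randomDnaStr(21), core39)
  b39 <- paste0(core39, randomDnaStr(21))
  # guard against an accidental longer qualifying overlap elsewhere
  expect_null(findBestOverlap(a39, b39, minOverlap = 40))
  expect_false(is.null(findBestOverlap(a39, b39, minOverlap = 39)))

  expect_error(findBestOverlap("ACGT", "ACGT", minOverlap = 0), "minOverlap")
  expect_error(findBestOverlap("ACGT", "ACGT", minIdentity = 1.2),
               "minIdentity")
})

test_that("overlap scan agrees with exhaustive enumeration", {
  set.seed(21)
  for (k in 1:25) {
    hap <- randomDnaStr(140)
    a <- substr(hap, 1, 90)
    b <- substr(hap, sample(10:45, 1), 140)
    if (k %% 3 == 0) b <- helperRevcomp(b)
    if (k %% 4 == 0) {       # sprinkle mismatches
      p <- sample(nchar(b), 3)
      for (i in p) substr(b, i, i) <- sample(c("A", "C", "G", "T"), 1)
    }
    got <- findBestOverlap(a, b, minOverlap = 30, minIdentity = 0.85)
    want <- oracleBestOverlap(a, b, minOverlap = 30, minIdentity = 0.85)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$score, want$score)
      expect_equal(got$length, want$length)
      expect_equal(got$matches, want$matches)
    }
  }
})

test_that("N bases never count as overlap matches", {
  x <- randomDnaStr(60, seed = 3)
  xn <- x
  substr(xn, 5, 5) <- "N"
  hit <- findBestOverlap(x, xn, minOverlap = 40)
  expect_equal(hit$matches, 59)
  expect_lt(hit$identity, 1)
})

test_that("layoutConsensus applies majority and documented tie-breaks", {
  # column 1: {A,A,G} majority A; all other columns identical
  s <- c("AAAA", "AAAA", "GAAA")
  cons <- layoutConsensus(s, c(0, 0, 0))
  expect_equal(cons$consensus, "AAAA")
  expect_equal(cons$depth, rep(3L, 4))
  # {A,G} tie without qualities: alphabetical
  expect_equal(layoutConsensus(c("A", "G"), c(0, 0))$consensus, "A")
  # N never wins a tie against a concrete base
  expect_equal(layoutConsensus(c("A", "N"), c(0, 0))$consensus, "A")
  # qualities outrank the alphabet on ties
  expect_equal(layoutConsensus(c("A", "G"), c(0, 0),
                               quals = c("#", "I"))$consensus, "G")
  expect_error(layoutConsensus(character(), integer()), "empty")
})

test_that("degenerate assemblies: empty input and a lone read", {
  a0 <- assemble(Biostrings::DNAStringSet())
  expect_length(contigs(a0), 0)
  expect_length(singletons(a0), 0)
  one <- Biostrings::DNAStringSet(c(r1 = randomDnaStr(150, seed = 2)))
  a1 <- assemble(one)
  expect_length(contigs(a1), 0)
  expect_equal(singletons(a1), "r1")
  expect_error(assemble(stats::setNames(c("ACGT", "ACGT"), c("x", "x"))),
               "unique")
})

test_that("error-free tiling reads of two alleles give back both haplotypes", {
  peps <- referencePeptides()
  set.seed(31)
  hapA <- embedPeptide(peps[["Allele_1"]], seed = 31, flankLen = 150)
  hapB <- embedPeptide(peps[["Allele_9"]], seed = 77, flankLen = 150)
  reads <- c(tilingReads(hapA, step = 15, prefix = "a"),
             tilingReads(hapB, step = 15, prefix = "b"))
  asm <- assemble(Biostrings::DNAStringSet(reads))
  expect_length(contigs(asm), 2)
  expect_length(singletons(asm), 0)
  expect_setequal(as.character(contigs(asm)), c(hapA, hapB))
})

test_that("reads are conserved and assembly is deterministic", {
  set.seed(8)
  peps <- referencePeptides()
  sim <- simulateSample("s", peps[[3]], peps[[20]], depth = 8,
                        errorRate = 0.002, flankLen = 120)
  asm1 <- assemble(sim$reads)
  nMem <- sum(vapply(contigMembers(asm1), nrow, 0L))
  expect_equal(nMem + length(singletons(asm1)), length(sim$reads))
  asm2 <- assemble(sim$reads)
  expect_identical(as.character(contigs(asm1)), as.character(contigs(asm2)))
  expect_identical(singletons(asm1), singletons(asm2))
  expect_identical(contigMembers(asm1), contigMembers(asm2))
})

test_that("distinct haplotypes with low cross-identity are never merged", {
  # every 40-base window differs by >= 5 nt between the two haplotypes
  set.seed(13)
  hapA <- randomDnaStr(300)
  hapB <- randomDnaStr(300)
  reads <- c(tilingReads(hapA, step = 30, prefix = "a"),
             tilingReads(hapB, step = 30, prefix = "b"))
  asm <- assemble(Biostrings::DNAStringSet(reads))
  expect_gte(length(contigs(asm)), 2)
  cons <- as.character(contigs(asm))
  expect_true(hapA %in% cons)
  expect_true(hapB %in% cons)
})

test_that("contig junctions on small instances satisfy the thresholds", {
  set.seed(17)
  for (rep in 1:5) {
    hap <- randomDnaStr(260)
    starts <- sort(sample(1:110, sample(4:8, 1)))
    reads <- substring(hap, starts, starts + 149)
    names(reads) <- paste0("r", seq_along(reads))
    asm <- assemble(Biostrings::DNAStringSet(reads))
    for (m in contigMembers(asm)) {
      for (i in seq_len(nrow(m))) {
        others <- setdiff(seq_len(nrow(m)), i)
        hasMate <- any(vapply(others, function(j) {
          ov <- oracleBestOverlap(reads[[m$read_id[i]]],
                                  reads[[m$read_id[j]]])
          !is.null(ov)
        }, TRUE))
        expect_true(hasMate,
                    info = paste("read", m$read_id[i], "has no qualifying",
                                 "overlap with any contig mate"))
      }
    }
  }
})
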