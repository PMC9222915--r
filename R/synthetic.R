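# Seeded synthetic cohorts: diploid samples drawing allele pairs from the
# reference pool, back-translated haplotypes embedded in random flanking
# DNA, 150 bp substitution-error reads, and a truth table for every stage.

#' Simulation configuration
#'
#' Defaults emulate the study regime: 150 bp Illumina-like reads, roughly
#' 40x combined coverage of the locus (about 20x per haplotype), a
#' substitution-only error model at 0.1 percent, allele pairs at least 5
#' amino acids apart (the heterozygosity margin known to secure female
#' development), and subspecies drawn with the cohort's observed
#' proportions.
#'
#' @param nSamples number of diploid samples.
#' @param depth mean per-haplotype coverage (default 20).
#' @param readLen read length in bp (default 150).
#' @param errorRate per-base substitution probability (default 0.001).
#' @param minPairAaDiff minimum alignment difference (mismatches + gap
#'   positions) between a sample's two alleles (default 5 aa).
#' @param flankLen random flanking DNA on each side of the back-translated
#'   allele (default 200 nt).
#' @param subspeciesWeights named probabilities over [subspeciesLevels()]
#'   (default: the sampled cohort's proportions 61/43/6/8/4/2/1 of 125).
#' @param allelePool named character vector of peptides to draw pairs from
#'   (default: the 88 packaged reference alleles).
#' @param seed integer RNG seed.
#' @return a list of class `simConfig`.
#' @export
simConfig <- function(nSamples = 50L, depth = 20, readLen = 150L,
                      errorRate = 0.001, minPairAaDiff = 5L,
                      flankLen = 200L, subspeciesWeights = NULL,
                      allelePool = NULL, seed = 1L) {
  if (is.null(subspeciesWeights)) {
    subspeciesWeights <- c(ligustica = 61, buckfast = 43, sicula = 6,
                           carnica = 8, mellifera = 4, hybrid_carnica = 2,
                           cecropia = 1) / 125
  }
  if (is.null(allelePool)) {
    pool <- hvrReferenceAlleles()
    allelePool <- stats::setNames(as.character(pool), names(pool))
  }
  stopifnot(depth > 0, errorRate >= 0, errorRate < 0.25,
            readLen >= 1, flankLen >= 0,
            abs(sum(subspeciesWeights) - 1) < 1e-6)
  structure(list(nSamples = as.integer(nSamples), depth = depth,
                 readLen = as.integer(readLen), errorRate = errorRate,
                 minPairAaDiff = as.integer(minPairAaDiff),
                 flankLen = as.integer(flankLen),
                 subspeciesWeights = subspeciesWeights,
                 allelePool = allelePool, seed = as.integer(seed)),
            class = "simConfig")
}

#' Back-translate a peptide into DNA
#'
#' Synonymous codons are chosen uniformly at random; with a `seed` the
#' choice is deterministic and the caller's RNG state is untouched.
#'
#' @param peptide amino-acid sequence over the 20 standard residues.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return a DNA string whose translation is `peptide`.
#' @examples
#' backTranslate("M")  # "ATG", the unique Met codon
#' @export
backTranslate <- function(peptide, seed = NULL) {
  res <- strsplit(toupper(peptide), "")[[1]]
  gc <- Biostrings::GENETIC_CODE
  codonsOf <- split(names(gc), gc)
  if (!all(res %in% names(codonsOf)) || any(res == "*"))
    stop("invalid residue in peptide")
  withSeed(seed, {
    paste(vapply(res, function(r) {
      cs <- codonsOf[[r]]
      cs[sample.int(length(cs), 1L)]
    }, "", USE.NAMES = FALSE), collapse = "")
  })
}

# Uniform random DNA of length n from the current RNG stream.
randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Apply iid substitution errors at rate `e` to a read string.
addSubstitutions <- function(read, e) {
  if (e <= 0) return(read)
  ch <- strsplit(read, "")[[1]]
  hit <- which(stats::runif(length(ch)) < e)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

#' Simulate reads for one diploid sample
#'
#' Each haplotype is `flank + back-translated allele + flank` with flanks
#' drawn independently per haplotype (emulating flanking divergence around
#' the HVR). Reads have uniform start positions, uniform strand, and iid
#' substitution errors; the expected read count per haplotype is
#' `round(depth * haplotype_length / readLen)`. Draws come from the
#' current RNG stream (seed at the cohort level).
#'
#' @param sampleId sample identifier used in read ids.
#' @param alleleA,alleleB the two allele peptides.
#' @param depth,readLen,errorRate,flankLen see [simConfig()].
#' @return list with `reads` (a `DNAStringSet` with `qual` metadata) and
#'   `truth` (one-row `data.frame`: `sample_id`, `allele_a_seq`,
#'   `allele_b_seq`, `dna_haplotype_a`, `dna_haplotype_b`).
#' @export
simulateSample <- function(sampleId, alleleA, alleleB, depth = 20,
                           readLen = 150L, errorRate = 0.001,
                           flankLen = 200L) {
  haps <- vapply(c(alleleA, alleleB), function(p) {
    paste0(randomDna(flankLen), backTranslate(p), randomDna(flankLen))
  }, "", USE.NAMES = FALSE)
  if (any(nchar(haps) < readLen))
    stop("haplotype shorter than the read length")
  seqs <- character(); ids <- character()
  for (h in 1:2) {
    hap <- haps[h]
    n <- round(depth * nchar(hap) / readLen)
    starts <- sample.int(nchar(hap) - readLen + 1L, n, replace = TRUE)
    for (k in seq_len(n)) {
      r <- substr(hap, starts[k], starts[k] + readLen - 1L)
      if (sample(c(TRUE, FALSE), 1L)) r <- revcompChr(r)
      seqs <- c(seqs, addSubstitutions(r, errorRate))
      ids <- c(ids, sprintf("%s_h%d_r%03d", sampleId, h, k))
    }
  }
  reads <- Biostrings::DNAStringSet(seqs)
  names(reads) <- ids
  S4Vectors::mcols(reads)$qual <- strrep("I", readLen)
  pair <- sort(c(alleleA, alleleB))
  list(reads = reads,
       truth = data.frame(sample_id = sampleId,
                          allele_a_seq = pair[1], allele_b_seq = pair[2],
                          dna_haplotype_a = haps[match(pair[1],
                                                 c(alleleA, alleleB))],
                          dna_haplotype_b = haps[match(pair[2],
                                                 c(alleleA, alleleB))],
                          stringsAsFactors = FALSE))
}

#' Generate a synthetic diploid cohort with truth table
#'
#' Allele pairs are drawn without replacement per sample from the pool and
#' re-drawn until they differ by at least `minPairAaDiff` amino acids;
#' subspecies labels follow the configured weights. Fully deterministic
#' for a given config (the caller's RNG state is preserved).
#'
#' @param config a [simConfig()].
#' @param outDir optional directory: per-sample FASTQ files plus
#'   `sample_sheet.tsv` and `truth.tsv` are written there.
#' @return list with `sampleSheet` (`sample_id`, `subspecies`, `path` —
#'   `NA` unless written), `reads` (named list of `DNAStringSet`), and
#'   `truth` (`data.frame`, one row per sample including subspecies).
#' @export
generateCohort <- function(config = simConfig(), outDir = NULL) {
  stopifnot(inherits(config, "simConfig"))
  pool <- config$allelePool
  if (length(pool) < 2) stop("allele pool must hold at least 2 alleles")
  withSeed(config$seed, {
    subsp <- sample(names(config$subspeciesWeights), config$nSamples,
                    replace = TRUE, prob = config$subspeciesWeights)
    readsList <- vector("list", config$nSamples)
    truths <- vector("list", config$nSamples)
    ids <- sprintf("sample_%03d", seq_len(config$nSamples))
    for (i in seq_len(config$nSamples)) {
      pair <- NULL
      for (try in 1:100) {
        cand <- sample(pool, 2L)
        v <- cpp_align_dist(cand[1], cand[2])
        if (v[1] >= config$minPairAaDiff) { pair <- cand; break }
      }
      if (is.null(pair))
        stop("allele pool too homogeneous for minPairAaDiff = ",
             config$minPairAaDiff)
      sim <- simulateSample(ids[i], pair[1], pair[2],
                            depth = config$depth,
                            readLen = config$readLen,
                            errorRate = config$errorRate,
                            flankLen = config$flankLen)
      readsList[[i]] <- sim$reads
      sim$truth$subspecies <- subsp[i]
      truths[[i]] <- sim$truth
    }
    names(readsList) <- ids
    truth <- do.call(rbind, truths)
    sheet <- data.frame(sample_id = ids, subspecies = subsp,
                        path = NA_character_, stringsAsFactors = FALSE)
    if (!is.null(outDir)) {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      sheet$path <- file.path(outDir, paste0(ids, ".fastq"))
      for (i in seq_along(ids))
        writeFastqReads(readsList[[i]], sheet$path[i])
      utils::write.table(sheet, file.path(outDir, "sample_sheet.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(truth, file.path(outDir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(sampleSheet = sheet, reads = readsList, truth = truth)
  })
}
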