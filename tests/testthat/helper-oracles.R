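# Independent oracles and fixture builders used across the test files.
# These deliberately avoid the package's own code paths (and its compiled
# scan): plain-R exhaustive enumeration and a hand-built codon table.

helperRevcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# Standard genetic code as the classic TCAG-ordered amino-acid string.
oracleCodonTable <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    "")[[1]]
  g <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                   stringsAsFactors = FALSE)  # b3 varies fastest
  codons <- paste0(g$b1, g$b2, g$b3)          # TTT, TTC, TTA, TTG, TCT, ...
  stats::setNames(aas, codons)
})

oracleTranslate <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3
  if (n < 3) return("")
  cods <- substring(dna, seq(1, n, 3), seq(3, n, 3))
  aa <- ifelse(grepl("N", cods), "X", unname(oracleCodonTable[cods]))
  paste(aa, collapse = "")
}

# Exhaustive gap-free overlap enumeration over all offsets and both
# orientations; mirrors the documented contract, not the implementation.
oracleBestOverlap <- function(a, b, minOverlap = 40, minIdentity = 0.9,
                              penalty = 2) {
  evalOne <- function(a, b, orient) {
    la <- nchar(a); lb <- nchar(b)
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    best <- NULL
    for (d in seq(-(lb - minOverlap), la - minOverlap)) {
      as0 <- max(0, d); bs0 <- max(0, -d)
      len <- min(la - as0, lb - bs0)
      if (len < minOverlap) next
      aseg <- av[(as0 + 1):(as0 + len)]
      bseg <- bv[(bs0 + 1):(bs0 + len)]
      m <- sum(aseg == bseg & aseg != "N")
      if (m / len < minIdentity - 1e-12) next
      sc <- m - penalty * (len - m)
      if (is.null(best) || sc > best$score + 1e-9 ||
          (abs(sc - best$score) <= 1e-9 && len > best$length)) {
        best <- list(score = sc, length = len, matches = m,
                     orientation = orient)
      }
    }
    best
  }
  b1 <- evalOne(a, b, "+")
  b2 <- evalOne(a, helperRevcomp(b), "-")
  if (is.null(b1)) return(b2)
  if (is.null(b2)) return(b1)
  if (b2$score > b1$score + 1e-9 ||
      (abs(b2$score - b1$score) <= 1e-9 && b2$length > b1$length)) b2
  else b1
}

# Error-free reads tiling a haplotype at a fixed step.
tilingReads <- function(hap, readLen = 150, step = 15, prefix = "r") {
  starts <- seq(1, nchar(hap) - readLen + 1, by = step)
  if (starts[length(starts)] != nchar(hap) - readLen + 1)
    starts <- c(starts, nchar(hap) - readLen + 1)
  reads <- substring(hap, starts, starts + readLen - 1)
  names(reads) <- paste0(prefix, seq_along(reads))
  reads
}

# Minimal headerful SAM writer for extraction tests.
writeSam <- function(path, qname, flag, pos, cigar, seq,
                     chrom = "NC_037640.1", ln = 13619445) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, ln))
  rec <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                 qname, flag, ifelse(flag == 4L, "*", chrom),
                 ifelse(flag == 4L, 0L, pos), ifelse(flag == 4L, "*", cigar),
                 seq, strrep("I", nchar(seq)))
  writeLines(c(hdr, rec), path)
  path
}

# Reference-span width of a cigar (M/D/N/=/X consume reference).
oracleCigarRefWidth <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]", "", ops))
  type <- sub("[0-9]+", "", ops)
  sum(n[type %in% c("M", "D", "N", "=", "X")])
}

# Brute-force SAM region filter: primary mapped records whose reference
# span overlaps [start, end] by >= 1 base.
oracleSamOverlap <- function(samPath, start, end) {
  lines <- readLines(samPath)
  lines <- lines[!startsWith(lines, "@")]
  keep <- character()
  for (l in lines) {
    f <- strsplit(l, "\t")[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0) next          # unmapped
    if (bitwAnd(flag, 256L) > 0) next        # secondary
    if (bitwAnd(flag, 2048L) > 0) next       # supplementary
    pos <- as.integer(f[4])
    refEnd <- pos + oracleCigarRefWidth(f[6]) - 1L
    if (pos <= end && refEnd >= start) keep <- c(keep, f[1])
  }
  keep
}

randomDnaStr <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

referencePeptides <- function() {
  x <- hvrReferenceAlleles()
  stats::setNames(as.character(x), names(x))
}

# A fake two-contig assembly object for filter tests (contigs need not be
# assemblable; validity only requires layout bookkeeping to be coherent).
fakeAssembly <- function(nContigs = 2, nSingles = 0) {
  mk <- function(i) {
    data.frame(read_id = paste0("c", i, "_r", 1:2),
               orientation = "+", offset = c(0L, 10L),
               stringsAsFactors = FALSE)
  }
  seqs <- vapply(seq_len(nContigs), function(i) randomDnaStr(160), "")
  methods::new("HvrAssembly",
    contigs = Biostrings::DNAStringSet(stats::setNames(
      seqs, paste0("contig_", seq_len(nContigs)))),
    members = lapply(seq_len(nContigs), mk),
    depth = lapply(seq_len(nContigs), function(i) rep(1L, 160)),
    singletons = if (nSingles > 0) paste0("s", seq_len(nSingles))
                 else character(),
    nReads = as.integer(2 * nContigs + nSingles))
}

# DNA encoding a peptide embedded in non-coding flanks, via the package
# back-translator (tests that must stay independent of it build DNA from
# the oracle codon table instead).
embedPeptide <- function(peptide, seed = 7, flankLen = 60) {
  set.seed(seed)
  paste0(randomDnaStr(flankLen), backTranslate(peptide, seed = seed + 1),
         randomDnaStr(flankLen))
}
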