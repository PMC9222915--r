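#' HVR genomic interval of the csd gene
#'
#' The hypervariable region of csd exon 7 on the Amel_HAv3.1 assembly,
#' `NC_037640.1:11771976-11772119` (1-based inclusive, 144 bp). This is the
#' default interval for [extractRegionReads()].
#'
#' @return a [GenomicRanges::GRanges] of length 1.
#' @examples
#' hvrRegion()
#' @export
hvrRegion <- function() {
  GenomicRanges::GRanges("NC_037640.1",
                         IRanges::IRanges(11771976L, 11772119L))
}

#' Parse a samtools-style region string
#'
#' @param region a string `"CHR:START-END"` (1-based inclusive) or a
#'   `GRanges` (returned unchanged).
#' @return a `GRanges` of length 1.
#' @examples
#' parseRegion("NC_037640.1:11771976-11772119")
#' @export
parseRegion <- function(region) {
  if (methods::is(region, "GRanges")) return(region)
  m <- regmatches(region, regexec("^(.+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4)
    stop("region must look like 'CHR:START-END': ", region)
  start <- as.integer(m[3]); end <- as.integer(m[4])
  if (start < 1 || end < start)
    stop("invalid region coordinates: ", region)
  GenomicRanges::GRanges(m[2], IRanges::IRanges(start, end))
}

#' Read sequencing reads from FASTA or FASTQ
#'
#' Light validating wrappers around Biostrings parsers. Read ids are the
#' header text up to the first whitespace; record order is preserved.
#' FASTQ qualities (Sanger offset) are carried along in `mcols(x)$qual`.
#'
#' @param path path to the file.
#' @return a [Biostrings::DNAStringSet] named by read id; for FASTQ with a
#'   `qual` metadata column.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "ACGT"), fa)
#' readFastaReads(fa)
#' @export
readFastaReads <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0)
    return(Biostrings::DNAStringSet())
  if (!startsWith(lines[nonblank[1]], ">"))
    stop("malformed FASTA at line ", nonblank[1], ": expected '>' header")
  bad <- nonblank[!startsWith(lines[nonblank], ">") &
                  grepl("[^ACGTNacgtn]", lines[nonblank])]
  if (length(bad))
    stop("malformed FASTA at line ", bad[1], ": non-DNA characters")
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' @rdname readFastaReads
#' @export
readFastqReads <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[seq_len(length(lines))]
  if (length(lines) == 0) return(Biostrings::DNAStringSet())
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ: truncated record near line ", length(lines))
  ids <- lines[seq(1, length(lines), by = 4)]
  seqs <- lines[seq(2, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  quals <- lines[seq(4, length(lines), by = 4)]
  badid <- which(!startsWith(ids, "@"))
  if (length(badid))
    stop("malformed FASTQ at line ", (badid[1] - 1) * 4 + 1,
         ": expected '@' header")
  badplus <- which(!startsWith(plus, "+"))
  if (length(badplus))
    stop("malformed FASTQ at line ", (badplus[1] - 1) * 4 + 3,
         ": expected '+' separator")
  badq <- which(nchar(quals) != nchar(seqs))
  if (length(badq))
    stop("malformed FASTQ at line ", (badq[1] - 1) * 4 + 4,
         ": quality length differs from sequence length")
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- sub("\\s.*$", "", sub("^@", "", ids))
  S4Vectors::mcols(x)$qual <- quals
  x
}

#' Write reads to FASTA or FASTQ
#'
#' @param reads a `DNAStringSet` named by read id (for FASTQ, with a `qual`
#'   metadata column; missing qualities are written as `"I"` per base).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFastaReads <- function(reads, path) {
  reads <- asReadSet(reads)
  writeLines(as.vector(rbind(paste0(">", names(reads)),
                             as.character(reads))), path)
  invisible(path)
}

#' @rdname writeFastaReads
#' @export
writeFastqReads <- function(reads, path) {
  reads <- asReadSet(reads)
  quals <- readQuals(reads)
  if (is.null(quals))
    quals <- vapply(Biostrings::width(reads),
                    function(w) strrep("I", w), "")
  writeLines(as.vector(rbind(paste0("@", names(reads)),
                             as.character(reads), "+", quals)), path)
  invisible(path)
}

#' Extract reads overlapping a genomic interval from a SAM file
#'
#' Returns the primary alignments whose reference span overlaps the
#' interval by at least `minOverlapBp` reference bases. Secondary and
#' supplementary alignments are ignored; duplicates are kept; sequences
#' are returned in reference orientation as stored in the SAM file.
#'
#' @param samPath path to a headerful SAM (or BAM) file.
#' @param region the target interval, as a `GRanges` or `"CHR:START-END"`
#'   string; default the csd HVR interval [hvrRegion()].
#' @param minOverlapBp minimum reference-base overlap (default 1).
#' @return a `DNAStringSet` named by (uniquified) read id, with `qual`,
#'   `mapped_start` and `mapped_end` metadata columns. An empty set if no
#'   alignment overlaps; an error if the chromosome is absent from the
#'   header.
#' @export
extractRegionReads <- function(samPath, region = hvrRegion(),
                               minOverlapBp = 1L) {
  if (!file.exists(samPath)) stop("no such file: ", samPath)
  region <- parseRegion(region)
  if (minOverlapBp < 1) stop("minOverlapBp must be >= 1")
  bam <- samPath
  if (grepl("\\.sam$", samPath, ignore.case = TRUE)) {
    dest <- tempfile()
    bam <- Rsamtools::asBam(samPath, dest, overwrite = TRUE,
                            indexDestination = TRUE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  chrom <- as.character(GenomicRanges::seqnames(region))
  if (!chrom %in% names(hdr))
    stop("chromosome '", chrom, "' absent from SAM header")
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(which = region, flag = flag,
                                   what = c("qname", "seq", "qual"))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  if (length(ga) == 0) return(Biostrings::DNAStringSet())
  spans <- GenomicRanges::granges(ga)
  ov <- GenomicRanges::pintersect(spans, rep(region, length(spans)))
  keep <- GenomicRanges::width(ov) >= minOverlapBp
  ga <- ga[keep]
  if (length(ga) == 0) return(Biostrings::DNAStringSet())
  reads <- S4Vectors::mcols(ga)$seq
  names(reads) <- make.unique(S4Vectors::mcols(ga)$qname, sep = "/")
  S4Vectors::mcols(reads)$qual <- as.character(S4Vectors::mcols(ga)$qual)
  S4Vectors::mcols(reads)$mapped_start <- GenomicRanges::start(ga)
  S4Vectors::mcols(reads)$mapped_end <- GenomicRanges::end(ga)
  reads
}

#' Write the cohort report tables
#'
#' Materialises the catalogue, genotype, sharing and funnel tables as TSV
#' with deterministic column order; percentage frequencies are formatted to
#' two decimals.
#'
#' @param catalog an [AlleleCatalog-class] (ideally after
#'   [alleleFrequencies()] and [annotateKnown()]).
#' @param genotypes `data.frame` of genotype calls (may be `NULL`).
#' @param funnel one-row `data.frame` from [funnelReport()] (may be `NULL`).
#' @param outDir output directory (created if needed).
#' @return named character vector of the file paths written.
#' @export
writeReportTables <- function(catalog, genotypes = NULL, funnel = NULL,
                              outDir = ".") {
  if (nrow(alleleRecords(catalog)) == 0)
    stop("catalogue is empty; nothing to report")
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  rec <- alleleRecords(catalog)
  fmt <- function(x) sprintf("%.2f", x)
  out <- data.frame(allele_id = rec$allele_id, peptide = rec$aa_seq,
                    length = rec$length, copies = rec$copies,
                    stringsAsFactors = FALSE)
  if ("pop_freq_pct" %in% names(rec))
    out$pop_freq_pct <- fmt(rec$pop_freq_pct)
  for (s in subspeciesLevels()) {
    cn <- paste0("freq_", s, "_pct")
    if (cn %in% names(rec)) out[[cn]] <- fmt(rec[[cn]])
  }
  if ("known_match_ids" %in% names(rec))
    out$known_match_ids <- rec$known_match_ids
  paths <- c(alleles = file.path(outDir, "alleles.tsv"))
  utils::write.table(out, paths["alleles"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sh <- sharingClasses(catalog)
  shdf <- data.frame(
    allele_id = rec$allele_id,
    class = ifelse(rec$allele_id %in% sh$private, "private",
            ifelse(rec$allele_id %in% sh$shared2, "shared2", "shared3plus")),
    stringsAsFactors = FALSE)
  paths["sharing"] <- file.path(outDir, "sharing.tsv")
  utils::write.table(shdf, paths["sharing"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(genotypes)) {
    paths["genotypes"] <- file.path(outDir, "genotypes.tsv")
    utils::write.table(genotypes, paths["genotypes"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(funnel)) {
    paths["funnel"] <- file.path(outDir, "funnel.tsv")
    utils::write.table(funnel, paths["funnel"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  paths
}
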