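# Six-frame translation of contig consensuses and selection of valid HVR
# peptides. A valid HVR peptide starts with the SSLS anchor, ends with the
# IEQI anchor, and contains no stop ('*') and no ambiguous residue ('X')
# inside the anchored span; translations truncated by an internal stop are
# discarded.

#' Translate a DNA sequence in all six frames
#'
#' Frames 1-3 are the forward strand offset by 0-2 bases; frames 4-6 are
#' the reverse complement offset likewise. Stop codons are rendered `*`,
#' codons containing `N` are rendered `X`, and 1-2 trailing bases that do
#' not fill a codon are ignored (EMBOSS transeq semantics).
#'
#' @param dna a DNA string (length >= 3).
#' @return character vector of six peptide strings, named `F1`..`F3`,
#'   `R1`..`R3`.
#' @examples
#' sixFrameTranslate("ATGTAA")[1]  # "M*"
#' @export
sixFrameTranslate <- function(dna) {
  dna <- toupper(as.character(dna))
  if (nchar(dna) < 3) stop("dna must be at least one codon long")
  rev <- chartr("ACGTN", "TGCAN", paste(rev(strsplit(dna, "")[[1]]),
                                        collapse = ""))
  frameSeq <- function(x, off) {
    n <- nchar(x) - off
    n <- n - n %% 3
    if (n < 3) "" else substr(x, off + 1L, off + n)
  }
  fr <- c(frameSeq(dna, 0L), frameSeq(dna, 1L), frameSeq(dna, 2L),
          frameSeq(rev, 0L), frameSeq(rev, 1L), frameSeq(rev, 2L))
  out <- character(6)
  ok <- nzchar(fr)
  if (any(ok)) {
    # the fuzzy-codon path is expensive; take it only when needed
    fuzzy <- grepl("N", dna, fixed = TRUE)
    out[ok] <- if (fuzzy) {
      as.character(Biostrings::translate(
        Biostrings::DNAStringSet(fr[ok]), if.fuzzy.codon = "X",
        no.init.codon = TRUE))
    } else {
      as.character(Biostrings::translate(
        Biostrings::DNAStringSet(fr[ok]), no.init.codon = TRUE))
    }
  }
  names(out) <- c("F1", "F2", "F3", "R1", "R2", "R3")
  out
}

#' Select and validate the HVR peptide encoded by a contig
#'
#' All six frame translations are scanned for the anchored motif span:
#' from the first occurrence of `startAnchor` to the end of the last
#' occurrence of `endAnchor` within the same frame. A span is valid when
#' it contains no stop (`*`), no ambiguous residue (`X`), and its length
#' lies within `[minLen, maxLen]`. If more than one frame yields a valid
#' span with *distinct* peptides the call is rejected as ambiguous;
#' identical peptides recovered in several frames are accepted (the lowest
#' frame is reported).
#'
#' @param dna contig consensus (DNA string) or an [HvrAssembly-class]
#'   contig sequence.
#' @param startAnchor,endAnchor peptide anchors delimiting the HVR
#'   (defaults `"SSLS"` and `"IEQI"`, the shared termini of all published
#'   alleles).
#' @param minLen,maxLen accepted peptide length bounds in amino acids
#'   (defaults 20 and 80).
#' @param sourceContig optional contig id recorded in the result.
#' @return a list: `status` (`"ok"`/`"rejected"`); on success `aa_seq`,
#'   `frame` (1-6) and `source_contig`; on rejection `reason`, one of
#'   `no_motif`, `internal_stop` (truncated or ambiguous consensus inside
#'   the span), `ambiguous_multi_frame`, `length_out_of_range`.
#' @export
selectHvrPeptide <- function(dna, startAnchor = "SSLS",
                             endAnchor = "IEQI", minLen = 20L,
                             maxLen = 80L, sourceContig = NA_character_) {
  peps <- sixFrameTranslate(dna)
  candidates <- list()
  sawStop <- FALSE
  sawLength <- FALSE
  for (f in seq_along(peps)) {
    p <- peps[[f]]
    if (!nzchar(p)) next
    i <- regexpr(startAnchor, p, fixed = TRUE)[1]
    if (i < 0) next
    ends <- gregexpr(endAnchor, p, fixed = TRUE)[[1]]
    ends <- ends[ends > i]
    if (length(ends) == 0 || ends[1] < 0) next
    j <- max(ends) + nchar(endAnchor) - 1L
    span <- substr(p, i, j)
    if (grepl("*", span, fixed = TRUE) || grepl("X", span, fixed = TRUE)) {
      sawStop <- TRUE
      next
    }
    if (nchar(span) < minLen || nchar(span) > maxLen) {
      sawLength <- TRUE
      next
    }
    candidates[[length(candidates) + 1L]] <- list(frame = f, aa_seq = span)
  }
  if (length(candidates) == 0) {
    reason <- if (sawStop) "internal_stop"
              else if (sawLength) "length_out_of_range"
              else "no_motif"
    return(list(status = "rejected", reason = reason))
  }
  seqsFound <- unique(vapply(candidates, `[[`, "", "aa_seq"))
  if (length(seqsFound) > 1)
    return(list(status = "rejected", reason = "ambiguous_multi_frame"))
  list(status = "ok", aa_seq = seqsFound,
       frame = candidates[[1]]$frame, source_contig = sourceContig)
}

#' Write validated HVR peptides as FASTA
#'
#' Headers carry the originating contig and reading frame.
#'
#' @param peptides list of successful [selectHvrPeptide()] results.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePeptideFasta <- function(peptides, path) {
  lines <- unlist(lapply(peptides, function(p) {
    c(sprintf(">%s frame=%d", p$source_contig, p$frame), p$aa_seq)
  }))
  writeLines(lines, path)
  invisible(path)
}
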