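# Packaged reference catalogue: the 88 published HVR amino-acid alleles
# with their per-subspecies frequencies and GenBank accessions, plus a
# synthetic Apis cerana-like outgroup peptide for tree rooting.

extdataPath <- function(file) {
  p <- system.file("extdata", file, package = "csdTyper")
  if (!nzchar(p)) stop("packaged file not found: ", file)
  p
}

#' Packaged reference HVR alleles
#'
#' The 88 published HVR amino-acid allele sequences (named `Allele_1` ..
#' `Allele_88`) and their metadata: length, printed population frequency,
#' per-subspecies percentage frequencies, novelty flag, and the GenBank
#' accessions reported as exact matches.
#'
#' @return `hvrReferenceAlleles()`: an [Biostrings::AAStringSet] of 88
#'   peptides. `hvrReferenceMeta()`: a `data.frame` with one row per
#'   allele, including `aa_seq`.
#' @examples
#' length(hvrReferenceAlleles())
#' @export
hvrReferenceAlleles <- function() {
  Biostrings::readAAStringSet(extdataPath("table1_alleles.faa"))
}

#' @rdname hvrReferenceAlleles
#' @export
hvrReferenceMeta <- function() {
  meta <- utils::read.delim(extdataPath("table1_meta.tsv"),
                            stringsAsFactors = FALSE)
  meta$genbank_ids[is.na(meta$genbank_ids)] <- ""
  seqs <- hvrReferenceAlleles()
  meta$aa_seq <- as.character(seqs)[paste0("Allele_", meta$allele_id)]
  meta
}

#' Reference catalogue reconstructed from published frequencies
#'
#' Builds an [AlleleCatalog-class] for the 88 reference alleles by
#' reconstructing integer copy counts from the published per-subspecies
#' percentage frequencies and the subspecies sequence totals
#' (ligustica 68, buckfast 42, sicula 8, carnica 10, mellifera 4,
#' hybrid carnica 4, cecropia 2; 138 sequences in all). The published
#' population-frequency column is known to be internally inconsistent for
#' at least one allele, so population frequencies are recomputed from the
#' reconstructed copies; the printed value is kept in
#' `pop_freq_printed_pct`.
#'
#' @param withFrequencies fill frequency columns via [alleleFrequencies()]
#'   (default `TRUE`).
#' @return an [AlleleCatalog-class] of 88 records over 138 sequences.
#' @examples
#' totalSequences(hvrReferenceCatalog())
#' @export
hvrReferenceCatalog <- function(withFrequencies = TRUE) {
  meta <- hvrReferenceMeta()
  levs <- subspeciesLevels()
  totals <- c(ligustica = 68L, buckfast = 42L, sicula = 8L, carnica = 10L,
              mellifera = 4L, hybrid_carnica = 4L, cecropia = 2L)[levs]
  copies <- vapply(levs, function(s) {
    as.integer(round(meta[[paste0("freq_", s, "_pct")]] / 100 * totals[[s]]))
  }, integer(nrow(meta)))
  colnames(copies) <- paste0("copies_", levs)
  rec <- data.frame(allele_id = meta$allele_id, aa_seq = meta$aa_seq,
                    length = meta$length, copies = rowSums(copies),
                    copies, pop_freq_printed_pct = meta$pop_freq_printed_pct,
                    novel = meta$novel, genbank_ids = meta$genbank_ids,
                    row.names = NULL, stringsAsFactors = FALSE)
  cat <- methods::new("AlleleCatalog", records = rec,
                      totalSequences = as.integer(sum(rec$copies)),
                      subspeciesTotals = totals)
  if (withFrequencies) cat <- alleleFrequencies(cat)
  cat
}

#' GenBank-accession reference for strict-identity matching
#'
#' Expands the packaged catalogue into one row per GenBank accession,
#' mapping each accession to its allele's peptide sequence. This is the
#' local stand-in for a remote identity search against the public protein
#' database.
#'
#' @return `data.frame` with columns `id` (accession) and `aa_seq`.
#' @export
genbankReference <- function() {
  meta <- hvrReferenceMeta()
  keep <- meta$genbank_ids != ""
  ids <- strsplit(meta$genbank_ids[keep], ",", fixed = TRUE)
  data.frame(id = unlist(ids),
             aa_seq = rep(meta$aa_seq[keep], lengths(ids)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Synthetic outgroup peptide for tree rooting
#'
#' A constructed, clearly divergent SSLS...IEQI peptide standing in for an
#' Apis cerana HVR sequence (whose published sequence is not distributed
#' with this package). Synthetic: used only to exercise outgroup rooting.
#'
#' @return named character vector of length 1.
#' @export
outgroupPeptide <- function() {
  x <- Biostrings::readAAStringSet(
    extdataPath("outgroup_cerana_synthetic.faa"))
  stats::setNames(as.character(x[1]), names(x)[1])
}
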