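# Per-sample acceptance rules and diploid genotype calling, plus the
# cohort funnel report.

#' Per-sample assembly acceptance filter
#'
#' A sample is kept only when its reads assembled into exactly two contigs
#' (the two expected allele haplotypes of a diploid) with at most one
#' singleton read left over.
#'
#' @param assembly an [HvrAssembly-class].
#' @param nContigs required contig count (default 2).
#' @param maxSingletons maximum singletons allowed (default 1).
#' @return list with `pass` (logical) and, on failure, `reason`
#'   (`"contig_count"` or `"singleton_count"`).
#' @export
filterSample <- function(assembly, nContigs = 2L, maxSingletons = 1L) {
  if (length(contigs(assembly)) != nContigs)
    return(list(pass = FALSE, reason = "contig_count"))
  if (length(singletons(assembly)) > maxSingletons)
    return(list(pass = FALSE, reason = "singleton_count"))
  list(pass = TRUE, reason = NA_character_)
}

#' Call the diploid HVR genotype of one sample
#'
#' Both contigs of a filtered assembly must yield valid HVR peptides; the
#' unordered pair is canonicalised lexicographically. Identical peptides
#' from the two contigs are retained with a homozygous flag (worker bees
#' are expected to be heterozygous) and still count as two copies.
#'
#' @param sampleId sample identifier.
#' @param subspecies subspecies label (see [subspeciesLevels()]).
#' @param assembly an [HvrAssembly-class] that passed [filterSample()].
#' @param ... anchor and length options passed to [selectHvrPeptide()].
#' @return list with `status`; on success `genotype`, a one-row
#'   `data.frame` (`sample_id`, `subspecies`, `allele_a`, `allele_b`,
#'   `homozygous`); on rejection `reason` (`one_allele_truncated` or
#'   `both_invalid`).
#' @export
callGenotype <- function(sampleId, subspecies, assembly, ...) {
  flt <- filterSample(assembly)
  if (!flt$pass)
    stop("callGenotype() requires an assembly that passed filterSample()")
  cs <- contigs(assembly)
  sels <- lapply(seq_along(cs), function(i) {
    selectHvrPeptide(as.character(cs[[i]]), ...,
                     sourceContig = names(cs)[i])
  })
  ok <- vapply(sels, function(s) s$status == "ok", TRUE)
  if (sum(ok) < 2) {
    reason <- if (sum(ok) == 1) "one_allele_truncated" else "both_invalid"
    return(list(status = "rejected", reason = reason, selections = sels))
  }
  pair <- sort(vapply(sels, `[[`, "", "aa_seq"))
  list(status = "ok",
       genotype = data.frame(sample_id = sampleId,
                             subspecies = subspecies,
                             allele_a = pair[1], allele_b = pair[2],
                             homozygous = pair[1] == pair[2],
                             stringsAsFactors = FALSE),
       selections = sels)
}

#' Cohort funnel report
#'
#' Counts how many samples and sequences survive each pipeline stage:
#' assembly filter, translation, peptide validation, and full diploid
#' resolution (both alleles valid).
#'
#' @param outcomes list with one element per sample, each a list with
#'   `pass` (assembly filter result), `nValid` (number of contigs yielding
#'   a valid peptide, 0-2, only meaningful when `pass`), and `called`
#'   (logical, genotype emitted).
#' @return one-row `data.frame` with columns `n_samples_in`,
#'   `n_pass_assembly_filter`, `n_contigs_translated`, `n_peptides_valid`,
#'   `n_samples_both_alleles`, `n_sequences_final`.
#' @export
funnelReport <- function(outcomes) {
  pass <- vapply(outcomes, function(o) isTRUE(o$pass), TRUE)
  nValid <- vapply(outcomes, function(o) {
    if (isTRUE(o$pass)) as.integer(o$nValid) else 0L
  }, 0L)
  called <- vapply(outcomes, function(o) isTRUE(o$called), TRUE)
  data.frame(
    n_samples_in = length(outcomes),
    n_pass_assembly_filter = sum(pass),
    n_contigs_translated = 2L * sum(pass),
    n_peptides_valid = sum(nValid),
    n_samples_both_alleles = sum(called),
    n_sequences_final = 2L * sum(called))
}
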