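# Allele catalogue: identity clustering of genotyped peptides, population
# and per-subspecies frequencies, sharing classes, diversity ratio, and
# matching against the packaged reference catalogue.

#' Cluster genotyped peptides into an allele catalogue
#'
#' Allele copies (two per genotype) are grouped by exact amino-acid
#' identity. Allele ids are assigned by descending copy number, ties by
#' first occurrence in the input.
#'
#' @param genotypes `data.frame` with columns `sample_id`, `subspecies`,
#'   `allele_a`, `allele_b` (as emitted by [callGenotype()]).
#' @return an [AlleleCatalog-class]; `totalSequences` is twice the number
#'   of genotypes.
#' @export
clusterAlleles <- function(genotypes) {
  levs <- subspeciesLevels()
  if (is.null(genotypes) || nrow(genotypes) == 0) {
    return(methods::new("AlleleCatalog",
      records = data.frame(allele_id = integer(), aa_seq = character(),
                           length = integer(), copies = integer()),
      totalSequences = 0L,
      subspeciesTotals = stats::setNames(integer(length(levs)), levs)))
  }
  seqsAll <- c(rbind(genotypes$allele_a, genotypes$allele_b))
  subAll <- rep(genotypes$subspecies, each = 2)
  firstAt <- match(unique(seqsAll), seqsAll)
  uniq <- unique(seqsAll)
  copies <- as.integer(table(factor(seqsAll, levels = uniq)))
  o <- order(-copies, firstAt)
  uniq <- uniq[o]; copies <- copies[o]
  subCounts <- t(vapply(uniq, function(s) {
    tab <- table(factor(subAll[seqsAll == s], levels = levs))
    as.integer(tab)
  }, integer(length(levs))))
  colnames(subCounts) <- paste0("copies_", levs)
  rec <- data.frame(allele_id = seq_along(uniq), aa_seq = uniq,
                    length = nchar(uniq), copies = copies,
                    subCounts, row.names = NULL, stringsAsFactors = FALSE)
  methods::new("AlleleCatalog", records = rec,
    totalSequences = 2L * nrow(genotypes),
    subspeciesTotals = stats::setNames(
      as.integer(table(factor(subAll, levels = levs))), levs))
}

#' Fill population and per-subspecies percentage frequencies
#'
#' Population frequency is `100 * copies / totalSequences`; per-subspecies
#' frequency uses the subspecies copy totals. Percentages are rounded
#' half-up to two decimals; the raw population fraction is kept in
#' `pop_freq_raw` so rounded columns never have to be re-derived.
#'
#' @param catalog an [AlleleCatalog-class] with at least one sequence.
#' @return the catalogue with `pop_freq_pct`, `pop_freq_raw` and
#'   `freq_<subspecies>_pct` columns filled.
#' @export
alleleFrequencies <- function(catalog) {
  tot <- totalSequences(catalog)
  if (tot <= 0) stop("catalogue has no sequences")
  rec <- alleleRecords(catalog)
  rec$pop_freq_raw <- rec$copies / tot
  rec$pop_freq_pct <- roundHalfUp(100 * rec$copies / tot, 2)
  st <- subspeciesTotals(catalog)
  for (s in names(st)) {
    cc <- rec[[paste0("copies_", s)]]
    rec[[paste0("freq_", s, "_pct")]] <-
      if (st[[s]] > 0) roundHalfUp(100 * cc / st[[s]], 2) else 0
  }
  methods::initialize(catalog, records = rec)
}

#' Private and shared allele classes
#'
#' An allele is "in" a subspecies when its copy count there is positive.
#' The three classes partition the catalogue: present in exactly one
#' subspecies (private), exactly two, or three and more.
#'
#' @param catalog an [AlleleCatalog-class].
#' @return list of integer allele-id vectors `private`, `shared2`,
#'   `shared3plus`.
#' @export
sharingClasses <- function(catalog) {
  rec <- alleleRecords(catalog)
  cc <- as.matrix(rec[, grep("^copies_", names(rec)), drop = FALSE])
  n <- rowSums(cc > 0)
  list(private = rec$allele_id[n == 1],
       shared2 = rec$allele_id[n == 2],
       shared3plus = rec$allele_id[n >= 3])
}

#' Allele diversity ratio
#'
#' The number of distinct alleles divided by the number of sequences
#' analysed. The default reporting mode truncates to two decimals (so
#' 88/138 = 0.6377 reports 0.63); half-up rounding is also available, and
#' the raw fraction can be requested.
#'
#' @param catalog an [AlleleCatalog-class].
#' @param rounding `"truncate"` (default) or `"half_up"`.
#' @param raw if `TRUE` return the unrounded fraction.
#' @return a single numeric value.
#' @export
diversityRatio <- function(catalog, rounding = c("truncate", "half_up"),
                           raw = FALSE) {
  rounding <- match.arg(rounding)
  tot <- totalSequences(catalog)
  if (tot <= 0) stop("catalogue has no sequences")
  r <- nrow(alleleRecords(catalog)) / tot
  if (raw) return(r)
  if (rounding == "truncate") truncDigits(r, 2) else roundHalfUp(r, 2)
}

#' Match a peptide against a reference set by strict identity
#'
#' Only full-length, exact (case-insensitive) matches count; anything less
#' is a novel allele.
#'
#' @param peptide query amino-acid sequence.
#' @param reference `data.frame` with columns `id` and `aa_seq` (default:
#'   the packaged GenBank-accession reference, [genbankReference()]).
#' @return character vector of matching reference ids (empty = novel).
#' @export
matchKnown <- function(peptide, reference = genbankReference()) {
  if (nrow(reference) == 0) stop("reference must be non-empty")
  reference$id[toupper(reference$aa_seq) == toupper(peptide)]
}

#' Annotate a catalogue with known-allele matches
#'
#' @param catalog an [AlleleCatalog-class].
#' @param reference as in [matchKnown()].
#' @return the catalogue with a `known_match_ids` column (comma-separated
#'   reference ids, empty string for novel alleles).
#' @export
annotateKnown <- function(catalog, reference = genbankReference()) {
  rec <- alleleRecords(catalog)
  rec$known_match_ids <- vapply(rec$aa_seq, function(p) {
    paste(matchKnown(p, reference), collapse = ",")
  }, "", USE.NAMES = FALSE)
  methods::initialize(catalog, records = rec)
}
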