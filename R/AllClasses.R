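#' @import methods
#' @importFrom Biostrings DNAStringSet AAStringSet
NULL

#' Assembly of one sample's HVR reads
#'
#' Result of the greedy overlap-layout-consensus assembly of the reads
#' extracted for one diploid sample. Contigs hold two or more member reads;
#' every read that joined no contig is a singleton. Read conservation is a
#' class invariant: each input read appears in exactly one contig layout or
#' exactly once among the singletons.
#'
#' @slot contigs [Biostrings::DNAStringSet] of consensus sequences, one per
#'   contig, named `contig_1`, `contig_2`, ...
#' @slot members list parallel to `contigs`; each element a `data.frame`
#'   with columns `read_id`, `orientation` (`"+"`/`"-"` relative to the
#'   consensus) and `offset` (0-based placement of the read on the
#'   consensus).
#' @slot depth list parallel to `contigs`; integer per-column read counts.
#' @slot singletons character vector of read ids assembled into no contig.
#' @slot nReads integer, number of reads given to the assembler.
#'
#' @seealso [assemble()], [filterSample()]
#' @export
setClass("HvrAssembly",
  slots = c(contigs = "DNAStringSet", members = "list", depth = "list",
            singletons = "character", nReads = "integer"))

setValidity("HvrAssembly", function(object) {
  msg <- NULL
  if (length(object@members) != length(object@contigs))
    msg <- c(msg, "members must be parallel to contigs")
  if (length(object@depth) != length(object@contigs))
    msg <- c(msg, "depth must be parallel to contigs")
  nmem <- sum(vapply(object@members, nrow, 0L))
  if (length(object@contigs) &&
      any(vapply(object@members, nrow, 0L) < 2L))
    msg <- c(msg, "every contig must have >= 2 member reads")
  if (nmem + length(object@singletons) != object@nReads)
    msg <- c(msg, "reads are not conserved across contigs and singletons")
  ids <- c(unlist(lapply(object@members, `[[`, "read_id")),
           object@singletons)
  if (anyDuplicated(ids))
    msg <- c(msg, "a read appears more than once in the assembly")
  if (is.null(msg)) TRUE else msg
})

#' Catalogue of distinct HVR alleles
#'
#' Distinct amino-acid alleles observed in a cohort, with copy counts,
#' per-subspecies counts and (once [alleleFrequencies()] has been applied)
#' population and per-subspecies percentage frequencies. An allele is a
#' distinct HVR peptide sequence; alleles are compared by exact identity.
#'
#' @slot records `data.frame` with one row per allele: `allele_id`,
#'   `aa_seq`, `length`, `copies`, one `copies_<subspecies>` column per
#'   subspecies, and optional frequency / known-match columns.
#' @slot totalSequences integer, total allele copies (2 per genotype).
#' @slot subspeciesTotals named integer, allele copies per subspecies.
#'
#' @seealso [clusterAlleles()], [alleleFrequencies()], [sharingClasses()]
#' @export
setClass("AlleleCatalog",
  slots = c(records = "data.frame", totalSequences = "integer",
            subspeciesTotals = "integer"))

setValidity("AlleleCatalog", function(object) {
  msg <- NULL
  rec <- object@records
  need <- c("allele_id", "aa_seq", "length", "copies")
  if (!all(need %in% names(rec)))
    msg <- c(msg, paste("records must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(rec$aa_seq))
      msg <- c(msg, "allele sequences must be pairwise distinct")
    if (sum(rec$copies) != object@totalSequences)
      msg <- c(msg, "sum of copies must equal totalSequences")
    if (any(rec$length != nchar(rec$aa_seq)))
      msg <- c(msg, "length column disagrees with aa_seq")
  }
  if (sum(object@subspeciesTotals) != object@totalSequences)
    msg <- c(msg, "subspeciesTotals must sum to totalSequences")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn HvrAssembly-class number of contigs
#' @param object,x an `HvrAssembly` or `AlleleCatalog`
#' @export
setMethod("show", "HvrAssembly", function(object) {
  cat("HvrAssembly:", length(object@contigs), "contig(s),",
      length(object@singletons), "singleton(s),",
      object@nReads, "reads\n")
  if (length(object@contigs)) {
    w <- Biostrings::width(object@contigs)
    n <- vapply(object@members, nrow, 0L)
    for (i in seq_along(object@contigs))
      cat(sprintf("  %s: %d bp, %d reads\n",
                  names(object@contigs)[i], w[i], n[i]))
  }
})

#' @export
setMethod("show", "AlleleCatalog", function(object) {
  cat("AlleleCatalog:", nrow(object@records), "distinct allele(s) from",
      object@totalSequences, "sequences\n")
  st <- object@subspeciesTotals
  st <- st[st > 0]
  if (length(st))
    cat("  subspecies totals:",
        paste(names(st), st, sep = "=", collapse = ", "), "\n")
})

#' Accessors for HvrAssembly
#'
#' @param x an [HvrAssembly-class] object
#' @return `contigs()` the consensus `DNAStringSet`; `singletons()` the
#'   singleton read ids; `contigMembers()` the per-contig layout tables;
#'   `contigDepth()` the per-contig per-column read counts.
#' @export
contigs <- function(x) x@contigs

#' @rdname contigs
#' @export
singletons <- function(x) x@singletons

#' @rdname contigs
#' @export
contigMembers <- function(x) x@members

#' @rdname contigs
#' @export
contigDepth <- function(x) x@depth

#' Accessors for AlleleCatalog
#'
#' @param x an [AlleleCatalog-class] object
#' @return `alleleRecords()` the per-allele `data.frame`;
#'   `totalSequences()` the total number of allele copies;
#'   `subspeciesTotals()` the named per-subspecies copy totals.
#' @export
alleleRecords <- function(x) x@records

#' @rdname alleleRecords
#' @export
totalSequences <- function(x) x@totalSequences

#' @rdname alleleRecords
#' @export
subspeciesTotals <- function(x) x@subspeciesTotals
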