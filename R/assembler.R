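# Greedy overlap-layout-consensus assembler for HVR read sets.
#
# Reproduces the user-visible contract of a CAP3-style clustering step:
# gap-free dovetail/containment overlaps with a minimum overlap length
# (default 40) and minimum percent identity (default 90), greedy merging of
# the best-scoring pair, contigs (>= 2 reads) plus singletons.

#' Best gap-free overlap between two sequences
#'
#' Scans every relative offset of `b` against `a`, in both orientations of
#' `b`, and returns the highest-scoring dovetail or containment overlap
#' with length >= `minOverlap` and identity >= `minIdentity`. The score is
#' `matches - mismatchPenalty * mismatches`; `N` never counts as a match.
#' Ties are broken by longer overlap, then forward orientation, then
#' smaller offset.
#'
#' @param a,b DNA sequences (plain strings over `A`,`C`,`G`,`T`,`N`).
#' @param minOverlap minimum overlap length in bases (>= 1).
#' @param minIdentity minimum fraction of identical columns, in `(0, 1]`.
#' @param mismatchPenalty per-mismatch score penalty (default 2).
#' @return `NULL` if no qualifying overlap; otherwise a list with elements
#'   `orientation` (`"+"` forward or `"-"` reverse complement of `b`),
#'   `offset` (shift of oriented `b` relative to `a`; negative if `b`
#'   starts first), `a_start`, `b_start` (0-based starts of the overlap in
#'   each oriented sequence), `length`, `matches`, `identity`, `score`.
#' @examples
#' findBestOverlap(strrep("ACGT", 15), strrep("ACGT", 15))$identity
#' @export
findBestOverlap <- function(a, b, minOverlap = 40L, minIdentity = 0.90,
                            mismatchPenalty = 2) {
  if (minOverlap < 1) stop("minOverlap must be >= 1")
  if (minIdentity <= 0 || minIdentity > 1)
    stop("minIdentity must be in (0, 1]")
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  hit <- cpp_best_overlap_both(a, b, as.integer(minOverlap), minIdentity,
                               mismatchPenalty)
  if (!hit$found) return(NULL)
  list(orientation = hit$orientation, offset = hit$offset,
       a_start = hit$a_start, b_start = hit$b_start,
       length = hit$length, matches = hit$matches,
       identity = hit$matches / hit$length, score = hit$score)
}

#' Majority-rule consensus of a gap-free read layout
#'
#' @param seqs character vector of oriented member sequences.
#' @param offsets 0-based placements of each member on the layout.
#' @param quals optional per-member quality strings (Sanger offset); used
#'   to break ties by summed quality.
#' @return list with `consensus` (string) and `depth` (integer per-column
#'   read count). Ties go to the higher summed quality, then the
#'   alphabetically first base; `N` never beats a concrete base on a tie.
#' @export
layoutConsensus <- function(seqs, offsets, quals = NULL) {
  if (length(seqs) == 0) stop("empty layout")
  stopifnot(length(offsets) == length(seqs))
  width <- max(offsets + nchar(seqs))
  bases <- c("A", "C", "G", "T", "N")
  counts <- matrix(0L, nrow = 5, ncol = width, dimnames = list(bases))
  qsum <- matrix(0, nrow = 5, ncol = width, dimnames = list(bases))
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "")[[1]]
    pos <- offsets[i] + seq_along(ch)
    idx <- match(ch, bases)
    ok <- !is.na(idx)
    ii <- cbind(idx[ok], pos[ok])
    counts[ii] <- counts[ii] + 1L   # positions are unique within a read
    if (!is.null(quals) && !is.na(quals[i]) && nzchar(quals[i])) {
      qv <- utf8ToInt(quals[i]) - 33
      qsum[ii] <- qsum[ii] + qv[ok]
    }
  }
  cons <- character(width)
  for (j in seq_len(width)) {
    cc <- counts[1:4, j]
    if (all(cc == 0L)) {
      cons[j] <- if (counts[5, j] > 0) "N" else stop("uncovered column ", j)
      next
    }
    if (counts[5, j] > max(cc)) { cons[j] <- "N"; next }
    top <- which(cc == max(cc))
    if (length(top) > 1) {
      qq <- qsum[1:4, j][top]
      top <- top[qq == max(qq)]
    }
    cons[j] <- bases[top[1]]   # alphabetical among remaining ties
  }
  list(consensus = paste(cons, collapse = ""),
       depth = as.integer(colSums(counts)))
}

# Re-orient a unit's member table for a reverse-complemented consensus.
flipMembers <- function(members, readLens, consensusLen) {
  members$offset <- consensusLen - (members$offset + readLens)
  members$orientation <- ifelse(members$orientation == "+", "-", "+")
  members
}

# Oriented sequence of a read given its stored orientation.
orientSeq <- function(seq, orientation) {
  if (orientation == "+") seq else revcompChr(seq)
}

#' Assemble reads into contigs and singletons
#'
#' Greedy agglomeration: all pairwise qualifying overlaps between current
#' units (reads or partial contigs) are computed, the highest-scoring pair
#' is merged (layout + majority consensus), and overlaps involving the new
#' unit are recomputed, until no qualifying overlap remains. Units with at
#' least two member reads become contigs; the rest are singletons. The
#' procedure is deterministic for a given input (ties broken as in
#' [findBestOverlap()], then by unit id).
#'
#' @param reads a `DNAStringSet` (or named character vector) with unique
#'   read ids; qualities in `mcols(reads)$qual` are used for consensus
#'   tie-breaking.
#' @param minOverlap,minIdentity,mismatchPenalty overlap acceptance
#'   parameters, see [findBestOverlap()]. Defaults mirror a CAP3-style
#'   clustering (`-o 40 -p 90`).
#' @param minContigDepth optional post-hoc filter: contigs whose median
#'   per-column depth is below this are demoted to singletons (default 0 =
#'   off), an automatable stand-in for manual inspection of poorly
#'   supported assemblies.
#' @return an [HvrAssembly-class].
#' @examples
#' hap <- strrep("ACGTTGCA", 30)
#' reads <- vapply(seq(1, 91, by = 30), function(s) substr(hap, s, s + 149), "")
#' names(reads) <- paste0("r", seq_along(reads))
#' assemble(reads)
#' @export
assemble <- function(reads, minOverlap = 40L, minIdentity = 0.90,
                     mismatchPenalty = 2, minContigDepth = 0) {
  reads <- asReadSet(reads)
  quals <- readQuals(reads)
  ids <- names(reads)
  seqs <- as.character(reads)
  qualOf <- function(id) {
    if (is.null(quals)) NA_character_ else quals[match(id, ids)]
  }
  if (length(reads) == 0)
    return(methods::new("HvrAssembly", contigs = Biostrings::DNAStringSet(),
                        members = list(), depth = list(),
                        singletons = character(), nReads = 0L))

  units <- lapply(seq_along(ids), function(i) {
    list(id = ids[i], seq = seqs[i],
         members = data.frame(read_id = ids[i], orientation = "+",
                              offset = 0L, stringsAsFactors = FALSE))
  })
  names(units) <- ids

  best <- function(u, v) {
    findBestOverlap(u$seq, v$seq, minOverlap, minIdentity, mismatchPenalty)
  }
  # overlap cache keyed "idA|idB" with idA < idB lexicographically
  ov <- new.env(parent = emptyenv())
  keyOf <- function(i, j) {
    if (i < j) paste0(i, "\r", j) else paste0(j, "\r", i)
  }
  setOv <- function(i, j, val) assign(keyOf(i, j), val, envir = ov)
  un <- names(units)
  for (i in seq_along(un)) {
    for (j in seq_len(i - 1L)) {
      hit <- best(units[[un[j]]], units[[un[i]]])
      if (!is.null(hit)) setOv(un[j], un[i], list(a = un[j], b = un[i],
                                                  hit = hit))
    }
  }

  rebuildUnit <- function(members, newId) {
    oseqs <- vapply(seq_len(nrow(members)), function(k) {
      orientSeq(seqs[match(members$read_id[k], ids)],
                members$orientation[k])
    }, "")
    shift <- min(members$offset)
    members$offset <- members$offset - shift
    qv <- vapply(members$read_id, qualOf, "")
    cons <- layoutConsensus(oseqs, members$offset,
                            if (all(is.na(qv))) NULL else qv)
    list(id = newId, seq = cons$consensus, members = members,
         depth = cons$depth)
  }

  nmerge <- 0L
  repeat {
    keys <- ls(ov)
    if (length(keys) == 0) break
    cand <- lapply(keys, get, envir = ov)
    # drop stale entries (units already merged away)
    alive <- vapply(cand, function(x) {
      !is.null(units[[x$a]]) && !is.null(units[[x$b]])
    }, TRUE)
    for (k in keys[!alive]) rm(list = k, envir = ov)
    cand <- cand[alive]
    if (length(cand) == 0) break
    sc <- vapply(cand, function(x) x$hit$score, 0)
    len <- vapply(cand, function(x) x$hit$length, 0L)
    fwd <- vapply(cand, function(x) x$hit$orientation == "+", TRUE)
    pa <- vapply(cand, function(x) min(x$a, x$b), "")
    pb <- vapply(cand, function(x) max(x$a, x$b), "")
    o <- order(-sc, -len, !fwd, pa, pb)
    pickIdx <- o[1]
    pick <- cand[[pickIdx]]
    u <- units[[pick$a]]; v <- units[[pick$b]]
    hit <- pick$hit
    vm <- v$members
    vLens <- vapply(vm$read_id,
                    function(r) nchar(seqs[match(r, ids)]), 0L)
    if (hit$orientation == "-")
      vm <- flipMembers(vm, vLens, nchar(v$seq))
    vm$offset <- vm$offset + hit$offset
    allm <- rbind(u$members, vm)
    nmerge <- nmerge + 1L
    newId <- sprintf("\001merged%06d", nmerge)
    newUnit <- rebuildUnit(allm, newId)
    units[[pick$a]] <- NULL
    units[[pick$b]] <- NULL
    for (other in names(units)) {
      hit2 <- best(newUnit, units[[other]])
      if (!is.null(hit2))
        setOv(newId, other, list(a = newId, b = other, hit = hit2))
    }
    units[[newId]] <- newUnit
  }

  sizes <- vapply(units, function(u) nrow(u$members), 0L)
  contigUnits <- units[sizes >= 2L]
  singles <- unlist(lapply(units[sizes < 2L],
                           function(u) u$members$read_id),
                    use.names = FALSE)
  if (is.null(singles)) singles <- character()

  if (minContigDepth > 0 && length(contigUnits)) {
    keep <- vapply(contigUnits, function(u) {
      stats::median(u$depth) >= minContigDepth
    }, TRUE)
    demoted <- contigUnits[!keep]
    contigUnits <- contigUnits[keep]
    singles <- c(singles, unlist(lapply(demoted,
                 function(u) u$members$read_id), use.names = FALSE))
  }

  # deterministic contig order: more members first, then consensus
  if (length(contigUnits)) {
    o <- order(-vapply(contigUnits, function(u) nrow(u$members), 0L),
               vapply(contigUnits, function(u) u$seq, ""))
    contigUnits <- contigUnits[o]
  }
  consensi <- Biostrings::DNAStringSet(
    vapply(contigUnits, function(u) u$seq, character(1)))
  names(consensi) <- if (length(contigUnits))
    paste0("contig_", seq_along(contigUnits)) else character()
  methods::new("HvrAssembly",
    contigs = consensi,
    members = unname(lapply(contigUnits, function(u) u$members)),
    depth = unname(lapply(contigUnits, function(u) u$depth)),
    singletons = sort(singles),
    nReads = length(reads))
}
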