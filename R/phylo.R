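# Distance-based peptide tree: pairwise global-alignment distances,
# canonical neighbor-joining, outgroup rooting on the pendant edge
# midpoint, newick I/O. A deliberately simple substitute for model-based
# maximum-likelihood inference.

#' Normalised alignment distance between two peptides
#'
#' Global alignment with cost 0 per match, 1 per mismatch and 1 per gap
#' position, normalised by the alignment length, giving a p-distance-like
#' value in `[0, 1]`. Among minimum-cost alignments the longest is used as
#' the normaliser (deterministic).
#'
#' @param a,b non-empty peptide strings.
#' @return numeric distance in `[0, 1]`.
#' @examples
#' peptideDistance("SSLSIEQI", "SSLSNIEQI")  # 1/9
#' @export
peptideDistance <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("peptides must be non-empty")
  v <- cpp_align_dist(toupper(a), toupper(b))
  v[1] / v[2]
}

#' Pairwise distance matrix for a set of peptides
#'
#' @param peptides named character vector (labels become matrix dimnames).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
peptideDistanceMatrix <- function(peptides) {
  if (is.null(names(peptides)) || anyDuplicated(names(peptides)))
    stop("peptides must have unique names")
  n <- length(peptides)
  d <- matrix(0, n, n, dimnames = list(names(peptides), names(peptides)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- peptideDistance(peptides[[i]], peptides[[j]])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining (via [ape::nj()]). Negative branch
#' lengths, an occasional NJ artefact, are clamped to zero and flagged in
#' the returned tree's `clamped` attribute.
#'
#' @param d symmetric distance matrix with at least 3 labelled rows.
#' @return an [ape::phylo] tree.
#' @export
njTree <- function(d) {
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  tr <- ape::nj(d)
  neg <- tr$edge.length < 0
  if (any(neg)) {
    tr$edge.length[neg] <- 0
    attr(tr, "clamped") <- sum(neg)
  } else {
    attr(tr, "clamped") <- 0L
  }
  tr
}

#' Root a tree on an outgroup leaf
#'
#' Places the root at the midpoint of the outgroup's pendant edge.
#'
#' @param tree an `ape::phylo` tree.
#' @param label tip label of the outgroup.
#' @return a rooted `phylo` tree.
#' @export
rootOnOutgroup <- function(tree, label) {
  tip <- match(label, tree$tip.label)
  if (is.na(tip)) stop("outgroup label not in tree: ", label)
  edge <- which(tree$edge[, 2] == tip)
  len <- tree$edge.length[edge]
  phytools::reroot(tree, tip, position = len / 2)
}

#' Newick serialisation
#'
#' @param tree an `ape::phylo` tree.
#' @param path optional file; when `NULL` the newick string is returned.
#' @return newick text (invisibly when written to file).
#' @export
writeNewick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname writeNewick
#' @param text newick string (or use `path`).
#' @export
readNewick <- function(text = NULL, path = NULL) {
  if (!is.null(path)) ape::read.tree(path) else ape::read.tree(text = text)
}

#' Build the allele tree for a catalogue
#'
#' Convenience wrapper: distances over the catalogue's distinct allele
#' peptides (labelled by allele id), optional outgroup appended, NJ tree,
#' rooted on the outgroup when present.
#'
#' @param catalog an [AlleleCatalog-class] with >= 3 alleles (>= 2 when an
#'   outgroup is added).
#' @param outgroup optional named character vector of length 1 (default
#'   the packaged synthetic outgroup, [outgroupPeptide()]); `NULL` for an
#'   unrooted tree.
#' @return an `ape::phylo` tree.
#' @export
alleleTree <- function(catalog, outgroup = outgroupPeptide()) {
  rec <- alleleRecords(catalog)
  peps <- stats::setNames(rec$aa_seq, paste0("Allele_", rec$allele_id))
  if (!is.null(outgroup)) peps <- c(peps, outgroup)
  tr <- njTree(peptideDistanceMatrix(peps))
  if (!is.null(outgroup)) tr <- rootOnOutgroup(tr, names(outgroup)[1])
  tr
}
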