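# Internal helpers shared across modules.

#' @useDynLib csdTyper, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Half-up rounding to `digits` decimals (so 2.375 -> 2.38), as used for all
# printed percentage frequencies.
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Truncation (round toward zero) to `digits` decimals.
truncDigits <- function(x, digits = 2) {
  p <- 10^digits
  trunc(x * p) / p
}

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. With seed = NULL the current RNG stream is used as-is.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Reverse complement of a plain character DNA string (keeps N).
revcompChr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Coerce reads given as a named character vector or DNAStringSet into a
# DNAStringSet with unique names; optional qualities carried in mcols.
asReadSet <- function(reads, quals = NULL) {
  if (is.character(reads)) {
    if (is.null(names(reads)))
      stop("reads must be named by read id")
    reads <- Biostrings::DNAStringSet(reads)
  }
  if (!methods::is(reads, "DNAStringSet"))
    stop("reads must be a DNAStringSet or named character vector")
  if (length(reads) > 0 &&
      (is.null(names(reads)) || anyDuplicated(names(reads))))
    stop("read ids must be present and unique")
  if (!is.null(quals)) {
    if (length(quals) != length(reads) ||
        any(nchar(quals) != Biostrings::width(reads)))
      stop("qualities must match read lengths")
    S4Vectors::mcols(reads)$qual <- quals
  }
  reads
}

readQuals <- function(reads) {
  mc <- S4Vectors::mcols(reads)
  if (!is.null(mc) && "qual" %in% names(mc)) as.character(mc$qual) else NULL
}

#' Subspecies labels of the study cohort
#'
#' The closed vocabulary of subspecies labels used throughout the package,
#' in the fixed column order of all reports.
#'
#' @return character vector of the seven labels.
#' @export
subspeciesLevels <- function() {
  c("ligustica", "buckfast", "sicula", "carnica", "mellifera",
    "hybrid_carnica", "cecropia")
}
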