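# End-to-end orchestration: per-sample extraction/assembly/typing, cohort
# catalogue, sharing classes, funnel and optional allele tree.

#' Pipeline configuration
#'
#' @param region HVR interval for SAM extraction (default [hvrRegion()]).
#' @param minOverlap,minIdentity,mismatchPenalty assembler thresholds, see
#'   [assemble()].
#' @param startAnchor,endAnchor,minPeptideLen,maxPeptideLen peptide
#'   validation, see [selectHvrPeptide()].
#' @param nContigs,maxSingletons sample acceptance, see [filterSample()].
#' @param minOverlapBp minimum reference overlap for SAM extraction.
#' @param buildTree build the NJ allele tree when at least 2 alleles were
#'   catalogued (default `TRUE`).
#' @return list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(region = hvrRegion(), minOverlap = 40L,
                           minIdentity = 0.90, mismatchPenalty = 2,
                           startAnchor = "SSLS", endAnchor = "IEQI",
                           minPeptideLen = 20L, maxPeptideLen = 80L,
                           nContigs = 2L, maxSingletons = 1L,
                           minOverlapBp = 1L, buildTree = TRUE) {
  structure(as.list(environment()), class = "pipelineConfig")
}

loadSampleReads <- function(path, config) {
  if (grepl("\\.(sam|bam)$", path, ignore.case = TRUE)) {
    extractRegionReads(path, config$region,
                       minOverlapBp = config$minOverlapBp)
  } else if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) {
    readFastqReads(path)
  } else {
    readFastaReads(path)
  }
}

#' Run the full typing pipeline on a cohort
#'
#' Per sample: load reads (FASTA/FASTQ directly, or extract the HVR
#' interval from SAM), assemble, apply the two-contig filter, translate
#' and validate both contigs, and call the diploid genotype. Cohort-wide:
#' allele catalogue with frequencies and known-allele annotation, sharing
#' classes, funnel report, and (optionally) the NJ allele tree rooted on
#' the packaged synthetic outgroup. A failing sample is recorded and the
#' pipeline continues.
#'
#' @param sampleSheet `data.frame` with columns `sample_id`, `subspecies`
#'   and either `path` (input file per sample) or — when `reads` is given —
#'   nothing else.
#' @param config a [pipelineConfig()].
#' @param reads optional named list of read sets (per `sample_id`),
#'   bypassing file input (e.g. straight from [generateCohort()]).
#' @param outDir optional directory for the TSV report bundle.
#' @return list with `genotypes`, `catalog`, `sharing`, `funnel`,
#'   `outcomes` (per-sample status), `tree` (or `NULL`), and `paths` when
#'   `outDir` was given.
#' @export
runPipeline <- function(sampleSheet, config = pipelineConfig(),
                        reads = NULL, outDir = NULL) {
  stopifnot(all(c("sample_id", "subspecies") %in% names(sampleSheet)))
  outcomes <- list()
  genos <- list()
  for (i in seq_len(nrow(sampleSheet))) {
    sid <- sampleSheet$sample_id[i]
    out <- list(sample_id = sid, pass = FALSE, nValid = 0L,
                called = FALSE, reason = NA_character_)
    res <- tryCatch({
      rd <- if (!is.null(reads)) reads[[sid]]
            else loadSampleReads(sampleSheet$path[i], config)
      asm <- assemble(rd, minOverlap = config$minOverlap,
                      minIdentity = config$minIdentity,
                      mismatchPenalty = config$mismatchPenalty)
      flt <- filterSample(asm, nContigs = config$nContigs,
                          maxSingletons = config$maxSingletons)
      out$pass <- flt$pass
      if (!flt$pass) {
        out$reason <- flt$reason
      } else {
        call <- callGenotype(sid, sampleSheet$subspecies[i], asm,
                             startAnchor = config$startAnchor,
                             endAnchor = config$endAnchor,
                             minLen = config$minPeptideLen,
                             maxLen = config$maxPeptideLen)
        out$nValid <- sum(vapply(call$selections,
                                 function(s) s$status == "ok", TRUE))
        if (call$status == "ok") {
          out$called <- TRUE
          genos[[length(genos) + 1L]] <- call$genotype
        } else {
          out$reason <- call$reason
        }
      }
      out
    }, error = function(e) {
      out$reason <- paste("error:", conditionMessage(e))
      out
    })
    outcomes[[sid]] <- res
  }
  genotypes <- if (length(genos)) do.call(rbind, genos) else NULL
  funnel <- funnelReport(outcomes)
  catalog <- clusterAlleles(genotypes)
  sharing <- NULL
  tree <- NULL
  if (nrow(alleleRecords(catalog)) > 0) {
    catalog <- annotateKnown(alleleFrequencies(catalog))
    sharing <- sharingClasses(catalog)
    if (isTRUE(config$buildTree) && nrow(alleleRecords(catalog)) >= 2)
      tree <- alleleTree(catalog)
  }
  bundle <- list(genotypes = genotypes, catalog = catalog,
                 sharing = sharing, funnel = funnel,
                 outcomes = outcomes, tree = tree)
  if (!is.null(outDir) && nrow(alleleRecords(catalog)) > 0) {
    bundle$paths <- writeReportTables(catalog, genotypes, funnel, outDir)
    if (!is.null(tree)) {
      treePath <- file.path(outDir, "allele_tree.nwk")
      writeNewick(tree, treePath)
      bundle$paths["tree"] <- treePath
    }
  }
  bundle
}
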