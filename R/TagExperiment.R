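#' Construct a TagExperiment
#'
#' Bundles a raw count matrix and a phenotype table into a
#' \linkS4class{SummarizedExperiment}-derived container, aligning samples by
#' identifier. The phenotype table's rownames must be sample identifiers; by
#' default every phenotype sample must be present in the counts.
#'
#' @param counts integer gene x sample matrix with dimnames.
#' @param phenotype data.frame keyed by sample identifiers (rownames), with
#'   the continuous trait column and any covariates.
#' @param trait name of the trait column in `phenotype`.
#' @param covariates character vector of default covariate columns.
#' @param allowSubset if TRUE, phenotype samples missing from the counts are
#'   dropped instead of raising an error.
#' @return a [TagExperiment-class].
#' @examples
#' sim <- simulateTagDataset(synthConfig(nGenes = 50, nSamples = 12, nTags = 2,
#'                                       seed = 1))
#' te <- TagExperiment(sim$counts, sim$phenotype)
#' te
#' @export
TagExperiment <- function(counts, phenotype, trait = "trait",
                          covariates = character(), allowSubset = FALSE) {
  assertCountMatrix(counts)
  assertPhenotype(phenotype, trait)
  al <- alignSamples(counts, phenotype, allowSubset = allowSubset)
  se <- SummarizedExperiment(
    assays = list(counts = al$counts),
    colData = DataFrame(al$phenotype))
  new("TagExperiment", se, traitName = trait,
      covariateNames = as.character(covariates))
}

#' @rdname tagseq-generics
#' @export
setMethod("traitName", "TagExperiment", function(x) x@traitName)

#' @rdname tagseq-generics
#' @export
setMethod("covariateNames", "TagExperiment", function(x) x@covariateNames)

#' @rdname tagseq-generics
#' @export
setMethod("normFactors", "TagExperiment", function(x, ...) {
  nf <- metadata(x)$normFactors
  if (is.null(nf)) stopf("no normalization factors: run normalizeTMM() first")
  nf
})

#' @rdname tagseq-generics
#' @export
setMethod("logCPM", "TagExperiment", function(x, ...) {
  if (!"logcpm" %in% assayNames(x))
    stopf("no 'logcpm' assay: run normalizeTMM() first")
  assay(x, "logcpm")
})

## Phenotype back as a plain data.frame (rownames = sample ids).
#' Extract the phenotype table of a TagExperiment
#' @param x a [TagExperiment-class].
#' @return data.frame keyed by sample identifier.
#' @export
phenotypeTable <- function(x) {
  stopifnot(is(x, "TagExperiment"))
  as.data.frame(colData(x))
}

setMethod("show", "TagExperiment", function(object) {
  callNextMethod()
  cat("trait:", object@traitName,
      if (length(object@covariateNames))
        paste0("| covariates: ",
               paste(object@covariateNames, collapse = ", ")) else "",
      "\n")
  if (!is.null(metadata(object)$normFactors))
    cat("TMM-normalized (assay 'logcpm' present)\n")
})

setMethod("show", "NormFactors", function(object) {
  cat("NormFactors:", length(object@factors), "samples, reference",
      object@referenceSample, "\n")
  print(head(setNames(object@factors, object@sampleIds), 8L))
  if (length(object@factors) > 8L) cat("...\n")
})

#' @rdname tagseq-generics
#' @export
setMethod("normFactors", "NormFactors", function(x, ...)
  setNames(x@factors, x@sampleIds))

#' @rdname tagseq-generics
#' @export
setMethod("referenceSample", "NormFactors", function(x) x@referenceSample)

setMethod("show", "GeneFit", function(object) {
  cat(sprintf("GeneFit [%s]%s: beta1 = %.4g (se %.4g), t = %.4g, df = %d, p = %.4g\n",
              object@method,
              if (length(object@geneId)) paste0(" ", object@geneId) else "",
              object@coefficients[2L], object@seBeta1, object@statistic,
              as.integer(object@df), object@pvalue))
  if (object@method == "huber")
    cat(sprintf("  scale = %.4g, k = %.4g, %d iterations, converged: %s\n",
                object@scale, object@k, object@nIter, object@converged))
})

setMethod("show", "TagScanResult", function(object) {
  tab <- object@table
  cat(sprintf("TagScanResult: %d genes, method = %s, n = %d\n",
              nrow(tab), object@method, object@nSamples))
  if (length(object@covariates))
    cat("  covariates:", paste(object@covariates, collapse = ", "), "\n")
  cat(sprintf("  significant (%s < %g): %d | flagged: %d\n",
              if (object@adjust == "fdr") "FDR" else "raw p", object@alpha,
              sum(tab$significant, na.rm = TRUE), sum(tab$flagged)))
  print(head(tab[, c("gene_id", "beta1", "se_beta1", "statistic",
                     "pvalue", "fdr")], 6L))
  if (nrow(tab) > 6L) cat("...\n")
})

#' @rdname tagseq-generics
#' @export
setMethod("scanTable", "TagScanResult", function(x, original_order = FALSE, ...) {
  tab <- x@table
  if (original_order) tab <- tab[order(tab$order), , drop = FALSE]
  tab
})

#' @rdname tagseq-generics
#' @export
setMethod("significantGenes", "TagScanResult", function(x, ...)
  x@table$gene_id[x@table$significant %in% TRUE])

setMethod("show", "MockResult", function(object) {
  cat(sprintf(
    "MockResult: method = %s, %d per group, %d repeats, alpha = %g\n",
    object@method, object@replicateCount, object@nRepeats, object@alpha))
  cat(sprintf("  mean PFD = %.4f (se %.4f), mean #significant(real) = %.1f\n",
              object@meanPfd, object@sePfd, object@meanNSigReal))
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(
    "SynthConfig: %d genes x %d samples, %d TAGs (slope %g), noise sd %g\n",
    object@nGenes, object@nSamples, object@nTags, object@effectSize,
    object@traitNoiseSd))
  cat(sprintf("  NB dispersion %g, lib sizes [%g, %g], seed %d\n",
              object@dispersion, object@libSizeRange[1],
              object@libSizeRange[2], object@seed))
  if (object@outlierFraction > 0)
    cat(sprintf("  trait outliers: %g%% at %g SD\n",
                100 * object@outlierFraction, object@outlierMagnitude))
})

#' @rdname tagseq-generics
#' @export
setMethod("trueTags", "SynthTruth", function(x) x@tagGenes)

setMethod("show", "SynthTruth", function(object) {
  cat(sprintf("SynthTruth: %d TAG genes, seed %d\n",
              length(object@tagGenes), object@seed))
  print(head(setNames(object@trueBeta, object@tagGenes), 6L))
})
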