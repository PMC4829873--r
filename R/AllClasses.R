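#' TMM scaling factors
#'
#' Per-sample trimmed-mean-of-M-values scaling factors, rescaled so their
#' geometric mean is 1. The effective library size of sample *k* is its raw
#' library size times `factors(x)[k]`.
#'
#' @slot sampleIds character vector of sample identifiers (ordered).
#' @slot factors positive numeric vector, one per sample, geometric mean 1.
#' @slot referenceSample identifier of the reference sample used for the
#'   pairwise M/A comparisons.
#' @seealso [tmmFactors()]
#' @exportClass NormFactors
setClass("NormFactors",
  representation(sampleIds = "character",
                 factors = "numeric",
                 referenceSample = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@sampleIds) != length(object@factors))
      msg <- c(msg, "sampleIds and factors lengths differ")
    if (any(!is.finite(object@factors)) || any(object@factors <= 0))
      msg <- c(msg, "all factors must be finite and > 0")
    else if (abs(mean(log(object@factors))) > 1e-9)
      msg <- c(msg, "factors must have geometric mean 1 (tolerance 1e-9)")
    if (anyDuplicated(object@sampleIds))
      msg <- c(msg, "duplicate sample identifiers")
    if (length(object@referenceSample) != 1L ||
        !object@referenceSample %in% object@sampleIds)
      msg <- c(msg, "referenceSample must name one of the samples")
    if (is.null(msg)) TRUE else msg
  })

#' One gene's fitted trait-association model
#'
#' Result of regressing the trait on one gene's expression (plus covariates)
#' by ordinary least squares ([fitOLS()]) or Huber IRWLS
#' ([fitHuberIRWLS()]). Inference is on the expression slope (the second
#' coefficient): `statistic = beta1 / seBeta1` referred to a t distribution
#' on `df = n - p` degrees of freedom.
#'
#' @slot geneId gene identifier (may be empty for ad-hoc fits).
#' @slot method `"ols"` or `"huber"`.
#' @slot coefficients named numeric: intercept, expression slope, covariates.
#' @slot seBeta1 standard error of the expression slope.
#' @slot statistic Wald t statistic for the expression slope.
#' @slot df residual degrees of freedom, n - p.
#' @slot pvalue two-sided p-value (NA when residual variance is zero and the
#'   slope is zero, a degenerate fit).
#' @slot residuals per-sample residuals at the final coefficients.
#' @slot weights per-sample robust weights in (0, 1]; all 1 for OLS.
#' @slot scale residual scale: MAD-based robust sigma-hat for Huber, the
#'   residual standard error for OLS.
#' @slot k Huber tuning constant in sigma units (1.345 default; Inf-like for
#'   OLS, stored as NA).
#' @slot nIter IRWLS iterations used (1 for OLS).
#' @slot converged logical convergence flag (always TRUE for OLS).
#' @slot gramInv unscaled inverse Gram matrix (X'X)^-1 of the design, kept so
#'   [robustWaldTest()] can recompute the sandwich standard error.
#' @exportClass GeneFit
setClass("GeneFit",
  representation(geneId = "character", method = "character",
                 coefficients = "numeric", seBeta1 = "numeric",
                 statistic = "numeric", df = "numeric", pvalue = "numeric",
                 residuals = "numeric", weights = "numeric",
                 scale = "numeric", k = "numeric", nIter = "integer",
                 converged = "logical", gramInv = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (!object@method %in% c("ols", "huber"))
      msg <- c(msg, "method must be 'ols' or 'huber'")
    if (!is.na(object@pvalue) &&
        (object@pvalue < 0 || object@pvalue > 1))
      msg <- c(msg, "pvalue must lie in [0, 1]")
    if (any(object@weights <= 0) || any(object@weights > 1 + 1e-12))
      msg <- c(msg, "weights must lie in (0, 1]")
    if (object@method == "ols" &&
        (object@nIter != 1L || any(object@weights != 1)))
      msg <- c(msg, "OLS fits must have nIter = 1 and unit weights")
    if (is.null(msg)) TRUE else msg
  })

#' Genome-wide trait-association scan result
#'
#' One row per gene, ordered by ascending p-value; the `order` column holds
#' each gene's position in the input expression matrix so the original order
#' is recoverable. `significant` applies the scan's threshold rule:
#' `fdr < alpha` when `adjust = "fdr"`, `pvalue < alpha` when
#' `adjust = "none"`. Genes whose fit failed are kept with `flagged = TRUE`
#' and NA statistics.
#'
#' @slot table data.frame with columns gene_id, order, beta1, se_beta1,
#'   statistic, df, pvalue, fdr, significant, flagged.
#' @slot method `"ols"` or `"huber"`.
#' @slot covariates covariate column names used (may be empty).
#' @slot alpha significance threshold.
#' @slot adjust `"none"` or `"fdr"` (Benjamini-Hochberg).
#' @slot k Huber tuning constant used (NA for OLS).
#' @slot nSamples number of samples entering the fits.
#' @seealso [tagScan()], [scanTable()]
#' @exportClass TagScanResult
setClass("TagScanResult",
  representation(table = "data.frame", method = "character",
                 covariates = "character", alpha = "numeric",
                 adjust = "character", k = "numeric", nSamples = "integer"),
  validity = function(object) {
    msg <- NULL
    tab <- object@table
    need <- c("gene_id", "order", "beta1", "se_beta1", "statistic", "df",
              "pvalue", "fdr", "significant", "flagged")
    if (!all(need %in% colnames(tab)))
      msg <- c(msg, paste("table missing columns:",
                          paste(setdiff(need, colnames(tab)), collapse = ", ")))
    else {
      ok <- !is.na(tab$pvalue) & !is.na(tab$fdr)
      if (any(tab$fdr[ok] < tab$pvalue[ok] - 1e-12))
        msg <- c(msg, "fdr must be >= pvalue for every gene")
      if (is.unsorted(tab$pvalue[!is.na(tab$pvalue)]))
        msg <- c(msg, "table must be ordered by ascending pvalue")
    }
    if (!object@adjust %in% c("none", "fdr"))
      msg <- c(msg, "adjust must be 'none' or 'fdr'")
    if (object@alpha <= 0 || object@alpha >= 1)
      msg <- c(msg, "alpha must lie in (0, 1)")
    if (is.null(msg)) TRUE else msg
  })

#' Mock-comparison result at one replicate count
#'
#' Per-repeat significant-gene counts and proportion-of-false-discoveries
#' (PFD) values from the permutation mock comparison, with their summary.
#' PFD for one repeat is |significant in real and mock| / |significant in
#' real|; repeats with an empty real set contribute NA and are excluded
#' from the mean.
#'
#' @slot method method label (e.g. "ols", "huber", or a plug-in name).
#' @slot alpha raw-p significance level used inside the comparison.
#' @slot replicateCount samples drawn per group (or n/2 for a continuous
#'   trait with no grouping).
#' @slot nRepeats number of subsample/permute repeats.
#' @slot repeats data.frame: repeat_index, seed, n_sig_real, n_sig_mock,
#'   n_common, pfd.
#' @slot meanPfd mean PFD over repeats with a non-empty real set.
#' @slot sePfd standard error of the PFD (sample SD / sqrt(#non-NA repeats)).
#' @slot meanNSigReal mean number of real-data significant genes.
#' @seealso [mockComparison()]
#' @exportClass MockResult
setClass("MockResult",
  representation(method = "character", alpha = "numeric",
                 replicateCount = "integer", nRepeats = "integer",
                 repeats = "data.frame", meanPfd = "numeric",
                 sePfd = "numeric", meanNSigReal = "numeric"),
  validity = function(object) {
    msg <- NULL
    rp <- object@repeats
    need <- c("repeat_index", "seed", "n_sig_real", "n_sig_mock",
              "n_common", "pfd")
    if (!all(need %in% colnames(rp)))
      msg <- c(msg, "repeats table missing required columns")
    else {
      ok <- !is.na(rp$pfd)
      if (any(rp$pfd[ok] < 0 | rp$pfd[ok] > 1))
        msg <- c(msg, "pfd must lie in [0, 1]")
      if (any(rp$n_common > pmin(rp$n_sig_real, rp$n_sig_mock)))
        msg <- c(msg, "n_common cannot exceed min(n_sig_real, n_sig_mock)")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Synthetic-dataset configuration
#'
#' Parameters of the negative-binomial RNA-seq generator with a linearly
#' trait-driving TAG subset. The NB parameterization is by dispersion phi
#' with variance mu + phi * mu^2. Defaults emulate a human-scale cohort:
#' 2,000 genes, 89 samples, 50 TAGs of slope 1 (trait units per log2-CPM
#' unit), Gaussian trait noise of SD 1.
#'
#' @slot nGenes,nSamples matrix dimensions.
#' @slot nTags number of trait-driving genes (<= nGenes).
#' @slot effectSize true slope shared by all TAGs (trait units per
#'   log2-expression unit).
#' @slot traitNoiseSd SD of the Gaussian trait noise.
#' @slot dispersion NB dispersion phi (> 0); variance mu + phi mu^2.
#' @slot libSizeRange length-2 positive range; library sizes drawn uniformly.
#' @slot baseMeanLog,baseMeanSdLog log-normal parameters of the gene base
#'   means (counts-per-million scale).
#' @slot covariateSpec list or empty: named covariate coefficients, e.g.
#'   `list(batch = 2, age = 0.05)`; "batch" generates a 2-level factor, any
#'   other name a standard-normal continuous covariate.
#' @slot outlierFraction fraction of samples whose trait is displaced
#'   (in [0, 0.5)).
#' @slot outlierMagnitude displacement size in trait-SD units.
#' @slot seed generative seed; one seed reproduces counts, trait and truth.
#' @seealso [synthConfig()], [simulateCounts()], [simulateTrait()]
#' @exportClass SynthConfig
setClass("SynthConfig",
  representation(nGenes = "integer", nSamples = "integer", nTags = "integer",
                 effectSize = "numeric", traitNoiseSd = "numeric",
                 dispersion = "numeric", libSizeRange = "numeric",
                 baseMeanLog = "numeric", baseMeanSdLog = "numeric",
                 covariateSpec = "list", outlierFraction = "numeric",
                 outlierMagnitude = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@nGenes < 1L || object@nSamples < 2L)
      msg <- c(msg, "need at least 1 gene and 2 samples")
    if (object@nTags < 0L || object@nTags > object@nGenes)
      msg <- c(msg, "nTags must lie in [0, nGenes]")
    if (object@traitNoiseSd < 0) msg <- c(msg, "traitNoiseSd must be >= 0")
    if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
    if (length(object@libSizeRange) != 2L || any(object@libSizeRange <= 0) ||
        object@libSizeRange[1] > object@libSizeRange[2])
      msg <- c(msg, "libSizeRange must be a positive (min, max) pair")
    if (object@outlierFraction < 0 || object@outlierFraction >= 0.5)
      msg <- c(msg, "outlierFraction must lie in [0, 0.5)")
    if (is.null(msg)) TRUE else msg
  })

#' Ground truth of a synthetic dataset
#'
#' @slot tagGenes identifiers of the trait-driving genes.
#' @slot trueBeta named per-TAG true slope.
#' @slot covariateCoefs named true covariate coefficients (possibly empty).
#' @slot seed the generative seed.
#' @exportClass SynthTruth
setClass("SynthTruth",
  representation(tagGenes = "character", trueBeta = "numeric",
                 covariateCoefs = "numeric", seed = "integer"),
  validity = function(object) {
    if (length(object@tagGenes) != length(object@trueBeta))
      "tagGenes and trueBeta lengths differ" else TRUE
  })

#' RNA-seq trait-association experiment container
#'
#' A \linkS4class{SummarizedExperiment} whose first assay `"counts"` holds
#' the raw gene x sample integer counts and whose `colData` holds the
#' phenotype table (continuous trait plus covariates). [normalizeTMM()]
#' adds the `"logcpm"` assay and stores the [NormFactors-class] in
#' `metadata(x)$normFactors`.
#'
#' @slot traitName name of the trait column in `colData`.
#' @slot covariateNames default covariate columns for scans.
#' @seealso [TagExperiment()], [tagScan()]
#' @exportClass TagExperiment
setClass("TagExperiment",
  contains = "SummarizedExperiment",
  representation(traitName = "character", covariateNames = "character"),
  validity = function(object) {
    msg <- NULL
    if (!"counts" %in% assayNames(object))
      msg <- c(msg, "assay 'counts' is required")
    else {
      cts <- assay(object, "counts")
      if (any(cts < 0) || any(cts != round(cts)))
        msg <- c(msg, "counts must be nonnegative integers")
    }
    if (ncol(object) < 2L) msg <- c(msg, "at least 2 samples required")
    if (is.null(rownames(object)) || is.null(colnames(object)))
      msg <- c(msg, "gene and sample identifiers are required")
    if (length(object@traitName) == 1L &&
        !object@traitName %in% colnames(colData(object)))
      msg <- c(msg, sprintf("trait column '%s' absent from colData",
                            object@traitName))
    if (length(object@covariateNames) &&
        !all(object@covariateNames %in% colnames(colData(object))))
      msg <- c(msg, "covariateNames absent from colData")
    if (is.null(msg)) TRUE else msg
  })
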