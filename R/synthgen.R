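## Synthetic RNA-seq generator: negative-binomial counts with sample-wise
## library sizes, a TAG subset whose log2-CPM expression linearly drives a
## Gaussian-noise continuous trait, optional covariates and trait outliers.

#' Build a synthetic-dataset configuration
#'
#' See [SynthConfig-class] for the meaning of every field. Defaults emulate
#' a human-scale bulk RNA-seq cohort (2,000 genes x 89 samples, 50 TAGs of
#' slope 1 with unit trait noise, NB dispersion 0.1, library sizes uniform
#' on 1-3 million).
#'
#' @param nGenes,nSamples,nTags,effectSize,traitNoiseSd,dispersion,libSizeRange,baseMeanLog,baseMeanSdLog,covariateSpec,outlierFraction,outlierMagnitude,seed
#'   see [SynthConfig-class].
#' @return a validated [SynthConfig-class].
#' @export
synthConfig <- function(nGenes = 2000L, nSamples = 89L, nTags = 50L,
                        effectSize = 1.0, traitNoiseSd = 1.0,
                        dispersion = 0.1, libSizeRange = c(1e6, 3e6),
                        baseMeanLog = log(100), baseMeanSdLog = 1.5,
                        covariateSpec = list(), outlierFraction = 0,
                        outlierMagnitude = 10, seed = 1L) {
  new("SynthConfig", nGenes = as.integer(nGenes),
      nSamples = as.integer(nSamples), nTags = as.integer(nTags),
      effectSize = effectSize, traitNoiseSd = traitNoiseSd,
      dispersion = dispersion, libSizeRange = as.numeric(libSizeRange),
      baseMeanLog = baseMeanLog, baseMeanSdLog = baseMeanSdLog,
      covariateSpec = covariateSpec, outlierFraction = outlierFraction,
      outlierMagnitude = outlierMagnitude, seed = as.integer(seed))
}

#' Simulate a negative-binomial count matrix
#'
#' Gene base means are drawn log-normally (CPM scale), library sizes
#' uniformly on `libSizeRange`, and counts negative-binomially with mean
#' `mu_g * N_k / 1e6` and variance `mu + dispersion * mu^2`. Fully
#' reproducible from `config@seed`.
#'
#' @param config a [SynthConfig-class].
#' @return integer gene x sample matrix with identifiers.
#' @export
simulateCounts <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  G <- config@nGenes; n <- config@nSamples
  withSeed(config@seed, {
    mu <- rlnorm(G, meanlog = config@baseMeanLog,
                 sdlog = config@baseMeanSdLog)
    libs <- round(runif(n, config@libSizeRange[1], config@libSizeRange[2]))
    m <- outer(mu, libs / 1e6)
    counts <- matrix(rnbinom(G * n, mu = m, size = 1 / config@dispersion),
                     nrow = G, ncol = n)
    dimnames(counts) <- list(sprintf("gene%04d", seq_len(G)),
                             sprintf("sample%03d", seq_len(n)))
    counts
  })
}

#' Simulate a TAG-driven continuous trait
#'
#' Chooses `nTags` genes uniformly at random and assembles the trait as
#' `sum over TAGs of effectSize * log2CPM(gene) + covariate terms +
#' N(0, traitNoiseSd)`. The predictor is the same TMM-normalized log2 CPM
#' the scans use, so true slopes are exact on the analysis scale.
#' Covariates from `covariateSpec` are appended to the phenotype: a
#' coefficient named `"batch"` yields a two-level factor, any other name a
#' standard-normal continuous covariate.
#'
#' @param counts matrix from [simulateCounts()].
#' @param config the same [SynthConfig-class].
#' @return list with `phenotype` (data.frame keyed by sample id, column
#'   `trait` + covariates) and `truth` (a [SynthTruth-class]).
#' @export
simulateTrait <- function(counts, config) {
  stopifnot(is(config, "SynthConfig"))
  assertCountMatrix(counts)
  n <- ncol(counts)
  expr <- log2CPM(counts, tmmFactors(counts))
  withSeed(config@seed + 1L, {
    tags <- if (config@nTags > 0L)
      sort(sample(rownames(counts), config@nTags)) else character()
    signal <- if (length(tags))
      config@effectSize * colSums(expr[tags, , drop = FALSE])
    else rep(0, n)
    pheno <- data.frame(trait = signal, row.names = colnames(counts))
    covCoefs <- numeric()
    for (nm in names(config@covariateSpec)) {
      coef <- config@covariateSpec[[nm]]
      if (identical(nm, "batch")) {
        v <- factor(sample(c("A", "B"), n, replace = TRUE))
        pheno$trait <- pheno$trait + coef * (as.integer(v) - 1L)
      } else {
        v <- rnorm(n)
        pheno$trait <- pheno$trait + coef * v
      }
      pheno[[nm]] <- v
      covCoefs[nm] <- coef
    }
    pheno$trait <- pheno$trait + rnorm(n, sd = config@traitNoiseSd)
    truth <- new("SynthTruth", tagGenes = tags,
                 trueBeta = setNames(rep(config@effectSize, length(tags)),
                                     tags),
                 covariateCoefs = covCoefs, seed = config@seed)
    list(phenotype = pheno, truth = truth)
  })
}

#' Inject gross trait outliers
#'
#' Displaces the trait of a random `outlierFraction` of samples by
#' `outlierMagnitude` trait-SDs, with random sign — the gross-error
#' contamination that motivates the robust scan.
#'
#' @param phenotype data.frame with the trait column.
#' @param config a [SynthConfig-class] (fraction, magnitude, seed).
#' @param trait trait column name.
#' @return list with `phenotype` (corrupted copy) and `outliers` (displaced
#'   sample identifiers).
#' @export
injectOutliers <- function(phenotype, config, trait = "trait") {
  stopifnot(is(config, "SynthConfig"))
  if (!trait %in% colnames(phenotype))
    stopf("trait column '%s' not found", trait)
  n <- nrow(phenotype)
  nOut <- round(config@outlierFraction * n)
  if (nOut == 0L) return(list(phenotype = phenotype, outliers = character()))
  withSeed(config@seed + 2L, {
    idx <- sample(rownames(phenotype), nOut)
    shift <- config@outlierMagnitude * sd(phenotype[[trait]]) *
      sample(c(-1, 1), nOut, replace = TRUE)
    phenotype[idx, trait] <- phenotype[idx, trait] + shift
    list(phenotype = phenotype, outliers = idx)
  })
}

#' Dichotomize a continuous trait
#'
#' Adds a two-level group column: `"high"` where `trait >= cutoff`, else
#' `"low"` — the forced group conversion (e.g. over-weight vs normal at
#' BMI 25) that the association approach is compared against.
#'
#' @param phenotype data.frame with the trait column.
#' @param cutoff threshold, strictly inside the trait range.
#' @param trait trait column name.
#' @param group name of the new group column.
#' @return phenotype with the added factor column; both levels non-empty.
#' @examples
#' ph <- data.frame(trait = c(20, 24.9, 25, 30),
#'                  row.names = paste0("s", 1:4))
#' dichotomizeTrait(ph, 25)$group
#' @export
dichotomizeTrait <- function(phenotype, cutoff, trait = "trait",
                             group = "group") {
  if (!trait %in% colnames(phenotype))
    stopf("trait column '%s' not found", trait)
  tr <- phenotype[[trait]]
  g <- factor(ifelse(tr >= cutoff, "high", "low"), levels = c("low", "high"))
  if (any(table(g) == 0L))
    stopf("cutoff %g leaves an empty group (trait range [%g, %g])",
          cutoff, min(tr), max(tr))
  phenotype[[group]] <- g
  phenotype
}

#' Simulate a complete benchmark dataset
#'
#' Runs [simulateCounts()], [simulateTrait()] and (when
#' `outlierFraction > 0`) [injectOutliers()] from one seed.
#'
#' @param config a [SynthConfig-class].
#' @return list: `counts`, `phenotype`, `truth`, `outliers`.
#' @examples
#' sim <- simulateTagDataset(synthConfig(nGenes = 100, nSamples = 20,
#'                                       nTags = 3, seed = 42))
#' str(sim$counts)
#' trueTags(sim$truth)
#' @export
simulateTagDataset <- function(config) {
  counts <- simulateCounts(config)
  tr <- simulateTrait(counts, config)
  outliers <- character()
  pheno <- tr$phenotype
  if (config@outlierFraction > 0) {
    oi <- injectOutliers(pheno, config)
    pheno <- oi$phenotype
    outliers <- oi$outliers
  }
  list(counts = counts, phenotype = pheno, truth = tr$truth,
       outliers = outliers)
}
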