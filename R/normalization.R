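## TMM normalization: pairwise trimmed, precision-weighted mean of
## log2 expression ratios against a reference sample, then log2 CPM on
## TMM-adjusted effective library sizes.

#' Choose the TMM reference sample
#'
#' The reference is the sample whose 75th-percentile counts-per-million is
#' closest to the mean of that quantity across samples; ties go to the
#' lowest sample index, so the choice is deterministic.
#'
#' @param counts integer gene x sample matrix with dimnames.
#' @return a sample identifier.
#' @examples
#' m <- matrix(rpois(200, 50), 50, 4,
#'             dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
#' selectReference(m)
#' @export
selectReference <- function(counts) {
  assertCountMatrix(counts)
  libs <- colSums(counts)
  if (any(libs == 0))
    stopf("sample(s) with all-zero counts: %s",
          paste(colnames(counts)[libs == 0], collapse = ", "))
  uq <- vapply(seq_len(ncol(counts)), function(k)
    unname(quantile(counts[, k] / libs[k] * 1e6, 0.75)), numeric(1))
  colnames(counts)[which.min(abs(uq - mean(uq)))]
}

## One pairwise TMM factor: sample k against reference r (log2 scale).
## Returns NA when no informative gene survives (caller raises the error).
tmmPairLog2 <- function(yk, yr, Nk, Nr, trimM, trimA) {
  pos <- yk > 0 & yr > 0
  yk <- yk[pos]; yr <- yr[pos]
  if (!length(yk)) return(NA_real_)
  M <- log2((yk / Nk) / (yr / Nr))
  A <- 0.5 * log2((yk / Nk) * (yr / Nr))
  ## asymptotic variance of M (delta method); weights are its inverse
  v <- (Nk - yk) / (Nk * yk) + (Nr - yr) / (Nr * yr)
  w <- 1 / v
  n <- length(M)
  loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) return(NA_real_)
  ## zero-weight genes (library-size-saturating counts) cannot occur for
  ## real data, but guard the division anyway
  sw <- sum(w[keep])
  if (sw == 0) return(mean(M[keep]))
  sum(w[keep] * M[keep]) / sw
}

#' Trimmed mean of M-values scaling factors
#'
#' For each sample against the reference, genes expressed in both samples
#' contribute a log ratio M and log abundance A; the top and bottom
#' `trimM` fraction by M and `trimA` fraction by A are discarded and the
#' surviving M values are averaged with inverse-asymptotic-variance weights.
#' The factor is 2 to that average. Factors are finally rescaled to
#' geometric mean 1; the reference's pre-rescaling factor is 1.
#'
#' @inheritParams selectReference
#' @param trimM,trimA symmetric trim fractions for the log-ratio and
#'   log-abundance dimensions (canonical defaults 0.30 and 0.05).
#' @param reference optional reference sample identifier; defaults to
#'   [selectReference()].
#' @return a [NormFactors-class].
#' @examples
#' m <- matrix(rpois(300, 100), 100, 3,
#'             dimnames = list(paste0("g", 1:100), paste0("s", 1:3)))
#' tmmFactors(m)
#' @export
tmmFactors <- function(counts, trimM = 0.30, trimA = 0.05, reference = NULL) {
  assertCountMatrix(counts)
  if (trimM < 0 || trimM >= 0.5 || trimA < 0 || trimA >= 0.5)
    stopf("trim fractions must lie in [0, 0.5)")
  ref <- if (is.null(reference)) selectReference(counts) else reference
  if (!ref %in% colnames(counts)) stopf("unknown reference sample '%s'", ref)
  libs <- colSums(counts)
  if (any(libs == 0))
    stopf("sample(s) with all-zero counts: %s",
          paste(colnames(counts)[libs == 0], collapse = ", "))
  ids <- colnames(counts)
  lf <- vapply(ids, function(s) {
    if (s == ref) return(0)
    v <- tmmPairLog2(counts[, s], counts[, ref], libs[s], libs[ref],
                     trimM, trimA)
    if (is.na(v))
      stopf("no genes survive TMM trimming for sample '%s'", s)
    v
  }, numeric(1))
  f <- 2^lf
  f <- f / exp(mean(log(f)))
  new("NormFactors", sampleIds = ids, factors = unname(f),
      referenceSample = ref)
}

#' log2 counts-per-million on TMM effective library sizes
#'
#' `value_gk = log2((y_gk + prior) / (N_k * f_k + 2 * prior) * 1e6)` where
#' `N_k` is the raw library size and `f_k` the TMM factor. The positive
#' prior count keeps every cell finite at zero counts.
#'
#' @inheritParams selectReference
#' @param factors a [NormFactors-class] aligned to the counts' samples, or
#'   NULL for unit factors (plain log2 CPM).
#' @param priorCount positive prior count (default 0.5).
#' @param minCPM optional minimum average-CPM filter: genes whose mean raw
#'   CPM falls below it are dropped. Off (`0`) by default — scans run on
#'   the whole gene set.
#' @return numeric matrix of log2 CPM values, same dimnames as `counts`
#'   (minus any filtered genes).
#' @export
log2CPM <- function(counts, factors = NULL, priorCount = 0.5, minCPM = 0) {
  assertCountMatrix(counts)
  if (priorCount <= 0) stopf("priorCount must be > 0")
  libs <- colSums(counts)
  if (is.null(factors)) {
    f <- rep(1, ncol(counts))
  } else {
    stopifnot(is(factors, "NormFactors"))
    if (!setequal(factors@sampleIds, colnames(counts)))
      stopf("factor/count sample sets differ: %s",
            paste(union(setdiff(factors@sampleIds, colnames(counts)),
                        setdiff(colnames(counts), factors@sampleIds)),
                  collapse = ", "))
    f <- factors@factors[match(colnames(counts), factors@sampleIds)]
  }
  if (minCPM > 0) {
    keep <- rowMeans(sweep(counts, 2, libs, "/") * 1e6) >= minCPM
    counts <- counts[keep, , drop = FALSE]
  }
  eff <- libs * f
  out <- log2(sweep(counts + priorCount, 2, eff + 2 * priorCount, "/") * 1e6)
  dimnames(out) <- dimnames(counts)
  out
}

#' @describeIn TagExperiment-class TMM-normalize: computes [tmmFactors()]
#'   and the [log2CPM()] matrix, storing them in the object.
#' @param x a [TagExperiment-class].
#' @param trimM,trimA,priorCount see [tmmFactors()] and [log2CPM()].
#' @param ... unused.
#' @export
setMethod("normalizeTMM", "TagExperiment",
  function(x, trimM = 0.30, trimA = 0.05, priorCount = 0.5, ...) {
    cts <- assay(x, "counts")
    nf <- tmmFactors(cts, trimM = trimM, trimA = trimA)
    assay(x, "logcpm") <- log2CPM(cts, nf, priorCount = priorCount)
    metadata(x)$normFactors <- nf
    validObject(x)
    x
  })
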