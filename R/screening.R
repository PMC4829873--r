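## Genome-wide scan orchestration: per-gene fits, Benjamini-Hochberg
## adjustment, Shapiro-Wilk residual screening, cross-method comparison.

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR adjustment: with the p-values sorted ascending,
#' `q_(i) = min over j >= i of min(1, p_(j) * m / j)`, returned in the
#' original order. Missing values pass through untouched and are excluded
#' from `m`.
#'
#' @param pvalues numeric vector in \[0, 1\] (NAs allowed).
#' @return adjusted vector, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))
#' @export
bhAdjust <- function(pvalues) {
  bad <- which(!is.na(pvalues) & (pvalues < 0 | pvalues > 1))
  if (length(bad))
    stopf("p-value(s) outside [0, 1] at index: %s",
          paste(bad, collapse = ", "))
  p.adjust(pvalues, method = "BH")
}

#' Shapiro-Wilk residual-normality screen
#'
#' Fits the OLS trait-association model for every gene and tests its
#' residuals for normality — the check that the t-based inference's
#' normality assumption holds genome-wide. Genes with (near-)constant
#' residuals are flagged and excluded from the FDR adjustment.
#'
#' @param expression numeric log2-CPM matrix (genes x samples, dimnames
#'   required).
#' @param phenotype data.frame keyed by sample identifier.
#' @param covariates covariate columns to adjust for.
#' @param trait trait column name.
#' @param alpha adjusted-p threshold used for the summary count
#'   (default 0.05).
#' @return data.frame with columns gene_id, W, pvalue, fdr, flagged;
#'   attributes `nSignificant` (count with fdr < alpha) and `alpha`.
#'   Sample sizes outside Shapiro-Wilk's 3..5000 validity range are an
#'   error.
#' @export
shapiroScreen <- function(expression, phenotype, covariates = character(),
                          trait = "trait", alpha = 0.05) {
  al <- alignExpression(expression, phenotype)
  expression <- al$expression; phenotype <- al$phenotype
  bd <- buildDesign(phenotype, expression[1L, ], covariates, trait)
  keep <- !(rownames(phenotype) %in% bd$removed)
  y <- bd$response
  n <- length(y)
  if (n < 3L || n > 5000L)
    stopf("Shapiro-Wilk test requires 3 <= n <= 5000 (n = %d)", n)
  design <- bd$design
  G <- nrow(expression)
  W <- pv <- rep(NA_real_, G)
  flagged <- logical(G)
  for (g in seq_len(G)) {
    design[, 2L] <- expression[g, keep]
    ft <- lm.fit(design, y)
    r <- ft$residuals
    if (ft$rank < ncol(design) || diff(range(r)) < 1e-10 * (1 + max(abs(r)))) {
      flagged[g] <- TRUE
      next
    }
    sw <- shapiro.test(r)
    W[g] <- unname(sw$statistic)
    pv[g] <- sw$p.value
  }
  out <- data.frame(gene_id = rownames(expression), W = W, pvalue = pv,
                    fdr = bhAdjust(pv), flagged = flagged,
                    stringsAsFactors = FALSE)
  attr(out, "nSignificant") <- sum(out$fdr < alpha, na.rm = TRUE)
  attr(out, "alpha") <- alpha
  out
}

## Align an expression matrix (genes x samples) with a phenotype table.
alignExpression <- function(expression, phenotype) {
  if (!is.matrix(expression) || is.null(rownames(expression)) ||
      is.null(colnames(expression)))
    stopf("expression must be a matrix with gene and sample dimnames")
  diffs <- union(setdiff(colnames(expression), rownames(phenotype)),
                 setdiff(rownames(phenotype), colnames(expression)))
  if (length(diffs))
    stopf("expression/phenotype sample sets differ: %s",
          paste(diffs, collapse = ", "))
  phenotype <- phenotype[colnames(expression), , drop = FALSE]
  list(expression = expression, phenotype = phenotype)
}

## Core scan on a plain expression matrix; the engine runs in C++.
tagScanMatrix <- function(expression, phenotype, trait = "trait",
                          method = c("ols", "huber"),
                          covariates = character(), alpha = 0.05,
                          adjust = c("fdr", "none"), k = 1.345,
                          tol = 1e-8, maxIter = 100L, verbose = FALSE) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  al <- alignExpression(expression, phenotype)
  expression <- al$expression; phenotype <- al$phenotype
  bd <- buildDesign(phenotype, expression[1L, ], covariates, trait)
  keep <- !(rownames(phenotype) %in% bd$removed)
  y <- bd$response
  Z <- bd$design[, -c(1L, 2L), drop = FALSE]
  ex <- expression[, keep, drop = FALSE]
  G <- nrow(ex)

  chunks <- if (verbose) split(seq_len(G), ceiling(seq_len(G) / 1000L))
            else list(seq_len(G))
  res <- do.call(rbind, lapply(seq_along(chunks), function(ci) {
    idx <- chunks[[ci]]
    r <- .scanEngine(ex[idx, , drop = FALSE], y, Z,
                     robust = (method == "huber"), k = k, tol = tol,
                     maxIter = as.integer(maxIter))
    if (verbose)
      message(sprintf("scanned %d / %d genes", max(idx), G))
    r
  }))

  tab <- data.frame(
    gene_id = rownames(ex),
    order = seq_len(G),
    beta1 = res[, "beta1"],
    se_beta1 = res[, "se_beta1"],
    statistic = res[, "statistic"],
    df = rep(length(y) - ncol(bd$design), G),
    pvalue = res[, "pvalue"],
    stringsAsFactors = FALSE)
  tab$fdr <- bhAdjust(tab$pvalue)
  tab$significant <- if (adjust == "fdr") tab$fdr < alpha
                     else tab$pvalue < alpha
  tab$significant[is.na(tab$significant)] <- FALSE
  tab$flagged <- res[, "flagged"] == 1 | is.na(res[, "pvalue"])
  nFlagged <- sum(tab$flagged)
  if (verbose && nFlagged)
    message(sprintf("%d gene(s) flagged (degenerate or failed fits)",
                    nFlagged))
  tab <- tab[order(tab$pvalue, tab$order, na.last = TRUE), , drop = FALSE]
  rownames(tab) <- NULL
  new("TagScanResult", table = tab, method = method,
      covariates = as.character(covariates), alpha = alpha, adjust = adjust,
      k = if (method == "huber") k else NA_real_,
      nSamples = length(y))
}

#' Genome-wide trait-association scan
#'
#' Fits the per-gene model `trait ~ expression (+ covariates)` for every
#' gene, by OLS or Huber robust regression, and assembles a
#' [TagScanResult-class]: slope, standard error, Wald t statistic, raw and
#' Benjamini-Hochberg-adjusted p-values, and a significance call at `alpha`
#' under the chosen `adjust` rule (`"fdr"`: adjusted < alpha, the stricter
#' rule used for well-powered cohorts; `"none"`: raw p < alpha, the softer
#' rule for small cohorts). Per-gene failures are flagged, never fatal.
#'
#' @param x a [TagExperiment-class] (normalized automatically if needed) or
#'   a log2-CPM expression matrix (genes x samples).
#' @param phenotype (matrix method) data.frame keyed by sample identifier.
#' @param trait trait column name.
#' @param method `"ols"` or `"huber"`.
#' @param covariates covariate columns; for the TagExperiment method,
#'   defaults to the object's `covariateNames`.
#' @param alpha significance threshold.
#' @param adjust `"fdr"` (default) or `"none"`.
#' @param k,tol,maxIter Huber IRWLS controls (see [fitHuberIRWLS()]).
#' @param verbose log progress every 1,000 genes.
#' @param ... passed through.
#' @return a [TagScanResult-class], rows ordered by ascending p-value.
#' @examples
#' sim <- simulateTagDataset(synthConfig(nGenes = 100, nSamples = 30,
#'                                       nTags = 5, seed = 7))
#' te <- normalizeTMM(TagExperiment(sim$counts, sim$phenotype))
#' tagScan(te, method = "ols", alpha = 0.1)
#' @rdname tagScan
#' @export
setMethod("tagScan", "TagExperiment",
  function(x, method = c("ols", "huber"), covariates = covariateNames(x),
           alpha = 0.05, adjust = c("fdr", "none"), k = 1.345, tol = 1e-8,
           maxIter = 100L, verbose = FALSE, ...) {
    if (!"logcpm" %in% assayNames(x)) x <- normalizeTMM(x)
    tagScanMatrix(assay(x, "logcpm"), phenotypeTable(x), trait = traitName(x),
                  method = match.arg(method), covariates = covariates,
                  alpha = alpha, adjust = match.arg(adjust), k = k,
                  tol = tol, maxIter = maxIter, verbose = verbose)
  })

#' @rdname tagScan
#' @export
setMethod("tagScan", "matrix",
  function(x, phenotype, trait = "trait", method = c("ols", "huber"),
           covariates = character(), alpha = 0.05,
           adjust = c("fdr", "none"), k = 1.345, tol = 1e-8,
           maxIter = 100L, verbose = FALSE, ...) {
    tagScanMatrix(x, phenotype, trait = trait, method = match.arg(method),
                  covariates = covariates, alpha = alpha,
                  adjust = match.arg(adjust), k = k, tol = tol,
                  maxIter = maxIter, verbose = verbose)
  })

#' Compare significant-gene sets across scans
#'
#' Tabulates every intersection pattern of the significant sets of two or
#' more scans over an identical gene universe, and labels each gene by the
#' methods calling it. Results may be [TagScanResult-class] objects or named
#' p-value vectors (the plug-in contract for externally computed methods);
#' significance for comparison is raw `p < alpha` throughout, the common
#' yardstick across heterogeneous methods.
#'
#' When `roles` maps each method to `"existing"`, `"suggesting"` or
#' `"robust"`, genes are additionally classified: `AM` (significant in all
#' methods), `EM` (only in existing methods), `SM` (only in
#' suggesting/robust), `RM` (only in robust), `mixed` otherwise, `none` if
#' nowhere significant.
#'
#' @param results named list of [TagScanResult-class] objects and/or named
#'   numeric p-value vectors.
#' @param alpha raw-p cutoff (default 0.05).
#' @param roles optional named character vector (one per method).
#' @return list with `counts` (data.frame: pattern, n), `labels` (per-gene
#'   comma-joined calling methods), `categories` (per-gene AM/EM/SM/RM, if
#'   roles given), `significant` (per-method logical matrix).
#' @export
compareScans <- function(results, alpha = 0.05, roles = NULL) {
  if (length(results) < 2L) stopf("need at least two result sets")
  if (is.null(names(results)) || any(names(results) == ""))
    names(results) <- paste0("method", seq_along(results))
  pv <- lapply(results, function(r) {
    if (is(r, "TagScanResult")) {
      tab <- scanTable(r, original_order = TRUE)
      setNames(tab$pvalue, tab$gene_id)
    } else if (is.numeric(r) && !is.null(names(r))) r
    else stopf("each result must be a TagScanResult or a named p-value vector")
  })
  universe <- names(pv[[1L]])
  for (i in seq_along(pv)[-1L]) {
    d <- union(setdiff(universe, names(pv[[i]])),
               setdiff(names(pv[[i]]), universe))
    if (length(d))
      stopf("gene universes differ (%s vs %s): %s", names(pv)[1L],
            names(pv)[i], paste(head(d, 10L), collapse = ", "))
  }
  sig <- vapply(pv, function(p) p[universe] < alpha & !is.na(p[universe]),
                logical(length(universe)))
  rownames(sig) <- universe
  pattern <- apply(sig, 1L, function(z) paste(as.integer(z), collapse = ""))
  counts <- as.data.frame(table(pattern = pattern), stringsAsFactors = FALSE)
  names(counts) <- c("pattern", "n")
  labels <- apply(sig, 1L, function(z)
    if (any(z)) paste(colnames(sig)[z], collapse = ",") else "none")
  out <- list(counts = counts, labels = labels, significant = sig,
              methods = colnames(sig), alpha = alpha)
  if (!is.null(roles)) {
    if (!all(colnames(sig) %in% names(roles)))
      stopf("roles must name every method")
    roles <- roles[colnames(sig)]
    out$categories <- apply(sig, 1L, function(z) {
      if (!any(z)) return("none")
      if (all(z)) return("AM")
      r <- unique(roles[z])
      if (all(r == "existing")) "EM"
      else if (all(r == "robust")) "RM"
      else if (all(r %in% c("suggesting", "robust"))) "SM"
      else "mixed"
    })
  }
  out
}
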