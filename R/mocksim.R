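## Mock-comparison simulation: permute the trait to build a null "mock"
## dataset, call significant genes in both, and estimate the proportion of
## false discoveries (PFD) as a function of biological-replicate count.

#' Permute the trait (and group) across samples
#'
#' Applies one uniform random permutation jointly to the trait and, if
#' present, the derived group column; covariates stay attached to their
#' original samples. Deterministic given the seed, and the caller's RNG
#' state is untouched.
#'
#' @param phenotype data.frame keyed by sample identifier.
#' @param seed integer seed.
#' @param trait trait column name.
#' @param group group column name (permuted together with the trait when
#'   present).
#' @return the permuted phenotype table.
#' @export
permuteTrait <- function(phenotype, seed, trait = "trait", group = "group") {
  if (!trait %in% colnames(phenotype))
    stopf("trait column '%s' not found", trait)
  n <- nrow(phenotype)
  if (n < 1L) stopf("empty phenotype table")
  perm <- withSeed(seed, sample.int(n))
  phenotype[[trait]] <- phenotype[[trait]][perm]
  if (group %in% colnames(phenotype))
    phenotype[[group]] <- phenotype[[group]][perm]
  phenotype
}

#' Proportion of false discoveries
#'
#' `|real intersect mock| / |real|` — the fraction of real-data significant
#' genes that are also called significant after the trait is permuted. NA
#' (with a warning) when the real set is empty.
#'
#' @param realSignificant,mockSignificant character vectors of gene ids.
#' @return scalar in \[0, 1\], or NA.
#' @examples
#' pfd(c("A", "B", "C", "D"), c("A", "C"))  # 0.5
#' @export
pfd <- function(realSignificant, mockSignificant) {
  if (length(realSignificant) == 0L) {
    warnf("empty real significant set: PFD undefined")
    return(NA_real_)
  }
  length(intersect(realSignificant, mockSignificant)) /
    length(unique(realSignificant))
}

#' Subsample biological replicates per group
#'
#' Draws `nPerGroup` samples uniformly without replacement from each of the
#' two groups, subsetting counts and phenotype consistently.
#'
#' @param counts gene x sample count matrix.
#' @param phenotype data.frame keyed by sample identifier, with a two-level
#'   group column.
#' @param nPerGroup samples to draw from each group.
#' @param seed integer seed.
#' @param group group column name.
#' @return list with `counts` and `phenotype` restricted to the draw.
#' @export
subsampleReplicates <- function(counts, phenotype, nPerGroup, seed,
                                group = "group") {
  if (!group %in% colnames(phenotype))
    stopf("group column '%s' not found; dichotomize the trait first", group)
  g <- as.factor(phenotype[[group]])
  if (nlevels(g) != 2L)
    stopf("group column must have exactly 2 levels (has %d)", nlevels(g))
  sizes <- table(g)
  if (any(sizes < nPerGroup))
    stopf("group(s) too small for %d per group (available: %s)", nPerGroup,
          paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "))
  ids <- withSeed(seed, {
    unlist(lapply(levels(g), function(lv)
      sample(rownames(phenotype)[g == lv], nPerGroup)), use.names = FALSE)
  })
  list(counts = counts[, ids, drop = FALSE],
       phenotype = phenotype[ids, , drop = FALSE])
}

## Unstratified draw for continuous traits with no group column: a grid
## value of n per group maps to a draw of 2n samples.
subsampleContinuous <- function(counts, phenotype, nTotal, seed) {
  if (nrow(phenotype) < nTotal)
    stopf("cannot draw %d of %d samples", nTotal, nrow(phenotype))
  ids <- withSeed(seed, sample(rownames(phenotype), nTotal))
  list(counts = counts[, ids, drop = FALSE],
       phenotype = phenotype[ids, , drop = FALSE])
}

## Built-in method plug-ins: full pipeline (TMM -> log2 CPM -> scan) on the
## subsampled counts, returning one raw p-value per gene.
builtinMethod <- function(method, trait, covariates, k) {
  force(method); force(trait); force(covariates); force(k)
  function(counts, phenotype) {
    ex <- log2CPM(counts, tmmFactors(counts))
    res <- tagScanMatrix(ex, phenotype, trait = trait, method = method,
                         covariates = covariates, alpha = 0.05,
                         adjust = "none", k = k)
    tab <- scanTable(res, original_order = TRUE)
    setNames(tab$pvalue, tab$gene_id)
  }
}

#' Mock-comparison sweep over replicate counts
#'
#' For each replicate count in `replicateGrid` and each repeat: subsample
#' that many samples per group (or twice that many, unstratified, for a
#' continuous trait with no group column), run the method on the real
#' phenotype and on a trait-permuted copy, call significance at raw
#' `p < alpha`, and record the per-repeat PFD (see [pfd()]). Summaries (mean
#' PFD, its standard error, mean number of real significant genes) are
#' collected per grid value. The whole sweep is reproducible from
#' `baseSeed`: every repeat's subsample and permutation seeds are derived
#' deterministically from it, so grid points are independent experiments.
#'
#' @param counts gene x sample count matrix.
#' @param phenotype data.frame keyed by sample identifier.
#' @param method `"ols"`, `"huber"`, or a plug-in `function(counts,
#'   phenotype)` returning one named p-value per gene (how externally
#'   computed DE methods enter the comparison).
#' @param replicateGrid integer vector of per-group replicate counts.
#' @param trait,covariates scan settings for the built-in methods.
#' @param alpha raw-p significance level inside the comparison (default
#'   0.05; the conventional choice for this simulation).
#' @param nRepeats repeats per grid value (default 1000).
#' @param baseSeed integer master seed.
#' @param group group column name; if absent the continuous-trait draw is
#'   used.
#' @param k Huber tuning constant for `method = "huber"`.
#' @param useFdr call significance at FDR < alpha instead of raw p (off by
#'   default).
#' @param methodLabel label stored in the results (defaults to the method
#'   name or "plugin").
#' @param verbose log each grid value.
#' @return named list of [MockResult-class], one per grid value.
#' @examples
#' sim <- simulateTagDataset(synthConfig(nGenes = 80, nSamples = 24,
#'                                       nTags = 0, seed = 3))
#' mockComparison(sim$counts, sim$phenotype, method = "ols",
#'                replicateGrid = c(5, 8), nRepeats = 5, baseSeed = 11)
#' @export
mockComparison <- function(counts, phenotype, method = "ols",
                           replicateGrid, trait = "trait",
                           covariates = character(), alpha = 0.05,
                           nRepeats = 1000L, baseSeed = 1L,
                           group = "group", k = 1.345, useFdr = FALSE,
                           methodLabel = NULL, verbose = FALSE) {
  assertCountMatrix(counts)
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  if (any(replicateGrid < 2L)) stopf("replicate counts must be >= 2")
  al <- alignSamples(counts, phenotype)
  counts <- al$counts; phenotype <- al$phenotype
  grouped <- group %in% colnames(phenotype)
  if (is.function(method)) {
    fn <- method
    label <- if (is.null(methodLabel)) "plugin" else methodLabel
  } else {
    method <- match.arg(method, c("ols", "huber"))
    fn <- builtinMethod(method, trait, covariates, k)
    label <- if (is.null(methodLabel)) method else methodLabel
  }

  out <- lapply(seq_along(replicateGrid), function(gi) {
    nPer <- as.integer(replicateGrid[gi])
    if (verbose)
      message(sprintf("mock comparison: %d per group, %d repeats",
                      nPer, nRepeats))
    rows <- vector("list", nRepeats)
    nFail <- 0L
    for (r in seq_len(nRepeats)) {
      seedSub <- deriveSeed(baseSeed, gi, 2L * r)
      seedPerm <- deriveSeed(baseSeed, gi, 2L * r + 1L)
      row <- tryCatch({
        sub <- if (grouped)
          subsampleReplicates(counts, phenotype, nPer, seedSub, group)
        else
          subsampleContinuous(counts, phenotype, 2L * nPer, seedSub)
        pReal <- fn(sub$counts, sub$phenotype)
        permPheno <- permuteTrait(sub$phenotype, seedPerm, trait = trait,
                                  group = group)
        pMock <- fn(sub$counts, permPheno)
        callSig <- function(p) {
          pp <- if (useFdr) bhAdjust(p) else p
          names(p)[!is.na(pp) & pp < alpha]
        }
        sigReal <- callSig(pReal)
        sigMock <- callSig(pMock)
        prop <- if (length(sigReal))
          length(intersect(sigReal, sigMock)) / length(sigReal)
        else NA_real_
        data.frame(repeat_index = r, seed = seedSub,
                   n_sig_real = length(sigReal),
                   n_sig_mock = length(sigMock),
                   n_common = length(intersect(sigReal, sigMock)),
                   pfd = prop)
      }, error = function(e) {
        if (verbose) message(sprintf("repeat %d failed: %s", r,
                                     conditionMessage(e)))
        NULL
      })
      if (is.null(row)) nFail <- nFail + 1L else rows[[r]] <- row
    }
    if (nFail > 0.1 * nRepeats)
      stopf("mock comparison aborted at %d per group: %d of %d repeats failed",
            nPer, nFail, nRepeats)
    rep_tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    okPfd <- rep_tab$pfd[!is.na(rep_tab$pfd)]
    new("MockResult", method = label, alpha = alpha,
        replicateCount = nPer, nRepeats = as.integer(nRepeats),
        repeats = rep_tab,
        meanPfd = if (length(okPfd)) mean(okPfd) else NA_real_,
        sePfd = if (length(okPfd) > 1L) sd(okPfd) / sqrt(length(okPfd))
                else NA_real_,
        meanNSigReal = mean(rep_tab$n_sig_real))
  })
  names(out) <- paste0("n", replicateGrid)
  out
}

#' Summarize a mock-comparison sweep as a table
#'
#' @param results list of [MockResult-class] from [mockComparison()].
#' @return data.frame: replicate_count, method, mean_pfd, se_pfd,
#'   mean_n_sig.
#' @export
mockSummary <- function(results) {
  if (is(results, "MockResult")) results <- list(results)
  do.call(rbind, lapply(results, function(m) {
    stopifnot(is(m, "MockResult"))
    data.frame(replicate_count = m@replicateCount, method = m@method,
               mean_pfd = m@meanPfd, se_pfd = m@sePfd,
               mean_n_sig = m@meanNSigReal, stringsAsFactors = FALSE)
  }))
}
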