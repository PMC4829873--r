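## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so package simulations never perturb user code.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic per-repeat seed derivation; stays inside 32-bit range.
deriveSeed <- function(baseSeed, gridIndex, repeatIndex = 0L) {
  s <- (as.double(baseSeed) + 7919 * as.double(gridIndex) +
          104729 * as.double(repeatIndex)) %% 2147483647
  as.integer(s) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assertCountMatrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stopf("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must carry gene (row) and sample (column) identifiers")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate gene identifiers: %s",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate sample identifiers: %s",
          paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                collapse = ", "))
  if (nrow(counts) < 1L || ncol(counts) < 2L)
    stopf("counts must have at least 1 gene and 2 samples")
  if (any(!is.finite(counts)) || any(counts < 0))
    stopf("counts must be finite and nonnegative")
  if (any(counts != round(counts)))
    stopf("counts must be integers")
  invisible(counts)
}

## Phenotype tables are data.frames keyed by rownames = sample ids.
assertPhenotype <- function(phenotype, trait = "trait") {
  if (!is.data.frame(phenotype))
    stopf("phenotype must be a data.frame with sample identifiers as rownames")
  if (is.null(rownames(phenotype)) ||
      identical(rownames(phenotype), as.character(seq_len(nrow(phenotype)))))
    stopf("phenotype must carry sample identifiers as rownames")
  if (!trait %in% colnames(phenotype))
    stopf("trait column '%s' not found in phenotype", trait)
  tr <- phenotype[[trait]]
  if (!is.numeric(tr)) stopf("trait column '%s' must be numeric", trait)
  if (length(unique(tr[is.finite(tr)])) < 2L)
    stopf("trait must have at least 2 distinct finite values")
  invisible(phenotype)
}

## Align a phenotype table to count-matrix samples by identifier.
alignSamples <- function(counts, phenotype, allowSubset = FALSE) {
  cs <- colnames(counts)
  ps <- rownames(phenotype)
  missing <- setdiff(ps, cs)
  if (length(missing) && !allowSubset)
    stopf("phenotype samples absent from counts: %s",
          paste(missing, collapse = ", "))
  common <- intersect(cs, ps)
  if (length(common) < 2L)
    stopf("fewer than 2 samples shared between counts and phenotype (missing: %s)",
          paste(union(setdiff(cs, ps), missing), collapse = ", "))
  list(counts = counts[, common, drop = FALSE],
       phenotype = phenotype[common, , drop = FALSE])
}

## Fixed-format float used by all writers so outputs are byte-reproducible.
fmtNum <- function(x, digits = 6L) {
  out <- ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
  out
}
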