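## Plain-text readers and writers. All writers emit a "#"-prefixed comment
## header carrying the package version and the run's parameters, use
## 6-significant-digit floats, and are deterministic: same inputs, same
## bytes. All readers skip "#" comment lines.

tagseqHeader <- function(params = character()) {
  paste0("# tagseq ", as.character(packageVersion("tagseq")),
         if (length(params)) paste0(" | ", paste(params, collapse = " ")) else "")
}

#' Read a count matrix from tab-separated text
#'
#' Expected dialect: optional "#" comment lines, a header row whose first
#' field labels the gene-id column and whose remaining fields are sample
#' identifiers, then one row per gene with integer cells. Ragged rows,
#' non-integer or negative cells and duplicate identifiers are errors that
#' cite the offending line.
#'
#' @param path file path.
#' @return integer gene x sample matrix.
#' @export
readCounts <- function(path) {
  lines <- readLines(path)
  lineNo <- seq_along(lines)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]; lineNo <- lineNo[keep]
  if (length(lines) < 2L) stopf("'%s': need a header and at least one gene", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(fields[[1L]])
  if (width < 3L) stopf("'%s': need at least 2 sample columns", path)
  samples <- fields[[1L]][-1L]
  bad <- which(lengths(fields) != width)
  if (length(bad))
    stopf("'%s': ragged row at line %d (%d fields, expected %d)",
          path, lineNo[bad[1L]], lengths(fields)[bad[1L]], width)
  genes <- vapply(fields[-1L], `[[`, character(1), 1L)
  cells <- t(vapply(fields[-1L], function(f) f[-1L], character(width - 1L)))
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  if (anyNA(num)) {
    ij <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stopf("'%s': non-numeric cell '%s' at line %d, column '%s'",
          path, cells[ij[1L], ij[2L]], lineNo[-1L][ij[1L]], samples[ij[2L]])
  }
  frac <- which(num != round(num), arr.ind = TRUE)
  if (nrow(frac)) {
    ij <- frac[1L, ]
    stopf("'%s': non-integer count '%s' at line %d, column '%s'",
          path, cells[ij[1L], ij[2L]], lineNo[-1L][ij[1L]], samples[ij[2L]])
  }
  if (any(num < 0)) {
    ij <- which(num < 0, arr.ind = TRUE)[1L, ]
    stopf("'%s': negative count at line %d, column '%s'",
          path, lineNo[-1L][ij[1L]], samples[ij[2L]])
  }
  if (anyDuplicated(genes))
    stopf("'%s': duplicated gene identifier '%s'",
          path, genes[duplicated(genes)][1L])
  if (anyDuplicated(samples))
    stopf("'%s': duplicated sample identifier '%s'",
          path, samples[duplicated(samples)][1L])
  dimnames(num) <- list(genes, samples)
  assertCountMatrix(num)
  num
}

#' Write a count matrix as tab-separated text
#'
#' @param counts gene x sample integer matrix.
#' @param path output path.
#' @param params optional character vector of `key=value` strings recorded
#'   in the comment header.
#' @return the path, invisibly.
#' @export
writeCounts <- function(counts, path, params = character()) {
  assertCountMatrix(counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tagseqHeader(params), con)
  writeLines(paste(c("gene_id", colnames(counts)), collapse = "\t"), con)
  body <- paste(rownames(counts),
                apply(format(counts, scientific = FALSE, trim = TRUE), 1L,
                      paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a phenotype table
#'
#' Comma- or tab-separated (auto-detected from the header), first column
#' sample identifier, "NA" recognized as missing. The trait column must be
#' present and numeric with at least one observed value; covariate columns
#' that are entirely missing are dropped with a warning.
#'
#' @param path file path.
#' @param trait trait column name (default "trait").
#' @return data.frame keyed by sample identifier (rownames).
#' @export
readPhenotype <- function(path, trait = "trait") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) < 2L) stopf("'%s': need a header and at least one sample", path)
  sep <- if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
  df <- read.delim(text = paste(lines, collapse = "\n"), sep = sep,
                   header = TRUE, check.names = FALSE, na.strings = "NA",
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stopf("'%s': duplicated sample identifier '%s'",
          path, ids[duplicated(ids)][1L])
  df <- df[, -1L, drop = FALSE]
  rownames(df) <- ids
  if (!trait %in% colnames(df))
    stopf("'%s': trait column '%s' not found (columns: %s)",
          path, trait, paste(colnames(df), collapse = ", "))
  if (!is.numeric(df[[trait]]))
    stopf("'%s': trait column '%s' is not numeric", path, trait)
  if (all(is.na(df[[trait]])))
    stopf("'%s': trait column '%s' is entirely missing", path, trait)
  allNA <- vapply(df, function(v) all(is.na(v)), logical(1))
  if (any(allNA)) {
    warnf("dropping entirely-missing column(s): %s",
          paste(colnames(df)[allNA], collapse = ", "))
    df <- df[, !allNA, drop = FALSE]
  }
  df
}

#' Write a phenotype table
#'
#' @param phenotype data.frame keyed by sample identifier.
#' @param path output path.
#' @param sep `","` (default) or `"\t"`.
#' @param params header `key=value` strings.
#' @return the path, invisibly.
#' @export
writePhenotype <- function(phenotype, path, sep = ",", params = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tagseqHeader(params), con)
  cols <- vapply(phenotype, function(v) {
    if (is.numeric(v)) fmtNum(v) else as.character(v)
  }, character(nrow(phenotype)))
  if (nrow(phenotype) == 1L) cols <- matrix(cols, nrow = 1L)
  writeLines(paste(c("sample_id", colnames(phenotype)), collapse = sep), con)
  writeLines(apply(cbind(rownames(phenotype), cols), 1L, paste,
                   collapse = sep), con)
  invisible(path)
}

#' Write TMM factors as two-column tab-separated text
#'
#' @param factors a [NormFactors-class].
#' @param path output path.
#' @param params header `key=value` strings.
#' @return the path, invisibly.
#' @export
writeNormFactors <- function(factors, path, params = character()) {
  stopifnot(is(factors, "NormFactors"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tagseqHeader(c(params,
    paste0("reference=", factors@referenceSample))), con)
  writeLines("sample_id\tfactor", con)
  writeLines(paste(factors@sampleIds, fmtNum(factors@factors, 10L),
                   sep = "\t"), con)
  invisible(path)
}

#' Write an expression (log2 CPM) matrix
#'
#' @param expression numeric matrix with dimnames.
#' @param path output path.
#' @param params header `key=value` strings.
#' @return the path, invisibly.
#' @export
writeExpression <- function(expression, path, params = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tagseqHeader(params), con)
  writeLines(paste(c("gene_id", colnames(expression)), collapse = "\t"), con)
  body <- paste(rownames(expression),
                apply(expression, 1L, function(r)
                  paste(fmtNum(r), collapse = "\t")), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Write a scan result table
#'
#' Tab-separated, fixed column order, 6-significant-digit floats, with the
#' scan's parameters in the comment header.
#'
#' @param result a [TagScanResult-class].
#' @param path output path.
#' @param params extra header `key=value` strings.
#' @return the path, invisibly.
#' @export
writeScanResult <- function(result, path, params = character()) {
  stopifnot(is(result, "TagScanResult"))
  tab <- result@table
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tagseqHeader(c(params,
    paste0("method=", result@method),
    paste0("covariates=", paste(result@covariates, collapse = "+")),
    paste0("alpha=", result@alpha),
    paste0("adjust=", result@adjust),
    if (!is.na(result@k)) paste0("k=", result@k),
    paste0("n=", result@nSamples))), con)
  writeLines(paste(c("gene_id", "order", "beta1", "se_beta1", "statistic",
                     "df", "pvalue", "fdr", "significant", "flagged"),
                   collapse = "\t"), con)
  writeLines(paste(tab$gene_id, tab$order, fmtNum(tab$beta1),
                   fmtNum(tab$se_beta1), fmtNum(tab$statistic), tab$df,
                   fmtNum(tab$pvalue), fmtNum(tab$fdr),
                   ifelse(tab$significant, "TRUE", "FALSE"),
                   ifelse(tab$flagged, "TRUE", "FALSE"), sep = "\t"), con)
  invisible(path)
}

#' Read a scan result table back as named p-values
#'
#' Reads the `gene_id` and `pvalue` columns of a [writeScanResult()] file
#' (or any tab-separated file with those two columns) — the plug-in
#' contract for [compareScans()] and [mockComparison()].
#'
#' @param path file path.
#' @return named numeric p-value vector.
#' @export
readPvalues <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  df <- read.delim(text = paste(lines, collapse = "\n"), sep = "\t",
                   header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!all(c("gene_id", "pvalue") %in% colnames(df)))
    stopf("'%s': need columns gene_id and pvalue", path)
  setNames(as.numeric(df$pvalue), as.character(df$gene_id))
}

#' Write a mock-comparison sweep summary
#'
#' One row per grid point: replicate_count, method, mean_pfd, se_pfd,
#' mean_n_sig — ready for replicate-count-vs-PFD curves.
#'
#' @param results list of [MockResult-class].
#' @param path output path.
#' @param params header `key=value` strings.
#' @return the path, invisibly.
#' @export
writeMockResults <- function(results, path, params = character()) {
  tab <- mockSummary(results)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tagseqHeader(params), con)
  writeLines("replicate_count\tmethod\tmean_pfd\tse_pfd\tmean_n_sig", con)
  writeLines(sprintf("%d\t%s\t%s\t%s\t%s", tab$replicate_count, tab$method,
                     fmtNum(tab$mean_pfd), fmtNum(tab$se_pfd),
                     fmtNum(tab$mean_n_sig)), con)
  invisible(path)
}

#' Write a synthetic-truth table
#'
#' @param truth a [SynthTruth-class].
#' @param geneIds full gene universe (truth rows cover every gene).
#' @param path output path.
#' @param params header `key=value` strings.
#' @return the path, invisibly.
#' @export
writeTruth <- function(truth, geneIds, path, params = character()) {
  stopifnot(is(truth, "SynthTruth"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tagseqHeader(c(params, paste0("seed=", truth@seed))), con)
  writeLines("gene_id\tis_tag\ttrue_beta1", con)
  isTag <- geneIds %in% truth@tagGenes
  beta <- ifelse(isTag, truth@trueBeta[match(geneIds, truth@tagGenes)], 0)
  writeLines(paste(geneIds, ifelse(isTag, "TRUE", "FALSE"), fmtNum(beta),
                   sep = "\t"), con)
  invisible(path)
}
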