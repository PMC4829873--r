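## Per-gene association models: trait (response) ~ expression + covariates,
## by OLS and by Huber M-estimation (IRWLS, MAD scale, Wald-type inference).

#' Build the per-gene regression design
#'
#' Assembles the response (trait) and design matrix for one gene: intercept
#' first, expression second, then dummy-coded covariates (first factor level
#' is the reference and is dropped). Samples with a missing value in any
#' used column are removed; the removed identifiers are returned.
#'
#' @param phenotype data.frame keyed by sample identifier (rownames), with
#'   the trait and covariate columns.
#' @param expression numeric vector of one gene's expression, aligned to
#'   (and named by) the phenotype samples.
#' @param covariates character vector of covariate column names (possibly
#'   empty).
#' @param trait name of the trait column.
#' @return list with `response`, `design` (n x p matrix), and `removed`
#'   (identifiers dropped by listwise deletion).
#' @export
buildDesign <- function(phenotype, expression, covariates = character(),
                        trait = "trait") {
  assertPhenotype(phenotype, trait)
  n <- nrow(phenotype)
  if (length(expression) != n)
    stopf("expression length (%d) does not match phenotype samples (%d)",
          length(expression), n)
  if (!is.null(names(expression)) &&
      !identical(names(expression), rownames(phenotype)))
    stopf("expression names do not match phenotype sample order")
  bad <- setdiff(covariates, colnames(phenotype))
  if (length(bad))
    stopf("unknown covariate column(s): %s", paste(bad, collapse = ", "))

  used <- data.frame(.trait = phenotype[[trait]],
                     .expr = as.numeric(expression))
  for (cv in covariates) used[[cv]] <- phenotype[[cv]]
  keep <- complete.cases(used)
  removed <- rownames(phenotype)[!keep]
  used <- used[keep, , drop = FALSE]

  design <- cbind("(Intercept)" = 1, expression = used$.expr)
  for (cv in covariates) {
    v <- used[[cv]]
    if (is.numeric(v)) {
      cols <- matrix(v, ncol = 1, dimnames = list(NULL, cv))
    } else {
      f <- factor(v)
      if (nlevels(f) < 2L)
        stopf("covariate '%s' is constant after missing-value removal", cv)
      mm <- model.matrix(~f)
      cols <- mm[, -1L, drop = FALSE]
      colnames(cols) <- paste0(cv, levels(f)[-1L])
    }
    design <- cbind(design, cols)
  }
  p <- ncol(design)
  if (nrow(design) <= p)
    stopf("too few samples: n = %d with %d coefficients", nrow(design), p)
  qrd <- qr(design)
  if (qrd$rank < p) {
    dep <- colnames(design)[qrd$pivot[(qrd$rank + 1L):p]]
    stopf("design is rank deficient; collinear column(s): %s",
          paste(dep, collapse = ", "))
  }
  list(response = used$.trait, design = design, removed = removed)
}

## Shared inference tail: given beta, residuals, weights and the design's
## inverse Gram, fill a GeneFit. Degenerate zero-variance fits get NA or 0
## p-values depending on whether the slope itself is zero.
makeOLSFit <- function(geneId, beta, response, design, residuals) {
  n <- nrow(design); p <- ncol(design)
  gramInv <- chol2inv(chol(crossprod(design)))
  dimnames(gramInv) <- list(colnames(design), colnames(design))
  rss <- sum(residuals^2)
  sigma2 <- rss / (n - p)
  scaleRef <- max(1, mean(response^2))
  degenerate <- sigma2 <= 1e-20 * scaleRef
  se1 <- sqrt(sigma2 * gramInv[2L, 2L])
  if (degenerate) {
    if (abs(beta[2L]) > 1e-8 * sqrt(scaleRef)) {
      stat <- unname(sign(beta[2L])) * Inf; pv <- 0
    } else {
      stat <- NA_real_; pv <- NA_real_
    }
  } else {
    stat <- unname(beta[2L]) / se1
    pv <- 2 * pt(-abs(stat), df = n - p)
  }
  new("GeneFit", geneId = geneId, method = "ols",
      coefficients = setNames(as.numeric(beta), colnames(design)),
      seBeta1 = se1, statistic = stat, df = as.numeric(n - p), pvalue = pv,
      residuals = as.numeric(residuals), weights = rep(1, n),
      scale = sqrt(sigma2), k = NA_real_, nIter = 1L, converged = TRUE,
      gramInv = gramInv)
}

#' Ordinary least-squares fit of the trait-association model
#'
#' Fits `trait = b0 + b1 * expression (+ covariates) + e` by least squares
#' and tests `H0: b1 = 0` with the t statistic `b1 / se(b1)` on `n - p`
#' degrees of freedom. A fit with zero residual variance is degenerate: the
#' p-value is 0 for a nonzero slope (perfect fit) and NA for a zero slope
#' (constant response).
#'
#' @param response numeric trait vector.
#' @param design full-rank design matrix from [buildDesign()] (intercept
#'   first, expression second).
#' @param geneId optional identifier stored in the result.
#' @return a [GeneFit-class].
#' @examples
#' x <- rnorm(20); y <- 1 + 2 * x + rnorm(20, sd = 0.1)
#' fitOLS(y, cbind(1, expression = x))
#' @export
fitOLS <- function(response, design, geneId = character()) {
  design <- as.matrix(design)
  n <- nrow(design); p <- ncol(design)
  if (length(response) != n) stopf("response/design dimension mismatch")
  if (n <= p) stopf("too few samples: n = %d with %d coefficients", n, p)
  if (is.null(colnames(design)))
    colnames(design) <- c("(Intercept)", "expression",
                          paste0("c", seq_len(max(0, p - 2L))))[seq_len(p)]
  ft <- lm.fit(design, response)
  if (ft$rank < p) stopf("singular design matrix")
  makeOLSFit(geneId, ft$coefficients, response, design, ft$residuals)
}

#' MAD residual-scale estimate
#'
#' `median(|r - median(r)|) / 0.6745`, the normal-consistent median absolute
#' deviation used as the robust sigma-hat inside the IRWLS loop.
#'
#' @param residuals numeric vector, length >= 2, not all identical.
#' @return positive scalar.
#' @export
madScale <- function(residuals) {
  if (length(residuals) < 2L) stopf("need at least 2 residuals")
  m <- median(abs(residuals - median(residuals))) / 0.6745
  if (m == 0) stopf("zero MAD: residuals are (more than half) identical")
  m
}

#' Huber weight function
#'
#' Weight 1 inside the threshold, `threshold / |residual|` outside — the
#' weight form of Huber's loss (quadratic inside, linear outside).
#'
#' @param residual numeric (vectorized).
#' @param threshold positive cutoff, usually `k * sigma` with k = 1.345.
#' @return weights in (0, 1].
#' @export
huberWeight <- function(residual, threshold) {
  if (any(threshold <= 0)) stopf("threshold must be > 0")
  ifelse(abs(residual) <= threshold, 1, threshold / abs(residual))
}

#' Huber M-estimator fit by IRWLS
#'
#' Starts from the OLS fit and alternates: re-estimate the residual scale by
#' [madScale()], compute Huber weights at threshold `k * sigma`, refit by
#' weighted least squares — until every coefficient changes by less than
#' `tol * max(1, |coefficient|)` or `maxIter` is reached (non-convergence is
#' recorded, not an error). Inference is the Wald-type test of
#' [robustWaldTest()].
#'
#' @inheritParams fitOLS
#' @param k Huber tuning constant in sigma units (default 1.345, ~95%
#'   efficiency at the Gaussian model).
#' @param tol relative coefficient-convergence tolerance.
#' @param maxIter maximum IRWLS iterations.
#' @return a [GeneFit-class] with method `"huber"`.
#' @examples
#' x <- rnorm(20); y <- x + rnorm(20, sd = 0.2); y[1] <- y[1] + 50
#' fitHuberIRWLS(y, cbind(1, expression = x))
#' @export
fitHuberIRWLS <- function(response, design, k = 1.345, tol = 1e-8,
                          maxIter = 100L, geneId = character()) {
  if (k <= 0) stopf("k must be > 0")
  design <- as.matrix(design)
  n <- nrow(design); p <- ncol(design)
  if (length(response) != n) stopf("response/design dimension mismatch")
  if (n <= p) stopf("too few samples: n = %d with %d coefficients", n, p)
  if (is.null(colnames(design)))
    colnames(design) <- c("(Intercept)", "expression",
                          paste0("c", seq_len(max(0, p - 2L))))[seq_len(p)]
  init <- lm.fit(design, response)
  if (init$rank < p) stopf("singular design matrix")
  beta <- init$coefficients
  res <- init$residuals
  converged <- FALSE
  iter <- 0L
  sigma <- NA_real_
  w <- rep(1, n)
  while (iter < maxIter) {
    iter <- iter + 1L
    sigma <- tryCatch(madScale(res), error = function(e)
      stopf("degenerate gene%s: %s",
            if (length(geneId)) paste0(" '", geneId, "'") else "",
            conditionMessage(e)))
    w <- huberWeight(res, k * sigma)
    wf <- lm.wfit(design, response, w)
    newBeta <- wf$coefficients
    delta <- abs(newBeta - beta)
    if (all(delta < tol * pmax(1, abs(newBeta)))) converged <- TRUE
    beta <- newBeta
    res <- response - drop(design %*% beta)
    if (converged) break
  }
  gramInv <- chol2inv(chol(crossprod(design)))
  dimnames(gramInv) <- list(colnames(design), colnames(design))
  fit <- new("GeneFit", geneId = geneId, method = "huber",
             coefficients = setNames(as.numeric(beta), colnames(design)),
             seBeta1 = NA_real_, statistic = NA_real_,
             df = as.numeric(n - p), pvalue = NA_real_,
             residuals = as.numeric(res), weights = as.numeric(w),
             scale = sigma, k = k, nIter = iter, converged = converged,
             gramInv = gramInv)
  wt <- robustWaldTest(fit)
  fit@seBeta1 <- wt$se
  fit@statistic <- wt$statistic
  fit@pvalue <- wt$pvalue
  validObject(fit)
  fit
}

#' Wald-type test for the robust expression slope
#'
#' The slope's sandwich variance is
#' `sigma^2 * [sum psi(r/sigma)^2 / (n - p)] / [mean psi'(r/sigma)]^2`
#' times the corresponding diagonal element of the design's inverse Gram
#' matrix, where psi is Huber's psi (identity clipped at +/- k). The
#' statistic `b1 / se(b1)` is referred to a t distribution on `n - p`
#' degrees of freedom — the small-sample-friendly Wald form. When every
#' standardized residual is inside k this reduces exactly to the OLS t test.
#'
#' @param fit a [GeneFit-class] from [fitHuberIRWLS()].
#' @return list with `statistic`, `df`, `pvalue`, `se`; if the fit did not
#'   converge the p-value is still computed and a warning is raised.
#' @export
robustWaldTest <- function(fit) {
  stopifnot(is(fit, "GeneFit"))
  if (fit@method != "huber")
    stopf("robustWaldTest expects a Huber fit; see fitOLS for OLS inference")
  if (!fit@converged)
    warnf("IRWLS did not converge after %d iterations; p-value is indicative",
          fit@nIter)
  n <- length(fit@residuals)
  p <- length(fit@coefficients)
  u <- fit@residuals / fit@scale
  psi <- pmin(pmax(u, -fit@k), fit@k)
  psiPrime <- as.numeric(abs(u) <= fit@k)
  denom <- mean(psiPrime)
  if (denom == 0) {
    se <- NA_real_; stat <- NA_real_; pv <- NA_real_
  } else {
    v <- fit@scale^2 * (sum(psi^2) / (n - p)) / denom^2 *
      fit@gramInv[2L, 2L]
    se <- sqrt(v)
    b1 <- fit@coefficients[2L]
    if (se == 0) {
      if (abs(b1) > 0) { stat <- sign(b1) * Inf; pv <- 0 }
      else { stat <- NA_real_; pv <- NA_real_ }
    } else {
      stat <- unname(b1 / se)
      pv <- 2 * pt(-abs(stat), df = n - p)
    }
  }
  list(statistic = stat, df = n - p, pvalue = pv, se = se)
}
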