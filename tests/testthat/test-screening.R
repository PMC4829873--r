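test_that("BH adjustment matches hand-worked and brute-force step-up values", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  for (s in 1:5) {
    set.seed(s)
    p <- runif(40)^2
    p[sample(40, 4)] <- NA
    expect_equal(bhAdjust(p), oracleBH(p), tolerance = 1e-12)
  }
  expect_error(bhAdjust(c(0.2, 1.3)), "index: 2")
})

test_that("BH adjustment never decreases p-values and preserves rejections", {
  set.seed(6)
  p <- runif(100)
  q <- bhAdjust(p)
  expect_true(all(q >= p))
  # adjusted values are monotone in the p-value ordering and capped at 1
  expect_false(is.unsorted(q[order(p)]))
  expect_true(all(q <= 1))
  # a vector that is its own valid adjustment (all equal) is a fixed point
  expect_equal(bhAdjust(rep(0.4, 10)), rep(0.4, 10))
})

test_that("Shapiro screen passes normal residuals and catches heavy tails", {
  set.seed(40)
  n <- 89; G <- 300
  expr <- matrix(rnorm(G * n), G, n,
                 dimnames = list(paste0("g", 1:G), paste0("s", 1:n)))
  phGood <- data.frame(trait = rnorm(n), row.names = colnames(expr))
  scrGood <- shapiroScreen(expr, phGood)
  expect_gt(mean(scrGood$pvalue > 0.05, na.rm = TRUE), 0.90)
  expect_identical(attr(scrGood, "nSignificant"), 0L)

  phBad <- data.frame(trait = rt(n, df = 1), row.names = colnames(expr))
  scrBad <- shapiroScreen(expr, phBad)
  expect_gt(mean(scrBad$pvalue < 0.05, na.rm = TRUE), 0.90)
})

test_that("a clean synthetic dataset reports no normality rejections", {
  sim <- smallDataset(nGenes = 150, nSamples = 40, seed = 41)
  ex <- log2CPM(sim$counts, tmmFactors(sim$counts))
  scr <- shapiroScreen(ex, sim$phenotype)
  expect_identical(attr(scr, "nSignificant"), 0L)
})

test_that("the scan recovers planted TAGs with controlled false discoveries", {
  # strong, well-separated signal: homogeneous NB variance so every TAG
  # carries comparable information; recall per dataset, FDR pooled over
  # repeats (single-dataset FDP is too granular at a handful of calls)
  nTrue <- nFalse <- nCalled <- 0
  recalls <- numeric(10)
  for (r in 1:10) {
    sim <- simulateTagDataset(synthConfig(nGenes = 2000, nSamples = 89,
                                          nTags = 3, effectSize = 3,
                                          traitNoiseSd = 1,
                                          dispersion = 0.3,
                                          baseMeanLog = log(500),
                                          baseMeanSdLog = 1,
                                          seed = 42 + 100 * r))
    res <- tagScan(log2CPM(sim$counts, tmmFactors(sim$counts)),
                   sim$phenotype, method = "ols", alpha = 0.1,
                   adjust = "fdr")
    called <- significantGenes(res)
    truth <- trueTags(sim$truth)
    recalls[r] <- mean(truth %in% called)
    nCalled <- nCalled + length(called)
    nFalse <- nFalse + sum(!(called %in% truth))
  }
  expect_gt(mean(recalls), 0.8)
  expect_lt(nFalse / nCalled, 0.2)  # pooled empirical FDR
})

test_that("a null scan calls about alpha of the genes at raw threshold", {
  sim <- simulateTagDataset(synthConfig(nGenes = 2000, nSamples = 89,
                                        nTags = 0, seed = 43))
  res <- tagScan(log2CPM(sim$counts, tmmFactors(sim$counts)),
                 sim$phenotype, method = "ols", alpha = 0.05,
                 adjust = "none")
  expect_lt(abs(length(significantGenes(res)) - 100), 30)
})

test_that("scans are deterministic and gene-order invariant", {
  sim <- smallDataset(seed = 44)
  ex <- log2CPM(sim$counts, tmmFactors(sim$counts))
  r1 <- tagScan(ex, sim$phenotype, method = "huber")
  r2 <- tagScan(ex, sim$phenotype, method = "huber")
  expect_identical(scanTable(r1), scanTable(r2))

  perm <- sample(nrow(ex))
  r3 <- tagScan(ex[perm, ], sim$phenotype, method = "huber")
  t1 <- scanTable(r1, original_order = TRUE)
  t3 <- scanTable(r3, original_order = TRUE)
  t3 <- t3[match(t1$gene_id, t3$gene_id), ]
  expect_equal(t1$statistic, t3$statistic, tolerance = 1e-12)
  expect_equal(t1$fdr, t3$fdr, tolerance = 1e-12)
})

test_that("the robust scan at huge k reproduces the OLS scan", {
  sim <- smallDataset(seed = 45)
  ex <- log2CPM(sim$counts, tmmFactors(sim$counts))
  ols <- scanTable(tagScan(ex, sim$phenotype, method = "ols"),
                   original_order = TRUE)
  hub <- scanTable(tagScan(ex, sim$phenotype, method = "huber", k = 1e6),
                   original_order = TRUE)
  for (col in c("beta1", "se_beta1", "statistic", "pvalue", "fdr"))
    expect_equal(hub[[col]], ols[[col]], tolerance = 1e-6)
})

test_that("the scan engine agrees with the per-gene reference fits", {
  sim <- smallDataset(nGenes = 40, nSamples = 30, seed = 46)
  sim$phenotype$batch <- factor(rep(c("A", "B"), length.out = 30))
  ex <- log2CPM(sim$counts, tmmFactors(sim$counts))
  for (method in c("ols", "huber")) {
    tab <- scanTable(tagScan(ex, sim$phenotype, method = method,
                             covariates = "batch"),
                     original_order = TRUE)
    for (g in c(1, 13, 40)) {
      bd <- buildDesign(sim$phenotype, ex[g, ], "batch")
      fit <- if (method == "ols") fitOLS(bd$response, bd$design)
             else fitHuberIRWLS(bd$response, bd$design)
      expect_equal(tab$beta1[g], unname(fit@coefficients[2]),
                   tolerance = 1e-8)
      expect_equal(tab$se_beta1[g], fit@seBeta1, tolerance = 1e-8)
      expect_equal(tab$pvalue[g], fit@pvalue, tolerance = 1e-8)
    }
  }
})

test_that("compareScans enumerates intersection patterns correctly", {
  sim <- smallDataset(nGenes = 30, nSamples = 25, seed = 47)
  ex <- log2CPM(sim$counts, tmmFactors(sim$counts))
  a <- tagScan(ex, sim$phenotype, method = "ols", adjust = "none")
  b <- tagScan(ex, sim$phenotype, method = "ols", adjust = "none")
  same <- compareScans(list(ols1 = a, ols2 = b))
  sig <- significantGenes(a)
  expect_equal(sum(same$significant[, 1] & same$significant[, 2]),
               length(sig))

  # disjoint synthetic sets via named p-value vectors
  genes <- paste0("g", 1:10)
  p1 <- setNames(c(rep(0.001, 3), rep(0.9, 7)), genes)
  p2 <- setNames(c(rep(0.9, 7), rep(0.001, 3)), genes)
  cmp <- compareScans(list(m1 = p1, m2 = p2))
  expect_false(any(cmp$significant[, 1] & cmp$significant[, 2]))

  # three sets on 10 genes vs brute-force enumeration
  set.seed(48)
  ps <- lapply(1:3, function(i) setNames(runif(10), genes))
  names(ps) <- c("deseq", "ols", "robust")
  cmp3 <- compareScans(ps, alpha = 0.5,
                       roles = c(deseq = "existing", ols = "suggesting",
                                 robust = "robust"))
  sigMat <- sapply(ps, function(p) p < 0.5)
  for (g in genes) {
    pat <- paste(as.integer(sigMat[g, ]), collapse = "")
    expect_identical(
      paste(as.integer(cmp3$significant[g, ]), collapse = ""), pat)
  }
  expect_equal(sum(cmp3$counts$n), 10)
  allSig <- rowSums(sigMat) == 3
  expect_true(all(cmp3$categories[allSig] == "AM"))
  onlyRobust <- sigMat[, "robust"] & !sigMat[, "ols"] & !sigMat[, "deseq"]
  expect_true(all(cmp3$categories[onlyRobust] == "RM"))

  pShort <- p1[1:9]
  expect_error(compareScans(list(a = p1, b = pShort)), "g10")
})
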