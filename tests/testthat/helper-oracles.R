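# Independent brute-force oracles used to pin down the numeric contracts.
# Each is written from the algorithm definition, separately from the
# package implementation, and stays deliberately naive.

randomCounts <- function(nGenes, nSamples, seed, lambda = 60) {
  set.seed(seed)
  m <- matrix(rpois(nGenes * nSamples, lambda), nGenes, nSamples)
  dimnames(m) <- list(paste0("g", seq_len(nGenes)),
                      paste0("s", seq_len(nSamples)))
  m
}

# reference choice: enumerate every sample's upper-quartile CPM distance
oracleSelectReference <- function(counts) {
  libs <- colSums(counts)
  uq <- numeric(ncol(counts))
  for (k in seq_len(ncol(counts)))
    uq[k] <- quantile(counts[, k] / libs[k] * 1e6, 0.75)
  target <- mean(uq)
  best <- 1L
  for (k in seq_len(ncol(counts)))
    if (abs(uq[k] - target) < abs(uq[best] - target)) best <- k
  colnames(counts)[best]
}

# step-by-step TMM for one sample against the reference
oracleTMMPair <- function(yk, yr, Nk, Nr, trimM = 0.30, trimA = 0.05) {
  keep0 <- which(yk > 0 & yr > 0)
  yk <- yk[keep0]; yr <- yr[keep0]
  M <- log2((yk / Nk) / (yr / Nr))
  A <- 0.5 * log2((yk / Nk) * (yr / Nr))
  w <- 1 / ((Nk - yk) / (Nk * yk) + (Nr - yr) / (Nr * yr))
  n <- length(M)
  inBand <- function(v, frac) {
    lo <- floor(n * frac) + 1
    hi <- n + 1 - lo
    r <- rank(v)
    r >= lo & r <= hi
  }
  keep <- inBand(M, trimM) & inBand(A, trimA)
  2^(sum(w[keep] * M[keep]) / sum(w[keep]))
}

oracleTMM <- function(counts, trimM = 0.30, trimA = 0.05) {
  ref <- oracleSelectReference(counts)
  libs <- colSums(counts)
  f <- numeric(ncol(counts))
  for (k in seq_len(ncol(counts))) {
    s <- colnames(counts)[k]
    f[k] <- if (s == ref) 1
            else oracleTMMPair(counts[, s], counts[, ref], libs[s], libs[ref],
                               trimM, trimA)
  }
  f / exp(mean(log(f)))
}

# explicit normal-equations least squares
oracleOLS <- function(y, X) {
  XtX <- t(X) %*% X
  XtXinv <- solve(XtX)
  beta <- XtXinv %*% t(X) %*% y
  res <- y - X %*% beta
  n <- nrow(X); p <- ncol(X)
  sigma2 <- sum(res^2) / (n - p)
  se1 <- sqrt(sigma2 * XtXinv[2, 2])
  tstat <- beta[2] / se1
  list(beta = drop(beta), se1 = se1, statistic = tstat,
       pvalue = 2 * pt(-abs(tstat), n - p), residuals = drop(res))
}

# quadratic-time BH step-up: q_i = min over j with p_j ranked >= rank_i
oracleBH <- function(p) {
  ok <- which(!is.na(p))
  pp <- p[ok]
  m <- length(pp)
  r <- rank(pp, ties.method = "first")
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in seq_len(m))
      if (r[j] >= r[i]) cand <- min(cand, min(1, pp[j] * m / r[j]))
    q[i] <- cand
  }
  out <- p
  out[ok] <- q
  out
}

# small aligned fixture for scan-level tests
smallDataset <- function(nGenes = 120, nSamples = 25, nTags = 3,
                         effect = 2, noise = 0.7, seed = 99, ...) {
  simulateTagDataset(synthConfig(nGenes = nGenes, nSamples = nSamples,
                                 nTags = nTags, effectSize = effect,
                                 traitNoiseSd = noise, seed = seed, ...))
}
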