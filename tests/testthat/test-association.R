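makeDesignData <- function(n = 20, seed = 1) {
  set.seed(seed)
  data.frame(trait = rnorm(n, 25, 4),
             sex = factor(sample(c("F", "M"), n, replace = TRUE)),
             age = rnorm(n, 50, 10),
             row.names = paste0("s", seq_len(n)))
}

test_that("buildDesign assembles intercept, expression and dummy-coded covariates", {
  ph <- makeDesignData(5)
  x <- rnorm(5)
  bd <- buildDesign(ph, x, character())
  expect_equal(dim(bd$design), c(5L, 2L))
  expect_equal(bd$design[, 1], rep(1, 5), ignore_attr = TRUE)

  ph2 <- makeDesignData(12)
  bd2 <- buildDesign(ph2, rnorm(12), "sex")
  expect_equal(ncol(bd2$design), 3L)
  expect_true(all(bd2$design[, 3] %in% c(0, 1)))
  expect_equal(unname(bd2$design[, 3]), as.numeric(ph2$sex == "M"))
})

test_that("buildDesign rejects collinear designs and records deletions", {
  ph <- makeDesignData(15)
  x <- rnorm(15)
  ph$dup <- x  # covariate duplicating the expression column
  expect_error(buildDesign(ph, x, "dup"), "collinear|rank")

  ph$age[c(3, 7)] <- NA
  bd <- buildDesign(ph, x, "age")
  expect_setequal(bd$removed, c("s3", "s7"))
  expect_equal(nrow(bd$design), 13L)

  tiny <- makeDesignData(3)
  expect_error(buildDesign(tiny, rnorm(3), c("sex", "age")), "few samples")
})

test_that("fitOLS interpolates exact lines and flags constant responses", {
  x <- c(-2, -1, 0, 1, 2)
  fit <- fitOLS(2 * x + 1, cbind(1, expression = x))
  expect_equal(unname(fit@coefficients), c(1, 2), tolerance = 1e-12)
  expect_equal(fit@residuals, rep(0, 5), tolerance = 1e-10)
  expect_equal(fit@pvalue, 0)

  flat <- fitOLS(rep(3, 6), cbind(1, expression = rnorm(6)))
  expect_equal(unname(flat@coefficients[2]), 0, tolerance = 1e-10)
  expect_true(is.na(flat@pvalue))
})

test_that("fitOLS matches the normal-equations oracle and stats::lm", {
  for (s in 1:6) {
    set.seed(s)
    n <- 20
    X <- cbind(1, expression = rnorm(n), cov = rnorm(n))
    y <- 1 + 0.5 * X[, 2] - 0.2 * X[, 3] + rnorm(n)
    fit <- fitOLS(y, X)
    orc <- oracleOLS(y, X)
    expect_equal(unname(fit@coefficients), unname(orc$beta),
                 tolerance = 1e-10)
    expect_equal(fit@seBeta1, orc$se1, tolerance = 1e-10)
    expect_equal(fit@statistic, unname(orc$statistic), tolerance = 1e-10)
    expect_equal(fit@pvalue, unname(orc$pvalue), tolerance = 1e-10)

    lmfit <- summary(lm(y ~ X[, 2] + X[, 3]))
    expect_equal(fit@statistic, lmfit$coefficients[2, "t value"],
                 tolerance = 1e-8)
  }
})

test_that("madScale evaluates the 0.6745-normalized MAD", {
  expect_equal(madScale(c(-1, 0, 1)), 1 / 0.6745, tolerance = 1e-12)
  r <- c(0.3, -1.2, 2.2, 0.1, -0.4)
  expect_equal(madScale(5 * r), 5 * madScale(r), tolerance = 1e-12)
  expect_error(madScale(rep(2, 4)), "zero MAD|identical")
  set.seed(20)
  expect_lt(abs(madScale(rnorm(101)) - 1), 0.3)
})

test_that("huberWeight is 1 inside the threshold and k*sigma/|r| outside", {
  expect_equal(huberWeight(0.5, 1.345), 1)
  expect_equal(huberWeight(2.690, 1.345), 0.5)
  expect_equal(huberWeight(-2.690, 1.345), 0.5)
  expect_error(huberWeight(1, 0), "threshold")
})

test_that("Huber IRWLS reduces to OLS when no residual is extreme", {
  set.seed(30)
  x <- rnorm(30)
  y <- 2 + x + 0.1 * sin(1:30)  # bounded residuals, all inside k*sigma
  ols <- fitOLS(y, cbind(1, expression = x))
  expect_lt(max(abs(ols@residuals)) / madScale(ols@residuals), 1.345)
  hub <- fitHuberIRWLS(y, cbind(1, expression = x))
  expect_equal(hub@coefficients, ols@coefficients, tolerance = 1e-10)
  expect_true(all(hub@weights == 1))
  expect_equal(hub@statistic, ols@statistic, tolerance = 1e-6)

  # k -> infinity limit on data that does contain outliers
  y2 <- y; y2[1] <- y2[1] + 30
  hubBig <- fitHuberIRWLS(y2, cbind(1, expression = x), k = 1e6)
  olsBig <- fitOLS(y2, cbind(1, expression = x))
  expect_equal(hubBig@coefficients, olsBig@coefficients, tolerance = 1e-8)
})

test_that("a gross outlier moves the OLS slope but not the robust slope", {
  set.seed(31)
  x <- seq(-2, 2, length.out = 21)
  y <- x + rnorm(21, sd = 0.05)
  y[21] <- y[21] + 50
  ols <- fitOLS(y, cbind(1, expression = x))
  hub <- fitHuberIRWLS(y, cbind(1, expression = x))
  expect_gt(abs(ols@coefficients[2] - 1), 0.3)
  expect_lt(abs(hub@coefficients[2] - 1), 0.1)
  expect_true(hub@converged)
  expect_lt(min(hub@weights), 0.1)  # the outlier is heavily downweighted

  # breakdown: pushing the outlier to arbitrary magnitude barely moves it
  y[21] <- y[21] + 1e6
  hub2 <- fitHuberIRWLS(y, cbind(1, expression = x))
  expect_lt(abs(hub2@coefficients[2] - 1), 0.5)
})

test_that("robust coefficients agree with MASS::rlm", {
  skip_if_not_installed("MASS")
  set.seed(32)
  x <- rnorm(40)
  y <- 1 + 2 * x + rnorm(40, sd = 0.5)
  y[c(3, 17)] <- y[c(3, 17)] + c(8, -12)
  hub <- fitHuberIRWLS(y, cbind(1, expression = x), tol = 1e-10,
                       maxIter = 200)
  ref <- MASS::rlm(y ~ x, k = 1.345, scale.est = "MAD", maxit = 200,
                   acc = 1e-10)
  expect_equal(unname(hub@coefficients), unname(coef(ref)),
               tolerance = 1e-4)
})

test_that("the Wald test reduces to OLS inference and is exact at beta1 = 0", {
  # symmetric construction keeps the slope exactly zero through IRWLS
  x <- c(-2, -1, 0, 1, 2)
  y <- x^2
  hub <- fitHuberIRWLS(y, cbind(1, expression = x))
  expect_equal(unname(hub@coefficients[2]), 0, tolerance = 1e-12)
  wt <- robustWaldTest(hub)
  expect_equal(wt$statistic, 0, tolerance = 1e-10)
  expect_equal(wt$pvalue, 1, tolerance = 1e-10)
})

test_that("trait affine transforms shift/scale coefficients but not p-values", {
  set.seed(33)
  x <- rnorm(25)
  y <- 0.8 * x + rnorm(25)
  X <- cbind(1, expression = x)
  for (fitter in list(fitOLS, fitHuberIRWLS)) {
    f0 <- fitter(y, X)
    fShift <- fitter(y + 7, X)
    expect_equal(unname(fShift@coefficients[1] - f0@coefficients[1]), 7,
                 tolerance = 1e-8)
    expect_equal(fShift@coefficients[2], f0@coefficients[2],
                 tolerance = 1e-8)
    expect_equal(fShift@pvalue, f0@pvalue, tolerance = 1e-8)
    fScale <- fitter(3 * y, X)
    expect_equal(unname(fScale@coefficients), unname(3 * f0@coefficients),
                 tolerance = 1e-8)
    expect_equal(fScale@seBeta1, 3 * f0@seBeta1, tolerance = 1e-8)
    # IRWLS convergence granularity (max(1,|beta|) in the stopping rule)
    # makes the scale invariance exact only up to the tolerance of the fit
    expect_equal(fScale@pvalue, f0@pvalue, tolerance = 1e-4)
  }
})

test_that("both tests hold their size on simulated null data", {
  nullScan <- function(n, G, method) {
    set.seed(34)
    expr <- matrix(rnorm(G * n), G, n,
                   dimnames = list(paste0("g", 1:G), paste0("s", 1:n)))
    ph <- data.frame(trait = rnorm(n), row.names = colnames(expr))
    scanTable(tagScan(expr, ph, method = method, adjust = "none"))$pvalue
  }
  # small-sample size check at n = 30
  for (method in c("ols", "huber")) {
    frac <- mean(nullScan(30, 1000, method) < 0.05, na.rm = TRUE)
    expect_lt(abs(frac - 0.05), 0.02)
  }
  # uniformity at the cohort scale, where the Wald approximation operates
  for (method in c("ols", "huber")) {
    ks <- ks.test(nullScan(89, 5000, method), "punif")
    expect_gt(ks$p.value, 0.01)
  }
})
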