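writeLinesTo <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

test_that("count files round-trip byte-identically", {
  sim <- smallDataset(nGenes = 20, nSamples = 4, seed = 70)
  f1 <- tempfile(); f2 <- tempfile()
  writeCounts(sim$counts, f1, params = "seed=70")
  back <- readCounts(f1)
  expect_identical(back, sim$counts + 0)  # storage mode is double
  writeCounts(back, f2, params = "seed=70")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("malformed count files fail with located errors", {
  good <- c("gene_id\ts1\ts2", "gA\t1\t2", "gB\t3\t4")
  expect_error(readCounts(writeLinesTo(c(good, "gA\t5\t6"))),
               "duplicated gene identifier 'gA'")
  expect_error(readCounts(writeLinesTo(c(good, "gC\t3.7\t1"))),
               "non-integer.*3\\.7.*line 4.*s1")
  expect_error(readCounts(writeLinesTo(c(good, "gC\t1"))),
               "ragged row at line 4")
  expect_error(readCounts(writeLinesTo(c(good, "gC\t-2\t1"))),
               "negative")
  expect_error(readCounts(writeLinesTo(c(good, "gC\tx\t1"))),
               "non-numeric")
})

test_that("phenotype files are parsed with delimiter and type detection", {
  f <- writeLinesTo(c("sample_id,bmi,sex,age",
                      "s1,24.5,F,61", "s2,31.2,M,58", "s3,NA,F,49"))
  ph <- readPhenotype(f, trait = "bmi")
  expect_equal(rownames(ph), c("s1", "s2", "s3"))
  expect_true(is.numeric(ph$bmi) && is.na(ph$bmi[3]))
  expect_true(is.character(ph$sex) || is.factor(ph$sex))
  expect_true(is.numeric(ph$age))

  ftab <- writeLinesTo(c("sample_id\ttrait", "s1\t5", "s2\t7"))
  expect_equal(readPhenotype(ftab)$trait, c(5, 7))

  fna <- writeLinesTo(c("sample_id,trait,junk", "s1,5,NA", "s2,7,NA"))
  expect_warning(ph2 <- readPhenotype(fna), "junk")
  expect_false("junk" %in% colnames(ph2))

  expect_error(readPhenotype(f, trait = "weight"), "not found")
})

test_that("sample mismatches between counts and phenotype are reported", {
  sim <- smallDataset(nGenes = 10, nSamples = 4, seed = 71)
  ph <- sim$phenotype
  rownames(ph)[1] <- "stranger"
  expect_error(TagExperiment(sim$counts, ph), "stranger")
})

test_that("scan results round-trip through the TSV writer as p-values", {
  sim <- smallDataset(nGenes = 25, nSamples = 12, seed = 72)
  res <- tagScan(log2CPM(sim$counts, tmmFactors(sim$counts)),
                 sim$phenotype, method = "ols")
  f <- tempfile()
  writeScanResult(res, f)
  first <- readLines(f, n = 1)
  expect_match(first, "^# tagseq .*method=ols")
  pv <- readPvalues(f)
  tab <- scanTable(res)
  expect_equal(unname(pv[tab$gene_id]), signif(tab$pvalue, 6),
               tolerance = 1e-6)
})

cliRun <- function(...) tagseqCLI(c(...))

test_that("the CLI pipeline runs end-to-end and validates its arguments", {
  dir <- tempfile(); dir.create(dir)
  expect_identical(cliRun("simulate", "--out-dir", dir,
                          "--n-genes", "60", "--n-samples", "16",
                          "--n-tags", "2", "--seed", "5"), 0L)
  expect_true(all(file.exists(file.path(dir,
    c("counts.tsv", "phenotype.csv", "truth.tsv")))))

  expect_identical(cliRun("normalize", "--counts",
                          file.path(dir, "counts.tsv"),
                          "--out-dir", dir), 0L)
  expect_true(file.exists(file.path(dir, "factors.tsv")))

  scanOut <- file.path(dir, "scan_ols.tsv")
  expect_identical(cliRun("scan", "--counts", file.path(dir, "counts.tsv"),
                          "--phenotype", file.path(dir, "phenotype.csv"),
                          "--method", "ols", "--adjust", "none",
                          "--out", scanOut), 0L)
  expect_true(file.exists(scanOut))

  checkOut <- file.path(dir, "normcheck.tsv")
  expect_identical(cliRun("normcheck", "--counts",
                          file.path(dir, "counts.tsv"),
                          "--phenotype", file.path(dir, "phenotype.csv"),
                          "--out", checkOut), 0L)

  mockOut <- file.path(dir, "mock.tsv")
  expect_identical(cliRun("mock", "--counts", file.path(dir, "counts.tsv"),
                          "--phenotype", file.path(dir, "phenotype.csv"),
                          "--grid", "3,4", "--repeats", "4",
                          "--seed", "7", "--out", mockOut), 0L)
  expect_true(file.exists(mockOut))

  # failures: unknown subcommand, missing required flag, bad method
  expect_identical(cliRun("frobnicate"), 1L)
  expect_identical(cliRun("scan", "--counts", file.path(dir, "counts.tsv")),
                   1L)
  expect_identical(cliRun("scan", "--counts", file.path(dir, "counts.tsv"),
                          "--phenotype", file.path(dir, "phenotype.csv"),
                          "--method", "bogus", "--out", scanOut), 1L)
})

test_that("robust scan at k = 1e6 equals the OLS scan through the CLI", {
  dir <- tempfile(); dir.create(dir)
  cliRun("simulate", "--out-dir", dir, "--n-genes", "80",
         "--n-samples", "20", "--n-tags", "3", "--seed", "8")
  outO <- file.path(dir, "o.tsv"); outR <- file.path(dir, "r.tsv")
  cliRun("scan", "--counts", file.path(dir, "counts.tsv"),
         "--phenotype", file.path(dir, "phenotype.csv"),
         "--method", "ols", "--out", outO)
  cliRun("scan", "--counts", file.path(dir, "counts.tsv"),
         "--phenotype", file.path(dir, "phenotype.csv"),
         "--method", "robust", "--k", "1e6", "--out", outR)
  po <- readPvalues(outO); pr <- readPvalues(outR)
  expect_equal(pr[names(po)], po, tolerance = 1e-6)

  cmpOut <- file.path(dir, "cmp.tsv")
  expect_identical(cliRun("compare", "--scans",
                          paste(outO, outR, sep = ","),
                          "--labels", "ols,robust",
                          "--out", cmpOut), 0L)
  lines <- readLines(cmpOut)
  expect_match(lines[3], "pattern\tn")
})

test_that("CLI reruns with the same seed produce byte-identical outputs", {
  d1 <- tempfile(); d2 <- tempfile()
  for (d in c(d1, d2)) {
    dir.create(d)
    cliRun("simulate", "--out-dir", d, "--n-genes", "50",
           "--n-samples", "14", "--n-tags", "2", "--seed", "7")
    cliRun("mock", "--counts", file.path(d, "counts.tsv"),
           "--phenotype", file.path(d, "phenotype.csv"),
           "--grid", "3,5", "--repeats", "4", "--seed", "7",
           "--out", file.path(d, "mock.tsv"))
  }
  for (f in c("counts.tsv", "phenotype.csv", "truth.tsv", "mock.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})
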