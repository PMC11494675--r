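test_that("total-area normalization closes rows and is idempotent", {
  mat <- matrix(c(2, 3, 5), nrow = 3, dimnames = list(paste0("P", 1:3), "s1"))
  tab <- toy_table(mat, state = "raw")
  norm <- totalAreaNormalize(tab)
  expect_equal(as.vector(SummarizedExperiment::assay(norm)), c(20, 30, 50))
  expect_equal(SummarizedExperiment::assay(totalAreaNormalize(norm)),
               SummarizedExperiment::assay(norm))
  # scale invariance
  scaled <- toy_table(mat * 7.3, state = "raw")
  expect_equal(SummarizedExperiment::assay(totalAreaNormalize(scaled)),
               SummarizedExperiment::assay(norm))
  # zeros preserved
  mat2 <- matrix(c(1, 0, 0, 3), nrow = 4,
                 dimnames = list(paste0("P", 1:4), "s1"))
  expect_equal(as.vector(SummarizedExperiment::assay(
    totalAreaNormalize(toy_table(mat2, state = "raw")))), c(25, 0, 0, 75))
  # all-zero measurement names the sample
  mat3 <- matrix(0, nrow = 2, ncol = 1, dimnames = list(c("P1", "P2"), "bad"))
  expect_error(totalAreaNormalize(toy_table(mat3, state = "raw")), "s1")
})

test_that("log and back transforms are mutually inverse on normalized data", {
  mat <- matrix(c(20, 30, 50, 10, 60, 30), nrow = 3,
                dimnames = list(paste0("P", 1:3), NULL))
  tab <- toy_table(mat)
  back <- backTransform(logTransform(tab))
  expect_equal(SummarizedExperiment::assay(back),
               SummarizedExperiment::assay(tab), tolerance = 1e-9)
  expect_identical(processingState(back), "normalized")
})

test_that("zero handling before the log follows the configured policy", {
  mat <- matrix(c(50, 50, 0, 60, 39.9, 0.1, 70, 29.8, 0.2), nrow = 3,
                dimnames = list(paste0("P", 1:3), NULL))
  tab <- toy_table(mat)
  lg <- logTransform(tab, zero_policy = "half-min")
  # substituted value is half the smallest positive value of that peak
  expect_equal(unname(SummarizedExperiment::assay(lg)["P3", 1]),
               log(0.1 / 2))
  lg2 <- logTransform(tab, zero_policy = "offset", offset = 1e-4)
  expect_equal(unname(SummarizedExperiment::assay(lg2)["P3", 1]),
               log(1e-4))
  expect_error(logTransform(tab, zero_policy = "error"), "zero value")
})

test_that("derived traits aggregate weighted peak groups per measurement", {
  mat <- matrix(c(10, 15, 75), nrow = 3,
                dimnames = list(paste0("P", 1:3), "s1"))
  tr <- computeDerivedTraits(toy_table(mat), toy_panel())
  expect_equal(SummarizedExperiment::assay(tr)["X", 1], 25)
  expect_identical(processingState(tr), "traits")
  # all-zero numerator gives trait 0
  mat0 <- matrix(c(0, 0, 100), nrow = 3,
                 dimnames = list(paste0("P", 1:3), "s1"))
  expect_equal(SummarizedExperiment::assay(
    computeDerivedTraits(toy_table(mat0), toy_panel()))["X", 1], 0)
  # missing peak is a configuration error naming the trait
  bad <- toy_table(mat[1:2, , drop = FALSE])
  expect_error(computeDerivedTraits(bad, toy_panel()), "trait 'Y'.*P3")
})

test_that("default panel reproduces the published trait block from grand means", {
  ref <- referencePrecisionTables()
  for (std in c(4, 5, 6)) {
    tr <- computeDerivedTraits(reference_table(std))
    got <- SummarizedExperiment::assay(tr)[, 1]
    want <- ref[ref$standard == std &
                  ref$trait %in% names(got), c("trait", "grand_mean")]
    expect_equal(got[want$trait], setNames(want$grand_mean, want$trait),
                 tolerance = 0.5 / 20)   # within 0.5 percentage points
    expect_true(all(abs(got[want$trait] - want$grand_mean) < 0.5))
  }
})

test_that("rank-inverse-normal matches Blom plotting positions", {
  z <- rankInverseNormal(c(3, 1, 2))
  expect_equal(z, qnorm((c(3, 1, 2) - 3 / 8) / (3 - 2 * 3 / 8 + 1)))
  expect_equal(z, c(0.8694, -0.8694, 0), tolerance = 1e-3)
  # permutation equivariance
  set.seed(1)
  v <- rnorm(40)
  perm <- sample(40)
  expect_equal(rankInverseNormal(v)[perm], rankInverseNormal(v[perm]))
  # invariance under monotone transforms
  expect_equal(rankInverseNormal(exp(v)), rankInverseNormal(v))
  expect_error(rankInverseNormal(rep(1, 5)), "constant")
  expect_error(rankInverseNormal(1), "at least two")
})

test_that("rank-normal output is standardized at cohort scale", {
  set.seed(7)
  v <- rnorm(795)
  z <- rankInverseNormal(v)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 0.02)
})

test_that("rank normalization is applied within analysis strata", {
  set.seed(3)
  mat <- matrix(rnorm(2 * 60, mean = 10), nrow = 2,
                dimnames = list(c("G0", "G2"), NULL))
  tab <- toy_table(mat, state = "traits",
                   sex = rep(c("M", "F"), each = 30))
  rn <- rankNormalizeTraits(tab, stratify = "sex")
  z <- SummarizedExperiment::assay(rn)
  for (s in c("M", "F")) {
    j <- which(rep(c("M", "F"), each = 30) == s)
    expect_lt(max(abs(rowMeans(z[, j]))), 1e-6)
    expect_equal(apply(z[, j], 1, sd), c(G0 = 1, G2 = 1), tolerance = 0.05)
  }
  expect_identical(processingState(rn), "rank_normal")
})
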