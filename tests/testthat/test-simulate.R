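test_that("the precision design yields the published measurement counts", {
  sim <- simulatePrecisionExperiment(precisionDesign(seed = 1))
  expect_identical(ncol(sim), 312L)
  cd <- SummarizedExperiment::colData(sim)
  expect_equal(unname(table(cd$subject_id)), rep(104L, 3),
               ignore_attr = TRUE)
  expect_true(all(cd$is_standard))
})

test_that("every simulated measurement is closed to 100", {
  sims <- list(
    simulatePrecisionExperiment(precisionDesign(seed = 2)),
    simulateCohort(cohortDesign(seed = 2)),
    simulateCohort(cpwcDesign(seed = 2)),
    simulateLongitudinalSubject(fiveYearDesign(seed = 2)))
  for (sim in sims) {
    expect_identical(processingState(sim), "normalized")
    expect_true(all(abs(colSums(SummarizedExperiment::assay(sim)) - 100)
                    < 1e-9))
  }
})

test_that("fixing the seed reproduces simulations bit-identically", {
  a <- simulateCohort(cohortDesign(seed = 77))
  b <- simulateCohort(cohortDesign(seed = 77))
  expect_identical(SummarizedExperiment::assay(a),
                   SummarizedExperiment::assay(b))
  c <- simulateCohort(cohortDesign(seed = 78))
  expect_false(identical(SummarizedExperiment::assay(a),
                         SummarizedExperiment::assay(c)))
})

test_that("cohort designs produce the expected dimensions", {
  amc <- simulateCohort(cohortDesign(seed = 1))
  expect_identical(ncol(amc), 38L * 4L)
  cd <- SummarizedExperiment::colData(amc)
  expect_equal(sum(cd$sex == "M"), 40)
  expect_equal(sort(unique(cd$time_days)), c(0, 30, 60, 90))
  # CPWC: 70 women x 12 weekly visits, ~5.4% missingness -> about 795 rows
  sizes <- vapply(1:10, function(s)
    ncol(simulateCohort(cpwcDesign(seed = s))), integer(1))
  expect_equal(mean(sizes), 840 * (1 - 0.054), tolerance = 0.02)
})

test_that("noise-free pools collapse to identical replicates", {
  sim <- simulatePrecisionExperiment(
    precisionDesign(sigma_plate = 0, sigma_replicate = 0, seed = 3))
  mat <- SummarizedExperiment::assay(sim)
  cd <- SummarizedExperiment::colData(sim)
  for (pool in unique(cd$subject_id)) {
    cols <- mat[, cd$subject_id == pool, drop = FALSE]
    expect_true(all(cols == cols[, 1]))
  }
})

test_that("between-run CVs increase with the plate-effect scale", {
  cv_at <- function(sp) {
    sim <- simulatePrecisionExperiment(
      precisionDesign(sigma_plate = sp, sigma_replicate = 0.005, seed = 9))
    pt <- precisionTable(sim, panel = NULL)
    median(pt$cv[pt$trait == "GP15"])
  }
  cvs <- vapply(c(0.004, 0.016, 0.064), cv_at, numeric(1))
  expect_true(all(diff(cvs) > 0))
})

test_that("the five-year schedule has 21 quarterly samples", {
  sim <- simulateLongitudinalSubject(fiveYearDesign(seed = 1))
  expect_identical(ncol(sim), 21L)
  cd <- SummarizedExperiment::colData(sim)
  expect_equal(cd$time_days[1], 0)
  expect_equal(cd$time_days[21], 1825)
})

test_that("noise-free trends hit their trait targets exactly", {
  # G0 rising 15% over 1825 days with zero noise
  d <- longitudinalDesign(schedule = round(91.25 * 0:20),
                          trend = c(G0 = 0.15 / 1825, S = -0.105 / 1825,
                                    G2 = -0.0931 / 1825),
                          sigma_analytical = 0, seed = 1)
  sim <- simulateLongitudinalSubject(d)
  rel <- baselineNormalize(computeDerivedTraits(sim))
  a <- SummarizedExperiment::assay(rel)
  expect_equal(unname(a["G0", 21]), 1.15)
  expect_equal(unname(a["S", 21]), 1 - 0.105)
  res <- suppressWarnings(fitSubjectTrend(rel))
  expect_equal(res$time_effect[res$trait == "G0"], 0.15 / 1825,
               tolerance = 1e-12)
})

test_that("intervention episodes attenuate the fitted ageing slope", {
  base <- longitudinalDesign(schedule = seq(0, 3650, by = 21),
                             trend = c(G0 = 0.000051, S = -0.000073,
                                       G2 = -0.000051),
                             sigma_analytical = 0, seed = 6)
  iv <- longitudinalDesign(schedule = seq(0, 3650, by = 21),
                           trend = c(G0 = 0.000051, S = -0.000073,
                                     G2 = -0.000051),
                           interventions = list(
                             # a counter-ageing dip late in the series pulls
                             # the fitted slope down
                             list(start = 2800, duration = 150,
                                  multiplier = c(G0 = 0.90, S = 1.10),
                                  half_life = 90)),
                           sigma_analytical = 0, seed = 6)
  slope <- function(d) {
    rel <- baselineNormalize(computeDerivedTraits(
      simulateLongitudinalSubject(d)))
    res <- suppressWarnings(fitSubjectTrend(rel))
    res$time_effect[res$trait == "G0"]
  }
  expect_lt(slope(iv), slope(base))
  expect_error(
    longitudinalDesign(schedule = 0:10,
                       trend = c(G0 = 1e-5),
                       interventions = list(list(start = 5, duration = 20,
                                                 multiplier = c(G0 = 0.9),
                                                 half_life = 10))),
    "outside the schedule span")
})

test_that("sample swaps are involutive and inert for identical subjects", {
  co <- simulateCohort(cohortDesign(seed = 4))
  sw <- injectSampleSwap(co, "S001", "S002", 30)
  expect_false(identical(SummarizedExperiment::assay(sw),
                         SummarizedExperiment::assay(co)))
  back <- injectSampleSwap(sw, "S001", "S002", 30)
  expect_identical(SummarizedExperiment::assay(back),
                   SummarizedExperiment::assay(co))
  expect_error(injectSampleSwap(co, "S001", "NOPE", 30), "exactly one")
  # a swap between subjects with identical glycomes flags nothing
  mat <- SummarizedExperiment::assay(co)
  cd <- SummarizedExperiment::colData(co)
  twin_cols <- which(cd$subject_id == "S001")
  for (j in which(cd$subject_id == "S002"))
    mat[, j] <- mat[, twin_cols[match(cd$time_days[j],
                                      cd$time_days[twin_cols])]]
  twin <- GlycanExperiment(mat, as.data.frame(cd),
                           panel = glycanPanel(co), state = "normalized")
  twin_sw <- injectSampleSwap(twin, "S001", "S002", 30)
  rel <- baselineNormalize(computeDerivedTraits(twin_sw))
  fl <- flagExtremes(rel)
  expect_false(any(fl$kind == "swap_candidate" &
                     fl$subject_id %in% c("S001", "S002") &
                     fl$time_days == 30))
})

test_that("injected swaps are recovered downstream with few false alarms", {
  hits <- 0
  for (seed in 1:5) {
    co <- simulateCohort(cpwcDesign(seed = seed))
    co <- inject_conspicuous_swaps(co, n_swaps = 2, day = 21,
                                   seed = seed + 500)
    truth <- S4Vectors::metadata(co)$swap_truth
    expect_identical(nrow(truth), 2L)
    rel <- baselineNormalize(computeDerivedTraits(co))
    fl <- flagExtremes(rel)
    sw <- fl[fl$kind == "swap_candidate", ]
    swapped <- c(truth$subject_a, truth$subject_b)
    found <- vapply(seq_len(2), function(r)
      any(sw$subject_id %in% c(truth$subject_a[r], truth$subject_b[r]) &
            sw$time_days == 21), logical(1))
    if (any(found)) hits <- hits + 1
    # false alarms: flagged points not belonging to an injected swap
    fp <- sum(!(sw$subject_id %in% swapped & sw$time_days == 21))
    expect_lte(fp, 2)
  }
  expect_gte(hits, 4)
})
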