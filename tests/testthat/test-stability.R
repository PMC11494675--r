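test_that("baseline normalization divides by the earliest time point", {
  mat <- matrix(c(2.0, 2.2, 1.8), nrow = 1, dimnames = list("G0", NULL))
  tab <- toy_table(mat, state = "traits", subject_id = "u1",
                   time_days = c(0, 30, 60))
  rel <- baselineNormalize(tab)
  expect_equal(as.vector(SummarizedExperiment::assay(rel)), c(1.0, 1.1, 0.9))
  # single time point
  one <- toy_table(mat[, 1, drop = FALSE], state = "traits",
                   subject_id = "u1", time_days = 0)
  expect_equal(as.vector(SummarizedExperiment::assay(baselineNormalize(one))),
               1)
  # invariance to rescaling a subject's whole series
  rel2 <- baselineNormalize(toy_table(mat * 3.7, state = "traits",
                                      subject_id = "u1",
                                      time_days = c(0, 30, 60)))
  expect_equal(SummarizedExperiment::assay(rel2),
               SummarizedExperiment::assay(rel))
  # zero baseline names subject and trait
  bad <- toy_table(matrix(c(0, 1, 1), nrow = 1, dimnames = list("G0", NULL)),
                   state = "traits", subject_id = "u9",
                   time_days = c(0, 1, 2))
  expect_error(baselineNormalize(bad), "u9.*G0")
})

test_that("single-subject trends recover noiseless slopes exactly", {
  days <- seq(0, 1825, by = 91.25)
  mat <- rbind(G0 = 1 + 1e-4 * days, G1 = rep(1, length(days)))
  tab <- toy_table(mat, state = "traits", subject_id = "u1",
                   time_days = days)
  res <- suppressWarnings(fitSubjectTrend(tab))
  expect_equal(res$time_effect[res$trait == "G0"], 1e-4)
  expect_equal(res$time_effect[res$trait == "G1"], 0)
  expect_identical(unique(res$model), "ols")
  short <- toy_table(mat[, 1:2], state = "traits", subject_id = "u1",
                     time_days = days[1:2])
  expect_error(fitSubjectTrend(short), ">= 3 time points")
  two <- toy_table(cbind(mat, mat), state = "traits",
                   subject_id = rep(c("u1", "u2"), each = length(days)),
                   time_days = c(days, days))
  expect_error(fitSubjectTrend(two), "single subject")
})

test_that("mixed-model slope recovery is unbiased under the generating model", {
  gen <- function(seed, beta) {
    set.seed(seed)
    n_subj <- 40; days <- c(0, 30, 60, 90)
    subj <- rep(sprintf("u%02d", 1:n_subj), each = length(days))
    time <- rep(days, n_subj)
    y <- beta * time + rep(rnorm(n_subj, 0, 0.5), each = length(days)) +
      rnorm(length(time), 0, 0.3)
    toy_table(matrix(y, nrow = 1, dimnames = list("G0", NULL)),
              state = "traits", subject_id = subj, time_days = time)
  }
  est <- vapply(1:60, function(s) {
    res <- suppressWarnings(fitMixedTimeEffect(gen(s, 0.001)))
    res$time_effect
  }, numeric(1))
  expect_equal(mean(est), 0.001, tolerance = 0.1)
  # type-I control: |estimate| < 2 SE in the large majority of null fits
  cover <- vapply(1:60, function(s) {
    res <- suppressWarnings(fitMixedTimeEffect(gen(1000 + s, 0)))
    abs(res$time_effect) < 2 * res$se
  }, logical(1))
  expect_gte(mean(cover), 0.93)
})

test_that("zero between-subject variance reduces the mixed model to OLS", {
  set.seed(1)   # seed chosen so the REML fit is singular (variance hits 0)
  n_subj <- 12; days <- c(0, 30, 60, 90)
  subj <- rep(sprintf("u%02d", 1:n_subj), each = length(days))
  time <- rep(days, n_subj)
  y <- 0.002 * time + rnorm(length(time), 0, 0.3)   # no subject effect
  tab <- toy_table(matrix(y, nrow = 1, dimnames = list("G0", NULL)),
                   state = "traits", subject_id = subj, time_days = time)
  expect_warning(res <- fitMixedTimeEffect(tab), "ordinary least squares")
  expect_identical(res$model, "ols")
  ols <- lm(y ~ time)
  expect_equal(res$time_effect, unname(coef(ols)[2]))
  expect_equal(res$se, summary(ols)$coefficients[2, 2])
})

test_that("p-value adjustment follows the BH ladder", {
  expect_equal(adjustPvalues(0.01), 0.01)            # m = 1
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.5)
  expect_equal(adjustPvalues(p), p.adjust(p, "BH"))
  expect_equal(adjustPvalues(p), c(0.06, 0.06, 0.06, 0.06, 0.06, 0.5))
  # one modest p among six: significance dissipates after adjustment
  p2 <- c(0.03, 0.3, 0.5, 0.6, 0.7, 0.9)
  expect_equal(adjustPvalues(p2)[1], 0.18)
  expect_true(all(adjustPvalues(p2) >= p2))
  expect_true(all(adjustPvalues(p2, "bonferroni") >= adjustPvalues(p2)))
  expect_error(adjustPvalues(c(0.5, 1.2)), "0, 1")
  expect_error(adjustPvalues(c(0.5, -0.1)), "0, 1")
})

test_that("threshold and spike flags follow the stated rules", {
  # 9.5% deviation at week 4 flanked by in-band neighbours
  traits <- c("G0", "G1", "G2", "S", "B", "F")
  mat <- matrix(1, nrow = 6, ncol = 5, dimnames = list(traits, NULL))
  mat["G0", ] <- c(1, 1.01, 1.095, 0.99, 1.0)
  tab <- toy_table(mat, state = "traits", subject_id = "u1",
                   time_days = (0:4) * 7)
  rel <- baselineNormalize(tab)
  fl <- flagExtremes(rel)
  kinds <- fl$kind[fl$trait %in% "G0" & fl$time_days == 14]
  expect_true("threshold_exceed" %in% kinds)
  expect_true("transient_spike" %in% kinds)
  expect_false("swap_candidate" %in% fl$kind)
  # quiet trajectories produce no threshold flags at all
  calm <- matrix(1 + 0.04 * sin(1:30), nrow = 6,
                 dimnames = list(traits, NULL))
  calm_tab <- toy_table(calm, state = "traits", subject_id = "u1",
                        time_days = seq_len(ncol(calm)))
  fl2 <- flagExtremes(baselineNormalize(calm_tab))
  expect_false(any(fl2$kind %in% c("threshold_exceed", "transient_spike",
                                   "swap_candidate")))
})

test_that("the published conspicuous-swap pattern is a swap candidate", {
  traits <- c("G0", "G1", "G2", "S", "B", "F")
  mat <- matrix(1, nrow = 6, ncol = 3, dimnames = list(traits, NULL))
  # one time point deviating G0 +80.1%, G2 -36%, S -36%, G1 +14.6%, B +11%
  mat[, 2] <- 1 + c(0.801, 0.146, -0.36, -0.36, 0.11, 0.0)
  tab <- toy_table(mat, state = "traits", subject_id = "u1",
                   time_days = c(0, 21, 28))
  fl <- flagExtremes(baselineNormalize(tab))
  sw <- fl[fl$kind == "swap_candidate", ]
  expect_identical(nrow(sw), 1L)
  expect_equal(sw$time_days, 21)
  expect_true(is.na(sw$trait))
})

test_that("decile flags capture the global tails", {
  set.seed(14)
  traits <- c("G0", "G1", "G2", "S", "B", "F")
  mat <- matrix(1 + rnorm(6 * 40, 0, 0.02), nrow = 6,
                dimnames = list(traits, NULL))
  tab <- toy_table(mat, state = "traits",
                   subject_id = rep(c("u1", "u2"), each = 20),
                   time_days = rep(seq_len(20), 2))
  fl <- flagExtremes(baselineNormalize(tab))
  n_vals <- length(mat)
  expect_equal(sum(fl$kind == "decile_top") / n_vals, 0.1, tolerance = 0.05)
  expect_equal(sum(fl$kind == "decile_bottom") / n_vals, 0.1,
               tolerance = 0.05)
})
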