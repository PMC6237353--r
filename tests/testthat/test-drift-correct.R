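# 20-injection single-batch sequence: QC_train every 5th, 2 QC_test,
# remaining slots biological samples.
drift_sheet_1b <- function() {
  roles <- rep("sample", 20)
  roles[c(1, 6, 11, 16)] <- "qc_train"
  roles[c(3, 13)] <- "qc_test"
  SampleSheet(data.frame(
    sample_id = sprintf("i%02d", 1:20), role = roles,
    injection_order = 1:20, batch_id = "b1", tissue = "pool",
    dilution_factor = 1))
}

test_that("IS normalization removes shared drift exactly", {
  sheet <- drift_sheet_1b()
  drift <- 1 + 0.02 * (1:20)
  mat <- rbind(F1 = 100 * drift, F2 = 200 * drift, IS = 50 * drift)
  colnames(mat) <- sheet$sample_id
  out <- isNormalize(mat, "IS")
  # feature identical to its IS: corrected values equal the IS grand mean
  outI <- isNormalize(rbind(IS = 50 * drift,
                            F1 = 50 * drift)[, , drop = FALSE], "IS")
  expect_equal(unname(outI["F1", ]), rep(mean(50 * drift), 20))
  expect_equal(rsd(outI["F1", ]), 0)
  # feature = 2 x IS everywhere: constant corrected series
  expect_equal(unname(out["F2", ]), rep(4 * mean(50 * drift), 20))
  expect_equal(rsd(out["F1", ]), 0)
})

test_that("IS normalization with independent noise propagates both CVs", {
  set.seed(21)
  n <- 2000; cv <- 0.05
  sdlog <- sqrt(log(1 + cv^2))
  f <- 1000 * rlnorm(n, -sdlog^2 / 2, sdlog)
  is_v <- 500 * rlnorm(n, -sdlog^2 / 2, sdlog)
  mat <- rbind(F1 = f, IS = is_v)
  colnames(mat) <- paste0("s", seq_len(n))
  out <- isNormalize(mat, "IS")
  expected <- sqrt(2) * cv * 100  # error-propagation oracle
  expect_equal(rsd(out["F1", ]), expected, tolerance = 0.08)
})

test_that("IS normalization flags samples with unusable IS", {
  mat <- rbind(F1 = c(10, 20, 30), IS = c(5, 0, 5))
  colnames(mat) <- c("a", "b", "c")
  expect_warning(out <- isNormalize(mat, "IS"), "missing or zero")
  expect_true(is.na(out["F1", "b"]))
  expect_false(anyNA(out["F1", c("a", "c")]))
})

test_that("linear drift fits recover exact and constant series", {
  qc <- matrix(seq(100, 200, by = 10), 1)  # orders 1..11, 100 -> 200
  m <- fitLinearSequence(qc, 1:11)
  expect_equal(m$slope, 10)
  expect_equal(m$intercept, 90)
  expect_equal(m$anchor, 150)  # mean fitted QC level
  expect_true(m$fit_ok)
  flat <- fitLinearSequence(matrix(7, 1, 5), 1:5)
  expect_equal(flat$slope, 0)
  expect_equal(flat$anchor, 7)
})

test_that("noisy drift fits match the normal-equations oracle", {
  set.seed(3)
  x <- c(1, 4, 9, 12, 17, 23, 30)
  y <- 120 + 2.5 * x + rnorm(7, sd = 4)
  m <- fitLinearSequence(matrix(y, 1), x)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(m$intercept, beta[1], tolerance = 1e-10)
  expect_equal(m$slope, beta[2], tolerance = 1e-10)
})

test_that("applying a drift model removes a perfectly linear trend", {
  sheet <- drift_sheet_1b()
  trend <- 100 * (1 + 0.03 * (1:20))
  mat <- matrix(trend, 1, dimnames = list("F1", sheet$sample_id))
  out <- linearSequenceCorrect(mat, sheet)
  qc_cols <- sheet$role == "qc_train"
  expect_equal(rsd(out["F1", qc_cols]), 0, tolerance = 1e-9)
  expect_equal(rsd(out["F1", ]), 0, tolerance = 1e-9)
  # slope-zero model is the identity
  models <- fitLinearSequence(matrix(7, 1, 4), c(1, 6, 11, 16))
  expect_equal(applyDrift(matrix(7, 1, 20), models, 1:20),
               matrix(7, 1, 20))
})

test_that("non-positive fitted trends and failed fits degrade gracefully", {
  models <- new("DriftModelSet", S4Vectors::DataFrame(
    feature_id = "F1", slope = -10, intercept = 50, anchor = 20,
    n_qc_used = 3L, fit_ok = TRUE))
  expect_warning(out <- applyDrift(matrix(1, 1, 10), models, 1:10),
                 "non-positive")
  expect_true(all(is.na(out[1, 5:10])))  # trend <= 0 from order 5 on
  bad <- new("DriftModelSet", S4Vectors::DataFrame(
    feature_id = "F1", slope = NA_real_, intercept = NA_real_,
    anchor = NA_real_, n_qc_used = 1L, fit_ok = FALSE))
  expect_equal(applyDrift(matrix(3, 1, 4), bad, 1:4), matrix(3, 1, 4))
})

test_that("batch anchoring removes a pure two-fold batch offset exactly", {
  set.seed(31)
  d <- makeDriftTable(30, 24, driftSpec(slope_range = 0, noise_cv = 0,
                                        batch_offsets = c(1, 2), seed = 31))
  out <- batchAnchorCorrect(d$table, d$sheet)
  meta <- d$sheet
  qc <- meta$role == "qc_train"
  m1 <- rowMeans(out[, qc & meta$batch_id == "b1"])
  m2 <- rowMeans(out[, qc & meta$batch_id == "b2"])
  expect_equal(unname(m1 / m2), rep(1, 30), tolerance = 1e-12)
  # offsets gone everywhere, not just in QCs
  s1 <- rowMeans(out[, !qc & meta$batch_id == "b1"])
  s2 <- rowMeans(out[, !qc & meta$batch_id == "b2"])
  expect_equal(unname(s1 / s2), rep(1, 30), tolerance = 1e-12)
})

test_that("batch anchoring on a single batch equals linear sequence
           correction", {
  d <- makeDriftTable(15, 12, driftSpec(batch_offsets = 1, seed = 4))
  expect_equal(batchAnchorCorrect(d$table, d$sheet),
               linearSequenceCorrect(d$table, d$sheet),
               ignore_attr = TRUE)
})

test_that("simulated two-batch runs end with unit between-batch QC ratios", {
  d <- makeDriftTable(40, 30, driftSpec(seed = 6))
  out <- batchAnchorCorrect(d$table, d$sheet)
  meta <- d$sheet
  qc <- meta$role == "qc_train"
  r <- rowMeans(out[, qc & meta$batch_id == "b1"]) /
    rowMeans(out[, qc & meta$batch_id == "b2"])
  expect_equal(r, rep(1, 40), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("strategies validate, compose and are deterministic", {
  d <- makeDriftTable(10, 12, driftSpec(seed = 8))
  expect_equal(runStrategy(d$table, d$sheet, "none"), d$table,
               ignore_attr = TRUE)
  expect_error(runStrategy(d$table, d$sheet, c("is_norm", "is_norm")),
               "invalid strategy")
  expect_error(runStrategy(d$table, d$sheet, "loess"), "invalid strategy")
  expect_error(runStrategy(d$table, d$sheet, "is_norm"), "IS map")
  a <- runStrategy(d$table, d$sheet, c("linear_sequence", "batch_anchor"))
  b <- runStrategy(d$table, d$sheet, c("linear_sequence", "batch_anchor"))
  expect_identical(a, b)
  expect_equal(attr(a, "steps"), c("linear_sequence", "batch_anchor"))
})

test_that("IS-first combinations flatten multiplicative co-drift", {
  sheet <- drift_sheet_1b()
  drift <- 1 + 0.04 * (1:20)
  mat <- rbind(F1 = 300 * drift, IS = 50 * drift)
  colnames(mat) <- sheet$sample_id
  out <- runStrategy(mat, sheet, c("is_norm", "linear_sequence"),
                     is_map = "IS")
  qc <- sheet$role == "qc_train"
  expect_equal(rsd(out["F1", qc]), 0, tolerance = 1e-9)
})

test_that("corrections are scale-equivariant so RSD counts are unchanged", {
  d <- makeDriftTable(12, 12, driftSpec(seed = 13))
  for (steps in list("linear_sequence", "batch_anchor")) {
    out1 <- runStrategy(d$table, d$sheet, steps)
    out3 <- runStrategy(3.7 * d$table, d$sheet, steps)
    expect_equal(out3, 3.7 * out1, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("linear correction does no harm on drift-free data with many QCs", {
  set.seed(17)
  n_qc <- 50
  ids <- sprintf("q%02d", 1:n_qc)
  sheet <- SampleSheet(data.frame(
    sample_id = ids, role = "qc_train", injection_order = 1:n_qc,
    batch_id = "b1", tissue = "pool", dilution_factor = 1))
  mat <- matrix(1000 * rlnorm(100 * n_qc, 0, 0.05), 100,
                dimnames = list(sprintf("F%03d", 1:100), ids))
  out <- linearSequenceCorrect(mat, sheet)
  rsd_raw <- apply(mat, 1, rsd)
  rsd_cor <- apply(out, 1, rsd)
  # fitting 2 parameters on 50 points can only nibble at the variance
  expect_lt(median(abs(rsd_cor - rsd_raw) / rsd_raw), 0.1)
})

test_that("fitted slopes and intercepts cover the truth at 3 standard
           errors", {
  set.seed(23)
  orders <- seq(1, 46, by = 5)  # 10 QCs across the sequence
  n_sim <- 1000
  hit <- logical(n_sim)
  X <- cbind(1, orders)
  XtX_inv <- solve(t(X) %*% X)
  for (i in seq_len(n_sim)) {
    slope <- runif(1, -3, 3); intercept <- runif(1, 500, 1500)
    sigma <- 20
    y <- intercept + slope * orders + rnorm(length(orders), sd = sigma)
    m <- fitLinearSequence(matrix(y, 1), orders)
    se <- sqrt(diag(XtX_inv)) * sigma  # sigma known by construction
    hit[i] <- abs(m$intercept - intercept) <= 3 * se[1] &&
      abs(m$slope - slope) <= 3 * se[2]
  }
  expect_gte(mean(hit), 0.99)
})

test_that("the strategy benchmark counts RSD thresholds coherently", {
  # all-constant features pass every threshold under every strategy
  d0 <- makeDriftTable(25, 20, driftSpec(slope_range = 0, noise_cv = 0,
                                         batch_offsets = c(1, 1), seed = 2))
  b0 <- benchmarkStrategies(d0$table, d0$sheet)
  expect_true(all(b0$summary$n_lt_15 == 25))
  # drifted table: correction never loses to no correction, and the
  # threshold counts are nested by construction
  d <- makeDriftTable(60, 40, driftSpec(seed = 3))
  bench <- benchmarkStrategies(d$table, d$sheet)
  expect_true(all(bench$summary$n_lt_15 <= bench$summary$n_lt_30))
  s <- bench$summary
  n30 <- function(strat, set)
    s$n_lt_30[s$strategy == strat & s$qc_set == set]
  expect_gte(n30("linear_sequence", "qc_train"), n30("none", "qc_train"))
  expect_s3_class(bench, "CorrectionBenchmark")
  expect_true(all(c("qc_train", "qc_test") %in% names(bench$winner)))
})
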