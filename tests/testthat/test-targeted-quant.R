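test_that("internal-standard quantification follows the area-ratio rule", {
  expect_equal(quantifyIS(1, 1, 0.5, 1), 0.5)
  expect_equal(quantifyIS(2, 1, 0.5, 10), 10)
  # independent spreadsheet-style oracle on random tuples
  oracle <- function(a, ai, ci, d) (a / ai) * ci * d
  set.seed(42)
  for (i in 1:200) {
    a <- runif(1, 0, 1e6); ai <- runif(1, 1, 1e6)
    ci <- runif(1, 0.01, 10); d <- sample(c(1, 5, 15, 100, 300), 1)
    expect_equal(quantifyIS(a, ai, ci, d), oracle(a, ai, ci, d),
                 tolerance = 1e-12)
  }
})

test_that("quantification is homogeneous in areas and linear in dilution", {
  set.seed(7)
  a <- runif(50, 0, 100); ai <- runif(50, 1, 100); c_scale <- runif(50, .1, 10)
  expect_equal(quantifyIS(a * c_scale, ai * c_scale, 0.19, 5),
               quantifyIS(a, ai, 0.19, 5), tolerance = 1e-12)
  expect_equal(quantifyIS(a, ai, 0.19, 5 * 3),
               3 * quantifyIS(a, ai, 0.19, 5), tolerance = 1e-12)
})

test_that("quantification rejects zero IS areas and negative inputs", {
  expect_error(quantifyIS(1, 0, 0.5, 1, analyte = "ala", sample = "s1"),
               "zero.*ala/s1")
  expect_error(quantifyIS(-1, 1, 0.5, 1), "negative")
  expect_error(quantifyIS(1, 1, 0.5, 0), "negative")
})

test_that("noiseless lines are recovered exactly under every weighting", {
  conc <- c(0.5, 1, 2, 5, 10, 20)
  resp <- 3 * conc
  for (w in c("none", "inv_x_squared")) {
    m <- fitCalibration(conc, resp, "linear", w)
    expect_equal(m@coefficients, c(0, 3), tolerance = 1e-10)
    expect_equal(m@r, 1, tolerance = 1e-12)
  }
  # log-log: the power law y = 3 x is exactly log-linear
  m <- fitCalibration(conc, resp, "linear", "log_log")
  expect_equal(m@coefficients, c(log10(3), 1), tolerance = 1e-10)
  expect_equal(m@r, 1, tolerance = 1e-12)
})

test_that("the 11-level calibration design round trips through inversion", {
  # geometric 11-level series spanning 346.3 pM to 161.2 uM
  levels <- exp(seq(log(346.3e-6), log(161.2), length.out = 11))
  resp <- 2.5 * levels
  m <- fitCalibration(levels, resp, "linear", "inv_x_squared")
  back <- invertCalibration(resp, m, dilution_factor = 1)
  expect_equal(back$conc, levels, tolerance = 1e-9)
  # dilution factor multiplies the back-calculated concentration
  one <- invertCalibration(2.5 * 1.0, m, dilution_factor = 5)
  expect_equal(one$conc, 5, tolerance = 1e-9)
})

test_that("unweighted linear fits equal the closed-form OLS solution", {
  set.seed(11)
  conc <- 1:8
  resp <- 2 + 0.7 * conc + rnorm(8, sd = 0.3)
  m <- fitCalibration(conc, resp, "linear", "none")
  sxx <- sum((conc - mean(conc))^2)
  b1 <- sum((conc - mean(conc)) * (resp - mean(resp))) / sxx
  b0 <- mean(resp) - b1 * mean(conc)
  expect_equal(m@coefficients, c(b0, b1), tolerance = 1e-10)
})

test_that("1/x^2 weighting reduces low-end relative bias under
           concentration-proportional noise", {
  set.seed(101)
  conc <- c(0.1, 0.5, 1, 5, 10, 50, 100)
  bias_w <- bias_u <- numeric(500)
  for (i in seq_len(500)) {
    resp <- 3 * conc * (1 + rnorm(length(conc), sd = 0.1))
    mw <- fitCalibration(conc, resp, "linear", "inv_x_squared")
    mu <- fitCalibration(conc, resp, "linear", "none")
    y0 <- 3 * 0.1  # true response at the lowest level
    bias_w[i] <- (invertCalibration(y0, mw)$conc - 0.1) / 0.1
    bias_u[i] <- (invertCalibration(y0, mu)$conc - 0.1) / 0.1
  }
  expect_lt(mean(abs(bias_w)), mean(abs(bias_u)))
})

test_that("quadratic fits invert through the in-range root only", {
  conc <- c(0.5, 1, 2, 4, 8, 16, 32, 64)
  resp <- 0.5 + 2 * conc + 0.05 * conc^2  # monotone on the range
  m <- fitCalibration(conc, resp, "quadratic", "none")
  back <- invertCalibration(resp, m)
  expect_equal(back$conc, conc, tolerance = 1e-9)
  # quadratic in log-log space
  resp2 <- 10^(0.1 + 0.9 * log10(conc) + 0.05 * log10(conc)^2)
  m2 <- fitCalibration(conc, resp2, "quadratic", "log_log")
  back2 <- invertCalibration(resp2, m2)
  expect_equal(back2$conc, conc, tolerance = 1e-9)
})

test_that("ambiguous and out-of-range inversions are flagged, not guessed", {
  # downward parabola with vertex inside the range: two in-range roots
  m <- new("CalibrationModel", analyte = "x", kind = "quadratic",
           weighting = "none", coefficients = c(0, 4, -0.5), r = 1,
           concRange = c(0.5, 7.5), responseRange = c(0, 8))
  expect_error(invertCalibration(6, m), "ambiguous")
  # response below the calibrated range: reported as 0 and flagged
  lin <- fitCalibration(1:6, 2 + 3 * (1:6), "linear", "none")
  low <- invertCalibration(1, lin)  # below intercept + slope * min
  expect_equal(low$conc, 0)
  expect_true(low$below_range)
  high <- invertCalibration(2 + 3 * 10, lin)
  expect_true(high$extrapolated)
  expect_equal(high$conc, 10, tolerance = 1e-9)
})

test_that("calibration preconditions are enforced", {
  expect_error(fitCalibration(1:4, 1:4, "linear", "none"), "at least 5")
  expect_error(fitCalibration(1:5, 1:5, "quadratic", "none"), "at least 6")
  expect_error(fitCalibration(c(0, 1:5), c(0, 1:5), "linear",
                              "inv_x_squared"), "strictly positive")
})

test_that("blank-based limits follow the 10x rule", {
  expect_equal(blankLod(c(0.2, 0.2)), c(lod = 2, loq = 2))
  expect_equal(blankLod(0), c(lod = 0, loq = 0))
  # mean-then-times-ten oracle
  expect_equal(blankLod(c(0.1, 0.3))[["lod"]], 10 * mean(c(0.1, 0.3)))
  expect_error(blankLod(numeric()), "at least one")
  expect_equal(snLod(0.0035, 10), 3 * 0.0035 / 10)
})

test_that("matrix quantification applies IS, dilution and blank LOD", {
  panel <- tiny_panel()
  sheet <- SampleSheet(data.frame(
    sample_id = c("s1", "blank1"), role = c("sample", "blank"),
    injection_order = 1:2, batch_id = "b1", tissue = "plasma",
    dilution_factor = c(5, 1)))
  areas <- matrix(c(2, 0.02, 1, 1), 2, 2,
                  dimnames = list(c("s1", "blank1"), c("ala", "IS_aa")))
  q <- quantifyMatrix(areas, panel, sheet)
  expect_equal(q$conc["s1", "ala"], 2 / 1 * 0.19 * 5)
  expect_equal(q$lod[["ala"]], 10 * (0.02 * 0.19))
  expect_false(q$below_lod["s1", "ala"])
})
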