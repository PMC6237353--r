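test_that("rsd matches closed forms and the two-pass oracle", {
  expect_equal(rsd(c(5, 5, 5)), 0)
  expect_equal(rsd(c(1, 2, 3)), 50)       # sd 1, mean 2
  set.seed(77)
  for (i in 1:50) {
    x <- rnorm(sample(3:20, 1), mean = runif(1, 1, 100), sd = runif(1, 0, 5))
    expect_equal(rsd(x), rsd_oracle(x), tolerance = 1e-12)
  }
  # scale invariance
  x <- rlnorm(10)
  expect_equal(rsd(13.7 * x), rsd(x), tolerance = 1e-12)
  # markers for non-evaluable inputs
  expect_true(is.na(rsd(5)))
  expect_true(is.nan(rsd(c(-1, 1))))
})

test_that("identical replicates give zero RSD in every scope", {
  sheet <- nist_sheet()
  conc <- matrix(4.2, 12, 2,
                 dimnames = list(sheet$sample_id, c("ala", "leu")))
  rep <- precisionReport(conc, sheet)
  expect_true(all(rep$rsd_pct == 0))
  expect_setequal(unique(rep$scope),
                  c("technical", "within_batch", "between_batch"))
})

test_that("batch-separated means produce the pooled between-batch RSD", {
  sheet <- nist_sheet()  # 4 + 8 replicates in two batches
  v <- c(rep(100, 4), rep(200, 8))
  conc <- matrix(v, 12, 1, dimnames = list(sheet$sample_id, "ala"))
  rep <- precisionReport(conc, sheet)
  wb <- rep$rsd_pct[rep$scope == "within_batch"]
  bb <- rep$rsd_pct[rep$scope == "between_batch"]
  expect_equal(wb, 0)
  expect_equal(bb, rsd_oracle(v), tolerance = 1e-12)  # 29.54% for 4+8 split
  expect_gt(bb, wb)  # batch shift only shows up between batches
  expect_equal(rep$n[rep$scope == "between_batch"], 12L)
})

test_that("the replicate design covers technical and batch scopes", {
  run <- makeTargetedRun(tiny_panel(), noise_cv = 0.03, seed = 12)
  q <- quantifyMatrix(run$areas, tiny_panel(), run$sheet)
  rep <- precisionReport(q$conc, run$sheet)
  expect_setequal(unique(rep$scope),
                  c("technical", "within_batch", "between_batch"))
  expect_true(all(rep$rsd_pct >= 0))
})

test_that("accuracy against a certificate uses the measured/reference
           ratio", {
  ref <- data.frame(analyte = c("ala", "leu", "gly"),
                    reference_value = c(10, 20, 5),
                    reference_uncertainty = c(1, 2, 0.5))
  measured <- c(ala = 10, leu = 0.73 * 20, val = 3)
  expect_message(acc <- accuracyVsReference(measured, ref), "val")
  expect_equal(acc$accuracy_pct[acc$analyte == "ala"], 100)
  expect_equal(acc$accuracy_pct[acc$analyte == "leu"], 73)
  expect_false("val" %in% acc$analyte)
})

test_that("the accuracy band is inclusive at its endpoints", {
  ref <- data.frame(analyte = c("a", "b", "c"), reference_value = 100)
  acc <- accuracyVsReference(c(a = 49, b = 150, c = 50), ref)
  expect_false(acc$in_band[acc$analyte == "a"])   # 49% outside
  expect_true(acc$in_band[acc$analyte == "b"])    # 150% inside
  expect_true(acc$in_band[acc$analyte == "c"])    # 50% inside
  expect_error(accuracyVsReference(c(a = 1),
    data.frame(analyte = "a", reference_value = 0)), "> 0")
})

test_that("platform comparison declares winners and partitions pairs", {
  # all-tie case
  t_rsd <- c(a = 5, b = 5); n_rsd <- c(fa = 5, fb = 5)
  mapping <- data.frame(compound = c("a", "b"), feature_id = c("fa", "fb"))
  res <- comparePlatforms(t_rsd, n_rsd, mapping)
  expect_true(all(res$pairs$winner == "tie"))
  expect_equal(res$summary$mean_targeted_rsd, res$summary$mean_nontarget_rsd)

  # 45 matched lipids, 44 better in the targeted platform
  set.seed(8)
  t45 <- setNames(runif(45, 3, 12), sprintf("lip%02d", 1:45))
  n45 <- setNames(t45 + runif(45, 10, 150), sprintf("feat%02d", 1:45))
  n45[1] <- t45[1] - 1  # the single non-target win
  map45 <- data.frame(compound = names(t45), feature_id = names(n45))
  res45 <- comparePlatforms(t45, n45, map45)
  expect_equal(res45$summary$n_matched, 45L)
  expect_equal(res45$summary$n_targeted_better, 44L)
  expect_equal(res45$summary$mean_targeted_rsd, mean(t45))
  expect_equal(res45$summary$mean_nontarget_rsd, mean(unname(n45)))
  with(res45$summary,
       expect_equal(n_targeted_better + n_nontarget_better + n_ties,
                    n_matched))

  # missing RSDs are excluded and counted
  n45[2] <- NA
  res_na <- comparePlatforms(t45, n45, map45)
  expect_equal(res_na$summary$n_excluded, 1L)
  expect_equal(res_na$summary$n_matched, 44L)
})

test_that("feature counts summarize to percentages and headline ratios", {
  counts <- data.frame(
    chromatography = c("HILIC", "HILIC", "C18", "C18"),
    polarity = c("pos", "neg", "pos", "neg"),
    n_features = c(40L, 30L, 20L, 10L))
  fc <- featureCountSummary(counts, tissue = "liver")
  expect_equal(sort(fc$table$pct_of_tissue_total), c(10, 20, 30, 40))
  expect_equal(sum(fc$table$pct_of_tissue_total), 100, tolerance = 0.1)
  pos_neg <- fc$ratios[fc$ratios$metric == "pos_vs_neg", ]
  expect_equal(pos_neg$pct_of, (40 + 20) / (30 + 10) * 100)
  expect_equal(pos_neg$pct_more, ((40 + 20) / (30 + 10) - 1) * 100)
  hilic <- fc$ratios[fc$ratios$metric == "hilic_vs_c18", ]
  expect_equal(hilic$pct_of, 70 / 30 * 100)
  # permuting the table rows changes nothing
  fc2 <- featureCountSummary(counts[c(3, 1, 4, 2), ], tissue = "liver")
  expect_equal(fc2$table, fc$table)
  expect_equal(fc2$ratios, fc$ratios)
  # the stated positive-vs-negative arithmetic: 240 vs 100 -> 240%
  fc3 <- featureCountSummary(data.frame(
    chromatography = c("HILIC", "HILIC", "C18", "C18"),
    polarity = c("pos", "neg", "pos", "neg"),
    n_features = c(140L, 60L, 100L, 40L)))
  expect_equal(fc3$ratios$pct_of[fc3$ratios$metric == "pos_vs_neg"], 240)
  # zero denominator is not evaluable
  fc0 <- featureCountSummary(data.frame(
    chromatography = c("HILIC", "C18"), polarity = "pos",
    n_features = c(10L, 5L)))
  expect_true(is.na(fc0$ratios$pct_of[fc0$ratios$metric == "pos_vs_neg"]))
})
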