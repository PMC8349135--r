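# Diagnostic metric suite: published-table reproduction lives in
# test-acceptance.R; here the algebraic properties and the plumbing.

test_that("evaluateCounts matches the exact rational oracle", {
  set.seed(41)
  for (i in 1:500) {
    v <- rpois(4, lambda = sample(c(0.5, 3, 50, 300), 1))
    if (sum(v) == 0) v[1] <- 1
    rep <- evaluateCounts(confusionCounts(v[1], v[2], v[3], v[4]))
    oracle <- rationalMetrics(v[1], v[2], v[3], v[4])
    got <- reportAsList(rep)
    for (m in metricSlots) {
      if (is.na(oracle[[m]])) {
        expect_true(is.na(got[[m]]), info = paste(m, paste(v, collapse = ",")))
      } else {
        expect_lt(abs(got[[m]] - oracle[[m]]) / max(1, abs(oracle[[m]])),
                  1e-12)
      }
    }
  }
})

test_that("complementarity, symmetry and bounds hold on random counts", {
  set.seed(99)
  for (i in 1:500) {
    v <- rpois(4, 20); if (sum(v) == 0) v[1] <- 1
    r <- evaluateCounts(confusionCounts(v[1], v[2], v[3], v[4]))
    if (!is.na(r@specificity)) expect_equal(r@fpr + r@specificity, 1)
    if (!is.na(r@sensitivity)) expect_equal(r@fnr + r@sensitivity, 1)
    if (!is.na(r@auc)) expect_equal(r@auc + r@eer, 1)
    fr <- c(r@sensitivity, r@specificity, r@precision, r@npv, r@fpr,
            r@fnr, r@auc, r@eer, r@f1)
    expect_true(all(is.na(fr) | (fr >= 0 & fr <= 1)))
    expect_true(all(is.na(c(r@lrp, r@lrn)) | c(r@lrp, r@lrn) >= 0))
    # swapping (tp,tn) and (fp,fn) swaps the paired metrics
    s <- evaluateCounts(confusionCounts(v[2], v[1], v[4], v[3]))
    expect_equal(s@sensitivity, r@specificity)
    expect_equal(s@specificity, r@sensitivity)
    expect_equal(s@precision, r@npv)
    expect_equal(s@npv, r@precision)
    expect_equal(s@fpr, r@fnr)
    expect_equal(s@fnr, r@fpr)
  }
})

test_that("undefined metrics are NA, never 0 or infinity", {
  r <- evaluateCounts(confusionCounts(0, 304, 0, 258))
  expect_true(is.na(r@precision))
  expect_true(is.na(r@f1))
  expect_identical(r@sensitivity, 0)
  expect_identical(r@specificity, 1)
  expect_true(is.na(r@lrp))      # specificity 1 -> zero denominator
  expect_equal(r@auc, 0.5)
  r2 <- evaluateCounts(confusionCounts(5, 0, 0, 0))
  expect_true(is.na(r2@specificity))
  expect_true(is.na(r2@npv))
  expect_true(is.na(r2@fpr))
  expect_true(is.na(r2@lrp))
  expect_true(is.na(r2@lrn))
  expect_true(is.na(r2@auc))
  expect_error(confusionCounts(-1, 2, 3, 4), "non-negative")
})

test_that("confusionFromPredictions tallies agree with a brute-force count", {
  t5 <- c(rep("sick", 5), rep("healthy", 5))
  cc <- confusionFromPredictions(t5, t5)
  expect_identical(c(cc@tp, cc@tn, cc@fp, cc@fn), c(5L, 5L, 0L, 0L))
  cc2 <- confusionFromPredictions(c("sick", "sick", "sick", "healthy",
                                    "healthy"),
                                  rep("healthy", 5))
  expect_identical(c(cc2@tp, cc2@tn, cc2@fp, cc2@fn), c(0L, 2L, 0L, 3L))
  set.seed(7)
  for (i in 1:50) {
    n <- sample(1:40, 1)
    tr <- sample(c("sick", "healthy"), n, replace = TRUE)
    pr <- sample(c("sick", "healthy"), n, replace = TRUE)
    cc <- confusionFromPredictions(tr, pr)
    tally <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
    for (k in seq_len(n)) {
      key <- if (tr[k] == "sick" && pr[k] == "sick") "tp"
        else if (tr[k] == "healthy" && pr[k] == "healthy") "tn"
        else if (tr[k] == "healthy") "fp" else "fn"
      tally[key] <- tally[key] + 1L
    }
    expect_identical(c(cc@tp, cc@tn, cc@fp, cc@fn), unname(tally))
    expect_identical(cc@tp + cc@fn, sum(tr == "sick"))
    expect_identical(cc@tn + cc@fp, sum(tr == "healthy"))
  }
  expect_error(confusionFromPredictions("sick", c("sick", "sick")),
               "equal length")
  expect_error(confusionFromPredictions(c("sick", "odd"), c("sick", "sick")),
               "binary")
})

test_that("report tables render at fixed precision and round-trip", {
  reports <- list(
    perfect = evaluateCounts(confusionCounts(258, 304, 0, 0)),
    mixed = evaluateCounts(confusionCounts(218, 159, 145, 40)))
  tab <- formatReportTable(reports)
  expect_identical(names(tab),
                   c("Method", "TP", "TN", "FP", "FN", "Accu", "Sen", "Spe",
                     "P", "NPV", "FPR", "FNR", "LRP", "LRN", "AUC", "EER",
                     "F1"))
  expect_identical(tab$Accu, c("100", "67.08"))
  expect_identical(tab$Sen[1], "1.000")
  expect_identical(tab$LRP[1], "NA")
  expect_identical(tab$F1[2], "0.702")
  # re-parsing the rendered counts and re-evaluating reproduces the strings
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(name = tab$Method, tp = tab$TP, tn = tab$TN,
                              fp = tab$FP, fn = tab$FN), path,
                   row.names = FALSE)
  again <- formatReportTable(evaluateCountsFile(path))
  expect_identical(again[, -1], tab[, -1])
})
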