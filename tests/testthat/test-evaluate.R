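test_that("confusion metrics equal an independent tally oracle", {
  # the published 40-line counts
  m <- ConfusionMetrics(tp = 24, fn = 3, fp = 11, tn = 2)
  expect_equal(sensitivity(m), 24 / 27)
  expect_equal(specificity(m), 2 / 13)
  expect_equal(ppv(m), 24 / 35)
  expect_equal(npv(m), 2 / 5)
  expect_equal(responseRate(m), 27 / 40)

  # perfect predictor
  p <- ConfusionMetrics(tp = 5, fp = 0, tn = 5, fn = 0)
  expect_equal(c(sensitivity(p), specificity(p), ppv(p), npv(p)),
               rep(1, 4))

  # 200 random cohorts vs literal count-and-divide oracle
  for (seed in 1:200) {
    coh <- randomResponseCohort(15, seed)
    m <- quietConfusion(coh, "DRUG")
    rs <- as.data.frame(responseData(coh))
    o <- tallyOracle(rs$prediction, rs$observed)
    ct <- counts(m)
    expect_equal(unname(ct[c("tp", "fp", "tn", "fn")]),
                 c(o$tp, o$fp, o$tn, o$fn))
    expect_equal(sensitivity(m), o$sens)
    expect_equal(specificity(m), o$spec)
    expect_equal(ppv(m), o$ppv)
    expect_equal(npv(m), o$npv)
    expect_equal(responseRate(m), o$rr)
    # exact integer identities
    if (!is.na(o$ppv)) expect_equal(ppv(m) * (o$tp + o$fp), o$tp)
    if (!is.na(o$npv)) expect_equal(npv(m) * (o$tn + o$fn), o$tn)
  }
})

test_that("zero denominators are undefined markers, never errors", {
  allObsPos <- ConfusionMetrics(tp = 3, fp = 0, tn = 0, fn = 2)
  expect_true(is.na(specificity(allObsPos)))   # tn + fp = 0
  expect_equal(npv(allObsPos), 0)              # 0/2: defined
  allPredPos <- ConfusionMetrics(tp = 3, fp = 2, tn = 0, fn = 0)
  expect_true(is.na(npv(allPredPos)))          # tn + fn = 0
  allNegPred <- ConfusionMetrics(tp = 0, fp = 0, tn = 2, fn = 3)
  expect_true(is.na(ppv(allNegPred)))
})

test_that("lines with missing prediction or observation are excluded loudly", {
  coh <- TP53Cohort(
    lineData = data.frame(cell_line = c("A", "B", "C"),
                          tp53_mrna = 200, cn_ratio = 1),
    response = data.frame(cell_line = c("A", "B", "C"), compound = "D",
                          prediction = c("sensitive", NA, "insensitive"),
                          observed = c("sensitive", "sensitive", "insensitive")))
  expect_message(m <- confusionMetrics(coh, "D"), "B")
  expect_equal(unname(counts(m)[["n"]]), 2L)
  expect_error(suppressMessages(confusionMetrics(coh, "NOPE")), "NOPE")
})

test_that("filtering splits on the call and never touches predictions", {
  coh <- sd1SyntheticValidation()
  calls <- quietCall(coh)
  split <- filterLikelyWT(coh, calls)
  expect_equal(nLines(split$kept), 40L)
  expect_equal(nLines(split$removed), 12L)
  expect_setequal(cellLines(split$removed), cellLines(table1Cohort()))
  # purity: each kept line's response rows are identical to the input's
  rsIn <- as.data.frame(responseData(coh))
  rsKept <- as.data.frame(responseData(split$kept))
  idx <- match(rsKept$cell_line, rsIn$cell_line)
  expect_identical(rsKept$prediction, rsIn$prediction[idx])
  expect_identical(rsKept$observed, rsIn$observed[idx])

  # a record without a call is an error naming the line
  expect_error(filterLikelyWT(oneLineCohort(line = "ORPHAN"), calls), "ORPHAN")

  # all-WT cohort: nothing removed
  wt <- oneLineCohort(line = "W", mrna = 200, cn = 1)
  expect_equal(nLines(filterLikelyWT(wt, quietCall(wt))$removed), 0L)
})

test_that("removal scenarios recount the complement exactly", {
  coh <- sd1SyntheticValidation()
  calls <- quietCall(coh)
  kept <- filterLikelyWT(coh, calls)$kept

  # the borderline true negative: its removal drops tn by one
  base <- quietConfusion(kept, "NVP-CGM097")
  dang <- suppressMessages(scenarioRemove(kept, "DAN-G", "dang", "NVP-CGM097"))
  expect_equal(specificity(metrics(dang)), 1 / 12)
  expect_equal(npv(metrics(dang)), 1 / 4)
  expect_true(specificity(metrics(dang)) < specificity(base))

  # no-op removal
  noop <- suppressMessages(scenarioRemove(kept, character(), "noop", "NVP-CGM097"))
  expect_identical(counts(metrics(noop)), counts(base))
  expect_error(scenarioRemove(kept, "NO-SUCH-LINE"), "NO-SUCH-LINE")

  # recount oracle: removing one random line drops exactly its cell
  set.seed(77)
  for (i in 1:20) {
    coh2 <- randomResponseCohort(15, 1000 + i)
    rs <- as.data.frame(responseData(coh2))
    drop <- sample(rs$cell_line, 1)
    m0 <- counts(quietConfusion(coh2, "DRUG"))
    m1 <- counts(metrics(suppressMessages(
      scenarioRemove(coh2, drop, "one", "DRUG"))))
    cell <- with(rs[rs$cell_line == drop, ],
                 if (prediction == "sensitive" && observed == "sensitive") "tp"
                 else if (prediction == "sensitive") "fp"
                 else if (observed == "sensitive") "fn" else "tn")
    expected <- m0; expected[cell] <- expected[cell] - 1L
    expected["n"] <- expected["n"] - 1L
    expect_identical(m1, expected)
  }
})

test_that("standard scenarios reproduce the published evaluation", {
  coh <- sd1SyntheticValidation()
  calls <- quietCall(coh)
  sc <- quietEval(coh, calls, "NVP-CGM097")
  expect_named(sc, c("all_lines", "likely_wt", "likely_wt_no_borderline"))

  m <- metrics(sc$likely_wt)
  expect_equal(unname(counts(m)), c(24L, 11L, 2L, 3L, 40L))
  expect_equal(sensitivity(m), 24 / 27)
  expect_equal(responseRate(m), 27 / 40)

  # borderline scenario = likely-WT minus DAN-G
  mb <- metrics(sc$likely_wt_no_borderline)
  expect_equal(specificity(mb), 1 / 12)
  expect_equal(npv(mb), 1 / 4)
  expect_setequal(setdiff(sc$likely_wt_no_borderline@removedLines,
                          sc$likely_wt@removedLines), "DAN-G")

  # no borderline lines -> scenarios (b) and (c) identical
  sim <- generateCohort(SyntheticCohortConfig(nLines = 60, seed = 3,
                                              exprLossMax = 20))
  cl <- quietCall(sim$cohort)
  bl <- vapply(annotations(cl), function(a) "borderline_mrna" %in% a, logical(1))
  if (!any(bl)) {
    sc2 <- quietEval(sim$cohort, cl, "SIMDRUG")
    expect_identical(counts(metrics(sc2$likely_wt)),
                     counts(metrics(sc2$likely_wt_no_borderline)))
  }
})

test_that("filtering insensitive inactivated lines cannot lower the response rate", {
  # under the mechanistic premise (inactivated => observed insensitive)
  for (seed in 1:25) {
    sim <- generateCohort(SyntheticCohortConfig(nLines = 80, seed = seed))
    cl <- quietCall(sim$cohort)
    split <- filterLikelyWT(sim$cohort, cl)
    if (nLines(split$kept) == 0L || nLines(split$removed) == 0L) next
    rrAll <- responseRate(quietConfusion(sim$cohort, "SIMDRUG"))
    rrKept <- responseRate(quietConfusion(split$kept, "SIMDRUG"))
    expect_gte(rrKept, rrAll)
  }
})

test_that("waterfall plot data is one deterministic bar per line", {
  coh <- sd1SyntheticValidation()
  calls <- quietCall(coh)
  kept <- filterLikelyWT(coh, calls)$kept
  p1 <- suppressMessages(waterfallPlot(kept, calls, "NVP-CGM097"))
  p2 <- suppressMessages(waterfallPlot(kept, calls, "NVP-CGM097"))
  expect_identical(p1$data, p2$data)
  expect_equal(nrow(p1$data), 40L)
  expect_equal(sum(p1$data$prediction == "sensitive"), 35L)
  expect_equal(sum(p1$data$borderline), 1L)  # DAN-G marked
  expect_setequal(p1$data$height, c(-1, 1))

  single <- oneLineCohort()
  ps <- suppressMessages(waterfallPlot(single, quietCall(single), "DRUG"))
  expect_equal(nrow(ps$data), 1L)

  path <- withr::local_tempfile(fileext = ".png")
  suppressMessages(waterfallPlot(kept, calls, "NVP-CGM097", path = path))
  expect_true(file.exists(path) && file.size(path) > 0)
})
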