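test_that("config validation rejects impossible settings before drawing", {
  expect_error(SyntheticCohortConfig(fracInactivated = 1.2), "\\[0, 1\\]")
  expect_error(SyntheticCohortConfig(mechanismMix = c(mutation = 0.5,
                                                      mrna_loss = 0.4,
                                                      cn_loss = 0.2)),
               "sum to 1")
  expect_error(SyntheticCohortConfig(exprLossMax = 40), "32")
  expect_error(SyntheticCohortConfig(nLines = 0), "nLines")
})

test_that("generation is deterministic and stable under appending lines", {
  cfg <- SyntheticCohortConfig(nLines = 200, seed = 17)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(as.data.frame(lineData(a$cohort)),
                   as.data.frame(lineData(b$cohort)))
  expect_identical(as.data.frame(responseData(a$cohort)),
                   as.data.frame(responseData(b$cohort)))
  expect_identical(a$truth, b$truth)

  # per-line substreams: the first 200 lines of a larger cohort are the same
  big <- generateCohort(SyntheticCohortConfig(nLines = 300, seed = 17))
  expect_identical(as.data.frame(lineData(a$cohort)),
                   as.data.frame(lineData(big$cohort))[1:200, ])

  # the generator does not disturb the caller's RNG stream
  set.seed(123); before <- runif(5)
  set.seed(123); invisible(generateCohort(cfg)); after <- runif(5)
  expect_identical(before, after)
})

test_that("degenerate settings produce the degenerate cohort", {
  sim <- generateCohort(SyntheticCohortConfig(nLines = 50, fracInactivated = 0,
                                              signatureConcordance = 1,
                                              seed = 2))
  expect_true(all(sim$truth == "wt"))
  rs <- as.data.frame(responseData(sim$cohort))
  expect_true(all(rs$prediction == "sensitive"))
  expect_equal(nrow(as.data.frame(mutations(sim$cohort))), 0L)
  st <- status(quietCall(sim$cohort))
  expect_true(mean(st == "likely_wt") > 0.95)  # rare tail draws only
})

test_that("generated structure matches its configuration statistically", {
  sim <- generateCohort(SyntheticCohortConfig(nLines = 4000,
                                              fracInactivated = 0.5,
                                              wtResponseRate = 0.5,
                                              signatureConcordance = 0.9,
                                              seed = 19))
  truth <- sim$truth
  rs <- as.data.frame(responseData(sim$cohort))
  rs <- rs[match(names(truth), rs$cell_line), ]

  # inactivated lines are always observed insensitive (mechanistic premise)
  expect_true(all(rs$observed[truth == "inactivated"] == "insensitive"))

  # WT response rate within 3 binomial standard errors
  wtObs <- rs$observed[truth == "wt"] == "sensitive"
  se <- sqrt(0.5 * 0.5 / length(wtObs))
  expect_lt(abs(mean(wtObs) - 0.5), 3 * se)

  # concordance within 3 standard errors
  concordant <- ifelse(truth == "inactivated", "insensitive", "sensitive")
  match9 <- mean(rs$prediction == concordant)
  expect_lt(abs(match9 - 0.9), 3 * sqrt(0.9 * 0.1 / length(truth)))

  # mRNA-loss lines sit below the cutoff, CN-loss lines below 0.25
  ld <- as.data.frame(lineData(sim$cohort))
  ld <- ld[match(names(truth), ld$cell_line), ]
  mutLines <- unique(as.data.frame(mutations(sim$cohort))$cell_line)
  pureLoss <- truth == "inactivated" & !(ld$cell_line %in% mutLines)
  expect_true(all(ld$tp53_mrna[pureLoss] < 32 | ld$cn_ratio[pureLoss] < 0.25))
})

test_that("simulated NMD exercises the annotation path", {
  sim <- generateCohort(SyntheticCohortConfig(nLines = 3000, seed = 23))
  cl <- quietCall(sim$cohort)
  ann <- annotations(cl)
  nmd <- vapply(ann, function(a) "nmd_likely" %in% a, logical(1))
  expect_gt(sum(nmd), 0L)
  # every NMD-flagged line has a truncating mutation and mRNA loss
  ev <- evidence(cl)
  for (l in names(ann)[nmd])
    expect_true(all(c("mutation", "mrna_loss") %in% ev[[l]]))
})

test_that("the evidence-row fixture writer is byte-stable and re-readable", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeFixtureTable1(d1); writeFixtureTable1(d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  coh <- readCohort(file.path(d1, "mutations.tsv"),
                    file.path(d1, "expression.tsv"),
                    file.path(d1, "cn_ratio.tsv"),
                    file.path(d1, "response.tsv"))
  expect_equal(nLines(coh), 12L)
  ld <- as.data.frame(lineData(coh))
  expect_equal(ld$tp53_mrna[ld$cell_line == "KASUMI-1"], 265)
  expect_true(all(status(quietCall(coh)) == "inactivated"))
})

test_that("synthetic supplementary cohorts realize the published margins", {
  v <- sd1SyntheticValidation()
  expect_equal(nLines(v), 52L)
  m <- quietConfusion(v[which(!cellLines(v) %in% cellLines(table1Cohort()))],
                      "NVP-CGM097")
  expect_equal(unname(counts(m)), c(24L, 11L, 2L, 3L, 40L))

  c2 <- sd1SyntheticCfc218()
  expect_equal(nLines(c2), 113L)
  st <- status(quietCall(c2))
  expect_equal(sum(st == "inactivated"), 29L)
})
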