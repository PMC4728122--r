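test_that("published evidence rows yield the published calls", {
  # missense mutation, expressed mRNA, hemizygous CN
  k <- callTP53Status("KASUMI-1", c("p.R248Q" = "missense"), 265, 0.54)
  expect_identical(k$status, "inactivated")
  expect_identical(k$evidence, "mutation")
  expect_identical(k$annotations, "allelic_loss")

  # no mutation, mRNA loss alone
  h <- callTP53Status("HDLM-2", character(), 1, 0.94)
  expect_identical(h$status, "inactivated")
  expect_identical(h$evidence, "mrna_loss")

  # frameshift + mRNA loss -> nonsense-mediated decay inferred
  g <- callTP53Status("IGR-37", c("p.C229fs" = "frameshift"), 9, 0.59)
  expect_identical(g$status, "inactivated")
  expect_setequal(g$evidence, c("mutation", "mrna_loss"))
  expect_true(all(c("nmd_likely", "allelic_loss") %in% g$annotations))

  # just above the mRNA cutoff: flagged borderline, call unchanged
  d <- callTP53Status("DAN-G", character(), 33, 1.0)
  expect_identical(d$status, "likely_wt")
  expect_identical(d$annotations, "borderline_mrna")
  expect_length(d$evidence, 0L)

  # clean wild type
  w <- callTP53Status("WT-1", character(), 200, 1.0)
  expect_identical(w$status, "likely_wt")
  expect_length(w$evidence, 0L)
  expect_length(w$annotations, 0L)
})

test_that("cutoffs are strict inequalities as stated", {
  # the cutoff value itself is NOT loss
  expect_identical(callTP53Status("X", character(), 32, 1.0)$status, "likely_wt")
  expect_identical(callTP53Status("X", character(), 31.999, 1.0)$status,
                   "inactivated")
  expect_identical(callTP53Status("X", character(), 200, 0.25)$status,
                   "likely_wt")
  expect_identical(callTP53Status("X", character(), 200, 0.2499)$status,
                   "inactivated")
  # allelic loss alone never inactivates
  a <- callTP53Status("X", character(), 200, 0.3)
  expect_identical(a$status, "likely_wt")
  expect_identical(a$annotations, "allelic_loss")
  # borderline zone is [32, 40) under the default margin
  expect_identical(callTP53Status("X", character(), 40, 1)$annotations,
                   character(0))
})

test_that("status equals 'any rule fired' over the full truth table", {
  # brute-force oracle: enumerate all 8 combinations of R1/R2/R3 firing
  for (r1 in c(FALSE, TRUE)) for (r2 in c(FALSE, TRUE)) for (r3 in c(FALSE, TRUE)) {
    mut <- if (r1) c("p.R248Q" = "missense") else character()
    mrna <- if (r2) 5 else 200
    cn <- if (r3) 0.1 else 1.0
    call <- callTP53Status("GRID", mut, mrna, cn)
    expected <- if (r1 || r2 || r3) "inactivated" else "likely_wt"
    expect_identical(call$status, expected)
    expect_identical(length(call$evidence) > 0L, r1 || r2 || r3)
    expect_identical("mutation" %in% call$evidence, r1)
    expect_identical("mrna_loss" %in% call$evidence, r2)
    expect_identical("biallelic_loss" %in% call$evidence, r3)
  }
})

test_that("calls are monotone in each evidence channel", {
  set.seed(31)
  for (i in 1:50) {
    mut <- if (runif(1) < 0.3) c("p.R248Q" = "missense") else character()
    mrna <- runif(1, 0, 300)
    cn <- runif(1, 0, 1.5)
    base <- callTP53Status("M", mut, mrna, cn)
    if (base$status == "inactivated") {
      # lowering mRNA or CN, or adding a mutation, can never flip to WT
      expect_identical(callTP53Status("M", mut, mrna * runif(1), cn)$status,
                       "inactivated")
      expect_identical(callTP53Status("M", mut, mrna, cn * runif(1))$status,
                       "inactivated")
      expect_identical(
        callTP53Status("M", c(mut, "p.R213*" = "nonsense"), mrna, cn)$status,
        "inactivated")
    }
  }
})

test_that("missing channels are skipped, fully-missing lines are uncallable", {
  m <- callTP53Status("X", c("p.R248Q" = "missense"), NA_real_, NA_real_)
  expect_identical(m$status, "inactivated")
  expect_true(any(grepl("skipped", m$trail)))
  expect_identical(callTP53Status("X", character(), NA_real_, 1.0)$status,
                   "likely_wt")
  expect_error(callTP53Status("LOST", character(), NA_real_, NA_real_),
               "LOST")
})

test_that("the class policy is configurable and silent never inactivates", {
  s <- callTP53Status("S", c("p.R175R" = "silent"), 200, 1.0)
  expect_identical(s$status, "likely_wt")
  strict <- TP53Thresholds(inactivatingClasses = c("nonsense", "frameshift"))
  m <- callTP53Status("S", c("p.R248Q" = "missense"), 200, 1.0, strict)
  expect_identical(m$status, "likely_wt")
  expect_true(any(grepl("not inactivating", m$trail)))
})

test_that("the 12-line evidence cohort is called inactivated end to end", {
  calls <- quietCall(table1Cohort())
  st <- status(calls)
  expect_length(st, 12L)
  expect_true(all(st == "inactivated"))

  ev <- evidence(calls)
  # regression guard: no printed CN ratio is below 0.25, so the
  # bi-allelic-loss rule never fires on these rows
  expect_false(any(vapply(ev, function(e) "biallelic_loss" %in% e, logical(1))))
  # mutation-only among expressed lines
  mutOnly <- vapply(ev, function(e) identical(e, "mutation"), logical(1))
  expect_equal(sum(mutOnly), 7L)
  # mRNA-loss-only lines
  lossOnly <- vapply(ev, function(e) identical(e, "mrna_loss"), logical(1))
  expect_setequal(names(ev)[lossOnly], c("HDLM-2", "RERF-LC-KJ"))
  # NMD inference on the frameshift + loss lines
  ann <- annotations(calls)
  nmd <- names(ann)[vapply(ann, function(a) "nmd_likely" %in% a, logical(1))]
  expect_setequal(nmd, c("IGR-37", "HCC202", "EFM-192A"))
  al <- names(ann)[vapply(ann, function(a) "allelic_loss" %in% a, logical(1))]
  expect_setequal(al, c("KASUMI-1", "IGR-37"))
})

test_that("cohort calling preserves order and names failing lines", {
  coh <- oneLineCohort(mrna = NA_real_, cn = NA_real_)
  expect_error(quietCall(coh), "TEST-1")
  c2 <- sd1SyntheticValidation()
  calls <- quietCall(c2)
  expect_identical(cellLines(calls), cellLines(c2))
})
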