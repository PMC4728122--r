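# Small in-code cohort builders shared across test files.

# One-line cohort with configurable evidence channels.
oneLineCohort <- function(line = "TEST-1", mutClass = NULL,
                          proteinChange = "p.R248Q",
                          mrna = 200, cn = 1.0,
                          prediction = "sensitive", observed = "sensitive",
                          compound = "DRUG") {
  muts <- if (is.null(mutClass)) NULL else
    data.frame(cell_line = line, protein_change = proteinChange,
               mut_class = mutClass, alt_reads = 50L, ref_reads = 10L,
               stringsAsFactors = FALSE)
  TP53Cohort(
    lineData = data.frame(cell_line = line, tp53_mrna = mrna, cn_ratio = cn,
                          stringsAsFactors = FALSE),
    mutations = if (is.null(muts)) TP53proxy:::emptyMutationTable() else muts,
    response = data.frame(cell_line = line, compound = compound,
                          prediction = prediction, observed = observed,
                          stringsAsFactors = FALSE))
}

# Random prediction/observation cohort for tally-oracle tests.
randomResponseCohort <- function(n, seed, compound = "DRUG") {
  set.seed(seed)
  lines <- sprintf("RC-%03d", seq_len(n))
  TP53Cohort(
    lineData = data.frame(cell_line = lines,
                          tp53_mrna = runif(n, 50, 400),
                          cn_ratio = runif(n, 0.7, 1.3),
                          stringsAsFactors = FALSE),
    response = data.frame(
      cell_line = lines, compound = compound,
      prediction = sample(c("sensitive", "insensitive"), n, replace = TRUE),
      observed = sample(c("sensitive", "insensitive"), n, replace = TRUE),
      stringsAsFactors = FALSE))
}

# Independent count-and-divide oracle for confusion metrics.
tallyOracle <- function(pred, obs) {
  tp <- sum(pred == "sensitive" & obs == "sensitive")
  fp <- sum(pred == "sensitive" & obs == "insensitive")
  tn <- sum(pred == "insensitive" & obs == "insensitive")
  fn <- sum(pred == "insensitive" & obs == "sensitive")
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sens = div(tp, tp + fn), spec = div(tn, tn + fp),
       ppv = div(tp, tp + fp), npv = div(tn, tn + fn),
       rr = div(tp + fn, tp + fp + tn + fn))
}

quietCall <- function(...) suppressMessages(callCohort(...))
quietConfusion <- function(...) suppressMessages(confusionMetrics(...))
quietEval <- function(...) suppressMessages(evaluateSignature(...))
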