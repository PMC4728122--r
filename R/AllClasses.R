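## Central S4 data model: evidence cohort, thresholds, status calls,
## confusion metrics, evaluation scenarios, simulator configuration.

#' Mutation classes recognised by the protein-change parser
#'
#' The closed set of values `parseProteinChange()` can return and that the
#' inactivating-class policy in [TP53Thresholds()] draws from.
#'
#' @export
MUTATION_CLASSES <- c("missense", "nonsense", "frameshift",
                      "inframe_indel", "splice", "silent", "other")

EVIDENCE_CODES   <- c("mutation", "mrna_loss", "biallelic_loss")
ANNOTATION_CODES <- c("allelic_loss", "nmd_likely", "borderline_mrna")
CALL_LEVELS      <- c("inactivated", "likely_wt")
SENSITIVITY_LEVELS <- c("sensitive", "insensitive")

## ------------------------------------------------------------------ ##
## TP53Thresholds
## ------------------------------------------------------------------ ##

#' @rdname TP53Thresholds
#' @export
setClass("TP53Thresholds", representation(
  cnAllelicLoss      = "numeric",
  cnBiallelicLoss    = "numeric",
  mrnaLoss           = "numeric",
  borderlineMargin   = "numeric",
  inactivatingClasses = "character"
))

setValidity("TP53Thresholds", function(object) {
  msg <- character()
  if (length(object@cnAllelicLoss) != 1L || length(object@cnBiallelicLoss) != 1L ||
      length(object@mrnaLoss) != 1L || length(object@borderlineMargin) != 1L)
    msg <- c(msg, "all threshold slots must be scalar")
  else {
    if (object@cnBiallelicLoss < 0 || object@cnBiallelicLoss >= object@cnAllelicLoss)
      msg <- c(msg, "need 0 <= cnBiallelicLoss < cnAllelicLoss")
    if (object@mrnaLoss <= 0) msg <- c(msg, "mrnaLoss must be > 0")
    if (object@borderlineMargin < 0) msg <- c(msg, "borderlineMargin must be >= 0")
  }
  bad <- setdiff(object@inactivatingClasses, MUTATION_CLASSES)
  if (length(bad))
    msg <- c(msg, paste0("unknown mutation class(es): ", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Evidence thresholds for TP53 status calling
#'
#' Cutoffs defining the three evidence rules and the reporting annotations.
#' All cutoffs are strict inequalities: a CN ratio below `cnBiallelicLoss`
#' is bi-allelic loss, below `cnAllelicLoss` allelic loss; an mRNA value
#' below `mrnaLoss` (on the MAS5-150 scale, probe 201746_at) is mRNA loss.
#' The value `mrnaLoss` itself is *not* loss. The borderline zone
#' `[mrnaLoss, mrnaLoss + borderlineMargin)` is flagged for reporting only
#' and never flips a call.
#'
#' @param cnAllelicLoss CN ratio below which one allele is considered lost
#'   (annotation only). Default 0.6.
#' @param cnBiallelicLoss CN ratio below which both alleles are considered
#'   lost (inactivating evidence). Default 0.25.
#' @param mrnaLoss MAS5-150 expression value below which TP53 mRNA is
#'   considered lost. Default 32.
#' @param borderlineMargin width of the just-above-cutoff zone flagged
#'   `borderline_mrna`. Default 8, so a value of 33 is flagged while
#'   unambiguous wild-type values (>= 40) are not.
#' @param inactivatingClasses mutation classes counted as inactivating.
#'   Default: every non-silent coding/splice class.
#'
#' @return A `TP53Thresholds` object.
#' @examples
#' TP53Thresholds()
#' TP53Thresholds(inactivatingClasses = c("nonsense", "frameshift"))
#' @export
TP53Thresholds <- function(cnAllelicLoss = 0.6,
                           cnBiallelicLoss = 0.25,
                           mrnaLoss = 32,
                           borderlineMargin = 8,
                           inactivatingClasses = c("missense", "nonsense",
                                                   "frameshift", "inframe_indel",
                                                   "splice")) {
  new("TP53Thresholds",
      cnAllelicLoss = as.numeric(cnAllelicLoss),
      cnBiallelicLoss = as.numeric(cnBiallelicLoss),
      mrnaLoss = as.numeric(mrnaLoss),
      borderlineMargin = as.numeric(borderlineMargin),
      inactivatingClasses = inactivatingClasses)
}

setMethod("show", "TP53Thresholds", function(object) {
  cat("TP53Thresholds\n",
      "  CN ratio < ", object@cnBiallelicLoss, " : bi-allelic loss (evidence)\n",
      "  CN ratio < ", object@cnAllelicLoss, "  : allelic loss (annotation)\n",
      "  mRNA < ", object@mrnaLoss, "          : mRNA loss (evidence)\n",
      "  borderline zone [", object@mrnaLoss, ", ",
      object@mrnaLoss + object@borderlineMargin, ")\n",
      "  inactivating classes: ",
      paste(object@inactivatingClasses, collapse = ", "), "\n", sep = "")
})

## ------------------------------------------------------------------ ##
## NormalizationSpec
## ------------------------------------------------------------------ ##

#' @rdname NormalizationSpec
#' @export
setClass("NormalizationSpec", representation(
  trimFraction = "numeric",
  target       = "numeric"
))

setValidity("NormalizationSpec", function(object) {
  msg <- character()
  if (object@trimFraction < 0 || object@trimFraction >= 0.5)
    msg <- c(msg, "trimFraction must be in [0, 0.5)")
  if (object@target <= 0) msg <- c(msg, "target must be > 0")
  if (length(msg)) msg else TRUE
})

#' Per-sample trimmed-mean rescaling convention
#'
#' The MAS5-150 convention: every sample (column) is rescaled so its
#' two-sided trimmed mean equals `target`. Defaults encode a 2% trim per
#' tail and a target of 150, the scale on which the mRNA-loss cutoff of 32
#' is defined.
#'
#' @param trimFraction fraction of observations dropped from *each* tail
#'   before averaging, in `[0, 0.5)`. Default 0.02.
#' @param target the value the trimmed mean of every sample is scaled to.
#'   Default 150.
#' @return A `NormalizationSpec` object.
#' @seealso [scaleToTarget()], [trimmedMean()]
#' @export
NormalizationSpec <- function(trimFraction = 0.02, target = 150) {
  new("NormalizationSpec", trimFraction = as.numeric(trimFraction),
      target = as.numeric(target))
}

setMethod("show", "NormalizationSpec", function(object) {
  cat("NormalizationSpec: ", object@trimFraction * 100,
      "% trimmed mean per tail scaled to ", object@target, "\n", sep = "")
})

## ------------------------------------------------------------------ ##
## TP53Cohort
## ------------------------------------------------------------------ ##

#' @rdname TP53Cohort
#' @export
setClass("TP53Cohort", representation(
  lineData  = "DFrame",   # cell_line, tp53_mrna, cn_ratio
  mutations = "DFrame",   # cell_line, protein_change, mut_class, alt_reads, ref_reads
  response  = "DFrame"    # cell_line, compound, prediction, observed
))

setValidity("TP53Cohort", function(object) {
  msg <- character()
  ld <- object@lineData
  need <- c("cell_line", "tp53_mrna", "cn_ratio")
  if (!all(need %in% colnames(ld)))
    return(paste0("lineData must have columns ", paste(need, collapse = ", ")))
  if (anyDuplicated(canonicalLineName(ld$cell_line)))
    msg <- c(msg, "cell_line must be unique within a cohort (after canonicalization)")
  if (any(!is.na(ld$tp53_mrna) & ld$tp53_mrna < 0))
    msg <- c(msg, "tp53_mrna must be >= 0")
  if (any(!is.na(ld$cn_ratio) & ld$cn_ratio < 0))
    msg <- c(msg, "cn_ratio must be >= 0")
  mt <- object@mutations
  needm <- c("cell_line", "protein_change", "mut_class", "alt_reads", "ref_reads")
  if (!all(needm %in% colnames(mt)))
    return(paste0("mutations must have columns ", paste(needm, collapse = ", ")))
  if (nrow(mt)) {
    bad <- setdiff(mt$mut_class, MUTATION_CLASSES)
    if (length(bad)) msg <- c(msg, paste0("unknown mut_class: ", paste(bad, collapse = ", ")))
    both <- !is.na(mt$alt_reads) & !is.na(mt$ref_reads)
    if (any(both & (mt$alt_reads + mt$ref_reads) <= 0))
      msg <- c(msg, "alt_reads + ref_reads must be > 0 when read counts are present")
    if (any(xor(is.na(mt$alt_reads), is.na(mt$ref_reads))))
      msg <- c(msg, "alt_reads and ref_reads must be present or absent together")
  }
  rs <- object@response
  needr <- c("cell_line", "compound", "prediction", "observed")
  if (!all(needr %in% colnames(rs)))
    return(paste0("response must have columns ", paste(needr, collapse = ", ")))
  if (nrow(rs)) {
    lv <- c(SENSITIVITY_LEVELS, NA)
    if (!all(rs$prediction %in% lv) || !all(rs$observed %in% lv))
      msg <- c(msg, "prediction/observed must be 'sensitive', 'insensitive' or NA")
    if (anyDuplicated(paste(canonicalLineName(rs$cell_line), rs$compound)))
      msg <- c(msg, "duplicate (cell_line, compound) rows in response table")
  }
  if (length(msg)) msg else TRUE
})

#' Multi-omic evidence cohort of cancer cell lines
#'
#' One record per cell line: TP53 mutation calls, TP53 mRNA expression
#' (MAS5-150, probe 201746_at), copy-number ratio at the TP53 locus
#' (1.0 = diploid), and per-compound binary signature predictions and
#' observed drug-sensitivity calls. Cell-line names are joined after
#' canonicalization (uppercase, punctuation stripped) but stored as given.
#'
#' @param lineData data.frame/DataFrame with columns `cell_line`,
#'   `tp53_mrna`, `cn_ratio` (NA = channel missing).
#' @param mutations data.frame/DataFrame with columns `cell_line`,
#'   `protein_change`, `mut_class`, `alt_reads`, `ref_reads`; may be empty.
#' @param response data.frame/DataFrame with columns `cell_line`,
#'   `compound`, `prediction`, `observed`
#'   (values `"sensitive"`/`"insensitive"`/NA); may be empty.
#' @return A `TP53Cohort` object.
#' @seealso [readCohort()], [callCohort()], [generateCohort()]
#' @export
TP53Cohort <- function(lineData,
                       mutations = emptyMutationTable(),
                       response = emptyResponseTable()) {
  new("TP53Cohort",
      lineData = DataFrame(as.data.frame(lineData)),
      mutations = DataFrame(as.data.frame(mutations)),
      response = DataFrame(as.data.frame(response)))
}

emptyMutationTable <- function() {
  data.frame(cell_line = character(), protein_change = character(),
             mut_class = character(), alt_reads = integer(),
             ref_reads = integer())
}

emptyResponseTable <- function() {
  data.frame(cell_line = character(), compound = character(),
             prediction = character(), observed = character())
}

#' @describeIn TP53Cohort cell-line names, original spelling
#' @export
setMethod("cellLines", "TP53Cohort", function(x) as.character(x@lineData$cell_line))

#' @describeIn TP53Cohort per-line evidence table (`DataFrame`)
#' @export
setMethod("lineData", "TP53Cohort", function(x) x@lineData)

#' @describeIn TP53Cohort TP53 mutation-call table (`DataFrame`)
#' @export
setMethod("mutations", "TP53Cohort", function(x) x@mutations)

#' @describeIn TP53Cohort prediction/sensitivity table (`DataFrame`)
#' @export
setMethod("responseData", "TP53Cohort", function(x) x@response)

#' @describeIn TP53Cohort number of cell lines
#' @export
setMethod("nLines", "TP53Cohort", function(x) nrow(x@lineData))

#' @describeIn TP53Cohort compounds with response data
#' @export
setMethod("compounds", "TP53Cohort", function(x) unique(as.character(x@response$compound)))

#' @describeIn TP53Cohort subset by line index, name or logical; evidence
#'   tables are subset consistently
#' @param x,i cohort and line index/name/logical selector
#' @param j,drop,... ignored (matrix-style calls tolerated)
#' @export
setMethod("[", "TP53Cohort", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    idx <- match(canonicalLineName(i), canonicalLineName(cellLines(x)))
    if (anyNA(idx))
      stop("unknown cell line(s): ", paste(i[is.na(idx)], collapse = ", "))
    i <- idx
  }
  keep <- canonicalLineName(cellLines(x)[i])
  mt <- x@mutations[canonicalLineName(x@mutations$cell_line) %in% keep, , drop = FALSE]
  rs <- x@response[canonicalLineName(x@response$cell_line) %in% keep, , drop = FALSE]
  new("TP53Cohort", lineData = x@lineData[i, , drop = FALSE],
      mutations = mt, response = rs)
})

setMethod("show", "TP53Cohort", function(object) {
  nmut <- nrow(object@mutations)
  cat("TP53Cohort with ", nLines(object), " cell line(s), ",
      nmut, " TP53 mutation call(s)\n", sep = "")
  cmp <- compounds(object)
  if (length(cmp))
    cat("  compounds: ", paste(cmp, collapse = ", "), "\n", sep = "")
  mis <- sum(is.na(object@lineData$tp53_mrna)) + sum(is.na(object@lineData$cn_ratio))
  if (mis) cat("  ", mis, " missing evidence value(s)\n", sep = "")
})

## ------------------------------------------------------------------ ##
## TP53StatusCalls
## ------------------------------------------------------------------ ##

#' @rdname callCohort
#' @export
setClass("TP53StatusCalls", representation(
  calls      = "DFrame",          # cell_line, status + CharacterList columns
  thresholds = "TP53Thresholds"
))

setValidity("TP53StatusCalls", function(object) {
  cl <- object@calls
  need <- c("cell_line", "status", "evidence", "annotations", "trail")
  if (!all(need %in% colnames(cl)))
    return(paste0("calls must have columns ", paste(need, collapse = ", ")))
  if (!all(cl$status %in% CALL_LEVELS))
    return("status must be 'inactivated' or 'likely_wt'")
  nonEmpty <- lengths(cl$evidence) > 0L
  if (!all((cl$status == "inactivated") == nonEmpty))
    return("status must be 'inactivated' iff the evidence set is non-empty")
  TRUE
})

#' @describeIn callCohort cell-line names of the calls
#' @export
setMethod("cellLines", "TP53StatusCalls", function(x) as.character(x@calls$cell_line))

#' @describeIn callCohort named character vector of status calls
#' @export
setMethod("status", "TP53StatusCalls", function(x) {
  stats::setNames(as.character(x@calls$status), cellLines(x))
})

#' @describeIn callCohort `CharacterList` of evidence codes per line
#' @export
setMethod("evidence", "TP53StatusCalls", function(x) {
  stats::setNames(x@calls$evidence, cellLines(x))
})

#' @describeIn callCohort `CharacterList` of annotation codes per line
#' @export
setMethod("annotations", "TP53StatusCalls", function(x) {
  stats::setNames(x@calls$annotations, cellLines(x))
})

#' @describeIn callCohort `CharacterList` of human-readable rule firings
#' @export
setMethod("trail", "TP53StatusCalls", function(x) {
  stats::setNames(x@calls$trail, cellLines(x))
})

#' @describeIn callCohort thresholds the calls were made with
#' @export
setMethod("thresholds", "TP53StatusCalls", function(x) x@thresholds)

#' @describeIn callCohort number of called lines
#' @export
setMethod("nLines", "TP53StatusCalls", function(x) nrow(x@calls))

setMethod("show", "TP53StatusCalls", function(object) {
  st <- status(object)
  bl <- sum(vapply(annotations(object), function(a) "borderline_mrna" %in% a, logical(1)))
  cat("TP53StatusCalls for ", length(st), " cell line(s): ",
      sum(st == "inactivated"), " inactivated, ",
      sum(st == "likely_wt"), " likely_wt",
      if (bl) paste0(" (", bl, " borderline)") else "", "\n", sep = "")
})

## ------------------------------------------------------------------ ##
## ConfusionMetrics
## ------------------------------------------------------------------ ##

#' @rdname ConfusionMetrics
#' @export
setClass("ConfusionMetrics", representation(
  tp = "integer", fp = "integer", tn = "integer", fn = "integer"
))

setValidity("ConfusionMetrics", function(object) {
  v <- c(object@tp, object@fp, object@tn, object@fn)
  if (length(v) != 4L || anyNA(v) || any(v < 0))
    "tp, fp, tn, fn must be scalar non-negative integers" else TRUE
})

#' Confusion-matrix counts and diagnostic metrics
#'
#' Positive class = observed sensitive to the compound; test-positive =
#' signature predicts sensitive. Derived metrics return `NA` when their
#' denominator is zero (undefined), never an error.
#'
#' @param tp,fp,tn,fn confusion-matrix counts.
#' @return A `ConfusionMetrics` object.
#' @seealso [confusionMetrics()] to tally one from a cohort.
#' @examples
#' m <- ConfusionMetrics(tp = 24, fn = 3, fp = 11, tn = 2)
#' sensitivity(m)   # 24/27
#' ppv(m)           # 24/35
#' @export
ConfusionMetrics <- function(tp, fp, tn, fn) {
  new("ConfusionMetrics", tp = as.integer(tp), fp = as.integer(fp),
      tn = as.integer(tn), fn = as.integer(fn))
}

#' @describeIn ConfusionMetrics named integer vector `c(tp, fp, tn, fn, n)`
#' @param x a `ConfusionMetrics` object
#' @export
setMethod("counts", "ConfusionMetrics", function(x) {
  c(tp = x@tp, fp = x@fp, tn = x@tn, fn = x@fn,
    n = x@tp + x@fp + x@tn + x@fn)
})

.safeDiv <- function(num, den) if (den == 0L) NA_real_ else num / den

#' @describeIn ConfusionMetrics tp / (tp + fn)
#' @export
setMethod("sensitivity", "ConfusionMetrics", function(x) .safeDiv(x@tp, x@tp + x@fn))

#' @describeIn ConfusionMetrics tn / (tn + fp)
#' @export
setMethod("specificity", "ConfusionMetrics", function(x) .safeDiv(x@tn, x@tn + x@fp))

#' @describeIn ConfusionMetrics tp / (tp + fp)
#' @export
setMethod("ppv", "ConfusionMetrics", function(x) .safeDiv(x@tp, x@tp + x@fp))

#' @describeIn ConfusionMetrics tn / (tn + fn)
#' @export
setMethod("npv", "ConfusionMetrics", function(x) .safeDiv(x@tn, x@tn + x@fn))

#' @describeIn ConfusionMetrics (tp + fn) / n — fraction observed sensitive
#' @export
setMethod("responseRate", "ConfusionMetrics", function(x) {
  .safeDiv(x@tp + x@fn, x@tp + x@fp + x@tn + x@fn)
})

.fmtFrac <- function(num, den) {
  if (den == 0L) return("undefined (0 denominator)")
  pct <- 100 * num / den
  paste0(formatC(pct, format = "fg", digits = 3), "% (", num, "/", den, ")")
}

setMethod("show", "ConfusionMetrics", function(object) {
  cat("ConfusionMetrics (n = ", counts(object)[["n"]], ")\n",
      "  tp=", object@tp, " fp=", object@fp,
      " tn=", object@tn, " fn=", object@fn, "\n",
      "  Sensitivity   ", .fmtFrac(object@tp, object@tp + object@fn), "\n",
      "  Specificity   ", .fmtFrac(object@tn, object@tn + object@fp), "\n",
      "  PPV           ", .fmtFrac(object@tp, object@tp + object@fp), "\n",
      "  NPV           ", .fmtFrac(object@tn, object@tn + object@fn), "\n",
      "  Response rate ", .fmtFrac(object@tp + object@fn,
                                   counts(object)[["n"]]), "\n", sep = "")
})

## ------------------------------------------------------------------ ##
## EvaluationScenario
## ------------------------------------------------------------------ ##

#' @rdname scenarioRemove
#' @export
setClass("EvaluationScenario", representation(
  label        = "character",
  compound     = "character",
  removedLines = "character",
  metrics      = "ConfusionMetrics"
))

#' @describeIn scenarioRemove the scenario's `ConfusionMetrics`
#' @export
setMethod("metrics", "EvaluationScenario", function(x) x@metrics)

setMethod("show", "EvaluationScenario", function(object) {
  cat("EvaluationScenario '", object@label, "' [", object@compound, "]",
      if (length(object@removedLines))
        paste0(" minus {", paste(object@removedLines, collapse = ", "), "}")
      else "", "\n", sep = "")
  show(object@metrics)
})

## ------------------------------------------------------------------ ##
## SyntheticCohortConfig
## ------------------------------------------------------------------ ##

#' @rdname SyntheticCohortConfig
#' @export
setClass("SyntheticCohortConfig", representation(
  nLines              = "integer",
  fracInactivated     = "numeric",
  wtResponseRate      = "numeric",
  signatureConcordance = "numeric",
  mechanismMix        = "numeric",   # named: mutation, mrna_loss, cn_loss
  nmdRate             = "numeric",
  exprWtLogmean       = "numeric",
  exprWtLogsd         = "numeric",
  exprLossMax         = "numeric",
  cnMean              = "numeric",
  cnSd                = "numeric",
  cnLossMax           = "numeric",
  seed                = "integer"
))

setValidity("SyntheticCohortConfig", function(object) {
  msg <- character()
  if (object@nLines < 1L) msg <- c(msg, "nLines must be >= 1")
  for (nm in c("fracInactivated", "wtResponseRate", "signatureConcordance")) {
    v <- slot(object, nm)
    if (v < 0 || v > 1) msg <- c(msg, paste0(nm, " must be in [0, 1]"))
  }
  mm <- object@mechanismMix
  if (!identical(sort(names(mm)), sort(c("mutation", "mrna_loss", "cn_loss"))))
    msg <- c(msg, "mechanismMix must be named mutation, mrna_loss, cn_loss")
  else {
    if (any(mm < 0)) msg <- c(msg, "mechanismMix entries must be >= 0")
    if (abs(sum(mm) - 1) > 1e-9) msg <- c(msg, "mechanismMix must sum to 1 (within 1e-9)")
  }
  if (object@nmdRate < 0 || object@nmdRate > 1)
    msg <- c(msg, "nmdRate must be in [0, 1]")
  if (object@exprLossMax >= 32)
    msg <- c(msg, "exprLossMax must be below the mRNA-loss threshold (32)")
  if (object@exprLossMax <= 0) msg <- c(msg, "exprLossMax must be > 0")
  if (object@exprWtLogsd <= 0) msg <- c(msg, "exprWtLogsd must be > 0")
  if (object@cnSd <= 0) msg <- c(msg, "cnSd must be > 0")
  if (object@cnLossMax <= 0) msg <- c(msg, "cnLossMax must be > 0")
  if (length(msg)) msg else TRUE
})

#' Configuration for the synthetic multi-omic cohort generator
#'
#' Encodes the statistical structure the signature re-evaluation assumes:
#' latent TP53 status is Bernoulli(`fracInactivated`); inactivated lines get
#' exactly one inactivating mechanism (mutation / mRNA loss / bi-allelic CN
#' loss per `mechanismMix`) and are always observed insensitive; true-WT
#' lines respond with probability `wtResponseRate`; the binary signature
#' prediction tracks latent status with probability `signatureConcordance`
#' (WT -> "sensitive", inactivated -> "insensitive") and is flipped
#' otherwise. Frameshift-mutation lines additionally lose mRNA expression
#' with probability `nmdRate` (nonsense-mediated decay).
#'
#' Defaults mirror the 52-line validation setting: 12/52 inactivated lines,
#' a WT response rate of 0.675 (27/40), mechanisms mixed 9:2:1
#' mutation : mRNA loss : CN loss, WT expression log-normal around ~250
#' MAS5-150 units, CN normal around 1 truncated at 0.
#'
#' @param nLines number of cell lines.
#' @param fracInactivated fraction of lines with latent inactivated TP53.
#' @param wtResponseRate Bernoulli response probability of true-WT lines.
#' @param signatureConcordance probability the signature prediction matches
#'   latent TP53 status.
#' @param mechanismMix named non-negative weights (`mutation`, `mrna_loss`,
#'   `cn_loss`) summing to 1.
#' @param nmdRate probability a frameshift-mutation line also loses mRNA.
#' @param exprWtLogmean,exprWtLogsd log-normal parameters of intact-mRNA
#'   expression on the MAS5-150 scale.
#' @param exprLossMax upper bound (exclusive of the 32 cutoff) of the
#'   uniform expression draw for mRNA-loss lines.
#' @param cnMean,cnSd normal CN-ratio parameters for non-CN-loss lines,
#'   truncated at 0.
#' @param cnLossMax upper bound of the uniform CN draw for CN-loss lines
#'   (the bi-allelic-loss threshold).
#' @param seed integer seed; the generator derives one substream per line
#'   from it, so a line's draws do not depend on cohort size or order.
#' @return A `SyntheticCohortConfig` object.
#' @seealso [generateCohort()]
#' @export
SyntheticCohortConfig <- function(nLines = 52L,
                                  fracInactivated = 12 / 52,
                                  wtResponseRate = 0.675,
                                  signatureConcordance = 0.9,
                                  mechanismMix = c(mutation = 9, mrna_loss = 2,
                                                   cn_loss = 1) / 12,
                                  nmdRate = 0.5,
                                  exprWtLogmean = log(250),
                                  exprWtLogsd = 0.6,
                                  exprLossMax = 25,
                                  cnMean = 1.0,
                                  cnSd = 0.2,
                                  cnLossMax = 0.25,
                                  seed = 1L) {
  new("SyntheticCohortConfig",
      nLines = as.integer(nLines),
      fracInactivated = as.numeric(fracInactivated),
      wtResponseRate = as.numeric(wtResponseRate),
      signatureConcordance = as.numeric(signatureConcordance),
      mechanismMix = mechanismMix,
      nmdRate = as.numeric(nmdRate),
      exprWtLogmean = as.numeric(exprWtLogmean),
      exprWtLogsd = as.numeric(exprWtLogsd),
      exprLossMax = as.numeric(exprLossMax),
      cnMean = as.numeric(cnMean),
      cnSd = as.numeric(cnSd),
      cnLossMax = as.numeric(cnLossMax),
      seed = as.integer(seed))
}

setMethod("show", "SyntheticCohortConfig", function(object) {
  cat("SyntheticCohortConfig: n=", object@nLines,
      ", frac inactivated=", signif(object@fracInactivated, 3),
      ", WT response rate=", object@wtResponseRate,
      ", concordance=", object@signatureConcordance,
      ", seed=", object@seed, "\n", sep = "")
})
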