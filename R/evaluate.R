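## Filter-then-re-evaluate engine: confusion-matrix diagnostics of a binary
## sensitivity signature, computed on the full cohort, on the likely-WT
## subset, and with borderline-flagged lines removed. Positive class =
## observed sensitive; test-positive = signature predicts sensitive.

.responseFor <- function(cohort, compound, requireComplete = TRUE) {
  rs <- as.data.frame(responseData(cohort))
  rs <- rs[rs$compound == compound, , drop = FALSE]
  if (nrow(rs) == 0L)
    stop("no response data for compound '", compound, "'")
  incomplete <- is.na(rs$prediction) | is.na(rs$observed)
  if (any(incomplete) && requireComplete)
    message("excluding ", sum(incomplete),
            " line(s) with missing prediction/observation: ",
            paste(rs$cell_line[incomplete], collapse = ", "))
  rs[!incomplete, , drop = FALSE]
}

#' Tally the confusion matrix of a signature against observed sensitivity
#'
#' Counts tp/fp/tn/fn for one compound, treating observed-sensitive as the
#' positive class and predicted-sensitive as test-positive. Lines with a
#' missing prediction or observation for the compound are excluded and
#' listed in a message, never silently dropped.
#'
#' @param cohort a [TP53Cohort()] with response data for `compound`.
#' @param compound compound identifier; default the cohort's first.
#' @return A [ConfusionMetrics()] object.
#' @examples
#' m <- confusionMetrics(sd1SyntheticValidation(), "NVP-CGM097")
#' specificity(m)   # 2/13 on the likely-WT 40-line set... see vignette
#' @export
confusionMetrics <- function(cohort, compound = compounds(cohort)[1]) {
  rs <- .responseFor(cohort, compound)
  if (nrow(rs) == 0L)
    stop("no evaluable lines for compound '", compound, "'")
  obs <- rs$observed == "sensitive"
  pred <- rs$prediction == "sensitive"
  ConfusionMetrics(tp = sum(pred & obs), fp = sum(pred & !obs),
                   tn = sum(!pred & !obs), fn = sum(!pred & obs))
}

#' Split a cohort into likely-WT and TP53-inactivated lines
#'
#' The paper-style filter: lines the caller flags inactivated are removed
#' before re-evaluating signature performance, since only wild-type TP53
#' lines can respond to a TP53-MDM2 inhibitor. The filter never touches
#' any line's prediction or observation.
#'
#' @param cohort a [TP53Cohort()].
#' @param calls [callCohort()] output covering every line of `cohort`.
#' @return list with `kept` (likely-WT sub-cohort) and `removed`
#'   (inactivated sub-cohort); the two partition the input.
#' @export
filterLikelyWT <- function(cohort, calls) {
  stopifnot(is(cohort, "TP53Cohort"), is(calls, "TP53StatusCalls"))
  st <- status(calls)
  idx <- match(canonicalLineName(cellLines(cohort)),
               canonicalLineName(names(st)))
  if (anyNA(idx))
    stop("no status call for line(s): ",
         paste(cellLines(cohort)[is.na(idx)], collapse = ", "))
  keep <- st[idx] == "likely_wt"
  list(kept = cohort[which(keep)], removed = cohort[which(!keep)])
}

#' Re-evaluate metrics after removing named cell lines
#'
#' Generalizes the paper's DAN-G footnote: recompute the confusion metrics
#' on the complement of `linesToRemove` and record what was removed.
#'
#' @param cohort a [TP53Cohort()].
#' @param linesToRemove character vector of line names (possibly empty);
#'   must all be cohort members.
#' @param label scenario label for reports.
#' @param compound compound identifier.
#' @return An `EvaluationScenario` holding the recomputed
#'   [ConfusionMetrics()]; see [metrics()].
#' @export
scenarioRemove <- function(cohort, linesToRemove = character(),
                           label = "custom_removal",
                           compound = compounds(cohort)[1]) {
  key <- canonicalLineName(cellLines(cohort))
  bad <- linesToRemove[!canonicalLineName(linesToRemove) %in% key]
  if (length(bad))
    stop("unknown cell line(s): ", paste(bad, collapse = ", "))
  sub <- cohort[which(!key %in% canonicalLineName(linesToRemove))]
  new("EvaluationScenario", label = label, compound = compound,
      removedLines = as.character(linesToRemove),
      metrics = confusionMetrics(sub, compound))
}

#' Run the standard evaluation scenarios for one compound
#'
#' Emits three scenarios: (a) all lines, (b) the likely-WT subset after
#' removing caller-flagged inactivated lines, and (c) the likely-WT subset
#' additionally minus borderline-mRNA-flagged lines. With
#' `borderlinePolicy = "keep"` only (a) and (b) are produced; with
#' `"drop"`, (a) and (c).
#'
#' @param cohort a [TP53Cohort()].
#' @param calls [callCohort()] output covering the cohort.
#' @param compound compound identifier.
#' @param borderlinePolicy `"both"` (default), `"keep"` or `"drop"`.
#' @return named list of `EvaluationScenario` objects.
#' @examples
#' coh <- sd1SyntheticValidation()
#' sc <- evaluateSignature(coh, callCohort(coh), "NVP-CGM097")
#' metrics(sc$likely_wt)
#' @export
evaluateSignature <- function(cohort, calls,
                              compound = compounds(cohort)[1],
                              borderlinePolicy = c("both", "keep", "drop")) {
  borderlinePolicy <- match.arg(borderlinePolicy)
  split <- filterLikelyWT(cohort, calls)
  out <- list(all_lines = scenarioRemove(cohort, character(),
                                         label = "all_lines",
                                         compound = compound))
  removedNames <- cellLines(split$removed)
  out$likely_wt <- new("EvaluationScenario", label = "likely_wt",
                       compound = compound,
                       removedLines = removedNames,
                       metrics = confusionMetrics(split$kept, compound))
  if (borderlinePolicy != "keep") {
    ann <- annotations(calls)
    bl <- names(ann)[vapply(ann, function(a) "borderline_mrna" %in% a,
                            logical(1))]
    blKept <- cellLines(split$kept)[
      canonicalLineName(cellLines(split$kept)) %in% canonicalLineName(bl)]
    sub <- scenarioRemove(split$kept, blKept,
                          label = "likely_wt_no_borderline",
                          compound = compound)
    sub@removedLines <- c(removedNames, blKept)
    out$likely_wt_no_borderline <- sub
  }
  if (borderlinePolicy == "drop") out$likely_wt <- NULL
  out
}

#' Waterfall-style overview of signature prediction vs observed response
#'
#' One signed unit bar per cell line (up = observed sensitive, down =
#' observed insensitive), lines grouped by observed call and coloured by
#' the signature prediction; borderline-mRNA lines are marked. Observed
#' sensitivity is binary in these data, so the plot shows the grouping the
#' diagnostics count rather than a continuous dose-response height.
#'
#' @param cohort a [TP53Cohort()].
#' @param calls [callCohort()] output covering the cohort.
#' @param compound compound identifier.
#' @param path optional file path (`.png`/`.pdf`); written when given.
#' @return invisibly, the `ggplot` object; its `$data` carries one row per
#'   bar and is deterministic for fixed input.
#' @export
waterfallPlot <- function(cohort, calls, compound = compounds(cohort)[1],
                          path = NULL) {
  rs <- .responseFor(cohort, compound)
  if (nrow(rs) == 0L) stop("no evaluable lines to plot")
  ann <- annotations(calls)
  bl <- names(ann)[vapply(ann, function(a) "borderline_mrna" %in% a,
                          logical(1))]
  df <- data.frame(
    cell_line = rs$cell_line,
    observed = factor(rs$observed, levels = SENSITIVITY_LEVELS),
    prediction = factor(rs$prediction, levels = SENSITIVITY_LEVELS),
    borderline = canonicalLineName(rs$cell_line) %in% canonicalLineName(bl),
    stringsAsFactors = FALSE)
  df <- df[order(df$observed, df$prediction, df$cell_line), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df$height <- ifelse(df$observed == "sensitive", 1, -1)

  p <- ggplot2::ggplot(df, ggplot2::aes(
         x = stats::reorder(cell_line, rank), y = height, fill = prediction)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::geom_point(data = df[df$borderline, , drop = FALSE],
                        ggplot2::aes(y = height * 1.1), shape = 8,
                        show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(sensitive = "#1b9e77",
                                          insensitive = "#d95f02"),
                               name = "signature prediction") +
    ggplot2::labs(x = NULL, y = paste("observed response to", compound),
                  title = paste("Observed sensitivity vs signature prediction:",
                                compound)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5, size = 6))
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 9, height = 4)
  invisible(p)
}
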