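## End-to-end driver: read evidence tables -> (optional) rescale expression
## -> call TP53 status -> evaluate scenarios per compound -> write reports
## and optional waterfall plot. Every threshold in force is echoed into the
## output headers so the reports are self-describing.

.pipelineStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Validate and normalize a pipeline configuration
#'
#' @param config named list, or path to a YAML file holding one. Required:
#'   `mutations`, `expression`, `cn`, `response` (input paths) and
#'   `out_dir`. Optional: `probe_id` (default "201746_at"), `compounds`
#'   (default: all in the response table), `normalize_expression` (default
#'   FALSE; rescale to the trimmed-mean target before calling),
#'   `thresholds` and `normalization` (named lists of [TP53Thresholds()] /
#'   [NormalizationSpec()] arguments), `borderline_policy`, `plot`
#'   (default FALSE), `remove` (extra lines for a custom removal scenario).
#' @return the validated config list with defaults filled in.
#' @export
runConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  for (nm in c("mutations", "expression", "cn", "response"))
    if (is.null(config[[nm]]))
      stop("config is missing required input path '", nm, "'")
  for (nm in c("mutations", "expression", "cn", "response"))
    if (!file.exists(config[[nm]]))
      stop("input file not found: ", config[[nm]], " ('", nm, "')")
  if (is.null(config$out_dir)) stop("config is missing 'out_dir'")
  config$probe_id <- config$probe_id %||% "201746_at"
  config$normalize_expression <- isTRUE(config$normalize_expression)
  config$borderline_policy <- config$borderline_policy %||% "both"
  config$plot <- isTRUE(config$plot)
  config$remove <- as.character(config$remove %||% character())
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full evaluation pipeline
#'
#' Chains the stages on the configured input tables and writes, under
#' `out_dir`: `evidence_trail.tsv` and `metrics.json` per compound (via
#' [writeReport()]) and optionally `waterfall_<compound>.png`. Counts at
#' each filter and all thresholds in force are logged. Errors carry the
#' failing stage's name.
#'
#' @param config see [runConfig()].
#' @return invisibly, a list with the `cohort`, `calls`, per-compound
#'   `scenarios` and the written `paths`.
#' @export
runPipeline <- function(config) {
  config <- .pipelineStage("config", runConfig(config))
  th <- .pipelineStage("config", do.call(TP53Thresholds,
                                         config$thresholds %||% list()))
  ns <- .pipelineStage("config", do.call(NormalizationSpec,
                                         config$normalization %||% list()))

  cohort <- .pipelineStage("read", {
    if (config$normalize_expression) {
      expr <- readExpressionMatrix(config$expression)
      expr <- scaleToTarget(expr, ns)
      tmp <- tempfile(fileext = ".tsv")
      .writeTsv(data.frame(probe = rownames(expr), expr, check.names = FALSE),
                tmp)
      on.exit(unlink(tmp), add = TRUE)
      readCohort(config$mutations, tmp, config$cn, config$response,
                 probeId = config$probe_id)
    } else {
      readCohort(config$mutations, config$expression, config$cn,
                 config$response, probeId = config$probe_id)
    }
  })

  calls <- .pipelineStage("call-status", callCohort(cohort, th))
  cmps <- config$compounds %||% compounds(cohort)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  scenarios <- list(); paths <- list()
  for (cmp in cmps) {
    sc <- .pipelineStage("evaluate",
      evaluateSignature(cohort, calls, cmp,
                        borderlinePolicy = config$borderline_policy))
    if (length(config$remove))
      sc$custom_removal <- .pipelineStage("evaluate",
        scenarioRemove(cohort, config$remove, "custom_removal", cmp))
    scenarios[[cmp]] <- sc
    sub <- file.path(config$out_dir, cmp)
    paths[[cmp]] <- .pipelineStage("report",
      writeReport(calls, sc, sub, cohort = cohort, compound = cmp))
    if (config$plot)
      .pipelineStage("plot",
        waterfallPlot(cohort, calls, cmp,
                      path = file.path(sub, paste0("waterfall_", cmp, ".png"))))
  }
  invisible(list(cohort = cohort, calls = calls,
                 scenarios = scenarios, paths = paths))
}
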