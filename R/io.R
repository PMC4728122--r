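## Readers/writers for the four evidence-table dialects and the reports.
## All tables are plain TSV with a header row; only the columns named in
## the dialect map are consumed, so arbitrary extra MAF columns are fine.

#' Canonicalize a cell-line name for joining
#'
#' Uppercases and strips spaces, hyphens and underscores, so that
#' `"KASUMI-1"`, `"Kasumi 1"` and `"KASUMI1"` join to the same record.
#' Original spellings are preserved for output.
#'
#' @param x character vector of cell-line names.
#' @return canonical keys, same length.
#' @examples
#' canonicalLineName(c("KASUMI-1", "kasumi 1"))
#' @export
canonicalLineName <- function(x) {
  gsub("[ _-]", "", toupper(as.character(x)))
}

#' Classify an HGVS protein change into a mutation class
#'
#' Deterministic, total classification of p.-notation strings as printed in
#' CCLE-style mutation tables. A leading `"p."` (with optional space) is
#' stripped. Rules, in order: suffix `fs` (optionally followed by a stop
#' and/or position, e.g. `fs*12`) is a frameshift; `_splice` a splice
#' variant; suffix `del`/`ins`/`dup` without `fs` an in-frame indel; a
#' `<ref><pos><alt>` substitution is nonsense when the new residue is `*`,
#' silent when it equals the reference, missense otherwise; anything
#' unparseable falls through to `"other"` with a warning — never an error.
#'
#' @param s character vector of protein-change strings.
#' @return character vector of classes from [MUTATION_CLASSES].
#' @examples
#' parseProteinChange(c("p.R248Q", "p.C229fs", "p. PPQH190del",
#'                      "p.I332_splice", "p.R213*", "p.R175R"))
#' @export
parseProteinChange <- function(s) {
  vapply(as.character(s), .parseOneProteinChange, character(1), USE.NAMES = FALSE)
}

.parseOneProteinChange <- function(s) {
  if (is.na(s)) return("other")
  x <- gsub("\\s+", "", sub("^p\\.\\s*", "", trimws(s)))
  if (!nzchar(x)) return("other")
  if (grepl("fs(\\*?[0-9]*)?$", x)) return("frameshift")
  if (grepl("_splice", x, fixed = TRUE)) return("splice")
  if (grepl("(del|ins|dup)[A-Za-z*]*$", x)) return("inframe_indel")
  m <- regmatches(x, regexec("^([A-Za-z])([0-9]+)([A-Za-z*])$", x))[[1]]
  if (length(m) == 4L) {
    ref <- toupper(m[2]); alt <- m[4]
    if (alt == "*") return("nonsense")
    if (toupper(alt) == ref) return("silent")
    return("missense")
  }
  "other"
}

#' Read a MAF-dialect TP53 mutation table
#'
#' Reads a tab-separated mutation table and returns one row per TP53
#' mutation call, with the mutation class derived from the protein change.
#' Only four columns are consumed — sample, gene, protein change and read
#' counts — making the reader tolerant of full CCLE MAF files. Rows whose
#' gene column (when present) is not TP53 are dropped; rows with an
#' unparseable protein change get class `"other"` and a warning.
#'
#' @param path TSV file with a header row.
#' @param dialect named character map from the four logical columns
#'   (`cell_line`, `gene`, `protein_change`, `alt_reads`, `ref_reads`) to
#'   the file's column names; `gene` and the read-count columns may be NA
#'   (absent).
#' @param gene gene symbol to keep when a gene column exists. Default "TP53".
#' @return data.frame with columns `cell_line`, `protein_change`,
#'   `mut_class`, `alt_reads`, `ref_reads`; empty (with the right columns)
#'   for a header-only file.
#' @export
readMutationTable <- function(path,
                              dialect = c(cell_line = "cell_line",
                                          gene = "gene",
                                          protein_change = "protein_change",
                                          alt_reads = "alt_reads",
                                          ref_reads = "ref_reads"),
                              gene = "TP53") {
  if (!file.exists(path)) stop("mutation table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("cell_line", "protein_change")
  for (nm in need) {
    col <- dialect[[nm]]
    if (is.na(col) || !col %in% colnames(tab))
      stop("mutation table is missing required column '", col,
           "' (logical field '", nm, "')")
  }
  if (!is.na(dialect["gene"]) && dialect[["gene"]] %in% colnames(tab))
    tab <- tab[tab[[dialect[["gene"]]]] == gene, , drop = FALSE]
  getOpt <- function(nm) {
    col <- dialect[nm]
    if (!is.na(col) && col %in% colnames(tab))
      suppressWarnings(as.integer(tab[[col]]))
    else rep(NA_integer_, nrow(tab))
  }
  out <- data.frame(
    cell_line = as.character(tab[[dialect[["cell_line"]]]]),
    protein_change = as.character(tab[[dialect[["protein_change"]]]]),
    mut_class = parseProteinChange(tab[[dialect[["protein_change"]]]]),
    alt_reads = getOpt("alt_reads"),
    ref_reads = getOpt("ref_reads"),
    stringsAsFactors = FALSE)
  if (any(out$mut_class == "other" & nzchar(out$protein_change)))
    warning("unparseable protein change(s) classified as 'other': ",
            paste(unique(out$protein_change[out$mut_class == "other"]),
                  collapse = ", "))
  out
}

#' Read a probes-by-samples expression matrix
#'
#' @param path TSV with probe IDs in the first column, one column per sample.
#' @return numeric matrix, probes in rows (rownames = probe IDs).
#' @export
readExpressionMatrix <- function(path) {
  if (!file.exists(path)) stop("expression matrix not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                           stringsAsFactors = FALSE, check.names = FALSE)
  as.matrix(tab)
}

#' Read a two-column copy-number-ratio table
#'
#' @param path TSV with columns `cell_line` and `cn_ratio`.
#' @return named numeric vector of CN ratios.
#' @export
readCNTable <- function(path) {
  if (!file.exists(path)) stop("CN table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (nm in c("cell_line", "cn_ratio"))
    if (!nm %in% colnames(tab)) stop("CN table is missing column '", nm, "'")
  stats::setNames(as.numeric(tab$cn_ratio), as.character(tab$cell_line))
}

#' Read a prediction / observed-sensitivity table
#'
#' @param path TSV with columns `cell_line`, `compound`, `prediction`,
#'   `observed`; values `sensitive`, `insensitive` or empty/NA for missing.
#' @return data.frame with those four columns, missing coded NA.
#' @export
readResponseTable <- function(path) {
  if (!file.exists(path)) stop("response table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", "", "missing"))
  for (nm in c("cell_line", "compound", "prediction", "observed"))
    if (!nm %in% colnames(tab)) stop("response table is missing column '", nm, "'")
  tab$cell_line <- as.character(tab$cell_line)
  tab$compound <- as.character(tab$compound)
  tab[c("cell_line", "compound", "prediction", "observed")]
}

#' Assemble a TP53Cohort from the four evidence tables
#'
#' One record per cell line appearing in the response table, with mutation,
#' expression and CN evidence joined by canonicalized cell-line name.
#' Lines missing an evidence channel get NA there (the caller then skips
#' that rule) and are reported in a message; duplicated cell-line rows in
#' the response table for one compound are an error.
#'
#' @param mutPath,exprPath,cnPath,responsePath the four TSV files (see
#'   [readMutationTable()], [readExpressionMatrix()], [readCNTable()],
#'   [readResponseTable()]).
#' @param probeId expression-matrix row holding the TP53 probe.
#'   Default `"201746_at"`.
#' @param dialect passed to [readMutationTable()].
#' @return A [TP53Cohort()].
#' @export
readCohort <- function(mutPath, exprPath, cnPath, responsePath,
                       probeId = "201746_at",
                       dialect = c(cell_line = "cell_line", gene = "gene",
                                   protein_change = "protein_change",
                                   alt_reads = "alt_reads",
                                   ref_reads = "ref_reads")) {
  muts <- readMutationTable(mutPath, dialect = dialect)
  expr <- readExpressionMatrix(exprPath)
  if (!probeId %in% rownames(expr))
    stop("probe '", probeId, "' not found in expression matrix")
  cn <- readCNTable(cnPath)
  resp <- readResponseTable(responsePath)

  dupKey <- paste(canonicalLineName(resp$cell_line), resp$compound)
  if (anyDuplicated(dupKey)) {
    dups <- unique(resp$cell_line[duplicated(dupKey)])
    stop("duplicate cell-line row(s) in response table: ",
         paste(dups, collapse = ", "))
  }

  lines <- resp$cell_line[!duplicated(canonicalLineName(resp$cell_line))]
  key <- canonicalLineName(lines)
  exprKey <- canonicalLineName(colnames(expr))
  cnKey <- canonicalLineName(names(cn))

  mrna <- as.numeric(expr[probeId, match(key, exprKey)])
  cnr <- as.numeric(cn[match(key, cnKey)])

  miss <- lines[is.na(mrna) | is.na(cnr)]
  if (length(miss))
    message("evidence missing for: ", paste(miss, collapse = ", "),
            " (affected rules will be skipped)")

  mt <- muts[canonicalLineName(muts$cell_line) %in% key, , drop = FALSE]
  TP53Cohort(
    lineData = data.frame(cell_line = lines, tp53_mrna = mrna,
                          cn_ratio = cnr, stringsAsFactors = FALSE),
    mutations = mt,
    response = resp)
}

#' Write a cohort back to the four evidence-table dialects
#'
#' Emits `mutations.tsv`, `expression.tsv` (single-probe matrix),
#' `cn_ratio.tsv` and `response.tsv` under `dir`, in the exact formats
#' [readCohort()] reads. Output is byte-stable for a fixed cohort.
#'
#' @param cohort a [TP53Cohort()].
#' @param dir output directory, created if needed.
#' @param probeId row name used for the expression matrix.
#' @return invisibly, the four file paths.
#' @export
writeCohort <- function(cohort, dir, probeId = "201746_at") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ld <- as.data.frame(lineData(cohort))
  paths <- file.path(dir, c("mutations.tsv", "expression.tsv",
                            "cn_ratio.tsv", "response.tsv"))
  names(paths) <- c("mutations", "expression", "cn", "response")

  mt <- as.data.frame(mutations(cohort))
  mt <- cbind(gene = rep("TP53", nrow(mt)), mt)[, c("cell_line", "gene",
         "protein_change", "alt_reads", "ref_reads")]
  .writeTsv(mt, paths["mutations"])

  em <- matrix(ld$tp53_mrna, nrow = 1,
               dimnames = list(probeId, ld$cell_line))
  emdf <- data.frame(probe = rownames(em), em, check.names = FALSE)
  .writeTsv(emdf, paths["expression"])

  .writeTsv(data.frame(cell_line = ld$cell_line, cn_ratio = ld$cn_ratio),
            paths["cn"])
  .writeTsv(as.data.frame(responseData(cohort)), paths["response"])
  invisible(paths)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", eol = "\n")
}

.fmt3 <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = 3))
}

#' Write the evidence-trail and metrics reports
#'
#' Produces `evidence_trail.tsv` (one row per cell line: status, evidence
#' codes, annotation flags, the full rule trail, and — when the cohort is
#' supplied — that compound's prediction and observed call, so every metric
#' is recomputable from the trail alone) and `metrics.json` (one block per
#' evaluation scenario, keys sorted, floats fixed at 3 decimals). Both are
#' byte-stable for fixed input, and both echo the thresholds in force.
#'
#' @param calls a [callCohort()] result (`TP53StatusCalls`).
#' @param scenarios list of `EvaluationScenario` objects (may be empty).
#' @param dir output directory, created if needed.
#' @param cohort optional [TP53Cohort()]; when given, per-compound
#'   prediction/observed columns are added to the trail.
#' @param compound compound whose response columns to include; default the
#'   first compound in the cohort.
#' @return invisibly, the two file paths.
#' @export
writeReport <- function(calls, scenarios = list(), dir, cohort = NULL,
                        compound = NULL) {
  stopifnot(is(calls, "TP53StatusCalls"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trailPath <- file.path(dir, "evidence_trail.tsv")
  metricsPath <- file.path(dir, "metrics.json")

  th <- thresholds(calls)
  header <- paste0("# thresholds: mrna_loss<", th@mrnaLoss,
                   " cn_biallelic<", th@cnBiallelicLoss,
                   " cn_allelic<", th@cnAllelicLoss,
                   " borderline_margin=", th@borderlineMargin,
                   " classes=", paste(th@inactivatingClasses, collapse = ","))

  cl <- calls@calls
  df <- data.frame(
    cell_line = as.character(cl$cell_line),
    status = as.character(cl$status),
    evidence = vapply(cl$evidence, function(e)
      if (length(e)) paste(sort(e), collapse = ";") else ".", character(1)),
    annotations = vapply(cl$annotations, function(a)
      if (length(a)) paste(sort(a), collapse = ";") else ".", character(1)),
    nmd_likely = vapply(cl$annotations, function(a)
      "nmd_likely" %in% a, logical(1)),
    borderline = vapply(cl$annotations, function(a)
      "borderline_mrna" %in% a, logical(1)),
    stringsAsFactors = FALSE)
  if (!is.null(cohort)) {
    rs <- as.data.frame(responseData(cohort))
    if (is.null(compound)) compound <- compounds(cohort)[1]
    rs <- rs[rs$compound == compound, , drop = FALSE]
    idx <- match(canonicalLineName(df$cell_line),
                 canonicalLineName(rs$cell_line))
    df$compound <- compound
    df$prediction <- rs$prediction[idx]
    df$observed <- rs$observed[idx]
  }
  df$trail <- vapply(cl$trail, paste, character(1), collapse = " | ")

  con <- file(trailPath, open = "wb")
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", eol = "\n")
  close(con)

  scen <- lapply(scenarios, function(s) {
    m <- metrics(s)
    ct <- counts(m)
    list(compound = s@compound,
         counts = list(fn = ct[["fn"]], fp = ct[["fp"]],
                       n = ct[["n"]], tn = ct[["tn"]], tp = ct[["tp"]]),
         metrics = list(npv = .fmt3(npv(m)),
                        ppv = .fmt3(ppv(m)),
                        response_rate = .fmt3(responseRate(m)),
                        sensitivity = .fmt3(sensitivity(m)),
                        specificity = .fmt3(specificity(m))),
         removed_lines = sort(s@removedLines))
  })
  names(scen) <- vapply(scenarios, function(s) s@label, character(1))
  doc <- list(scenarios = scen[order(names(scen))],
              thresholds = list(
                borderline_margin = th@borderlineMargin,
                cn_allelic_loss = th@cnAllelicLoss,
                cn_biallelic_loss = th@cnBiallelicLoss,
                inactivating_classes = sort(th@inactivatingClasses),
                mrna_loss = th@mrnaLoss))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(json, metricsPath)
  invisible(c(trail = trailPath, metrics = metricsPath))
}
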