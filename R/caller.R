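## The core procedure: integrate mutation, copy-number and expression
## evidence into a TP53 status call per cell line. Three independent rules
## contribute evidence; status is inactivated iff any rule fires:
##   R1  any mutation of an inactivating class
##   R2  TP53 mRNA below the mRNA-loss cutoff (MAS5-150 units)
##   R3  CN ratio below the bi-allelic-loss cutoff
## Hemizygous loss (cnBiallelicLoss <= CN < cnAllelicLoss) only annotates:
## one wild-type allele can suffice, so it never inactivates by itself.
## A just-above-cutoff mRNA value is flagged borderline but never flips a
## call. Frameshift/nonsense mutation plus mRNA loss is annotated as likely
## nonsense-mediated decay.

#' Call TP53 status for a single cell line
#'
#' Evaluates the three evidence rules on one line's evidence bundle and
#' returns the call with its evidence set, annotations and a human-readable
#' trail of every rule tested. Missing channels (NA) are skipped and noted
#' in the trail; a line with all three channels missing is uncallable.
#'
#' @param cellLine line identifier (used in messages and the trail).
#' @param mutClasses character vector of this line's TP53 mutation classes
#'   (see [MUTATION_CLASSES]); may be empty. Optionally named by protein
#'   change for a richer trail.
#' @param tp53Mrna TP53 mRNA value in MAS5-150 units, or NA.
#' @param cnRatio CN ratio at the TP53 locus (1 = diploid), or NA.
#' @param thresholds a [TP53Thresholds()].
#' @return list with elements `cell_line`, `status` ("inactivated" /
#'   "likely_wt"), `evidence` (character subset of mutation, mrna_loss,
#'   biallelic_loss), `annotations` (subset of allelic_loss, nmd_likely,
#'   borderline_mrna) and `trail` (character vector of rule firings).
#' @examples
#' callTP53Status("KASUMI-1", c("p.R248Q" = "missense"), 265, 0.54)
#' callTP53Status("HDLM-2", character(), 1, 0.94)
#' @export
callTP53Status <- function(cellLine, mutClasses = character(),
                           tp53Mrna = NA_real_, cnRatio = NA_real_,
                           thresholds = TP53Thresholds()) {
  stopifnot(is(thresholds, "TP53Thresholds"))
  t <- thresholds
  if (length(mutClasses) == 0L && is.na(tp53Mrna) && is.na(cnRatio))
    stop("uncallable line '", cellLine, "': all three evidence channels missing")

  evid <- character()
  anno <- character()
  trl <- character()

  ## R1: inactivating mutation
  if (length(mutClasses)) {
    lab <- if (is.null(names(mutClasses))) mutClasses else
      paste0(names(mutClasses), " (", mutClasses, ")")
    hit <- mutClasses %in% t@inactivatingClasses
    trl <- c(trl, paste0("R1 mutation: ", paste(lab, collapse = ", "),
                         if (any(hit)) " -> inactivating" else " -> not inactivating"))
    if (any(hit)) evid <- c(evid, "mutation")
  } else {
    trl <- c(trl, "R1 mutation: none on record")
  }

  ## R2: mRNA loss (strict '<'; the cutoff value itself is not loss)
  if (is.na(tp53Mrna)) {
    trl <- c(trl, "R2 mRNA: value missing, rule skipped")
  } else {
    fired <- tp53Mrna < t@mrnaLoss
    trl <- c(trl, paste0("R2 mRNA: ", tp53Mrna,
                         if (fired) paste0(" < ", t@mrnaLoss, " -> mRNA loss")
                         else paste0(" >= ", t@mrnaLoss, " -> expressed")))
    if (fired) evid <- c(evid, "mrna_loss")
    if (!fired && tp53Mrna < t@mrnaLoss + t@borderlineMargin) {
      anno <- c(anno, "borderline_mrna")
      trl <- c(trl, paste0("R2b mRNA ", tp53Mrna, " in borderline zone [",
                           t@mrnaLoss, ", ", t@mrnaLoss + t@borderlineMargin,
                           ") -> flagged, call unchanged"))
    }
  }

  ## R3: bi-allelic copy-number loss; allelic loss annotates only
  if (is.na(cnRatio)) {
    trl <- c(trl, "R3 CN: value missing, rule skipped")
  } else if (cnRatio < t@cnBiallelicLoss) {
    evid <- c(evid, "biallelic_loss")
    trl <- c(trl, paste0("R3 CN: ", cnRatio, " < ", t@cnBiallelicLoss,
                         " -> bi-allelic loss"))
  } else if (cnRatio < t@cnAllelicLoss) {
    anno <- c(anno, "allelic_loss")
    trl <- c(trl, paste0("R3 CN: ", cnRatio, " in [", t@cnBiallelicLoss,
                         ", ", t@cnAllelicLoss,
                         ") -> allelic loss (annotation only)"))
  } else {
    trl <- c(trl, paste0("R3 CN: ", cnRatio, " >= ", t@cnAllelicLoss,
                         " -> no DNA loss"))
  }

  ## NMD inference: truncating mutation with expression loss
  if ("mutation" %in% evid && "mrna_loss" %in% evid &&
      any(mutClasses %in% c("frameshift", "nonsense"))) {
    anno <- c(anno, "nmd_likely")
    trl <- c(trl, "NMD: truncating mutation + mRNA loss -> nonsense-mediated decay likely")
  }

  statusCall <- if (length(evid)) "inactivated" else "likely_wt"
  trl <- c(trl, paste0("status: ", statusCall,
                       " (evidence: ", if (length(evid))
                         paste(sort(evid), collapse = ", ") else "none", ")"))
  list(cell_line = cellLine, status = statusCall,
       evidence = sort(unique(evid)), annotations = sort(unique(anno)),
       trail = trl)
}

#' Call TP53 status for every line of a cohort
#'
#' Applies [callTP53Status()] to each record, preserving order, and logs
#' summary counts. Per-line errors are re-raised with the cell line named.
#'
#' @param cohort a [TP53Cohort()] with at least one line.
#' @param thresholds a [TP53Thresholds()].
#' @return A `TP53StatusCalls` object; see [status()], [evidence()],
#'   [annotations()], [trail()].
#' @examples
#' coh <- table1Cohort()
#' calls <- callCohort(coh)
#' table(status(calls))
#' @export
callCohort <- function(cohort, thresholds = TP53Thresholds()) {
  stopifnot(is(cohort, "TP53Cohort"))
  ld <- lineData(cohort)
  if (nrow(ld) == 0L) stop("callCohort: empty cohort")
  mt <- as.data.frame(mutations(cohort))
  mtKey <- canonicalLineName(mt$cell_line)

  res <- lapply(seq_len(nrow(ld)), function(i) {
    line <- as.character(ld$cell_line[i])
    sel <- mtKey == canonicalLineName(line)
    mc <- stats::setNames(mt$mut_class[sel], mt$protein_change[sel])
    tryCatch(
      callTP53Status(line, mc, ld$tp53_mrna[i], ld$cn_ratio[i], thresholds),
      error = function(e) stop("call failed for cell line '", line, "': ",
                               conditionMessage(e), call. = FALSE))
  })

  calls <- DataFrame(
    cell_line = vapply(res, `[[`, character(1), "cell_line"),
    status = vapply(res, `[[`, character(1), "status"),
    evidence = IRanges::CharacterList(lapply(res, `[[`, "evidence")),
    annotations = IRanges::CharacterList(lapply(res, `[[`, "annotations")),
    trail = IRanges::CharacterList(lapply(res, `[[`, "trail")))
  out <- new("TP53StatusCalls", calls = calls, thresholds = thresholds)
  st <- status(out)
  nb <- sum(vapply(annotations(out), function(a) "borderline_mrna" %in% a,
                   logical(1)))
  message(sum(st == "inactivated"), " inactivated, ",
          sum(st == "likely_wt"), " likely_wt (", nb, " borderline)")
  out
}
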