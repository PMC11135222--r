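# Conversion of docking interface scores into binding classes.

#' Classify a docking interface score into a binding band
#'
#' Interface scores (Rosetta SnugDock units; lower = better predicted
#' binding) are banded: scores above `upper` (-8.0) are `POOR` binders
#' outright, scores below `lower` (-9.0) are `GOOD` outright, and scores in
#' the closed interval `[lower, upper]` — including the endpoints — are
#' `REVIEW`: in the original protocol these complexes were inspected
#' visually; here they are flagged for resolution by [resolveReview()].
#'
#' @param score Numeric vector of interface scores; must be finite.
#' @param upper Poor-binding threshold (default -8.0).
#' @param lower Good-binding threshold (default -9.0); must be `< upper`.
#' @return Character vector over [bindingClasses()].
#' @export
#' @examples
#' classifyInterfaceScore(c(-7.5, -9.5, -8.5))  # POOR, GOOD, REVIEW
classifyInterfaceScore <- function(score, upper = -8.0, lower = -9.0) {
  stopifnot(length(upper) == 1L, length(lower) == 1L, lower < upper)
  if (any(!is.finite(score)))
    stop("interface scores must be finite; offending index ",
         which(!is.finite(score))[1L])
  out <- rep("REVIEW", length(score))
  out[score > upper] <- "POOR"
  out[score < lower] <- "GOOD"
  out
}

#' Label a pair table from its docking scores
#'
#' Applies [classifyInterfaceScore()] to every record with a docking score;
#' records without a score keep their existing label (pairs labeled from a
#' database rather than from docking carry no score).
#'
#' @param table A [PairTable-class].
#' @inheritParams classifyInterfaceScore
#' @return The relabeled table; `label_provenance` records `"interface_score"`
#'   for relabeled rows.
#' @export
labelPairTable <- function(table, upper = -8.0, lower = -9.0) {
  stopifnot(is(table, "PairTable"))
  rec <- records(table)
  has <- !is.na(rec$docking_score)
  rec$label[has] <- classifyInterfaceScore(rec$docking_score[has],
                                           upper, lower)
  if (is.null(rec$label_provenance))
    rec$label_provenance <- NA_character_
  rec$label_provenance[has] <- "interface_score"
  initialize(table, records = rec)
}

#' Resolve REVIEW labels
#'
#' The REVIEW band was resolved by visual docking inspection in the original
#' protocol; this operation ingests that outcome. Rules: `"manual_file"`
#' applies a per-row resolution table, `"drop"` removes REVIEW rows,
#' `"all_good"`/`"all_poor"` assign the whole band to one class.
#'
#' @param table A [PairTable-class].
#' @param rule One of `"manual_file"`, `"drop"`, `"all_good"`, `"all_poor"`.
#' @param resolutions For `"manual_file"`: a data.frame with columns `row`
#'   (row number in `table`) and `label` (`GOOD`/`POOR`) covering every
#'   REVIEW row.
#' @return The table with no REVIEW labels; `label_provenance` records
#'   `"review:<rule>"` for resolved rows.
#' @export
resolveReview <- function(table,
                          rule = c("manual_file", "drop", "all_good",
                                   "all_poor"),
                          resolutions = NULL) {
  rule <- match.arg(rule)
  stopifnot(is(table, "PairTable"))
  rec <- records(table)
  if (is.null(rec$label_provenance)) rec$label_provenance <- NA_character_
  rev <- which(!is.na(rec$label) & rec$label == "REVIEW")
  if (rule == "manual_file") {
    if (is.null(resolutions))
      stop("rule 'manual_file' requires a resolutions table")
    stopifnot(all(c("row", "label") %in% names(resolutions)),
              all(resolutions$label %in% c("GOOD", "POOR")))
    unresolved <- setdiff(rev, resolutions$row)
    if (length(unresolved) > 0L)
      stop("REVIEW row(s) without a resolution: ",
           paste(head(unresolved), collapse = ", "))
    hit <- intersect(resolutions$row, rev)
    rec$label[hit] <-
      resolutions$label[match(hit, resolutions$row)]
    rec$label_provenance[hit] <- "review:manual_file"
  } else if (rule == "drop") {
    if (length(rev) > 0L) {
      rec <- rec[-rev, , drop = FALSE]
      rownames(rec) <- NULL
    }
  } else {
    to <- if (rule == "all_good") "GOOD" else "POOR"
    rec$label[rev] <- to
    rec$label_provenance[rev] <- paste0("review:", rule)
  }
  initialize(table, records = rec)
}
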