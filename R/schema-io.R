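# Pair-table CSV reader/writer and FASTA import for CDR sequences.

#' Read a pair-table CSV
#'
#' Reads the 22-column antibody-antigen pair table (six CDR sequences,
#' twelve physicochemical feature columns, epitope, docking score, antigen,
#' docking result), validates it against the dialect, canonicalizes the
#' binding labels to GOOD/POOR/REVIEW, and quarantines (or rejects) rows
#' with malformed amino-acid strings.
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect A [pairTableDialect()] describing headers, label
#'   spellings, and invalid-row policy.
#' @return A [PairTable-class]. Quarantined rows (if any) are recorded in
#'   `attr(, "rejected")`, a data.frame with the offending row numbers and
#'   reasons; `attr(, "nInput")` carries the input row count.
#' @export
#' @seealso [writePairTable()]
readPairTable <- function(path, dialect = pairTableDialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    read.csv(path, check.names = FALSE, colClasses = "character"),
    error = function(e) stop("cannot parse CSV ", path, ": ",
                             conditionMessage(e)))
  if (base::nrow(raw) == 0L && length(names(raw)) == 0L)
    stop("empty file (no header row): ", path)
  headers <- dialect$headers
  missing <- setdiff(unname(headers), names(raw))
  if (length(missing) > 0L)
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  rec <- as.data.frame(raw[, unname(headers)], stringsAsFactors = FALSE)
  names(rec) <- names(headers)

  reasons <- rep(NA_character_, base::nrow(rec))
  alphabet <- .dialectAlphabet(dialect)
  for (cc in .CDR_COLS) {
    rec[[cc]] <- toupper(trimws(rec[[cc]]))
    bad <- !.validSeq(rec[[cc]], alphabet)
    reasons[bad & is.na(reasons)] <-
      paste0("invalid amino-acid string in ", cc)
  }
  bad_ag <- is.na(rec$antigen) | !nzchar(trimws(rec$antigen))
  reasons[bad_ag & is.na(reasons)] <- "empty antigen identifier"

  lab <- .canonicalLabel(rec$label, dialect)
  unrec <- attr(lab, "unrecognized")
  reasons[unrec][is.na(reasons[unrec])] <- "unrecognized binding label"
  rec$label <- as.character(lab)

  for (fc in c(.FEATURE_COLS, "docking_score")) {
    v <- suppressWarnings(as.numeric(rec[[fc]]))
    rec[[fc]] <- ifelse(nzchar(trimws(rec[[fc]])) & !is.na(rec[[fc]]),
                        v, NA_real_)
  }

  keep <- is.na(reasons)
  if (!all(keep)) {
    msg <- paste0(sum(!keep), " malformed row(s), e.g. row ",
                  which(!keep)[1L], ": ", reasons[!keep][1L])
    if (dialect$onInvalid == "error") stop(msg)
    warning(msg, "; quarantined")
  }
  out <- PairTable(rec[keep, , drop = FALSE], dialect)
  attr(out, "rejected") <- data.frame(row = which(!keep),
                                      reason = reasons[!keep],
                                      stringsAsFactors = FALSE)
  attr(out, "nInput") <- base::nrow(rec)
  out
}

#' Write a pair table as CSV
#'
#' Writes the 22 canonical columns under the dialect's headings. Labels are
#' serialized with the dialect's output spellings; missing docking scores
#' become empty cells. `readPairTable(writePairTable(x))` reproduces `x`
#' field-for-field (floats to full double precision).
#'
#' @param table A [PairTable-class].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writePairTable <- function(table, path) {
  stopifnot(is(table, "PairTable"))
  dialect <- table@dialect
  rec <- records(table)[, .CANONICAL_COLS, drop = FALSE]
  rec$label <- c(GOOD = dialect$goodOut, POOR = dialect$poorOut,
                 REVIEW = dialect$reviewOut)[rec$label]
  for (fc in c(.FEATURE_COLS, "docking_score"))
    rec[[fc]] <- ifelse(is.na(rec[[fc]]), "",
                        format(rec[[fc]], digits = 17, trim = TRUE,
                               scientific = FALSE))
  names(rec) <- unname(dialect$headers[.CANONICAL_COLS])
  ok <- tryCatch({
    write.csv(rec, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write pair table to: ", path)
  invisible(path)
}

#' Read CDR sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences; names are the
#'   FASTA record ids (first whitespace-delimited token).
#' @export
readCdrFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  setNames(toupper(as.character(set)), ids)
}
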