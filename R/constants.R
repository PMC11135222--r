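# Shared constants: amino-acid alphabet, canonical column names, CSV dialect.

#' The 20 standard one-letter amino-acid codes
#'
#' @return Character vector of the 20 standard residues, alphabetical.
#' @export
#' @examples aminoAcids()
aminoAcids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# canonical (internal) column names of a pair table, in on-disk order
.CDR_COLS <- c("h_cdr1", "h_cdr2", "h_cdr3", "l_cdr1", "l_cdr2", "l_cdr3")
.FEATURE_COLS <- c(
  "hyd_l_cdr1", "pi_l_cdr1", "hyd_l_cdr2", "pi_l_cdr2",
  "hyd_l_cdr3", "pi_l_cdr3", "hyd_h_cdr1", "pi_h_cdr1",
  "hyd_h_cdr2", "pi_h_cdr2", "hyd_h_cdr3", "pi_h_cdr3"
)
.META_COLS <- c("epitope", "docking_score", "antigen", "label")
.CANONICAL_COLS <- c(.CDR_COLS, .FEATURE_COLS, .META_COLS)

# the 22 published column headings, keyed by canonical name
.DEFAULT_HEADERS <- c(
  h_cdr1 = "H chain CDR1 sequence",
  h_cdr2 = "H chain CDR2 sequence",
  h_cdr3 = "H chain CDR3 sequence",
  l_cdr1 = "L chain CDR1 sequence",
  l_cdr2 = "L chain CDR2 sequence",
  l_cdr3 = "L chain CDR3 sequence",
  hyd_l_cdr1 = "Hydrophilicity of L CDR1",
  pi_l_cdr1 = "pI of L CDR1",
  hyd_l_cdr2 = "Hydrophilicity of L CDR2",
  pi_l_cdr2 = "pI of L CDR2",
  hyd_l_cdr3 = "Hydrophilicity of L CDR3",
  pi_l_cdr3 = "pI of L CDR3",
  hyd_h_cdr1 = "Hydrophilicity of H CDR1",
  pi_h_cdr1 = "pI of H CDR1",
  hyd_h_cdr2 = "Hydrophilicity of H CDR2",
  pi_h_cdr2 = "pI of H CDR2",
  hyd_h_cdr3 = "Hydrophilicity of H CDR3",
  pi_h_cdr3 = "pI of H CDR3",
  epitope = "Antigen Epitope",
  docking_score = "Rosetta Docking score",
  antigen = "Antigen",
  label = "Docking result"
)

.BINDING_CLASSES <- c("GOOD", "POOR", "REVIEW")

#' Binding class vocabulary
#'
#' Binding labels are canonicalized to `GOOD` (good affinity), `POOR`
#' (low affinity) or the transient `REVIEW` state used for docking scores
#' in the visually-inspected band. `REVIEW` must be resolved (see
#' [resolveReview()]) before training or evaluation.
#'
#' @return Character vector `c("GOOD", "POOR", "REVIEW")`.
#' @export
bindingClasses <- function() .BINDING_CLASSES

#' Describe the pair-table CSV dialect
#'
#' The deposited data set's exact header spellings and label vocabulary are
#' not pinned down, so the reader/writer are parameterized by a dialect: the
#' mapping from canonical field names to CSV headings, the accepted label
#' spellings, and how malformed rows are treated.
#'
#' @param headers Named character vector mapping the 22 canonical field names
#'   to CSV column headings. Default: the published headings.
#' @param goodLabels,poorLabels,reviewLabels Accepted (case-insensitive)
#'   spellings for each binding class in the "Docking result" column.
#' @param goodOut,poorOut,reviewOut Spellings written back out.
#' @param allowX Logical; accept `X` (unknown residue) in CDR sequences.
#' @param onInvalid `"quarantine"` (drop malformed rows, record reasons) or
#'   `"error"`.
#' @return A list with class `"PairTableDialect"`.
#' @export
#' @examples
#' d <- pairTableDialect(goodLabels = c("yes", "binder"))
pairTableDialect <- function(headers = .DEFAULT_HEADERS,
                             goodLabels = c("GOOD", "YES", "GOOD AFFINITY", "1", "TRUE"),
                             poorLabels = c("POOR", "NO", "LOW AFFINITY", "BAD", "0", "FALSE"),
                             reviewLabels = "REVIEW",
                             goodOut = "YES", poorOut = "NO", reviewOut = "REVIEW",
                             allowX = FALSE,
                             onInvalid = c("quarantine", "error")) {
  onInvalid <- match.arg(onInvalid)
  stopifnot(is.character(headers))
  missing <- setdiff(.CANONICAL_COLS, names(headers))
  if (length(missing) > 0L) {
    stop("dialect headers missing canonical fields: ",
         paste(missing, collapse = ", "))
  }
  structure(
    list(headers = headers[.CANONICAL_COLS],
         goodLabels = toupper(goodLabels),
         poorLabels = toupper(poorLabels),
         reviewLabels = toupper(reviewLabels),
         goodOut = goodOut, poorOut = poorOut, reviewOut = reviewOut,
         allowX = isTRUE(allowX), onInvalid = onInvalid),
    class = "PairTableDialect"
  )
}

# residues permitted by a dialect
.dialectAlphabet <- function(dialect) {
  if (isTRUE(dialect$allowX)) c(aminoAcids(), "X") else aminoAcids()
}

# TRUE where x is a non-empty string over `alphabet`
.validSeq <- function(x, alphabet = aminoAcids()) {
  ok <- !is.na(x) & nzchar(x)
  pat <- paste0("^[", paste(alphabet, collapse = ""), "]+$")
  ok & grepl(pat, x)
}

.canonicalLabel <- function(x, dialect = pairTableDialect()) {
  up <- toupper(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[up %in% dialect$goodLabels] <- "GOOD"
  out[up %in% dialect$poorLabels] <- "POOR"
  out[up %in% dialect$reviewLabels] <- "REVIEW"
  bad <- !is.na(x) & nzchar(trimws(as.character(x))) & is.na(out)
  attr(out, "unrecognized") <- which(bad)
  out
}
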