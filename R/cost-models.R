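# Substitution cost models: identity and BLOSUM62-derived.

#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-separated scoring-matrix format distributed with
#' BLAST (`#` comments, a header row of residue letters, one labeled row per
#' residue).
#'
#' @param path Path to the matrix file.
#' @return Integer score matrix with residue dimnames.
#' @export
#' @examples
#' m <- readSubstitutionMatrix(system.file("extdata", "BLOSUM62.txt",
#'                                         package = "CDRknn"))
#' m["L", "I"]
readSubstitutionMatrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a substitution matrix file: ", path)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n <- length(header)
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  if (any(lengths(rows) != n + 1L))
    stop("malformed matrix row(s): expected ", n + 1L, " fields")
  labels <- vapply(rows, `[`, "", 1L)
  m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1L])))
  dimnames(m) <- list(labels, header)
  if (!identical(rownames(m), colnames(m)))
    stop("matrix row and column labels disagree")
  storage.mode(m) <- "integer"
  m
}

# cached copy of the embedded BLOSUM62 matrix (full 24-letter rendition)
.pkgCache <- new.env(parent = emptyenv())

#' The embedded BLOSUM62 scoring matrix
#'
#' The standard half-bit integer BLOSUM62 matrix as distributed with NCBI
#' BLAST, read from the package's data files. The 20x20 block over the
#' standard residues sums to -426 with diagonal sum 116; this checksum is
#' verified on first load.
#'
#' @param full Logical; return the full 24-letter matrix (including B, Z, X,
#'   `*`) rather than the standard 20-residue block.
#' @return Integer score matrix.
#' @export
#' @examples
#' blosum62Matrix()["W", "W"]
blosum62Matrix <- function(full = FALSE) {
  if (is.null(.pkgCache$blosum62)) {
    path <- system.file("extdata", "BLOSUM62.txt", package = "CDRknn")
    m <- readSubstitutionMatrix(path)
    core <- m[aminoAcids(), aminoAcids()]
    if (sum(core) != -426L || sum(diag(core)) != 116L)
      stop("embedded BLOSUM62 matrix failed its checksum")
    .pkgCache$blosum62 <- m
  }
  m <- .pkgCache$blosum62
  if (full) m else m[aminoAcids(), aminoAcids()]
}

# append an X row/column whose mismatch cost is the mean off-diagonal cost
.addXCosts <- function(costs) {
  aa <- rownames(costs)
  avg <- mean(costs[upper.tri(costs)])
  costs <- rbind(cbind(costs, X = avg), X = c(rep(avg, length(aa)), 0))
  rownames(costs) <- c(aa, "X")
  costs
}

#' Identity (unit-cost) substitution model
#'
#' The classic Levenshtein setting: substituting any residue for a different
#' one costs 1, as do insertions and deletions.
#'
#' @param indelCost Insertion/deletion cost (default 1).
#' @param allowX Logical; extend the alphabet with `X`, which mismatches any
#'   residue at the model's average mismatch cost (here, 1).
#' @return A [SubstitutionCostModel-class].
#' @export
#' @examples
#' editDistance("KASQ", "KASE", identityCostModel())
identityCostModel <- function(indelCost = 1, allowX = FALSE) {
  aa <- aminoAcids()
  costs <- matrix(1, length(aa), length(aa), dimnames = list(aa, aa))
  diag(costs) <- 0
  if (allowX) costs <- .addXCosts(costs)
  new("SubstitutionCostModel", name = "identity", costs = costs,
      indelCost = as.numeric(indelCost))
}

#' Derive a cost model from a substitution scoring matrix
#'
#' Converts similarity scores `S` into mismatch costs. With the default
#' `"clamped"` normalization,
#' `cost(a, b) = min(1, max(0, 1 - 2 * S_ab / (S_aa + S_bb)))`,
#' so identical residues cost 0, conservative substitutions (score close to
#' the self-scores) are cheap, and costs stay in `[0, 1]`, commensurate with
#' the identity model. The `"linear"` alternative uses
#' `(S_aa + S_bb) / 2 - S_ab`, rescaled linearly to `[0, 1]` by its maximum.
#'
#' @param scores Integer/numeric similarity matrix with residue dimnames
#'   covering the 20 standard residues.
#' @param normalization `"clamped"` (default) or `"linear"`.
#' @param indelCost Insertion/deletion cost (default 1, the identity-model
#'   mismatch scale).
#' @param name Model name recorded in results.
#' @param allowX Logical; extend with an average-cost `X` residue.
#' @return A [SubstitutionCostModel-class].
#' @export
substitutionCostModel <- function(scores,
                                  normalization = c("clamped", "linear"),
                                  indelCost = 1, name = "custom",
                                  allowX = FALSE) {
  normalization <- match.arg(normalization)
  aa <- aminoAcids()
  if (!all(aa %in% rownames(scores)))
    stop("scores must cover the 20 standard residues")
  s <- scores[aa, aa]
  self <- diag(s)
  denom <- outer(self, self, "+")
  costs <- switch(normalization,
    clamped = pmin(pmax(1 - 2 * s / denom, 0), 1),
    linear = {
      d <- denom / 2 - s
      d / max(d)
    })
  diag(costs) <- 0
  costs <- (costs + t(costs)) / 2  # guard against asymmetric input
  dimnames(costs) <- list(aa, aa)
  if (allowX) costs <- .addXCosts(costs)
  m <- new("SubstitutionCostModel", name = name, costs = costs,
           indelCost = as.numeric(indelCost))
  attr(m@costs, "normalization") <- NULL
  m
}

#' BLOSUM62-derived substitution cost model
#'
#' Costs derived from the BLOSUM62 matrix (see [substitutionCostModel()] for
#' the normalization), making biologically conservative substitutions
#' cheaper than radical ones in the generalized Levenshtein distance.
#'
#' @inheritParams substitutionCostModel
#' @return A [SubstitutionCostModel-class] named
#'   `"blosum62"`/`"blosum62-linear"`.
#' @export
#' @examples
#' m <- blosum62CostModel()
#' costMatrix(m)["L", "I"] < costMatrix(m)["L", "D"]
blosum62CostModel <- function(normalization = c("clamped", "linear"),
                              indelCost = 1, allowX = FALSE) {
  normalization <- match.arg(normalization)
  name <- if (normalization == "clamped") "blosum62" else "blosum62-linear"
  substitutionCostModel(blosum62Matrix(), normalization = normalization,
                        indelCost = indelCost, name = name, allowX = allowX)
}
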