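# Generalized Levenshtein distance, CDR distance vectors, antibody distance
# (Euclidean over the six CDRs), and the cross-antigen pair distance.

.alphabetString <- function(model) paste(rownames(model@costs), collapse = "")

#' Generalized Levenshtein distance between amino-acid strings
#'
#' Minimum total cost of insertions, deletions (each `indelCost(model)`) and
#' substitutions (the model's residue-pair cost) converting `a` into `b`,
#' computed by the standard dynamic program. With [identityCostModel()] this
#' is the classic Levenshtein distance.
#'
#' @param a,b Character vectors of sequences (recycled to a common length).
#'   Empty strings are allowed.
#' @param model A [SubstitutionCostModel-class].
#' @return Numeric vector of distances, `>= 0`.
#' @export
#' @examples
#' editDistance("KASQ", "KASE", identityCostModel())           # 1
#' editDistance("KASQ", "KASE", blosum62CostModel())           # graded cost
editDistance <- function(a, b, model = identityCostModel()) {
  stopifnot(is(model, "SubstitutionCostModel"))
  n <- max(length(a), length(b))
  a <- rep_len(toupper(as.character(a)), n)
  b <- rep_len(toupper(as.character(b)), n)
  if (anyNA(a) || anyNA(b)) stop("sequences must not be NA")
  edit_dist_pairs_cpp(a, b, model@costs, model@indelCost,
                      .alphabetString(model))
}

# all-pairs edit distances between two string vectors, cached over unique
# strings (pair tables contain many repeated CDRs)
.editDistCross <- function(x, y, model) {
  ux <- unique(x)
  uy <- unique(y)
  m <- edit_dist_cross_cpp(ux, uy, model@costs, model@indelCost,
                           .alphabetString(model))
  m[match(x, ux), match(y, uy), drop = FALSE]
}

#' Per-CDR distance vector between two antibodies
#'
#' The six generalized edit distances between equivalent CDRs (H1 vs H1,
#' ..., L3 vs L3).
#'
#' @param p,q [AntibodyCdrSet-class] objects.
#' @param model A [SubstitutionCostModel-class].
#' @return Named numeric vector of length 6.
#' @export
cdrDistanceVector <- function(p, q, model = blosum62CostModel()) {
  stopifnot(is(p, "AntibodyCdrSet"), is(q, "AntibodyCdrSet"))
  d <- editDistance(cdrs(p), cdrs(q), model)
  names(d) <- .CDR_COLS
  d
}

#' Euclidean antibody distance over the six CDRs
#'
#' The distance between two antibodies is the Euclidean norm of their CDR
#' distance vector: `sqrt(sum_i d(CDR_i(p), CDR_i(q))^2)` over the six CDRs.
#'
#' @inheritParams cdrDistanceVector
#' @return A single non-negative number.
#' @export
#' @examples
#' ab <- AntibodyCdrSet("GYTFTSYW", "IYPGDSDT", "ARWGGDGFYAMD",
#'                      "QSLLNSRTRKNY", "WASTRES", "KQSYNLYT")
#' antibodyDistance(ab, ab)  # 0
antibodyDistance <- function(p, q, model = blosum62CostModel()) {
  sqrt(sum(cdrDistanceVector(p, q, model)^2))
}

#' All-pairs antibody distance matrix for a pair table
#'
#' Computes the Euclidean CDR distance between every antibody of `x` and
#' every antibody of `y` (default: `x` against itself). This is the
#' workhorse behind K-NN search and leave-one-out cross-validation; repeated
#' CDR strings are deduplicated before the dynamic program runs.
#'
#' @param x,y [PairTable-class] objects (`y` defaults to `x`).
#' @param model A [SubstitutionCostModel-class].
#' @return Numeric `nrow(x)` x `nrow(y)` matrix.
#' @export
antibodyDistanceMatrix <- function(x, y = x, model = blosum62CostModel()) {
  stopifnot(is(x, "PairTable"), is(y, "PairTable"))
  rx <- records(x)
  ry <- records(y)
  acc <- matrix(0, base::nrow(rx), base::nrow(ry))
  for (cc in .CDR_COLS) {
    d <- .editDistCross(rx[[cc]], ry[[cc]], model)
    acc <- acc + d * d
  }
  sqrt(acc)
}

#' Distance between two antibody-antigen pairs (with cross-antigen penalty)
#'
#' The antibody distance, plus a fixed penalty of 1000 when the two records
#' involve different antigens. The penalty keeps nearest neighbors on the
#' same antigen whenever same-antigen training pairs exist, while still
#' allowing cross-antigen fallback.
#'
#' @param p,q Single-row [PairTable-class] objects (or a `PairTable` and a
#'   row index pair via `p[i]`).
#' @param model A [SubstitutionCostModel-class].
#' @param penalty Fixed cross-antigen penalty (default 1000).
#' @return List with `value` (the distance) and `sameAntigen` (logical).
#' @export
pairDistance <- function(p, q, model = blosum62CostModel(), penalty = 1000) {
  stopifnot(is(p, "PairTable"), is(q, "PairTable"),
            nrow(p) == 1L, nrow(q) == 1L)
  agp <- antigenIds(p)
  agq <- antigenIds(q)
  if (!nzchar(agp) || !nzchar(agq)) stop("records must carry an antigen id")
  same <- identical(agp, agq)
  d <- antibodyDistance(cdrSet(p, 1L), cdrSet(q, 1L), model)
  list(value = d + if (same) 0 else penalty, sameAntigen = same)
}

#' All-pairs distance matrix with the cross-antigen penalty applied
#'
#' @inheritParams antibodyDistanceMatrix
#' @param penalty Fixed penalty added where antigens differ (default 1000).
#' @return Numeric matrix of penalized pair distances.
#' @export
pairDistanceMatrix <- function(x, y = x, model = blosum62CostModel(),
                               penalty = 1000) {
  d <- antibodyDistanceMatrix(x, y, model)
  d + penalty * outer(antigenIds(x), antigenIds(y), "!=")
}
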