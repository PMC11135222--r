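# Distance-weighted K-nearest-neighbor classification.

# core vote: given distances to training rows (in training-row order) and
# their labels, pick the k nearest (stable ties by row order), weight votes
# by inverse distance, break weight ties toward `tieBreak`.
.knnVote <- function(d, labels, k, epsilon = 1e-8, tieBreak = "GOOD") {
  n <- length(d)
  if (k > n) stop("k (", k, ") exceeds the number of training records (", n, ")")
  ord <- order(d)[seq_len(k)]  # radix order: stable, earlier rows win ties
  w <- 1 / (d[ord] + epsilon)
  wg <- sum(w[labels[ord] == "GOOD"])
  wp <- sum(w[labels[ord] == "POOR"])
  label <- if (wg > wp) "GOOD" else if (wp > wg) "POOR" else tieBreak
  list(label = label, weightGood = wg, weightPoor = wp, index = ord,
       distance = d[ord], weight = w)
}

.checkTrainingLabels <- function(labels) {
  if (any(is.na(labels)))
    stop("training records must all be labeled GOOD or POOR")
  if (any(labels == "REVIEW"))
    stop("training table contains REVIEW labels; run resolveReview() first")
  invisible(labels)
}

#' Find the K nearest labeled pairs for a query
#'
#' Ranks the training records by penalized pair distance to the query
#' (Euclidean CDR distance plus the fixed cross-antigen penalty) and
#' returns the K nearest. Distance ties at the K-th rank keep earlier
#' training rows.
#'
#' @param query A single-row [PairTable-class] (the held-out pair).
#' @param training A [PairTable-class] of labeled pairs, not containing the
#'   query.
#' @param k Number of neighbors (default 2, the best-performing setting).
#' @param model A [SubstitutionCostModel-class].
#' @param penalty Cross-antigen penalty (default 1000).
#' @param epsilon Small constant in the inverse-distance weight
#'   `w = 1 / (d + epsilon)`.
#' @return Data.frame with one row per neighbor: `rank`, `index` (training
#'   row), `antigen`, `label`, `distance`, `weight`, `sameAntigen`; sorted
#'   ascending by distance.
#' @export
findNeighbors <- function(query, training, k = 2, model = blosum62CostModel(),
                          penalty = 1000, epsilon = 1e-8) {
  stopifnot(is(query, "PairTable"), nrow(query) == 1L,
            is(training, "PairTable"), nrow(training) >= 1L)
  d <- as.vector(pairDistanceMatrix(query, training, model, penalty))
  labs <- bindingLabels(training)
  v <- .knnVote(d, labs, k, epsilon)
  data.frame(rank = seq_len(k), index = v$index,
             antigen = antigenIds(training)[v$index],
             label = labs[v$index],
             distance = v$distance, weight = v$weight,
             sameAntigen = antigenIds(training)[v$index] ==
               antigenIds(query),
             stringsAsFactors = FALSE)
}

#' Distance-weighted K-NN prediction of binding
#'
#' Each of the K nearest training pairs votes its own label with weight
#' `1 / (distance + epsilon)`, so nearer neighbors count for more; the
#' predicted class is the one with the larger summed weight (ties go to
#' `tieBreak`, GOOD by default).
#'
#' @inheritParams findNeighbors
#' @param tieBreak Label predicted when the class weights tie exactly.
#' @return For a single-row query, a [Prediction-class]; for a multi-row
#'   query, a data.frame with columns `label`, `weightGood`, `weightPoor`.
#' @export
#' @examples
#' tab <- simulatePairTable(simConfig(nAntigens = 3, pairsPerAntigen = 6,
#'                                    seed = 7))
#' knnPredict(tab[1], tab[-1], k = 2)
knnPredict <- function(query, training, k = 2, model = blosum62CostModel(),
                       penalty = 1000, epsilon = 1e-8, tieBreak = "GOOD") {
  stopifnot(is(query, "PairTable"), is(training, "PairTable"))
  .checkTrainingLabels(bindingLabels(training))
  labs <- bindingLabels(training)
  D <- pairDistanceMatrix(query, training, model, penalty)
  if (nrow(query) == 1L) {
    v <- .knnVote(D[1L, ], labs, k, epsilon, tieBreak)
    nb <- data.frame(index = v$index,
                     antigen = antigenIds(training)[v$index],
                     label = labs[v$index], distance = v$distance,
                     weight = v$weight,
                     sameAntigen = antigenIds(training)[v$index] ==
                       antigenIds(query),
                     stringsAsFactors = FALSE)
    return(new("Prediction", label = v$label, weightGood = v$weightGood,
               weightPoor = v$weightPoor, neighbors = nb))
  }
  res <- lapply(seq_len(nrow(query)), function(i)
    .knnVote(D[i, ], labs, k, epsilon, tieBreak))
  data.frame(label = vapply(res, `[[`, "", "label"),
             weightGood = vapply(res, `[[`, 0, "weightGood"),
             weightPoor = vapply(res, `[[`, 0, "weightPoor"),
             stringsAsFactors = FALSE)
}
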