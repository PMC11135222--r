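# Per-feature voting ensemble: 13 single-feature K-NN voters (the CDR
# string distance plus 12 physicochemical columns) combined by simple
# majority. Not a conventional random forest: no bootstrapping, no feature
# subsampling, no impurity splits.

#' The 13 default ensemble features
#'
#' @return Character vector: `"cdr_string_distance"` followed by the 12
#'   hydrophilicity/pI column names.
#' @export
forestFeatures <- function() c("cdr_string_distance", .FEATURE_COLS)

#' Construct a single feature tree
#'
#' @param feature One of [forestFeatures()].
#' @param k Neighbors the tree's K-NN vote uses (default 2).
#' @return A [FeatureTree-class].
#' @export
featureTree <- function(feature, k = 2) {
  new("FeatureTree", feature = feature, k = as.integer(k))
}

#' Construct the voting ensemble
#'
#' @param k Neighbors per tree (default 2, matching the main classifier);
#'   may be a single value or one per feature.
#' @param features Feature names; default all 13. Subset forests are
#'   supported for ablation.
#' @return List of [FeatureTree-class] objects.
#' @export
featureTrees <- function(k = 2, features = forestFeatures()) {
  stopifnot(all(features %in% forestFeatures()),
            !anyDuplicated(features))
  k <- rep_len(as.integer(k), length(features))
  mapply(featureTree, features, k, SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

# per-tree distances from one query record to every training record
.treeDistances <- function(tree, query, training, model, penalty) {
  if (tree@feature == "cdr_string_distance") {
    as.vector(pairDistanceMatrix(query, training, model, penalty))
  } else {
    qv <- records(query)[[tree@feature]][1L]
    tv <- records(training)[[tree@feature]]
    if (is.na(qv))
      stop("query is missing feature: ", tree@feature)
    if (anyNA(tv))
      stop("training table is missing values for feature: ", tree@feature)
    abs(tv - qv) + penalty * (antigenIds(training) != antigenIds(query))
  }
}

#' One tree's K-NN vote
#'
#' Runs the tree's K-NN classification using only its feature's distance:
#' the penalized antibody CDR distance for `"cdr_string_distance"`, or the
#' absolute scalar difference (plus the cross-antigen penalty) for a
#' physicochemical feature.
#'
#' @param tree A [FeatureTree-class].
#' @param query Single-row [PairTable-class].
#' @param training Labeled [PairTable-class].
#' @inheritParams knnPredict
#' @return The tree's vote, `"GOOD"` or `"POOR"`.
#' @export
treeVote <- function(tree, query, training, model = blosum62CostModel(),
                     penalty = 1000, epsilon = 1e-8, tieBreak = "GOOD") {
  stopifnot(is(tree, "FeatureTree"), is(query, "PairTable"),
            nrow(query) == 1L, is(training, "PairTable"))
  .checkTrainingLabels(bindingLabels(training))
  d <- .treeDistances(tree, query, training, model, penalty)
  .knnVote(d, bindingLabels(training), tree@k, epsilon, tieBreak)$label
}

#' Majority-vote ensemble prediction
#'
#' Each feature tree casts one K-NN vote; the predicted class is the simple
#' majority. With the default 13 trees the vote count is odd, so no tie is
#' possible; even-sized subset forests fall back to `tieBreak`.
#'
#' @inheritParams treeVote
#' @param trees List of [FeatureTree-class] voters (default: all 13).
#' @return A [ForestPrediction-class].
#' @export
#' @examples
#' tab <- simulatePairTable(simConfig(nAntigens = 3, pairsPerAntigen = 6,
#'                                    seed = 7))
#' forestPredict(tab[1], tab[-1])
forestPredict <- function(query, training, trees = featureTrees(),
                          model = blosum62CostModel(), penalty = 1000,
                          epsilon = 1e-8, tieBreak = "GOOD") {
  stopifnot(length(trees) >= 1L)
  votes <- vapply(trees, function(tr)
    treeVote(tr, query, training, model, penalty, epsilon, tieBreak), "")
  names(votes) <- vapply(trees, function(tr) tr@feature, "")
  tg <- sum(votes == "GOOD")
  tp <- sum(votes == "POOR")
  label <- if (tg > tp) "GOOD" else if (tp > tg) "POOR" else tieBreak
  new("ForestPrediction", votes = votes, tallyGood = as.integer(tg),
      tallyPoor = as.integer(tp), label = label)
}
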