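# Leave-one-out cross-validation and accuracy reporting.

#' Leave-one-out cross-validation of a binding classifier
#'
#' For every record, trains on the remaining n-1 records and predicts the
#' held-out pair, repeating until every pair has been tested; accuracy is
#' the fraction of correctly predicted pairs, reported per antigen and
#' overall. The training pool is globally pooled across antigens: the fixed
#' cross-antigen penalty makes same-antigen neighbors dominate whenever they
#' exist, and predictions that had to fall back on cross-antigen neighbors
#' (fewer than `k` same-antigen training pairs, e.g. singleton antigens)
#' are flagged. Set `restrictToAntigen = TRUE` to restrict each training
#' pool to the held-out record's antigen instead.
#'
#' @param table A fully labeled [PairTable-class] (GOOD/POOR only), `>= 2`
#'   rows.
#' @param method `"knn"` (distance-weighted K-NN) or `"forest"` (the
#'   13-feature majority-vote ensemble).
#' @param k Neighbors (for `"forest"`, the per-tree k).
#' @param model A [SubstitutionCostModel-class].
#' @param penalty Cross-antigen penalty (default 1000).
#' @param epsilon Inverse-distance weight constant.
#' @param tieBreak Label used on exact weight/vote ties.
#' @param features For `"forest"`: the participating feature names
#'   (default all 13).
#' @param restrictToAntigen Logical; restrict training pools per antigen.
#' @return An [EvalReport-class].
#' @export
#' @examples
#' tab <- simulatePairTable(simConfig(nAntigens = 4, pairsPerAntigen = 6,
#'                                    seed = 11))
#' rep <- loocv(tab, k = 2)
#' accuracy(rep)
loocv <- function(table, method = c("knn", "forest"), k = 2,
                  model = blosum62CostModel(), penalty = 1000,
                  epsilon = 1e-8, tieBreak = "GOOD",
                  features = forestFeatures(), restrictToAntigen = FALSE) {
  method <- match.arg(method)
  stopifnot(is(table, "PairTable"), nrow(table) >= 2L)
  labs <- bindingLabels(table)
  if (any(is.na(labs)))
    stop("all records must be labeled GOOD or POOR before evaluation")
  if (any(labs == "REVIEW"))
    stop("table contains REVIEW labels; run resolveReview() first")
  n <- nrow(table)
  if (k > n - 1L) stop("k exceeds the size of the training pool (n - 1)")
  ags <- antigenIds(table)

  D <- pairDistanceMatrix(table, table, model, penalty)
  if (restrictToAntigen)
    D[outer(ags, ags, "!=")] <- Inf
  diag(D) <- Inf  # a record never neighbors itself under LOOCV

  sameCount <- as.vector(table(ags)[ags]) - 1L
  fallback <- sameCount < k

  predOne <- function(d) .knnVote(d, labs, k, epsilon, tieBreak)$label
  if (method == "knn") {
    pred <- vapply(seq_len(n), function(i) predOne(D[i, ]), "")
  } else {
    rec <- records(table)
    trees <- featureTrees(k, features)
    votes <- matrix("", n, length(trees))
    for (t_i in seq_along(trees)) {
      tr <- trees[[t_i]]
      if (tr@feature == "cdr_string_distance") {
        Dt <- D
      } else {
        v <- rec[[tr@feature]]
        if (anyNA(v)) stop("missing values for feature: ", tr@feature)
        Dt <- abs(outer(v, v, "-")) + penalty * outer(ags, ags, "!=")
        if (restrictToAntigen) Dt[outer(ags, ags, "!=")] <- Inf
        diag(Dt) <- Inf
      }
      votes[, t_i] <- vapply(seq_len(n), function(i)
        .knnVote(Dt[i, ], labs, tr@k, epsilon, tieBreak)$label, "")
    }
    tg <- rowSums(votes == "GOOD")
    tp <- rowSums(votes == "POOR")
    pred <- ifelse(tg > tp, "GOOD", ifelse(tp > tg, "POOR", tieBreak))
  }

  correct <- pred == labs
  perAg <- do.call(rbind, lapply(split(seq_len(n), ags), function(idx) {
    data.frame(antigen = ags[idx[1L]], n = length(idx),
               correct = sum(correct[idx]),
               accuracy = mean(correct[idx]),
               cross_antigen_fallback = sum(fallback[idx]),
               stringsAsFactors = FALSE)
  }))
  rownames(perAg) <- NULL
  conf <- table(factor(labs, levels = c("GOOD", "POOR")),
                factor(pred, levels = c("GOOD", "POOR")))
  conf <- matrix(as.integer(conf), 2, 2,
                 dimnames = list(true = c("GOOD", "POOR"),
                                 predicted = c("GOOD", "POOR")))
  config <- list(method = method, k = k, costModel = modelName(model),
                 indelCost = indelCost(model), penalty = penalty,
                 weight = "inverse_distance", epsilon = epsilon,
                 tieBreak = tieBreak,
                 restrictToAntigen = restrictToAntigen)
  if (method == "forest") config$features <- features
  new("EvalReport", method = method, config = config,
      overall = list(n = n, correct = sum(correct),
                     accuracy = mean(correct)),
      perAntigen = perAg, confusion = conf,
      predictions = data.frame(antigen = ags, label = labs,
                               predicted = pred, correct = correct,
                               cross_antigen_fallback = fallback,
                               stringsAsFactors = FALSE))
}

#' Compare K values and cost models by LOOCV accuracy
#'
#' @param table A labeled [PairTable-class].
#' @param ks Integer vector of K values (duplicates are dropped with a
#'   warning).
#' @param models List of [SubstitutionCostModel-class] objects.
#' @param ... Passed to [loocv()].
#' @return Data.frame with one row per (k, model): `k`, `model`,
#'   `accuracy`, `n`. The full reports are attached as `attr(, "reports")`.
#' @export
compareK <- function(table, ks = c(1, 2, 3),
                     models = list(blosum62CostModel()), ...) {
  if (anyDuplicated(ks)) {
    warning("duplicate k values dropped: ",
            paste(unique(ks[duplicated(ks)]), collapse = ", "))
    ks <- unique(ks)
  }
  grid <- expand.grid(ki = seq_along(ks), mi = seq_along(models))
  reports <- lapply(seq_len(base::nrow(grid)), function(g) {
    loocv(table, method = "knn", k = ks[grid$ki[g]],
          model = models[[grid$mi[g]]], ...)
  })
  out <- data.frame(
    k = ks[grid$ki],
    model = vapply(models[grid$mi], modelName, ""),
    accuracy = vapply(reports, accuracy, 0),
    n = nrow(table),
    stringsAsFactors = FALSE)
  attr(out, "reports") <- reports
  out
}

# serializable form of an EvalReport
.evalReportToList <- function(report) {
  list(method = report@method, config = report@config,
       overall = report@overall,
       per_antigen = report@perAntigen,
       confusion = list(
         good_good = report@confusion["GOOD", "GOOD"],
         good_poor = report@confusion["GOOD", "POOR"],
         poor_good = report@confusion["POOR", "GOOD"],
         poor_poor = report@confusion["POOR", "POOR"]))
}

#' Write an evaluation report to disk
#'
#' Emits `<prefix>.json` (method, config, overall accuracy, confusion
#' counts, per-antigen table) and `<prefix>_per_antigen.csv`.
#'
#' @param report An [EvalReport-class].
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
writeEvalReport <- function(report, prefix) {
  stopifnot(is(report, "EvalReport"))
  json <- paste0(prefix, ".json")
  csv <- paste0(prefix, "_per_antigen.csv")
  jsonlite::write_json(.evalReportToList(report), json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write.csv(report@perAntigen, csv, row.names = FALSE)
  invisible(c(json, csv))
}
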