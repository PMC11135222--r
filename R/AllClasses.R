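# S4 classes for the central data objects.

#' AntibodyCdrSet: the six CDR sequences of one antibody
#'
#' Holds the heavy- and light-chain CDR1/2/3 amino-acid strings of a single
#' antibody. All binding predictions in this package are functions of these
#' six strings (plus, for the voting ensemble, features derived from them).
#'
#' @slot cdrs Named character vector of length 6 with names
#'   `h_cdr1, h_cdr2, h_cdr3, l_cdr1, l_cdr2, l_cdr3`; uppercase strings over
#'   the 20-letter amino-acid alphabet (optionally `X`).
#' @export
setClass("AntibodyCdrSet", representation(cdrs = "character"))

setValidity("AntibodyCdrSet", function(object) {
  x <- object@cdrs
  if (length(x) != 6L || !identical(names(x), .CDR_COLS))
    return("cdrs must be a named character vector with names h_cdr1..l_cdr3")
  ok <- .validSeq(x, c(aminoAcids(), "X"))
  if (!all(ok))
    return(paste0("invalid CDR sequence(s): ",
                  paste(names(x)[!ok], collapse = ", ")))
  TRUE
})

#' Construct an AntibodyCdrSet
#'
#' @param hCdr1,hCdr2,hCdr3 Heavy-chain CDR1/2/3 amino-acid strings.
#' @param lCdr1,lCdr2,lCdr3 Light-chain CDR1/2/3 amino-acid strings.
#' @return An [AntibodyCdrSet-class] object. Sequences are uppercased.
#' @export
#' @examples
#' ab <- AntibodyCdrSet("GYTFTSYW", "IYPGDSDT", "ARWGGDGFYAMD",
#'                      "QSLLNSRTRKNY", "WASTRES", "KQSYNLYT")
#' cdrs(ab)
AntibodyCdrSet <- function(hCdr1, hCdr2, hCdr3, lCdr1, lCdr2, lCdr3) {
  cdrs <- toupper(c(hCdr1, hCdr2, hCdr3, lCdr1, lCdr2, lCdr3))
  names(cdrs) <- .CDR_COLS
  new("AntibodyCdrSet", cdrs = cdrs)
}

#' @describeIn AntibodyCdrSet Extract the named CDR vector.
#' @param x An `AntibodyCdrSet`.
#' @export
setGeneric("cdrs", function(x) standardGeneric("cdrs"))

#' @rdname AntibodyCdrSet-class
#' @export
setMethod("cdrs", "AntibodyCdrSet", function(x) x@cdrs)

setMethod("show", "AntibodyCdrSet", function(object) {
  cat("AntibodyCdrSet\n")
  for (nm in .CDR_COLS)
    cat(sprintf("  %-7s %s\n", nm, object@cdrs[[nm]]))
})

#' PairTable: a validated table of antibody-antigen pairs
#'
#' One row per antibody-antigen interaction: six CDR sequences, twelve
#' physicochemical feature columns (hydrophilicity and isoelectric point per
#' CDR), the opaque predicted-epitope string, the docking interface score
#' (may be missing), the antigen identifier, and the binding label.
#'
#' @slot records A data.frame with the 22 canonical columns (see
#'   [pairTableDialect()]) plus optional bookkeeping columns such as
#'   `label_provenance`.
#' @slot dialect The [pairTableDialect()] used for I/O.
#' @export
setClass("PairTable", representation(records = "data.frame", dialect = "list"))

setValidity("PairTable", function(object) {
  rec <- object@records
  missing <- setdiff(.CANONICAL_COLS, names(rec))
  if (length(missing) > 0L)
    return(paste0("records missing column(s): ", paste(missing, collapse = ", ")))
  if (nrow(rec) > 0L) {
    for (cc in .CDR_COLS) {
      ok <- .validSeq(rec[[cc]], c(aminoAcids(), "X"))
      if (!all(ok))
        return(paste0("invalid sequence(s) in ", cc, " at row(s) ",
                      paste(head(which(!ok)), collapse = ", ")))
    }
    if (any(is.na(rec$antigen) | !nzchar(rec$antigen)))
      return("antigen identifiers must be non-empty")
    lab <- rec$label
    bad <- !is.na(lab) & !(lab %in% .BINDING_CLASSES)
    if (any(bad))
      return(paste0("labels must be GOOD/POOR/REVIEW or NA; offending row(s) ",
                    paste(head(which(bad)), collapse = ", ")))
  }
  TRUE
})

#' Construct a PairTable from a canonical data.frame
#'
#' @param records Data.frame holding (at least) the canonical columns; CDR
#'   sequences are uppercased, feature columns missing from `records` are
#'   added as `NA` (fill them with [featurizeTable()]).
#' @param dialect A [pairTableDialect()].
#' @return A validated [PairTable-class].
#' @export
#' @examples
#' tab <- PairTable(data.frame(
#'   h_cdr1 = "GYTFTSYW", h_cdr2 = "IYPGDSDT", h_cdr3 = "ARWGGDGFYAMD",
#'   l_cdr1 = "QSLLNSRTRKNY", l_cdr2 = "WASTRES", l_cdr3 = "KQSYNLYT",
#'   antigen = "SARS-CoV-2", label = "GOOD"))
#' nrow(tab)
PairTable <- function(records, dialect = pairTableDialect()) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (cc in .CDR_COLS) {
    if (!cc %in% names(records))
      stop("records missing CDR column: ", cc)
    records[[cc]] <- toupper(as.character(records[[cc]]))
  }
  for (fc in .FEATURE_COLS) {
    records[[fc]] <- if (fc %in% names(records))
      as.numeric(records[[fc]]) else NA_real_
  }
  if (!"epitope" %in% names(records)) records$epitope <- ""
  records$epitope <- as.character(records$epitope)
  records$epitope[is.na(records$epitope)] <- ""
  records$docking_score <- if ("docking_score" %in% names(records))
    as.numeric(records$docking_score) else NA_real_
  if (!"antigen" %in% names(records)) stop("records missing column: antigen")
  records$antigen <- as.character(records$antigen)
  records$label <- if ("label" %in% names(records))
    as.character(records$label) else NA_character_
  extra <- setdiff(names(records), .CANONICAL_COLS)
  records <- records[, c(.CANONICAL_COLS, extra), drop = FALSE]
  rownames(records) <- NULL
  new("PairTable", records = records, dialect = unclass(dialect))
}

#' @describeIn PairTable The underlying canonical data.frame.
#' @param x A `PairTable`.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname PairTable-class
#' @export
setMethod("records", "PairTable", function(x) x@records)

#' @describeIn PairTable Antigen identifier of every record.
#' @export
setGeneric("antigenIds", function(x) standardGeneric("antigenIds"))

#' @rdname PairTable-class
#' @export
setMethod("antigenIds", "PairTable", function(x) x@records$antigen)

#' @describeIn PairTable Binding label of every record (GOOD/POOR/REVIEW/NA).
#' @export
setGeneric("bindingLabels", function(x) standardGeneric("bindingLabels"))

#' @rdname PairTable-class
#' @export
setMethod("bindingLabels", "PairTable", function(x) x@records$label)

#' @describeIn PairTable The [AntibodyCdrSet-class] of record `i`.
#' @param i Row index.
#' @export
setGeneric("cdrSet", function(x, i) standardGeneric("cdrSet"))

#' @rdname PairTable-class
#' @export
setMethod("cdrSet", "PairTable", function(x, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= nrow(x@records))
  cdrs <- unlist(x@records[i, .CDR_COLS])
  names(cdrs) <- .CDR_COLS
  new("AntibodyCdrSet", cdrs = cdrs)
})

setGeneric("nrow")

#' @rdname PairTable-class
#' @export
setMethod("nrow", "PairTable", function(x) base::nrow(x@records))

#' @rdname PairTable-class
#' @export
setMethod("length", "PairTable", function(x) base::nrow(x@records))

#' @rdname PairTable-class
#' @param j,drop Ignored (row subsetting only).
#' @param ... Ignored.
#' @export
setMethod("[", "PairTable", function(x, i, j, ..., drop = FALSE) {
  initialize(x, records = x@records[i, , drop = FALSE], dialect = x@dialect)
})

#' @rdname PairTable-class
#' @param row.names,optional Passed through to [base::as.data.frame()].
#' @export
setMethod("as.data.frame", "PairTable",
          function(x, row.names = NULL, optional = FALSE, ...) {
  df <- x@records
  rownames(df) <- row.names
  df
})

setMethod("show", "PairTable", function(object) {
  rec <- object@records
  lab <- table(factor(rec$label, levels = .BINDING_CLASSES))
  cat(sprintf("PairTable with %d pair(s), %d antigen(s)\n",
              nrow(rec), length(unique(rec$antigen))))
  cat(sprintf("  labels: GOOD=%d POOR=%d REVIEW=%d unlabeled=%d\n",
              lab[["GOOD"]], lab[["POOR"]], lab[["REVIEW"]],
              sum(is.na(rec$label))))
})

#' SubstitutionCostModel: per-residue-pair mismatch costs
#'
#' Defines the cost of substituting one residue for another (and the
#' insertion/deletion cost) in the generalized Levenshtein distance. The
#' identity model charges 1 for every mismatch; the BLOSUM62 model derives
#' graded costs from the substitution matrix so that conservative
#' replacements are cheaper than radical ones.
#'
#' @slot name Model name, e.g. `"identity"` or `"blosum62"`.
#' @slot costs Square numeric matrix, residues as dimnames; symmetric,
#'   zero diagonal, non-negative, finite.
#' @slot indelCost Positive insertion/deletion cost.
#' @export
setClass("SubstitutionCostModel",
         representation(name = "character", costs = "matrix",
                        indelCost = "numeric"))

setValidity("SubstitutionCostModel", function(object) {
  m <- object@costs
  if (!is.numeric(m) || nrow(m) != ncol(m)) return("costs must be square numeric")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    return("costs must have identical row/col residue names")
  if (any(!is.finite(m)) || any(m < 0)) return("costs must be finite and >= 0")
  if (any(diag(m) != 0)) return("cost(a, a) must be 0 for every residue")
  if (!isTRUE(all.equal(m, t(m)))) return("costs must be symmetric")
  if (length(object@indelCost) != 1L || !is.finite(object@indelCost) ||
      object@indelCost <= 0)
    return("indelCost must be a single positive number")
  TRUE
})

setMethod("show", "SubstitutionCostModel", function(object) {
  off <- object@costs[upper.tri(object@costs)]
  cat(sprintf("SubstitutionCostModel '%s': %d residues, indel=%g, mismatch cost range [%g, %g]\n",
              object@name, nrow(object@costs), object@indelCost,
              min(off), max(off)))
})

#' @describeIn SubstitutionCostModel The residue-pair cost matrix.
#' @param x A `SubstitutionCostModel`.
#' @export
setGeneric("costMatrix", function(x) standardGeneric("costMatrix"))

#' @rdname SubstitutionCostModel-class
#' @export
setMethod("costMatrix", "SubstitutionCostModel", function(x) x@costs)

#' @describeIn SubstitutionCostModel The insertion/deletion cost.
#' @export
setGeneric("indelCost", function(x) standardGeneric("indelCost"))

#' @rdname SubstitutionCostModel-class
#' @export
setMethod("indelCost", "SubstitutionCostModel", function(x) x@indelCost)

#' @describeIn SubstitutionCostModel The model's name.
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))

#' @rdname SubstitutionCostModel-class
#' @export
setMethod("modelName", "SubstitutionCostModel", function(x) x@name)

#' Prediction: the outcome of one K-NN query
#'
#' @slot label Predicted binding class (`GOOD` or `POOR`).
#' @slot weightGood,weightPoor Summed inverse-distance vote weights.
#' @slot neighbors Data.frame of the K nearest training rows (index,
#'   antigen, label, distance, weight, sameAntigen), sorted by distance.
#' @export
setClass("Prediction",
         representation(label = "character", weightGood = "numeric",
                        weightPoor = "numeric", neighbors = "data.frame"))

setValidity("Prediction", function(object) {
  if (!(object@label %in% c("GOOD", "POOR"))) return("label must be GOOD or POOR")
  nb <- object@neighbors
  if (nrow(nb) > 1L) {
    if (is.unsorted(nb$distance)) return("neighbors must be sorted by distance")
    if (is.unsorted(rev(nb$weight))) return("weights must be non-increasing in distance")
  }
  winner <- if (object@weightGood > object@weightPoor) "GOOD"
            else if (object@weightPoor > object@weightGood) "POOR" else NA
  if (!is.na(winner) && winner != object@label)
    return("label must carry the larger class weight")
  TRUE
})

setMethod("show", "Prediction", function(object) {
  cat(sprintf("Prediction: %s (weight GOOD=%.4g, POOR=%.4g; k=%d)\n",
              object@label, object@weightGood, object@weightPoor,
              nrow(object@neighbors)))
})

#' ForestPrediction: a 13-tree majority vote
#'
#' @slot votes Named character vector, one vote (GOOD/POOR) per feature tree.
#' @slot tallyGood,tallyPoor Integer vote counts.
#' @slot label Majority-vote binding class.
#' @export
setClass("ForestPrediction",
         representation(votes = "character", tallyGood = "integer",
                        tallyPoor = "integer", label = "character"))

setValidity("ForestPrediction", function(object) {
  if (object@tallyGood + object@tallyPoor != length(object@votes))
    return("tallies must sum to the number of participating trees")
  if (object@tallyGood != sum(object@votes == "GOOD"))
    return("tallyGood must count GOOD votes")
  if (object@tallyGood != object@tallyPoor) {
    maj <- if (object@tallyGood > object@tallyPoor) "GOOD" else "POOR"
    if (object@label != maj) return("label must be the majority vote")
  }
  TRUE
})

setMethod("show", "ForestPrediction", function(object) {
  cat(sprintf("ForestPrediction: %s (votes GOOD=%d, POOR=%d of %d trees)\n",
              object@label, object@tallyGood, object@tallyPoor,
              length(object@votes)))
})

#' FeatureTree: one voter of the per-feature ensemble
#'
#' Each "tree" is a K-NN classifier over a single feature: the antibody CDR
#' string distance, or the absolute difference of one scalar physicochemical
#' column; both with the cross-antigen penalty.
#'
#' @slot feature `"cdr_string_distance"` or one of the 12 feature column
#'   names (`hyd_*`/`pi_*`).
#' @slot k Neighbors used by this tree.
#' @export
setClass("FeatureTree", representation(feature = "character", k = "integer"))

setValidity("FeatureTree", function(object) {
  if (!(object@feature %in% c("cdr_string_distance", .FEATURE_COLS)))
    return(paste0("unknown feature: ", object@feature))
  if (object@k < 1L) return("k must be >= 1")
  TRUE
})

#' EvalReport: leave-one-out cross-validation results
#'
#' @slot method `"knn"` or `"forest"`.
#' @slot config Fingerprint of the configuration (k, cost model, penalty,
#'   weight function, tie rule).
#' @slot overall List with `n`, `correct`, `accuracy`.
#' @slot perAntigen Data.frame with one row per antigen: `antigen`, `n`,
#'   `correct`, `accuracy`, `cross_antigen_fallback` (predictions that had to
#'   borrow cross-antigen neighbors).
#' @slot confusion 2x2 matrix of true x predicted label counts.
#' @slot predictions Data.frame with one row per record: antigen, label,
#'   predicted, correct, cross-antigen-fallback flag.
#' @export
setClass("EvalReport",
         representation(method = "character", config = "list",
                        overall = "list", perAntigen = "data.frame",
                        confusion = "matrix", predictions = "data.frame"))

setValidity("EvalReport", function(object) {
  ov <- object@overall
  if (!all(c("n", "correct", "accuracy") %in% names(ov)))
    return("overall must contain n, correct, accuracy")
  if (sum(object@perAntigen$n) != ov$n)
    return("overall n must equal the sum of per-antigen n")
  if (ov$n > 0 && abs(ov$accuracy - ov$correct / ov$n) > 1e-12)
    return("accuracy must equal correct / n")
  if (sum(object@confusion) != ov$n)
    return("confusion counts must sum to n")
  TRUE
})

setMethod("show", "EvalReport", function(object) {
  ov <- object@overall
  cat(sprintf("EvalReport (%s, leave-one-out)\n", object@method))
  cat(sprintf("  overall accuracy: %.4f (%d / %d)\n",
              ov$accuracy, ov$correct, ov$n))
  cat(sprintf("  antigens: %d\n", nrow(object@perAntigen)))
  cat("  confusion (true x predicted):\n")
  print(object@confusion)
})

#' @describeIn EvalReport Overall LOOCV accuracy.
#' @param x An `EvalReport`.
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname EvalReport-class
#' @export
setMethod("accuracy", "EvalReport", function(x) x@overall$accuracy)

#' @describeIn EvalReport Per-antigen accuracy table.
#' @export
setGeneric("perAntigenAccuracy", function(x) standardGeneric("perAntigenAccuracy"))

#' @rdname EvalReport-class
#' @export
setMethod("perAntigenAccuracy", "EvalReport", function(x) x@perAntigen)

#' @describeIn EvalReport The 2x2 confusion matrix (true x predicted).
#' @export
setGeneric("confusion", function(x) standardGeneric("confusion"))

#' @rdname EvalReport-class
#' @export
setMethod("confusion", "EvalReport", function(x) x@confusion)

#' @describeIn EvalReport Per-record predictions.
#' @export
setGeneric("predictions", function(x) standardGeneric("predictions"))

#' @rdname EvalReport-class
#' @export
setMethod("predictions", "EvalReport", function(x) x@predictions)

#' SimConfig: synthetic pair-table generator settings
#'
#' @slot nAntigens Number of antigens.
#' @slot pairsPerAntigen Antibody-antigen pairs per antigen.
#' @slot cdrLengths Named integer vector of CDR lengths
#'   (h_cdr1..l_cdr3).
#' @slot mutationRate Per-position substitution probability within a class.
#' @slot separation Minimum per-CDR substitution distance between the GOOD
#'   and POOR archetype of an antigen.
#' @slot labelNoise Probability a record's label is flipped.
#' @slot classBalance Probability a record belongs to the GOOD class.
#' @slot seed RNG seed; a fixed seed reproduces the table exactly.
#' @slot scoreBands List with `GOOD` and `POOR`, each `c(mean=, sd=)`, the
#'   normal bands simulated interface scores are drawn from.
#' @slot indelRate Per-record probability of a single random indel
#'   (stress-test mode; default 0 keeps archetype distances predictable).
#' @export
setClass("SimConfig",
         representation(nAntigens = "integer", pairsPerAntigen = "integer",
                        cdrLengths = "integer", mutationRate = "numeric",
                        separation = "integer", labelNoise = "numeric",
                        classBalance = "numeric", seed = "integer",
                        scoreBands = "list", indelRate = "numeric"))

setValidity("SimConfig", function(object) {
  if (object@nAntigens < 1L || object@pairsPerAntigen < 1L)
    return("nAntigens and pairsPerAntigen must be >= 1")
  if (!identical(names(object@cdrLengths), .CDR_COLS))
    return("cdrLengths must be named h_cdr1..l_cdr3")
  if (any(object@cdrLengths < 1L)) return("CDR lengths must be >= 1")
  for (r in c(object@mutationRate, object@labelNoise, object@indelRate))
    if (r < 0 || r > 1) return("rates must be in [0, 1]")
  if (object@classBalance <= 0 || object@classBalance >= 1)
    return("classBalance must be in (0, 1)")
  if (object@separation < 0) return("separation must be >= 0")
  if (object@separation > min(object@cdrLengths))
    return("separation exceeds the shortest CDR length (unsatisfiable)")
  for (cls in c("GOOD", "POOR")) {
    b <- object@scoreBands[[cls]]
    if (is.null(b) || !all(c("mean", "sd") %in% names(b)) || b[["sd"]] <= 0)
      return(paste0("scoreBands$", cls, " must provide mean and sd > 0"))
  }
  TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: %d antigens x %d pairs, mutation=%.3g, ",
                     "separation=%d, noise=%.3g, balance=%.2f, seed=%d\n"),
              object@nAntigens, object@pairsPerAntigen, object@mutationRate,
              object@separation, object@labelNoise, object@classBalance,
              object@seed))
})
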