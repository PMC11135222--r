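# Synthetic pair-table generator: per-antigen binder/non-binder CDR
# archetypes with point-mutation noise, simulated interface scores, and the
# same column schema as the CSV reader.

#' Synthetic-data generator settings
#'
#' Defaults describe the study conditions the generator emulates: 57
#' antigens (as in the collated data set) with 20 pairs each, CDR lengths
#' typical of heavy/light chains, a per-CDR archetype separation of 4
#' substitutions between binder and non-binder, 2% within-class point
#' mutation, no label noise, balanced classes, and interface-score bands
#' centered at -10 (GOOD) and -7 (POOR) that avoid the review interval.
#'
#' @param nAntigens,pairsPerAntigen Table dimensions.
#' @param cdrLengths Named (h_cdr1..l_cdr3) or positional lengths of the six
#'   CDRs; defaults 8, 8, 12 (heavy) and 11, 7, 9 (light).
#' @param mutationRate Per-position substitution probability within a class.
#' @param separation Per-CDR substitution distance between the GOOD and POOR
#'   archetypes of an antigen.
#' @param labelNoise Probability of flipping a record's label.
#' @param classBalance Probability a record is a GOOD binder.
#' @param seed RNG seed (fixed seed, identical table).
#' @param scoreBands List of `GOOD`/`POOR` normal bands `c(mean=, sd=)`.
#' @param indelRate Per-record probability of one random indel (stress mode).
#' @return A [SimConfig-class].
#' @export
simConfig <- function(nAntigens = 57, pairsPerAntigen = 20,
                      cdrLengths = c(h_cdr1 = 8, h_cdr2 = 8, h_cdr3 = 12,
                                     l_cdr1 = 11, l_cdr2 = 7, l_cdr3 = 9),
                      mutationRate = 0.02, separation = 4, labelNoise = 0,
                      classBalance = 0.5, seed = 1,
                      scoreBands = list(GOOD = c(mean = -10, sd = 0.3),
                                        POOR = c(mean = -7, sd = 0.3)),
                      indelRate = 0) {
  if (is.null(names(cdrLengths))) names(cdrLengths) <- .CDR_COLS
  cdrLengths <- as.integer(cdrLengths[.CDR_COLS])
  names(cdrLengths) <- .CDR_COLS
  new("SimConfig", nAntigens = as.integer(nAntigens),
      pairsPerAntigen = as.integer(pairsPerAntigen),
      cdrLengths = cdrLengths, mutationRate = mutationRate,
      separation = as.integer(separation), labelNoise = labelNoise,
      classBalance = classBalance, seed = as.integer(seed),
      scoreBands = scoreBands, indelRate = indelRate)
}

.randomPeptide <- function(len) {
  paste(sample(aminoAcids(), len, replace = TRUE), collapse = "")
}

# mutate `separation` distinct positions to different residues
.separateArchetype <- function(seq, separation) {
  if (separation == 0L) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  pos <- sample(length(chars), separation)
  for (p in pos)
    chars[p] <- sample(setdiff(aminoAcids(), chars[p]), 1L)
  paste(chars, collapse = "")
}

# i.i.d. per-position substitutions at `rate`
.pointMutate <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  hit <- which(runif(length(chars)) < rate)
  for (p in hit)
    chars[p] <- sample(setdiff(aminoAcids(), chars[p]), 1L)
  paste(chars, collapse = "")
}

.maybeIndel <- function(seq, rate) {
  if (rate <= 0 || runif(1L) >= rate) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  if (length(chars) > 1L && runif(1L) < 0.5) {
    chars <- chars[-sample(length(chars), 1L)]
  } else {
    at <- sample(length(chars) + 1L, 1L)
    chars <- append(chars, sample(aminoAcids(), 1L), after = at - 1L)
  }
  paste(chars, collapse = "")
}

# run `expr` under the config's seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic pair table
#'
#' For each antigen, a GOOD-binder archetype antibody is drawn uniformly and
#' a POOR archetype is derived from it at the configured per-CDR
#' substitution separation. Every record copies its class archetype with
#' i.i.d. per-position substitutions at the mutation rate; labels are
#' flipped at the noise rate; docking scores are drawn from the labeled
#' class's score band; the 12 physicochemical feature columns are computed
#' with the same code path as [featurizeTable()], so stored columns always
#' match recomputation.
#'
#' @param config A [simConfig()].
#' @return A [PairTable-class] with `nAntigens * pairsPerAntigen` rows and
#'   an extra `class_archetype` provenance column (the pre-noise class).
#' @export
#' @examples
#' tab <- simulatePairTable(simConfig(nAntigens = 2, pairsPerAntigen = 4,
#'                                    seed = 42))
#' table(antigenIds(tab), bindingLabels(tab))
simulatePairTable <- function(config = simConfig()) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  .withSeed(config@seed, {
    rows <- vector("list", config@nAntigens)
    for (a in seq_len(config@nAntigens)) {
      ag <- sprintf("AG%03d", a)
      good <- vapply(config@cdrLengths, .randomPeptide, "")
      poor <- vapply(good, .separateArchetype, "",
                     separation = config@separation)
      names(good) <- names(poor) <- .CDR_COLS
      epi <- .randomPeptide(8L)
      cls <- ifelse(rbinom(config@pairsPerAntigen, 1L,
                           config@classBalance) == 1L, "GOOD", "POOR")
      cdrs <- t(vapply(cls, function(cl) {
        arch <- if (cl == "GOOD") good else poor
        vapply(arch, function(s)
          .maybeIndel(.pointMutate(s, config@mutationRate),
                      config@indelRate), "")
      }, character(6L)))
      rownames(cdrs) <- NULL
      lab <- cls
      flip <- runif(length(lab)) < config@labelNoise
      lab[flip] <- ifelse(lab[flip] == "GOOD", "POOR", "GOOD")
      band <- config@scoreBands
      score <- vapply(lab, function(l)
        rnorm(1L, band[[l]][["mean"]], band[[l]][["sd"]]), 0)
      df <- as.data.frame(cdrs, stringsAsFactors = FALSE)
      names(df) <- .CDR_COLS
      df$epitope <- epi
      df$docking_score <- unname(score)
      df$antigen <- ag
      df$label <- lab
      df$class_archetype <- cls
      rows[[a]] <- df
    }
    tab <- PairTable(do.call(rbind, rows))
    featurizeTable(tab)
  })
}

#' Simulate interface scores for a set of labels
#'
#' Draws a score for each label from its class band. Bands must keep GOOD
#' means below the review interval and POOR means above it (so
#' [classifyInterfaceScore()] recovers the label for draws outside
#' `[lower, upper]`); draws that land in the review interval are flagged.
#'
#' @param labels Character vector of `GOOD`/`POOR`.
#' @param config A [simConfig()] providing the score bands.
#' @param upper,lower The review-interval bounds used for the flag.
#' @return Numeric scores with `attr(, "review")`, a logical vector marking
#'   draws inside the review interval.
#' @export
simulateScores <- function(labels, config = simConfig(), upper = -8.0,
                           lower = -9.0) {
  stopifnot(all(labels %in% c("GOOD", "POOR")))
  band <- config@scoreBands
  if (band$GOOD[["mean"]] >= lower || band$POOR[["mean"]] <= upper)
    stop("score bands must not center inside the review interval [",
         lower, ", ", upper, "]")
  .withSeed(config@seed, {
    out <- vapply(labels, function(l)
      rnorm(1L, band[[l]][["mean"]], band[[l]][["sd"]]), 0)
    out <- unname(out)
    attr(out, "review") <- out >= lower & out <= upper
    out
  })
}
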