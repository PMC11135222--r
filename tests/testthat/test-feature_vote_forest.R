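# helper: build a table with hand-set feature columns (no recomputation)
forest_fixture <- function(pi_l1, labels, antigens = rep("ag1", length(labels)),
                           cdrs = NULL) {
  n <- length(labels)
  if (is.null(cdrs)) cdrs <- replicate(n, base_cdrs, simplify = FALSE)
  tab <- toy_table(cdrs, antigens, labels)
  rec <- records(tab)
  for (fc in grep("^(hyd|pi)_", names(rec), value = TRUE)) rec[[fc]] <- 0
  rec$pi_l_cdr1 <- pi_l1
  PairTable(rec)
}

test_that("a scalar feature tree votes with the nearest value", {
  tab <- forest_fixture(c(6.0, 5.9, 8.0), c("GOOD", "GOOD", "POOR"))
  tr <- featureTree("pi_l_cdr1", k = 1)
  expect_identical(treeVote(tr, tab[1], tab[-1]), "GOOD")
  # flipping which value is nearest flips the vote
  tab2 <- forest_fixture(c(7.9, 5.9, 8.0), c("GOOD", "GOOD", "POOR"))
  expect_identical(treeVote(tr, tab2[1], tab2[-1]), "POOR")
})

test_that("a training duplicate decides every tree", {
  tab <- simulatePairTable(simConfig(nAntigens = 2, pairsPerAntigen = 4,
                                     seed = 15))
  rec <- records(tab)
  dup <- rbind(rec[1, ], rec)  # row 2 duplicates the query exactly
  dup$label[2] <- "POOR"
  dup$label[1] <- "GOOD"
  tab2 <- PairTable(dup)
  for (f in c("cdr_string_distance", "pi_l_cdr1", "hyd_h_cdr3"))
    expect_identical(treeVote(featureTree(f, k = 1), tab2[1], tab2[-1]),
                     "POOR")
  # forest agrees with plain K-NN on duplicates
  fp <- forestPredict(tab2[1], tab2[-1], featureTrees(k = 1))
  expect_identical(fp@label, knnPredict(tab2[1], tab2[-1], k = 1)@label)
})

test_that("cross-antigen rows rank after same-antigen rows in scalar trees", {
  tab <- forest_fixture(c(6.0, 9.0, 6.0), c("GOOD", "POOR", "GOOD"),
                        antigens = c("ag1", "ag1", "ag2"))
  # |6 - 9| = 3 beats |6 - 6| + 1000
  expect_identical(treeVote(featureTree("pi_l_cdr1", k = 1),
                            tab[1], tab[-1]), "POOR")
})

test_that("a missing feature value is an error naming the feature", {
  tab <- forest_fixture(c(6, NA, 7), c("GOOD", "POOR", "GOOD"))
  expect_error(treeVote(featureTree("pi_l_cdr1", k = 1), tab[1], tab[-1]),
               "pi_l_cdr1")
  expect_error(treeVote(featureTree("pi_l_cdr1", k = 1), tab[2], tab[-2]),
               "pi_l_cdr1")
})

test_that("13 trees cast an odd number of votes with a majority label", {
  set.seed(29)
  for (trial in 1:4) {
    tab <- simulatePairTable(simConfig(nAntigens = 2, pairsPerAntigen = 6,
                                       seed = 200 + trial,
                                       mutationRate = 0.15))
    fp <- forestPredict(tab[1], tab[-1])
    expect_length(fp@votes, 13L)
    expect_identical(fp@tallyGood + fp@tallyPoor, 13L)
    expect_true(fp@tallyGood != fp@tallyPoor)  # odd count: no tie possible
    mode_label <- names(which.max(table(fp@votes)))
    expect_identical(fp@label, mode_label)
    expect_setequal(names(fp@votes), forestFeatures())
  }
})

test_that("removing a tree changes the tally by exactly one vote", {
  tab <- simulatePairTable(simConfig(nAntigens = 2, pairsPerAntigen = 6,
                                     seed = 33, mutationRate = 0.1))
  full <- forestPredict(tab[1], tab[-1])
  sub <- forestPredict(tab[1], tab[-1],
                       featureTrees(features = forestFeatures()[-13]))
  expect_identical(fullTally <- full@tallyGood + full@tallyPoor, 13L)
  expect_identical(sub@tallyGood + sub@tallyPoor, 12L)
  removed <- full@votes[[13]]
  if (removed == "GOOD") {
    expect_identical(sub@tallyGood, full@tallyGood - 1L)
  } else {
    expect_identical(sub@tallyPoor, full@tallyPoor - 1L)
  }
})

test_that("an even subset forest breaks exact ties toward GOOD", {
  # two-tree forest engineered to split 1-1: the string tree sees a GOOD
  # duplicate, the pI tree sees a POOR value match
  cdrs_q <- base_cdrs
  cdrs_far <- base_cdrs
  for (i in 1:6) cdrs_far <- mutate_cdr(cdrs_far, i, 1, "P")
  tab <- forest_fixture(c(6.0, 9.0, 6.0), c("GOOD", "GOOD", "POOR"),
                        cdrs = list(cdrs_q, cdrs_q, cdrs_far))
  trees <- list(featureTree("cdr_string_distance", 1),
                featureTree("pi_l_cdr1", 1))
  fp <- forestPredict(tab[1], tab[-1], trees)
  expect_identical(sort(unname(fp@votes)), c("GOOD", "POOR"))
  expect_identical(fp@label, "GOOD")
  expect_identical(forestPredict(tab[1], tab[-1], trees,
                                 tieBreak = "POOR")@label, "POOR")
})
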