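test_that("an exact same-antigen duplicate is the first neighbor and wins", {
  far <- base_cdrs
  for (i in 1:6) far <- mutate_cdr(far, i, 1, "P")
  tab <- toy_table(list(base_cdrs, base_cdrs, far),
                   c("ag1", "ag1", "ag1"), c("POOR", "GOOD", "POOR"))
  nb <- findNeighbors(tab[1], tab[-1], k = 2)
  expect_identical(nb$distance[1], 0)
  expect_identical(nb$label[1], "GOOD")
  # 1/epsilon dominance: the zero-distance duplicate outvotes any finite
  # opposing weight
  pred <- knnPredict(tab[1], tab[-1], k = 2)
  expect_identical(pred@label, "GOOD")
  expect_gt(pred@weightGood, 1e7)
})

test_that("inverse-distance weights decide the vote", {
  # GOOD neighbor at distance 0.5 (one L->I substitution under BLOSUM62
  # costs), POOR neighbor at distance 4 (four radical substitutions):
  # weights 1/0.5 = 2 vs 1/4 = 0.25
  cdrs_q <- base_cdrs                       # l_cdr1 = QSLLNSRTRKNY
  cdrs_g <- mutate_cdr(base_cdrs, 4, 3, "I")  # L -> I, cost 0.5
  cdrs_p <- base_cdrs
  for (pos in 1:4) cdrs_p <- mutate_cdr(cdrs_p, 2, pos, "D")  # cost 1 each
  tab <- toy_table(list(cdrs_q, cdrs_g, cdrs_p), rep("ag1", 3),
                   c("GOOD", "GOOD", "POOR"))
  bl <- blosum62CostModel()
  expect_equal(antibodyDistance(cdrSet(tab, 1), cdrSet(tab, 2), bl), 0.5)
  expect_equal(antibodyDistance(cdrSet(tab, 1), cdrSet(tab, 3), bl), 4)
  pred <- knnPredict(tab[1], tab[-1], k = 2, model = bl)
  expect_identical(pred@label, "GOOD")
  expect_equal(pred@weightGood, 2, tolerance = 1e-6)
  expect_equal(pred@weightPoor, 0.25, tolerance = 1e-6)
  # unanimous neighbors
  tab2 <- toy_table(list(cdrs_q, cdrs_g, cdrs_p), rep("ag1", 3),
                    c("POOR", "GOOD", "GOOD"))
  expect_identical(knnPredict(tab2[1], tab2[-1], k = 2, model = bl)@label,
                   "GOOD")
})

test_that("k is bounded by the training size and k = n returns all, sorted", {
  tab <- simulatePairTable(simConfig(nAntigens = 2, pairsPerAntigen = 4,
                                     seed = 2))
  expect_error(findNeighbors(tab[1], tab[-1], k = 8), "exceeds")
  nb <- findNeighbors(tab[1], tab[-1], k = 7)
  expect_equal(base::nrow(nb), 7L)
  expect_false(is.unsorted(nb$distance))
  expect_setequal(nb$index, 1:7)
})

test_that("cross-antigen rows fill remaining slots at penalized distances", {
  tab <- toy_table(list(base_cdrs, base_cdrs, mutate_cdr(base_cdrs, 1, 1, "P")),
                   c("ag1", "ag1", "ag2"), c("GOOD", "GOOD", "POOR"))
  nb <- findNeighbors(tab[1], tab[-1], k = 2)
  expect_identical(nb$sameAntigen, c(TRUE, FALSE))
  expect_gte(nb$distance[2], 1000)
})

test_that("prediction is invariant to training-row permutation", {
  tab <- simulatePairTable(simConfig(nAntigens = 3, pairsPerAntigen = 6,
                                     seed = 31, mutationRate = 0.1))
  training <- tab[-1]
  p0 <- knnPredict(tab[1], training, k = 2)
  set.seed(4)
  for (r in 1:5) {
    perm <- sample(nrow(training))
    pp <- knnPredict(tab[1], training[perm], k = 2)
    expect_identical(pp@label, p0@label)
    expect_equal(pp@weightGood, p0@weightGood)
    expect_equal(pp@weightPoor, p0@weightPoor)
  }
})

test_that("k = 1 returns the nearest neighbor's label", {
  tab <- simulatePairTable(simConfig(nAntigens = 3, pairsPerAntigen = 5,
                                     seed = 8, mutationRate = 0.15))
  for (i in c(1L, 5L, 12L)) {
    nb <- findNeighbors(tab[i], tab[-i], k = 1)
    expect_identical(knnPredict(tab[i], tab[-i], k = 1)@label, nb$label[1])
  }
})

test_that("cross-antigen records cannot change covered predictions", {
  # with >= k same-antigen training rows (within-antigen distances < 1000),
  # adding records from other antigens never alters the prediction
  set.seed(17)
  for (trial in 1:5) {
    tab <- simulatePairTable(simConfig(nAntigens = 3, pairsPerAntigen = 6,
                                       seed = 100 + trial,
                                       mutationRate = 0.08))
    ag <- antigenIds(tab)
    own <- which(ag == "AG001")
    for (i in own[1:3]) {
      sameOnly <- tab[setdiff(own, i)]
      all_ <- tab[-i]
      expect_identical(knnPredict(tab[i], all_, k = 2)@label,
                       knnPredict(tab[i], sameOnly, k = 2)@label)
    }
  }
})

test_that("unlabeled or REVIEW training tables are refused", {
  rec <- records(simulatePairTable(simConfig(nAntigens = 2,
                                             pairsPerAntigen = 3, seed = 6)))
  rec$label[2] <- "REVIEW"
  tab <- PairTable(rec)
  expect_error(knnPredict(tab[1], tab[-1], k = 1), "resolveReview")
  rec$label[2] <- NA
  tab2 <- PairTable(rec)
  expect_error(knnPredict(tab2[1], tab2[-1], k = 1), "labeled")
})
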