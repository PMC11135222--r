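test_that("zero mutation and noise reproduce the archetypes exactly", {
  tab <- simulatePairTable(simConfig(nAntigens = 3, pairsPerAntigen = 8,
                                     mutationRate = 0, labelNoise = 0,
                                     seed = 2))
  rec <- records(tab)
  for (ag in unique(rec$antigen)) {
    sub <- rec[rec$antigen == ag, ]
    for (cls in c("GOOD", "POOR")) {
      rows <- sub[sub$label == cls, ]
      if (base::nrow(rows) > 1L) {
        for (cc in c("h_cdr1", "h_cdr2", "h_cdr3",
                     "l_cdr1", "l_cdr2", "l_cdr3"))
          expect_length(unique(rows[[cc]]), 1L)
      }
    }
    # archetypes differ by the configured separation per CDR
    g <- sub[sub$label == "GOOD", ][1, ]
    p <- sub[sub$label == "POOR", ][1, ]
    for (cc in c("h_cdr1", "l_cdr2")) {
      diffs <- sum(strsplit(g[[cc]], "")[[1]] != strsplit(p[[cc]], "")[[1]])
      expect_identical(diffs, 4L)
    }
  }
})

test_that("generation is seed-deterministic", {
  cfg <- simConfig(nAntigens = 2, pairsPerAntigen = 5, seed = 99)
  t1 <- simulatePairTable(cfg)
  t2 <- simulatePairTable(cfg)
  expect_identical(records(t1), records(t2))
  t3 <- simulatePairTable(simConfig(nAntigens = 2, pairsPerAntigen = 5,
                                    seed = 100))
  expect_false(identical(records(t1), records(t3)))
})

test_that("stored feature columns equal recomputation to 1e-9", {
  tab <- simulatePairTable(simConfig(nAntigens = 2, pairsPerAntigen = 6,
                                     seed = 50))
  re <- featurizeTable(tab)
  for (fc in grep("^(hyd|pi)_", names(records(tab)), value = TRUE))
    expect_equal(records(tab)[[fc]], records(re)[[fc]], tolerance = 1e-9)
})

test_that("class balance tracks the configured probability", {
  tab <- simulatePairTable(simConfig(nAntigens = 10, pairsPerAntigen = 20,
                                     classBalance = 0.7, seed = 31))
  frac <- mean(bindingLabels(tab) == "GOOD")
  se <- sqrt(0.7 * 0.3 / nrow(tab))
  expect_lt(abs(frac - 0.7), 4 * se)
})

test_that("label noise flips labels away from the class archetype", {
  tab <- simulatePairTable(simConfig(nAntigens = 4, pairsPerAntigen = 25,
                                     labelNoise = 0.3, seed = 13))
  rec <- records(tab)
  flipped <- mean(rec$label != rec$class_archetype)
  expect_gt(flipped, 0.15)
  expect_lt(flipped, 0.45)
})

test_that("mutation load degrades mean LOOCV accuracy monotonically", {
  # rates span the regime from clean archetypes to near-random sequences
  rates <- c(0.05, 0.6, 0.8)
  means <- vapply(rates, function(r) {
    accs <- vapply(1:10, function(s) {
      tab <- simulatePairTable(simConfig(nAntigens = 6, pairsPerAntigen = 10,
                                         mutationRate = r, seed = 300 + s))
      accuracy(loocv(tab, k = 2))
    }, 0)
    mean(accs)
  }, 0)
  expect_true(all(diff(means) <= 0))
})

test_that("simulated scores land in their class band and round-trip", {
  cfg <- simConfig(seed = 8)
  labels <- rep(c("GOOD", "POOR"), 50)
  sc <- simulateScores(labels, cfg)
  flag <- attr(sc, "review")
  clean <- !flag
  expect_identical(classifyInterfaceScore(sc[clean]), labels[clean])
  # bands at 3+ SD from the review interval: essentially no review draws
  expect_lt(mean(flag), 0.05)
  badCfg <- simConfig(scoreBands = list(GOOD = c(mean = -8.5, sd = 0.3),
                                        POOR = c(mean = -7, sd = 0.3)))
  expect_error(simulateScores(labels, badCfg), "review interval")
})

test_that("docking scores in a generated table match their labels", {
  tab <- simulatePairTable(simConfig(nAntigens = 3, pairsPerAntigen = 10,
                                     seed = 61))
  rec <- records(tab)
  cls <- classifyInterfaceScore(rec$docking_score)
  ok <- cls != "REVIEW"
  expect_identical(cls[ok], rec$label[ok])
})

test_that("unsatisfiable archetype separation is refused", {
  expect_error(simConfig(cdrLengths = c(3, 3, 3, 3, 3, 3), separation = 4),
               "separation")
})

test_that("the study-scale pipeline reproduces its frozen regression accuracy", {
  # 57 antigens x 20 pairs, separation 4, mutation 0.02, no noise, seed 1;
  # value frozen from one pipeline run
  tab <- simulatePairTable(simConfig(seed = 1))
  expect_identical(nrow(tab), 1140L)
  rep <- loocv(tab, k = 2, model = blosum62CostModel())
  expect_identical(accuracy(rep), 1)
  expect_gte(accuracy(rep), 0.95)
})
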