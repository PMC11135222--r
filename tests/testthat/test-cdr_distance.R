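test_that("edit distance handles identity, empties, and known cases", {
  id <- identityCostModel()
  bl <- blosum62CostModel()
  expect_identical(editDistance("KASQ", "KASQ", id), 0)
  expect_identical(editDistance("ACD", "", id), 3)
  expect_identical(editDistance("", "ACD", id), 3)
  expect_identical(editDistance("", "", id), 0)
  # frozen from the exhaustive edit-script enumeration oracle
  expect_identical(editDistance("KASQ", "KASE", id), 1)
  expect_equal(editDistance("KASQ", "KASE", bl), 0.6, tolerance = 1e-12)
  expect_equal(editDistance("KASQ", "KASE", bl),
               brute_edit("KASQ", "KASE", bl))
  expect_error(editDistance("KAS1Q", "KASQ", id), "invalid residue")
})

test_that("the dynamic program matches exhaustive enumeration on short strings", {
  strs <- all_strings(c("A", "C", "D", "G"), 3)
  idx <- expand.grid(i = seq_along(strs), j = seq_along(strs))
  a <- strs[idx$i]
  b <- strs[idx$j]
  for (model in list(identityCostModel(), blosum62CostModel())) {
    expect_equal(editDistance(a, b, model), brute_edit(a, b, model),
                 tolerance = 1e-12)
  }
})

test_that("identity-model edit distance is a metric", {
  id <- identityCostModel()
  set.seed(11)
  x <- rand_peps(60, 1, 10)
  y <- rand_peps(60, 1, 10)
  z <- rand_peps(60, 1, 10)
  dxy <- editDistance(x, y, id)
  dyx <- editDistance(y, x, id)
  dyz <- editDistance(y, z, id)
  dxz <- editDistance(x, z, id)
  expect_true(all(dxy >= 0))
  expect_identical(dxy, dyx)
  expect_true(all(dxz <= dxy + dyz))
  expect_identical(editDistance(x, x, id), rep(0, length(x)))
})

test_that("edit distance never exceeds deleting and re-inserting everything", {
  set.seed(19)
  x <- rand_peps(40, 0 + 1, 12)
  y <- rand_peps(40, 0 + 1, 12)
  for (model in list(identityCostModel(), blosum62CostModel(),
                     blosum62CostModel("linear"))) {
    expect_true(all(editDistance(x, y, model) <=
                      indelCost(model) * (nchar(x) + nchar(y))))
  }
})

test_that("BLOSUM62 costs are zero on identity, symmetric, and graded", {
  m <- costMatrix(blosum62CostModel())
  expect_true(all(diag(m) == 0))
  expect_identical(m, t(m))
  expect_true(all(m >= 0 & m <= 1))
  # conservative substitution cheaper than radical one, per the embedded
  # matrix arithmetic: S_LI = 2, S_LL = S_II = 4; S_LD = -4, S_DD = 6
  s <- blosum62Matrix()
  expect_equal(m["L", "I"], 1 - 2 * s["L", "I"] / (s["L", "L"] + s["I", "I"]))
  expect_lt(m["L", "I"], m["L", "D"])
  expect_identical(m["L", "D"], 1)  # clamped at the identity-model scale
  # linear normalization spans [0, 1] exactly
  ml <- costMatrix(blosum62CostModel("linear"))
  expect_equal(max(ml), 1)
  expect_true(all(diag(ml) == 0))
})

test_that("the embedded BLOSUM62 rendition matches an independent copy", {
  ref <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  aa <- aminoAcids()
  # renditions differ in ambiguity-code conventions (B/Z/X/J rows), so the
  # cross-check covers the 20-residue block the distance model uses
  expect_true(all(blosum62Matrix() == ref[aa, aa]))
  full <- blosum62Matrix(full = TRUE)
  expect_identical(full, t(full))
})

test_that("the NCBI-format matrix reader validates its input", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "  A C", "A 4 0", "C 0 9"), path)
  m <- readSubstitutionMatrix(path)
  expect_identical(m, matrix(c(4L, 0L, 0L, 9L), 2, 2,
                             dimnames = list(c("A", "C"), c("A", "C"))))
  writeLines(c("  A C", "A 4 0", "C 0"), path)
  expect_error(readSubstitutionMatrix(path), "malformed")
  expect_error(readSubstitutionMatrix("/nonexistent/m.txt"), "not found")
})

test_that("antibody distance is the Euclidean norm of the six CDR distances", {
  id <- identityCostModel()
  p <- do.call(AntibodyCdrSet, as.list(base_cdrs))
  expect_identical(antibodyDistance(p, p, id), 0)
  # one CDR differs by distance 2, rest identical -> distance 2
  q_cdrs <- mutate_cdr(mutate_cdr(base_cdrs, 3, 1, "S"), 3, 2, "T")
  q <- do.call(AntibodyCdrSet, as.list(q_cdrs))
  expect_identical(antibodyDistance(p, q, id), 2)
  expect_identical(antibodyDistance(q, p, id), 2)
  # all six CDRs at distance 1 -> sqrt(6)
  r_cdrs <- base_cdrs
  for (i in 1:6) r_cdrs <- mutate_cdr(r_cdrs, i, 1, "P")
  stopifnot(!mapply(identical, r_cdrs, base_cdrs))
  r <- do.call(AntibodyCdrSet, as.list(r_cdrs))
  expect_equal(antibodyDistance(p, r, id), sqrt(6))
  v <- cdrDistanceVector(p, r, id)
  expect_identical(unname(v), rep(1, 6))
})

test_that("the cross-antigen penalty is additive and flagged", {
  id <- identityCostModel()
  tab <- toy_table(list(base_cdrs, base_cdrs,
                        mutate_cdr(base_cdrs, 1, 1, "P")),
                   c("ag1", "ag2", "ag2"), c("GOOD", "GOOD", "POOR"))
  same <- pairDistance(tab[2], tab[3], id)
  expect_true(same$sameAntigen)
  expect_identical(same$value, 1)
  cross0 <- pairDistance(tab[1], tab[2], id)
  expect_false(cross0$sameAntigen)
  expect_identical(cross0$value, 1000)
  cross <- pairDistance(tab[1], tab[3], id)
  expect_identical(cross$value,
                   1000 + antibodyDistance(cdrSet(tab, 1), cdrSet(tab, 3), id))
  D <- pairDistanceMatrix(tab, model = id)
  expect_identical(D[1, 2], 1000)
  expect_identical(D[2, 3], 1)
  expect_identical(diag(D), rep(0, 3))
})
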