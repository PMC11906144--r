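test_that("k-mer counting matches hand-counted examples", {
  c1 <- kmerCounts("AAG", 1)
  expect_equal(length(c1), 20L)
  expect_equal(unname(c1[c("A", "G", "C")]), c(2L, 1L, 0L))
  c2 <- kmerCounts("AAG", 2)
  expect_equal(length(c2), 400L)
  expect_equal(unname(c2[c("AA", "AG", "GA")]), c(1L, 1L, 0L))
  expect_equal(sum(c2), 2L)
  c3 <- kmerCounts("AAG", 3)
  expect_equal(length(c3), 8000L)
  expect_equal(unname(c3["AAG"]), 1L)
  expect_equal(sum(c3), 1L)
})

test_that("proportions normalize over windows", {
  p1 <- kmerProportions("AAG", 1)
  expect_equal(unname(p1[c("A", "G")]), c(2 / 3, 1 / 3))
  expect_equal(unname(kmerProportions("AAAA", 2)["AA"]), 1)
})

test_that("count conservation and normalization hold on random sequences", {
  set.seed(11)
  for (i in 1:100) {
    len <- sample(5:60, 1)
    s <- randomAASequence(len)
    for (k in 1:3) {
      expect_identical(sum(kmerCounts(s, k)), len - k + 1L)
      expect_equal(sum(kmerProportions(s, k)), 1, tolerance = 1e-9)
    }
  }
})

test_that("invalid sequences are rejected with position information", {
  expect_error(kmerCounts("AG", 3), "shorter")
  expect_error(kmerCounts("AXG", 1), "'X' at position 2")
  expect_error(kmerCounts("ABG", 2), "'B'")
})

test_that("composition is shuffle-invariant but adjacency is not", {
  set.seed(3)
  s <- randomAASequence(40)
  shuffled <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(kmerCounts(s, 1), kmerCounts(shuffled, 1))
  expect_false(identical(kmerCounts("AG", 2), kmerCounts("GA", 2)))
})

test_that("alignment one-hot is a valid per-position indicator", {
  aln <- Biostrings::AAStringSet(c(r1 = "A-", r2 = "AA"))
  fb <- alignmentOneHot(aln)
  m <- featureMatrix(fb)
  expect_equal(dim(m), c(2L, 42L))
  expect_equal(unname(rowSums(m)), c(2, 2))
  # one 1 in every 21-slot position block
  for (i in 1:2) for (p in 1:2)
    expect_equal(sum(m[i, (p - 1) * 21 + 1:21]), 1)
  expect_equal(unname(m["r1", "pos2_-"]), 1)  # gap state is explicit

  expect_error(alignmentOneHot(Biostrings::AAStringSet(c(a = "A", b = "AG"))),
               "unequal")
})

test_that("featurizeReceptors produces the advertised vocabularies", {
  recs <- tinyReceptors()
  expect_equal(dim(featurizeReceptors(recs, "1AAF")), c(3L, 20L))
  expect_equal(dim(featurizeReceptors(recs, "2AAF")), c(3L, 400L))
  expect_equal(dim(featurizeReceptors(recs, "3AAF")), c(3L, 8000L))

  perc <- featureMatrix(featurizeReceptors(recs, "1AAFperc"))
  expect_equal(unname(rowSums(perc)), rep(1, 3), tolerance = 1e-9)
  perc100 <- featureMatrix(featurizeReceptors(recs, "1AAFperc",
                                              percentScale = TRUE))
  expect_equal(unname(rowSums(perc100)), rep(100, 3), tolerance = 1e-6)

  expect_error(featurizeReceptors(recs, "alignment"), "alignment")
  aln <- Biostrings::AAStringSet(
    stats::setNames(rep("MK-TA", 3), names(recs)))
  fb <- featurizeReceptors(recs, "alignment", alignment = aln)
  expect_equal(ncol(featureMatrix(fb)), 5L * 21L)
})
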