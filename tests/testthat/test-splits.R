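# Split algebra: encodings, canonical forms, compatibility, circularity,
# weight retention.

test_that("split encoding of small trees has the expected splits and weights", {
  pr <- readTreeProfile(text = "((a:1,b:1):1,c:1,d:1);")
  enc <- splitEncoding(pr$trees[[1]], pr$taxa)
  expect_equal(nSplits(enc), 5L)           # 4 trivial + ab|cd
  expect_true(all(enc$weight == 1))
  sizes <- sort(vapply(enc$parts, length, 1L))
  expect_equal(sizes, c(1L, 1L, 1L, 2L, 3L))  # {b},{c},{d},{c,d},{b,c,d}
  star <- readTreeProfile(text = "(a:1,b:1,c:1,d:1,e:1);")
  encS <- splitEncoding(star$trees[[1]], star$taxa)
  expect_equal(nSplits(encS), 5L)
  expect_true(all(isTrivialSplit(encS)))
})

test_that("a random binary tree on n taxa has exactly 2n-3 splits", {
  for (seed in 1:25) {
    n <- sample(4:20, 1)
    phy <- randomTree(n, seed = seed)
    enc <- splitEncoding(phy, sort(phy$tip.label))
    expect_equal(nSplits(enc), 2L * n - 3L)
  }
})

test_that("split encodings agree with the phangorn oracle", {
  skip_if_not_installed("phangorn")
  for (seed in 1:5) {
    phy <- randomTree(8, seed = seed)
    taxa <- sort(phy$tip.label)
    enc <- splitEncoding(phy, taxa)
    ph <- phangorn::as.splits(phy)
    phKeys <- vapply(ph, function(s) {
      part <- sort(match(attr(ph, "labels")[s], taxa))
      if (1L %in% part) part <- setdiff(seq_along(taxa), part)
      paste(part, collapse = " ")
    }, "")
    phKeys <- phKeys[!phKeys %in% c("", paste(seq_along(taxa), collapse = " "))]
    expect_setequal(splitKeys(enc, canonical = TRUE), unique(phKeys))
  }
})

test_that("canonical keys avoid x0 and are stable under part flips", {
  taxa <- letters[1:6]
  s1 <- splitSystem(taxa, list(c(2L, 3L)), 1, 1, x0 = 1L)
  s2 <- splitSystem(taxa, list(c(1L, 4L, 5L, 6L)), 1, 1, x0 = 2L)
  # {b,c}|{a,d,e,f} seen from x0=a and from x0=b is the same bipartition
  expect_identical(splitKeys(s1, canonical = TRUE),
                   splitKeys(s2, canonical = TRUE))
  expect_error(splitSystem(taxa, list(c(1L, 2L)), 1, 1, x0 = 1L),
               "must not contain x0")
  expect_error(splitSystem(taxa, list(2L, 2L), c(1, 1), c(1, 1)), "duplicate")
})

test_that("compatibility follows the empty-intersection rule", {
  taxa <- letters[1:4]
  sys <- splitSystem(taxa, list(c(3L, 4L), c(2L, 4L), 2L), c(1, 1, 1), c(1, 1, 1))
  expect_false(areCompatible(sys, 1, 2))   # ab|cd vs ac|bd
  expect_true(areCompatible(sys, 1, 3))    # anything vs trivial
  expect_true(areCompatible(sys, 2, 3))
  # all pairs within one tree's encoding are compatible
  for (seed in 1:8) {
    phy <- randomTree(9, seed = seed)
    enc <- splitEncoding(phy, sort(phy$tip.label))
    k <- nSplits(enc)
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
      expect_true(areCompatible(enc, i, j))
  }
})

test_that("circularity: tree encodings are circular, crossing quartets are not", {
  # splits {b,c}|rest and {c,d}|rest are both intervals of (a,b,c,d,e)
  taxa <- letters[1:5]
  sys <- splitSystem(taxa, list(c(2L, 3L), c(3L, 4L)), c(1, 1), c(1, 1))
  expect_true(isCircular(sys, 1:5))
  bad <- splitSystem(letters[1:4], list(c(2L, 4L)), 1, 1)  # {b,d} vs (a,b,c,d)
  expect_false(isCircular(bad, 1:4))
  for (seed in 1:10) {
    phy <- randomTree(sample(5:12, 1), seed = seed)
    taxa <- sort(phy$tip.label)
    enc <- splitEncoding(phy, taxa)
    pq <- pqNew(length(taxa))
    for (p in enc$parts) pqAccept(pq, p)
    expect_true(isCircular(enc, pqExtractOrdering(pq)))
  }
  expect_error(isCircular(sys, c(1L, 1L, 2L, 3L, 4L)), "permutation")
})

test_that("profile split pooling counts supports and averages weights", {
  pr <- quartetProfile()  # ab|cd twice, ac|bd once
  S <- extractProfileSplits(pr)
  kAB <- which(vapply(S$parts, function(p) identical(p, c(3L, 4L)), TRUE))
  kAC <- which(vapply(S$parts, function(p) identical(p, c(2L, 4L)), TRUE))
  expect_equal(S$treeCount[kAB], 2L)
  expect_equal(S$treeCount[kAC], 1L)
  expect_true(all(S$treeCount[isTrivialSplit(S)] == 3L))
  # identical trees: every split has support m
  prI <- makeProfile(7, 4, "yule_identical", seed = 9)
  SI <- extractProfileSplits(prI)
  expect_true(all(SI$treeCount == 4L))
  expect_equal(nSplits(SI), 11L)
})

test_that("two trees sharing no internal split: internal support 1, trivial 2", {
  pr <- readTreeProfile(text = paste(
    "(((a:1,b:1):1,c:1):1,d:1,e:1);",
    "(((a:1,d:1):1,c:1):1,b:1,e:1);", sep = "\n"))
  S <- extractProfileSplits(pr)
  triv <- isTrivialSplit(S)
  expect_true(all(S$treeCount[triv] == 2L))
  expect_true(all(S$treeCount[!triv] == 1L))
})

test_that("edge_support mode sums edge labels and rejects unlabeled trees", {
  pr <- readTreeProfile(text = paste(
    "((a:1,b:1)90:1,c:1,d:1);",
    "((a:1,b:1)60:2,c:1,d:1);", sep = "\n"))
  S <- extractProfileSplits(pr, supportMode = "edge_support")
  k <- which(vapply(S$parts, length, 1L) == 2L)
  expect_equal(S$support[k], 150)
  expect_equal(S$weight[k], 1.5)   # mean of the two branch lengths
  bare <- readTreeProfile(text = "((a:1,b:1):1,c:1,d:1);\n((a:1,b:1):1,c:1,d:1);")
  expect_error(extractProfileSplits(bare, supportMode = "edge_support"),
               "no support labels")
})

test_that("weight retention matches a hand computation and is monotone", {
  pr <- readTreeProfile(text = paste(
    "((a:1,b:2):1,c:3,(d:1,e:1):2);",   # L = 11
    "((a:2,c:1):1,b:1,(d:2,e:2):1);",   # L = 10
    sep = "\n"))
  S <- extractProfileSplits(pr)
  expect_equal(weightRetention(S, S, pr), 100)
  expect_equal(weightRetention(S, S[integer(0)], pr), 0)
  trivOnly <- S[isTrivialSplit(S)]
  # trivial contributions: (1+2+3+1+1)/11 + (2+1+1+2+2)/10, total 11/11 + 10/10
  expect_equal(weightRetention(S, trivOnly, pr),
               100 * (8 / 11 + 8 / 10) / 2, tolerance = 1e-12)
  # monotone in the kept set
  set.seed(7)
  ord <- sample(nSplits(S))
  last <- 0
  for (k in seq_along(ord)) {
    r <- weightRetention(S, S[sort(ord[seq_len(k)])], pr)
    expect_gte(r, last - 1e-12)
    last <- r
  }
  expect_error(weightRetention(trivOnly, S, pr), "subset")
})

test_that("zero-length trees make retention undefined", {
  pr <- readTreeProfile(text = "((a:0,b:0):0,c:0,d:0);")
  S <- extractProfileSplits(pr)
  expect_error(weightRetention(S, S, pr), "total length 0")
})
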