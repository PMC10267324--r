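# Reading/writing tree profiles and split systems.

test_that("multi-tree Newick parses with the shared lexicographic taxon space", {
  pr <- readTreeProfile(text = "((a:1,b:1):1,(c:1,d:1):1);\n((a:1,c:1):1,(b:1,d:1):1);")
  expect_equal(nTaxa(pr), 4L)
  expect_equal(nTrees(pr), 2L)
  expect_identical(pr$taxa, c("a", "b", "c", "d"))
})

test_that("internal-node numeric labels become edge support, others warn", {
  pr <- readTreeProfile(text = "((a:1,b:1)95:2,c:1,d:1);")
  enc <- splitEncoding(pr$trees[[1]], pr$taxa)
  k <- which(vapply(enc$parts, length, 1L) == 2L)
  expect_equal(enc$weight[k], 2)
  expect_equal(enc$support[k], 95)
  expect_warning(readTreeProfile(text = "((a:1,b:1)cladeX:2,c:1,d:1);"),
                 "node labels ignored")
})

test_that("degenerate and malformed inputs fail loudly", {
  expect_error(readTreeProfile(text = "(a:1,b:1);"), "at least 3 taxa")
  expect_error(readTreeProfile(text = "((a:1,b:1):1,(c:1,d:1):1;"), "parse error")
  expect_error(readTreeProfile(text = "((a:1,b:1):1,c:1,d:1);\n((a:1,b:1):1,c:1,e:1);"),
               "tree 2.*symmetric difference.*d.*e")
})

test_that("rooted input is unrooted: the two root edges merge into one split", {
  pr <- readTreeProfile(text = "((a:1,b:1):2,(c:1,d:1):3);")
  enc <- splitEncoding(pr$trees[[1]], pr$taxa)
  expect_equal(nSplits(enc), 5L)
  k <- which(vapply(enc$parts, length, 1L) == 2L)
  expect_equal(enc$weight[k], 5)  # 2 + 3 summed across the old root
  # unrooting is idempotent: re-normalising changes nothing
  again <- treeProfile(pr$trees)
  expect_equal(splitKeys(splitEncoding(again$trees[[1]], again$taxa)),
               splitKeys(enc))
})

test_that("missing branch lengths default to 1 with a warning", {
  expect_warning(pr <- readTreeProfile(text = "((a,b),c,d);"), "branch lengths")
  expect_true(all(pr$trees[[1]]$edge.length == 1))
})

test_that("profiles survive a Newick write/read round trip", {
  pr <- makeProfile(9, 4, "bootstrap_like", nniRate = 0.2, seed = 21)
  f <- tempfile(fileext = ".nwk")
  writeTreeProfile(pr, f)
  pr2 <- readTreeProfile(f)
  expect_identical(pr2$taxa, pr$taxa)
  for (i in seq_len(nTrees(pr))) {
    a <- splitEncoding(pr$trees[[i]], pr$taxa)
    b <- splitEncoding(pr2$trees[[i]], pr2$taxa)
    expect_setequal(splitKeys(a), splitKeys(b))
    m <- match(splitKeys(b), splitKeys(a))
    expect_equal(b$weight, a$weight[m], tolerance = 1e-9)
  }
})

test_that("Nexus TREES blocks (with translate table) are readable", {
  pr <- makeProfile(6, 3, "nni_mixture", seed = 4)
  f <- tempfile(fileext = ".nex")
  ape::write.nexus(structure(pr$trees, class = "multiPhylo"), file = f)
  pr2 <- readTreeProfile(f)
  expect_equal(nTrees(pr2), 3L)
  expect_identical(pr2$taxa, pr$taxa)
})

test_that("SPLITS Nexus: canonical serialization and exact round trip", {
  taxa <- c("a", "b", "c", "d")
  sys <- splitSystem(taxa, list(c(2L, 3L, 4L), c(3L, 4L)), c(1, 1.5), c(3, 2))
  f <- tempfile(fileext = ".nex")
  writeSplitsNexus(sys, f, ordering = c(1L, 2L, 3L, 4L))
  txt <- readLines(f)
  expect_true(any(grepl("DIMENSIONS ntax=4 nsplits=2;", txt)))
  expect_true(any(grepl("^2 1.5 2 3 4,$", txt)))
  expect_true(any(grepl("^CYCLE 1 2 3 4;$", txt)))
  rt <- readSplitsNexus(f)
  expect_identical(splitKeys(rt$splits), splitKeys(sys))
  expect_equal(rt$splits$weight, sys$weight)
  expect_equal(rt$splits$support, sys$support)
  expect_identical(rt$ordering, 1:4)
  # empty system is still a valid file
  writeSplitsNexus(splitSystem(taxa), f)
  expect_equal(nSplits(readSplitsNexus(f)$splits), 0L)
  # a larger random circular system round-trips exactly
  rc <- randomCircularSystem(9, 20, seed = 2)
  writeSplitsNexus(rc$splits, f, ordering = rc$ordering)
  rt <- readSplitsNexus(f)
  expect_identical(splitKeys(rt$splits), splitKeys(rc$splits))
  expect_identical(rt$splits$weight, rc$splits$weight)
  expect_identical(rt$splits$support, rc$splits$support)
  expect_identical(rt$ordering, rc$ordering)
})

test_that("compatible splits write as the tree that encodes them", {
  phy <- randomTree(8, seed = 13)
  taxa <- sort(phy$tip.label)
  enc <- splitEncoding(phy, taxa)
  nwk <- writeTreeNewick(enc)
  pr <- readTreeProfile(text = nwk)
  enc2 <- splitEncoding(pr$trees[[1]], pr$taxa)
  expect_setequal(splitKeys(enc2, canonical = TRUE),
                  splitKeys(enc, canonical = TRUE))
  m <- match(splitKeys(enc2, canonical = TRUE), splitKeys(enc, canonical = TRUE))
  expect_equal(enc2$weight, enc$weight[m], tolerance = 1e-9)
  # only trivial splits: a star tree
  taxa4 <- letters[1:4]
  triv <- splitSystem(taxa4, list(c(2L, 3L, 4L), 2L, 3L, 4L), rep(1, 4), rep(1, 4))
  star <- readTreeProfile(text = writeTreeNewick(triv))
  expect_true(all(isTrivialSplit(splitEncoding(star$trees[[1]], star$taxa))))
  # the classic incompatible quartet pair is refused
  bad <- splitSystem(taxa4, list(c(3L, 4L), c(2L, 4L)), c(1, 1), c(1, 1))
  expect_error(writeTreeNewick(bad), "incompatible split pair")
})
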