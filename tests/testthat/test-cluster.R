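test_that("euclidean distances match hand arithmetic and a loop oracle", {
  x <- rbind(a = c(0, 0), b = c(3, 4), c = c(0, 0))
  d <- as.matrix(euclideanDistances(x))
  expect_equal(d["a", "b"], 5)
  expect_equal(d["a", "c"], 0)
  expect_equal(diag(d), setNames(rep(0, 3), rownames(x)))

  set.seed(31)
  y <- matrix(rnorm(40), 5, 8,
              dimnames = list(paste0("s", 1:5), NULL))
  dm <- as.matrix(euclideanDistances(y))
  for (i in 1:5) for (j in 1:5)
    expect_equal(dm[i, j], sqrt(sum((y[i, ] - y[j, ])^2)),
                 tolerance = 1e-10)

  y[2, 3] <- NA
  expect_error(euclideanDistances(y), "s2")
})

test_that("Ward linkage merges the closest pair first and stays monotone", {
  two <- dist(matrix(c(1, 1), 2, 1, dimnames = list(c("p", "q"), NULL)))
  h <- wardLinkage(two)
  expect_equal(h$height, 0)
  expect_identical(sort(h$merge[1, ]), c(-2L, -1L))

  pts <- matrix(c(0, 1, 10), 3, 1,
                dimnames = list(c("x0", "x1", "x10"), NULL))
  h3 <- wardLinkage(dist(pts))
  expect_identical(sort(h3$merge[1, ]), c(-2L, -1L))  # {0, 1} first
  cl <- cutDendrogram(h3, 2)
  expect_identical(unname(cl["x0"]), unname(cl["x1"]))
  expect_false(cl["x0"] == cl["x10"])

  set.seed(41)
  big <- matrix(rnorm(80), 10, 8)
  hb <- wardLinkage(dist(big))
  expect_true(all(diff(hb$height) >= -1e-12))

  asym <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(wardLinkage(asym), "symmetric")
})

test_that("Ward linkage agrees with the exhaustive variance-increase oracle", {
  set.seed(51)
  for (trial in 1:25) {
    n <- sample(3:6, 1)
    x <- matrix(rnorm(n * 4), n, 4)
    h <- wardLinkage(dist(x))
    oracle <- wardOracle(x)
    expect_equal(h$height, oracle$heights, tolerance = 1e-9)
    for (s in seq_len(n - 1))
      expect_identical(
        partitionSignature(hclustPartition(h, n - s)),
        partitionSignature(oracle$partitions[[s]]))
  }
})

test_that("Ward linkage reproduces stats::hclust ward.D2 exactly", {
  set.seed(61)
  x <- matrix(rnorm(15 * 6), 15, 6,
              dimnames = list(sprintf("s%02d", 1:15), NULL))
  d <- dist(x)
  mine <- wardLinkage(d)
  ref <- hclust(d, method = "ward.D2")
  expect_equal(mine$height, ref$height, tolerance = 1e-10)
  for (k in 2:14)
    expect_identical(partitionSignature(hclustPartition(mine, k)),
                     partitionSignature(hclustPartition(ref, k)))
})

test_that("relabeling samples permutes leaves without changing structure", {
  set.seed(71)
  x <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(letters[1:8], NULL))
  perm <- sample(8)
  h1 <- wardLinkage(dist(x))
  h2 <- wardLinkage(dist(x[perm, ]))
  expect_equal(sort(h1$height), sort(h2$height), tolerance = 1e-12)
  c1 <- cutDendrogram(h1, 3)
  c2 <- cutDendrogram(h2, 3)
  for (i in letters[1:8]) for (j in letters[1:8])
    expect_identical(c1[i] == c1[j], c2[i] == c2[j])
})

test_that("tree cutting is bounded and deterministic", {
  set.seed(81)
  x <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("s", 1:6), NULL))
  h <- wardLinkage(dist(x))
  expect_identical(unname(cutDendrogram(h, 6)), 1:6)
  expect_identical(unname(cutDendrogram(h, 1)), rep(1L, 6))
  cl <- cutDendrogram(h, 3)
  ## ids numbered by first appearance in leaf order
  expect_identical(unique(unname(cl)), 1:3)
  expect_error(cutDendrogram(h, 0), "between")
  expect_error(cutDendrogram(h, 7), "between")
})

test_that("species recovery scores pure clusters only", {
  truth <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  perfect <- c(a1 = 1, a2 = 1, b1 = 2, b2 = 2)
  r <- speciesRecovery(perfect, truth)
  expect_equal(r$recovered, 2)
  expect_equal(r$purity, 1.0)

  lumped <- c(a1 = 1, a2 = 1, b1 = 1, b2 = 1)
  expect_equal(speciesRecovery(lumped, truth)$purity, 0.0)

  ## one misplaced sample poisons both species
  mixed <- c(a1 = 1, a2 = 2, b1 = 2, b2 = 2)
  r2 <- speciesRecovery(mixed, truth)
  expect_equal(r2$recovered, 0)
  expect_equal(r2$purity, 0.0)

  expect_error(speciesRecovery(perfect[1:3], truth), "same sample ids")
})

test_that("Newick export round-trips through ape with all leaves", {
  set.seed(91)
  x <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("sp", 1:5), NULL))
  h <- wardLinkage(dist(x))
  txt <- dendrogramNewick(h)
  phy <- ape::read.tree(text = txt)
  expect_setequal(phy$tip.label, paste0("sp", 1:5))
  f <- tempfile(fileext = ".nwk")
  dendrogramNewick(h, f)
  expect_identical(readLines(f), txt)
})
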