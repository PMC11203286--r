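test_that("bucket geometry matches brute-force enumeration", {
  spec <- BucketSpec()
  edges <- makeBuckets(spec)
  oracle <- bruteForceBuckets(spec)
  expect_equal(nrow(edges), 1040)
  expect_equal(edges$low, oracle$low, tolerance = 1e-12)
  expect_equal(edges$high, oracle$high, tolerance = 1e-12)
  ## no retained bucket touches any exclusion window
  for (k in seq_len(nrow(spec@exclusions))) {
    ex <- spec@exclusions[k, ]
    expect_false(any(edges$low < ex$high - 1e-9 &
                     edges$high > ex$low + 1e-9))
  }

  plain <- BucketSpec(1, 2, 0.01, exclusions = data.frame())
  expect_equal(nrow(makeBuckets(plain)), 100)

  gone <- BucketSpec(1, 2, 0.01,
                     exclusions = data.frame(low = 0, high = 3))
  expect_equal(nrow(makeBuckets(gone)), 0)
})

test_that("bucket integration takes the positive part, unscaled", {
  ax <- seq(2.1, 0.9, length.out = 4096)
  neg <- NMRSpectrum(ax, rep(-1, 4096))
  spec <- BucketSpec(1, 2, 0.01, exclusions = data.frame())
  expect_true(all(bucketSpectrum(neg, spec) == 0))

  ## unit-area Lorentzian wholly inside [1.50, 1.51): integral ~ 1 there
  ax2 <- seq(2.1, 0.9, length.out = 40000)
  hw <- 1e-4
  y <- (1 / pi) * hw / ((ax2 - 1.505)^2 + hw^2)
  lor <- NMRSpectrum(ax2, y)
  v <- bucketSpectrum(lor, spec)
  expect_equal(unname(v[["1.505"]]), 1, tolerance = 0.05)
  expect_true(all(v[names(v) != "1.505"] < 0.01))

  dbl <- NMRSpectrum(ax2, 2 * y)
  expect_equal(unname(bucketSpectrum(dbl, spec)), unname(2 * v),
               tolerance = 1e-12)

  short <- NMRSpectrum(seq(1.5, 0.9, length.out = 256), numeric(256))
  expect_error(bucketSpectrum(short, spec), "does not cover")
})

test_that("vectorized bucketing equals the per-point linear-search oracle", {
  set.seed(11)
  ax <- seq(2.2, 0.8, length.out = 1500)
  y <- abs(rnorm(1500)) * runif(1500) - 0.2
  s <- NMRSpectrum(ax, y)
  spec <- BucketSpec(1, 2, 0.1,
                     exclusions = data.frame(low = 1.35, high = 1.52))
  expect_equal(unname(bucketSpectrum(s, spec)),
               bruteForceBucketVector(s, spec), tolerance = 1e-12)
})

test_that("normalization maps below-mean to 0 and above-mean onto 1..100", {
  expect_identical(unname(normalizeBuckets(c(0, 0, 0, 10))),
                   c(0L, 0L, 0L, 100L))
  expect_identical(unname(normalizeBuckets(c(5, 5, 5, 5))), rep(0L, 4))
  expect_identical(unname(normalizeBuckets(numeric(4))), rep(0L, 4))

  set.seed(21)
  for (i in 1:50) {
    v <- rexp(50)
    out <- normalizeBuckets(v)
    m <- mean(v)
    expect_true(all(out[v <= m] == 0L))
    expect_identical(max(out), 100L)
    expect_true(min(out[v > m]) >= 1L)
    ## scale invariance
    expect_identical(out, normalizeBuckets(v * 7.3))
  }

  expect_error(normalizeBuckets(c(1, -1)), "non-negative")
  expect_error(normalizeBuckets(c(1, NA)), "finite")
})

test_that("bucket tables align rows with samples and respect permutation", {
  design <- smallDesign(k = 3, r = 1, cv = 0)
  spectra <- generateCohort(design, flowerSignatureLibrary(),
                            noiselessParams(8192L), seed = 2)
  tab <- buildBucketTable(spectra, BucketSpec(), normalize = TRUE)
  expect_identical(dim(bucketValues(tab)), c(3L, 1040L))
  expect_identical(sampleIds(tab), design@entries$sample_id)
  expect_true(isNormalized(tab))
  v <- bucketValues(tab)
  expect_true(all(v == round(v) & v >= 0 & v <= 100))

  perm <- c(3, 1, 2)
  tab2 <- buildBucketTable(spectra[perm], BucketSpec(), normalize = TRUE)
  expect_identical(bucketValues(tab2), bucketValues(tab)[perm, ])

  empty <- buildBucketTable(list(), BucketSpec())
  expect_identical(ncol(empty), 0L)
  expect_identical(nrow(bucketEdges(empty)), 1040L)
})
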