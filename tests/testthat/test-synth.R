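test_that("multiplet patterns follow first-order splitting rules", {
  s <- multipletPattern("s", numeric(), 400)
  expect_equal(s$offset, 0)
  expect_equal(s$weight, 1)

  d <- multipletPattern("d", 7.2, 400)
  expect_equal(d$offset, c(-0.009, 0.009))
  expect_equal(d$weight, c(0.5, 0.5))

  tr <- multipletPattern("t", 2.3, 400)
  expect_equal(tr$offset, c(-0.00575, 0, 0.00575))
  expect_equal(tr$weight, c(0.25, 0.5, 0.25))

  dd <- multipletPattern("dd", c(2.0, 2.1), 400)
  expect_equal(sort(dd$offset), sort(c(-4.1, -0.1, 0.1, 4.1) / 800))
  expect_equal(dd$weight, rep(0.25, 4))
})

test_that("pattern weights sum to one and offsets are symmetric", {
  cases <- list(list("s", numeric()), list("d", 7.2), list("t", 2.3),
                list("dd", c(2.0, 2.1)), list("dd", c(5.6, 7.5)),
                list("m", numeric()))
  for (cs in cases) {
    pat <- multipletPattern(cs[[1]], cs[[2]], 400)
    expect_equal(sum(pat$weight), 1, tolerance = 1e-12)
    expect_equal(sum(pat$offset * pat$weight), 0, tolerance = 1e-12)
  }
})

test_that("inconsistent J counts are rejected by name", {
  expect_error(multipletPattern("d", numeric(), 400), "requires 1")
  expect_error(multipletPattern("dd", 2.0, 400), "requires 2")
  expect_error(multipletPattern("s", 1.0, 400), "requires 0")
  expect_error(multipletPattern("q", 1.0, 400), "unknown multiplicity")
})

test_that("rendering is linear, deterministic, and empty in the null case", {
  lib <- flowerSignatureLibrary()
  p0 <- noiselessParams(8192L)

  empty <- renderSpectrum(lib, setNames(numeric(), character()), p0)
  expect_true(all(intensity(empty) == 0))

  one <- renderSpectrum(lib, c(Alanine = 1), p0)
  two <- renderSpectrum(lib, c(Alanine = 2), p0)
  expect_equal(intensity(two), 2 * intensity(one), tolerance = 1e-12)

  pn <- SpectrumParams(noise_sigma = 0.01, n_points = 8192L)
  a <- renderSpectrum(lib, c(Sucrose = 1), pn, seed = 7)
  b <- renderSpectrum(lib, c(Sucrose = 1), pn, seed = 7)
  expect_identical(intensity(a), intensity(b))
  c2 <- renderSpectrum(lib, c(Sucrose = 1), pn, seed = 8)
  expect_false(identical(intensity(a), intensity(c2)))

  expect_error(renderSpectrum(lib, c(Caffeine = 1), p0), "Caffeine")
})

test_that("the sucrose anomeric doublet renders as two maxima near 5.41 ppm", {
  s <- renderOne("Sucrose")
  a <- list(ppm = rev(ppm(s)), y = rev(intensity(s)))
  win <- a$ppm > 5.3 & a$ppm < 5.5
  y <- a$y[win]
  i <- 2:(length(y) - 1)
  n_max <- sum(y[i] > y[i - 1] & y[i] > y[i + 1] & y[i] > 0.01)
  expect_identical(n_max, 2L)
})

test_that("doublet midpoints recover the resonance center within one axis step", {
  lib <- flowerSignatureLibrary()
  df <- resonances(lib)
  doublets <- df[df$multiplicity == "d", ]
  step <- 13 / 32767
  for (r in seq_len(nrow(doublets))) {
    s <- renderSpectrum(lib, setNames(1, doublets$metabolite[r]),
                        noiselessParams())
    pk <- pickPeaks(s)
    pk <- pk[abs(pk$position - doublets$center[r]) < 0.1, ]
    top2 <- pk[order(-pk$height)[1:2], ]
    expect_lt(abs(mean(top2$position) - doublets$center[r]), step)
  }
})

test_that("cohort generation honors the design and its determinism contract", {
  design <- smallDesign(k = 3, r = 2, cv = 0)
  p0 <- noiselessParams(8192L)
  spectra <- generateCohort(design, flowerSignatureLibrary(), p0, seed = 5)
  expect_length(spectra, 6)
  expect_identical(
    vapply(spectra, function(s) spectrumMeta(s)$species, character(1)),
    setNames(design@entries$species, design@entries$sample_id))
  ## cv = 0 and no noise: same-species samples are bit-identical
  expect_identical(intensity(spectra[["T01"]]), intensity(spectra[["T02"]]))
  ## different species differ
  expect_false(identical(intensity(spectra[["T01"]]),
                         intensity(spectra[["T03"]])))
})

test_that("per-sample sub-seeds are deterministic and distinct", {
  expect_identical(subSeed(42, "S01"), subSeed(42, "S01"))
  expect_false(subSeed(42, "S01") == subSeed(42, "S02"))
  expect_false(subSeed(42, "S01") == subSeed(43, "S01"))
  expect_true(subSeed(0, "x") >= 1 && subSeed(0, "x") < 2^31)
})

test_that("a variant edit changes the spectrum only inside its multiplet footprint", {
  mets <- libraryMetabolites(flowerSignatureLibrary())
  prof <- setNames(rep(1, length(mets)), mets)
  entries <- data.frame(sample_id = c("A", "B"), species = "sp",
                        variant = c("base", "edited"),
                        extraction = "methanol")
  edits <- data.frame(species = "sp", variant = "edited", action = "delete",
                      metabolite = "Alanine", center = 1.49)
  design <- CohortDesign(entries, list(sp = prof), cv = 0,
                         variant_edits = edits)
  p0 <- noiselessParams(8192L)
  sp <- generateCohort(design, flowerSignatureLibrary(), p0, seed = 1)
  dif <- abs(intensity(sp[["A"]]) - intensity(sp[["B"]]))
  ax <- ppm(sp[["A"]])
  inside <- abs(ax - 1.49) <= 0.25
  expect_gt(max(dif[inside]), 0.1)
  expect_lt(max(dif[!inside]), 1e-3 * max(dif))
})
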