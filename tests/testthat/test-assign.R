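test_that("peak picking finds isolated lines and nothing in flat spectra", {
  s <- renderOne("Succinic acid")
  pk <- pickPeaks(s)
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$position - 2.56), 13 / 32767)

  ala <- pickPeaks(renderOne("Alanine"))
  expect_identical(nrow(ala), 2L)
  expect_lt(abs(diff(ala$position) - 0.018), 0.001)

  flat <- NMRSpectrum(seq(12.5, -0.5, length.out = 1024), numeric(1024))
  expect_identical(nrow(pickPeaks(flat)), 0L)
})

test_that("pure noise rarely yields peaks at the default threshold", {
  p <- SpectrumParams(solvent_peaks = data.frame(ppm = numeric(),
                                                 amplitude = numeric()))
  lib <- flowerSignatureLibrary()
  n_clean <- sum(vapply(1:50, function(sd)
    nrow(pickPeaks(renderSpectrum(lib, c(Sucrose = 0), p, seed = sd))),
    numeric(1)) == 0)
  expect_gte(n_clean, 49)
})

test_that("multiplet grouping recovers pattern and coupling", {
  obs <- groupMultiplets(pickPeaks(renderOne("Alanine")))
  expect_identical(nrow(obs), 1L)
  expect_identical(obs$pattern_guess, "d")
  expect_equal(obs$j_estimate, 7.2, tolerance = 0.35)
  expect_equal(obs$centroid, 1.49, tolerance = 0.005)

  lone <- data.frame(position = 5.0, height = 1, snr = 100)
  o1 <- groupMultiplets(lone)
  expect_identical(o1$pattern_guess, "s")
  expect_identical(o1$n_lines, 1L)

  ## 50 Hz apart at 400 MHz (0.125 ppm) exceeds the 12 Hz window
  far <- data.frame(position = c(5.0, 5.125), height = c(1, 1),
                    snr = c(100, 100))
  expect_identical(nrow(groupMultiplets(far)), 2L)

  expect_identical(nrow(groupMultiplets(far[0, ])), 0L)
})

test_that("library matching identifies single metabolites without bycatch", {
  lib <- flowerSignatureLibrary()
  rep1 <- matchLibrary(groupMultiplets(pickPeaks(renderOne("Sucrose"))), lib)
  expect_identical(identifiedMetabolites(rep1), "Sucrose")

  ## single-metabolite renderings identify that metabolite and only
  ## metabolites whose full signature they happen to cover
  for (met in c("Alanine", "Succinic acid", "Kaempferol")) {
    r <- matchLibrary(groupMultiplets(pickPeaks(renderOne(met))), lib)
    expect_true(met %in% identifiedMetabolites(r))
    expect_false("Valine" %in% identifiedMetabolites(r))
  }

  none <- matchLibrary(groupMultiplets(pickPeaks(
    NMRSpectrum(seq(12.5, -0.5, length.out = 256), numeric(256)))), lib)
  expect_length(identifiedMetabolites(none), 0)
  expect_false(any(none@matches$matched))
})

test_that("extraneous observations never un-identify a metabolite", {
  lib <- flowerSignatureLibrary()
  obs <- groupMultiplets(pickPeaks(renderOne("Alanine")))
  base <- identifiedMetabolites(matchLibrary(obs, lib))
  extra <- rbind(obs, data.frame(centroid = 11.3, n_lines = 1L,
                                 pattern_guess = "s", j_estimate = NA_real_))
  more <- identifiedMetabolites(matchLibrary(extra, lib))
  expect_true(all(base %in% more))
})

test_that("an empty library is rejected", {
  obs <- data.frame(centroid = 1.0, n_lines = 1L, pattern_guess = "s",
                    j_estimate = NA_real_)
  expect_error(matchLibrary(obs, SignatureLibrary(
    data.frame(metabolite = character(), center = numeric(),
               multiplicity = character()))))
})

test_that("spectral regions partition the 0-10 ppm range", {
  expect_identical(classifyRegion(8.07), "aromatic")
  expect_identical(classifyRegion(5.41), "sugar")
  expect_identical(classifyRegion(1.49), "organic_amino")
  expect_identical(classifyRegion(c(-0.2, 10.5)), c("outside", "outside"))
  ## boundaries belong to the lower region
  expect_identical(classifyRegion(c(3.5, 6.0, 10.0, 0.0)),
                   c("organic_amino", "sugar", "aromatic", "organic_amino"))
  grid <- seq(0, 10, by = 0.005)
  labels <- classifyRegion(grid)
  expect_false(any(labels == "outside"))
  expect_identical(length(labels), length(grid))
})
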