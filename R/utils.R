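## internal helpers shared across modules

## polynomial rolling hash of a string, exact in double arithmetic
## (every intermediate stays far below 2^53)
stringHash <- function(x) {
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 131 + b) %% 2147483647
  h
}

#' Derive a per-sample sub-seed from a master seed
#'
#' Splittable seeding scheme for cohort generation: each sample's RNG seed
#' is a deterministic function of the master seed and the sample id, so a
#' cohort is reproducible sample-by-sample and inserting or removing samples
#' does not disturb the spectra of the others.
#'
#' @param master non-negative integer master seed.
#' @param sample_id character sample identifier.
#' @return an integer seed in [1, 2^31 - 2].
#' @export
subSeed <- function(master, sample_id) {
  stopifnot(is.numeric(master), master >= 0)
  as.integer((master %% 2147483647 + stringHash(as.character(sample_id)) *
                2654435761 %% 2147483647) %% 2147483646 + 1)
}

## unit-height Lorentzian centered at pos with full width at half maximum fwhm
lorentzian <- function(x, pos, fwhm) {
  hw2 <- (fwhm / 2)^2
  hw2 / ((x - pos)^2 + hw2)
}

## return (ppm, intensity) with ppm strictly increasing, for internal math
ascending <- function(spectrum) {
  p <- spectrum@ppm
  i <- spectrum@intensity
  if (length(p) >= 2 && p[1] > p[2]) {
    p <- rev(p)
    i <- rev(i)
  }
  list(ppm = p, intensity = i)
}

## enforce the storage convention: strictly decreasing ppm
asDecreasing <- function(p, i) {
  if (length(p) >= 2 && p[1] < p[2]) {
    p <- rev(p)
    i <- rev(i)
  }
  list(ppm = p, intensity = i)
}
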