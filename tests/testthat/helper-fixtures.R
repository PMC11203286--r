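## shared fixtures and independent oracles

## noiseless, solvent-free simulation parameters at full digital resolution
noiselessParams <- function(n_points = 32768L)
  SpectrumParams(noise_sigma = 0, n_points = n_points,
                 solvent_peaks = data.frame(ppm = numeric(),
                                            amplitude = numeric()))

## render a single metabolite from the packaged library, noiselessly
renderOne <- function(metabolite, amount = 1, params = noiselessParams()) {
  renderSpectrum(flowerSignatureLibrary(), setNames(amount, metabolite),
                 params)
}

## small cohort design: k species, r replicates each, no variant edits
smallDesign <- function(k = 4, r = 2, cv = 0.05, profile_seed = 99) {
  mets <- libraryMetabolites(flowerSignatureLibrary())
  set.seed(profile_seed)
  profiles <- lapply(seq_len(k), function(i) {
    conc <- round(exp(rnorm(length(mets), 0, 1)), 3)
    names(conc) <- mets
    conc[sample(seq_along(mets), 6)] <- 0
    conc
  })
  names(profiles) <- paste0("species", seq_len(k))
  entries <- data.frame(
    sample_id = sprintf("T%02d", seq_len(k * r)),
    species = rep(names(profiles), each = r),
    variant = "", extraction = "methanol")
  CohortDesign(entries, profiles, cv = cv)
}

## brute-force bucket enumeration: walk every bucket, test every exclusion
bruteForceBuckets <- function(spec) {
  n <- round((spec@range_high - spec@range_low) / spec@width)
  keep <- data.frame(low = numeric(), high = numeric())
  for (i in seq_len(n)) {
    lo <- spec@range_low + (i - 1) * spec@width
    hi <- spec@range_low + i * spec@width
    drop <- FALSE
    for (k in seq_len(nrow(spec@exclusions))) {
      ex <- spec@exclusions[k, ]
      if (lo < ex$high - 1e-9 && hi > ex$low + 1e-9) drop <- TRUE
    }
    if (!drop) keep <- rbind(keep, data.frame(low = lo, high = hi))
  }
  keep
}

## per-point linear-search bucket classifier (oracle for bucketSpectrum)
bruteForceBucketVector <- function(spectrum, spec) {
  edges <- bruteForceBuckets(spec)
  p <- rev(ppm(spectrum)); y <- rev(intensity(spectrum))
  step <- abs(mean(diff(p)))
  out <- numeric(nrow(edges))
  for (i in seq_along(p)) {
    for (b in seq_len(nrow(edges))) {
      if (p[i] >= edges$low[b] && p[i] < edges$high[b]) {
        out[b] <- out[b] + max(y[i], 0) * step
        break
      }
    }
  }
  out
}

## exhaustive Ward oracle on raw coordinates: at every step evaluate the
## exact variance increase of every candidate merge and take the minimum
wardOracle <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), identity)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- Inf; bi <- 0; bj <- 0
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        a <- clusters[[i]]; b <- clusters[[j]]
        ma <- colMeans(x[a, , drop = FALSE])
        mb <- colMeans(x[b, , drop = FALSE])
        delta <- length(a) * length(b) / (length(a) + length(b)) *
          sum((ma - mb)^2)
        if (delta < best) { best <- delta; bi <- i; bj <- j }
      }
    }
    merged <- sort(c(clusters[[bi]], clusters[[bj]]))
    clusters <- c(clusters[-c(bi, bj)], list(merged))
    heights <- c(heights, sqrt(2 * best))
    partitions <- c(partitions, list(clusters))
  }
  list(heights = heights, partitions = partitions)
}

## canonical signature of a flat partition, for order-free comparison
partitionSignature <- function(groups) {
  sig <- sort(vapply(groups, function(g)
    paste(sort(g), collapse = ","), character(1)))
  paste(sig, collapse = ";")
}

## partition implied by an hclust tree cut to k clusters
hclustPartition <- function(h, k) {
  cl <- cutree(h, k)
  unname(split(seq_along(cl), cl))
}
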