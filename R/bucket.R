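#' Construct a BucketSpec
#'
#' Defaults follow the standard fingerprinting geometry: 0.01 ppm
#' rectangular buckets covering 1 to 12 ppm with the residual water
#' (4.75-5.06 ppm), methanol (3.16-3.45 ppm) and reference
#' (-0.05-0.05 ppm) windows excluded.
#'
#' @param range_low,range_high bucketing range in ppm.
#' @param width bucket width in ppm.
#' @param exclusions data.frame with columns \code{low}, \code{high}.
#' @return a \linkS4class{BucketSpec}.
#' @export
BucketSpec <- function(range_low = 1.0, range_high = 12.0, width = 0.01,
                       exclusions = data.frame(
                         low = c(4.75, 3.16, -0.05),
                         high = c(5.06, 3.45, 0.05))) {
  new("BucketSpec", range_low = range_low, range_high = range_high,
      width = width, exclusions = as.data.frame(exclusions))
}

#' Bucket edges retained under a BucketSpec
#'
#' Contiguous half-open intervals [low, low + width) covering
#' [range_low, range_high), computed by index arithmetic (never repeated
#' addition) to avoid floating-point drift. Any bucket overlapping any
#' exclusion interval is dropped entirely, so no solvent signal can leak
#' into the fingerprint. Order is ascending.
#'
#' @param spec a \linkS4class{BucketSpec}.
#' @return data.frame with columns \code{low}, \code{high}, one row per
#'   retained bucket.
#' @export
makeBuckets <- function(spec = BucketSpec()) {
  validObject(spec)
  n <- round((spec@range_high - spec@range_low) / spec@width)
  low <- spec@range_low + (seq_len(n) - 1) * spec@width
  high <- spec@range_low + seq_len(n) * spec@width
  keep <- rep(TRUE, n)
  eps <- 1e-9
  for (k in seq_len(nrow(spec@exclusions))) {
    ex <- spec@exclusions[k, ]
    keep <- keep & !(low < ex$high - eps & high > ex$low + eps)
  }
  data.frame(low = low[keep], high = high[keep])
}

#' Integrate a spectrum into rectangular buckets of positive intensities
#'
#' Each axis point whose ppm value falls in a bucket's half-open interval
#' [low, high) contributes max(intensity, 0) x |axis step| to that bucket
#' ("positive intensities, without scaling": no division by bucket width
#' or point count). Points in excluded regions never contribute.
#'
#' @param spectrum an \linkS4class{NMRSpectrum} whose axis covers the
#'   bucketing range.
#' @param spec a \linkS4class{BucketSpec}.
#' @return named numeric vector of non-negative bucket values, one per
#'   retained bucket (names are bucket centers to 3 decimals).
#' @export
bucketSpectrum <- function(spectrum, spec = BucketSpec()) {
  stopifnot(is(spectrum, "NMRSpectrum"))
  a <- ascending(spectrum)
  if (min(a$ppm) > spec@range_low + 1e-9 ||
      max(a$ppm) < spec@range_high - 1e-9)
    stop("spectrum axis [", min(a$ppm), ", ", max(a$ppm),
         "] does not cover the bucketing range [", spec@range_low, ", ",
         spec@range_high, "] ppm")
  step <- abs(mean(diff(a$ppm)))
  n_all <- round((spec@range_high - spec@range_low) / spec@width)
  idx <- floor((a$ppm - spec@range_low) / spec@width + 1e-9) + 1
  inside <- idx >= 1 & idx <= n_all & a$ppm >= spec@range_low - 1e-12
  vals <- pmax(a$intensity[inside], 0) * step
  rs <- rowsum(vals, idx[inside], reorder = TRUE)
  full_named <- numeric(n_all)
  full_named[as.integer(rownames(rs))] <- as.numeric(rs)
  edges <- makeBuckets(spec)
  all_low <- spec@range_low + (seq_len(n_all) - 1) * spec@width
  keep_idx <- match(round(edges$low, 9), round(all_low, 9))
  out <- full_named[keep_idx]
  names(out) <- sprintf("%.3f", (edges$low + edges$high) / 2)
  out
}

#' Per-spectrum integer normalization of a bucket vector
#'
#' Implements the below-mean/above-mean rule: with m the arithmetic mean
#' of the vector, values <= m map to 0 and values > m map linearly onto
#' 1..100 (round half up), so the smallest above-mean value becomes 1 and
#' the largest exactly 100. If all above-mean values are equal they map to
#' 100; an all-zero vector stays all-zero.
#'
#' @param raw numeric vector of finite, non-negative bucket values.
#' @return integer vector of the same length with values in 0..100.
#' @export
normalizeBuckets <- function(raw) {
  if (any(!is.finite(raw))) stop("bucket values must be finite")
  if (any(raw < 0)) stop("bucket values must be non-negative")
  out <- integer(length(raw))
  m <- mean(raw)
  above <- raw > m
  if (any(above)) {
    a <- min(raw[above])
    b <- max(raw[above])
    out[above] <- if (b == a) 100L else
      as.integer(floor(1 + 99 * (raw[above] - a) / (b - a) + 0.5))
  }
  names(out) <- names(raw)
  out
}

#' Build a samples-by-buckets fingerprint table
#'
#' Buckets every spectrum under one \linkS4class{BucketSpec} and optionally
#' applies the per-spectrum integer normalization. Rows of the returned
#' \linkS4class{BucketTable} are buckets, columns are samples (input
#' order).
#'
#' @param spectra list of \linkS4class{NMRSpectrum}.
#' @param spec a \linkS4class{BucketSpec}.
#' @param normalize logical; apply \code{\link{normalizeBuckets}} per
#'   spectrum.
#' @return a \linkS4class{BucketTable}.
#' @export
buildBucketTable <- function(spectra, spec = BucketSpec(), normalize = TRUE) {
  edges <- makeBuckets(spec)
  ids <- vapply(seq_along(spectra), function(i) {
    sid <- spectra[[i]]@meta$sample_id
    if (is.null(sid)) paste0("S", i) else as.character(sid)
  }, character(1))
  vals <- matrix(0, nrow = nrow(edges), ncol = length(spectra))
  for (i in seq_along(spectra)) {
    v <- tryCatch(bucketSpectrum(spectra[[i]], spec),
                  error = function(e) stop("sample ", ids[i], ": ",
                                           conditionMessage(e)))
    if (normalize) v <- normalizeBuckets(v)
    vals[, i] <- v
  }
  colnames(vals) <- ids
  rownames(vals) <- sprintf("%.3f", (edges$low + edges$high) / 2)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(buckets = vals),
    rowData = S4Vectors::DataFrame(low = edges$low, high = edges$high,
                                   center = (edges$low + edges$high) / 2))
  S4Vectors::metadata(se) <- list(normalized = normalize, spec = spec)
  new("BucketTable", se)
}
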