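#' Pick peaks from a preprocessed spectrum
#'
#' Local intensity maxima whose height exceeds \code{snr_threshold} times
#' the noise floor, estimated robustly as 1.4826 x the median absolute
#' deviation of the intensities (signal points are sparse, so the MAD
#' tracks the noise). A flat spectrum yields an empty peak list.
#'
#' @param spectrum an \linkS4class{NMRSpectrum}, ideally calibrated and
#'   baseline-corrected.
#' @param snr_threshold minimum peak height in units of the noise floor.
#' @return data.frame with columns \code{position} (ppm, ascending),
#'   \code{height}, \code{snr}.
#' @export
pickPeaks <- function(spectrum, snr_threshold = 5) {
  stopifnot(is(spectrum, "NMRSpectrum"))
  a <- ascending(spectrum)
  y <- a$intensity
  n <- length(y)
  if (n < 3)
    return(data.frame(position = numeric(), height = numeric(),
                      snr = numeric()))
  noise <- mad(y)
  thr <- max(snr_threshold * noise, 1e-9 * max(abs(y), 1e-300))
  i <- 2:(n - 1)
  is_max <- y[i] > y[i - 1] & y[i] > y[i + 1] & y[i] > thr & y[i] > 0
  idx <- i[is_max]
  data.frame(position = a$ppm[idx], height = y[idx],
             snr = if (noise > 0) y[idx] / noise else rep(Inf, length(idx)))
}

#' Group picked peaks into multiplet observations
#'
#' Adjacent peaks closer than \code{j_window_hz} (converted to ppm via the
#' spectrometer frequency) are taken to belong to one multiplet. Each
#' group is summarized by its height-weighted centroid, its line count, a
#' pattern guess from line count and spacing/height regularity (2 lines ->
#' 'd'; 3 regularly spaced lines with a dominant middle line -> 't'; 4
#' lines -> 'dd'; otherwise 'unresolved'; a lone line -> 's'), and a
#' coupling estimate J = field x adjacent-line spacing for 'd' and 't'.
#'
#' @param peaks data.frame from \code{\link{pickPeaks}} (ascending
#'   positions).
#' @param field_mhz spectrometer frequency in MHz.
#' @param j_window_hz grouping window in Hz.
#' @return data.frame with columns \code{centroid}, \code{n_lines},
#'   \code{pattern_guess}, \code{j_estimate} (Hz, NA when undefined).
#' @export
groupMultiplets <- function(peaks, field_mhz = 400, j_window_hz = 12) {
  if (nrow(peaks) == 0)
    return(data.frame(centroid = numeric(), n_lines = integer(),
                      pattern_guess = character(),
                      j_estimate = numeric()))
  gap_ppm <- j_window_hz / field_mhz
  o <- order(peaks$position)
  pos <- peaks$position[o]
  h <- peaks$height[o]
  grp <- cumsum(c(1, diff(pos) >= gap_ppm))
  out <- lapply(split(seq_along(pos), grp), function(ii) {
    p <- pos[ii]; w <- h[ii]
    centroid <- sum(p * w) / sum(w)
    nl <- length(ii)
    sp <- diff(p)
    pattern <- "unresolved"
    j <- NA_real_
    if (nl == 1) {
      pattern <- "s"
    } else if (nl == 2) {
      pattern <- "d"
      j <- field_mhz * sp[1]
    } else if (nl == 3) {
      regular <- abs(sp[1] - sp[2]) <= 0.25 * mean(sp)
      triplet_heights <- w[2] > w[1] && w[2] > w[3] &&
        abs(w[1] - w[3]) <= 0.5 * max(w[1], w[3])
      if (regular && triplet_heights) {
        pattern <- "t"
        j <- field_mhz * mean(sp)
      }
    } else if (nl == 4) {
      ## a genuine dd presents symmetric outer spacings and near-equal
      ## line heights; anything else is a chained/unresolved cluster
      symmetric <- abs(sp[1] - sp[3]) <= 0.25 * mean(sp[c(1, 3)])
      even_heights <- max(w) <= 2 * min(w)
      if (symmetric && even_heights) pattern <- "dd"
    }
    data.frame(centroid = centroid, n_lines = nl, pattern_guess = pattern,
               j_estimate = j)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$centroid), , drop = FALSE]
}

## can an observed pattern arise from a library resonance?
## exact code match; library 'm' matches anything; observed 'unresolved'
## matches anything; and a dd whose couplings differ by less than the
## instrument can resolve (|J1 - J2| <= j_tol) is admitted in its
## pseudo-triplet ('t') or collapsed-doublet ('d'/'s') presentation.
patternCompatible <- function(observed, lib_mult, j1, j2, j_tol) {
  if (lib_mult == "m" || observed == "unresolved") return(TRUE)
  if (observed == lib_mult) return(TRUE)
  if (lib_mult == "dd" && !is.na(j1) && !is.na(j2) &&
      abs(j1 - j2) <= j_tol && observed %in% c("t", "d", "s")) return(TRUE)
  FALSE
}

## expected J for comparing against an observed d/t estimate
libraryJ <- function(lib_mult, j1, j2) {
  if (lib_mult %in% c("d", "t")) return(j1)
  if (lib_mult == "dd") return((j1 + j2) / 2)   # pseudo-triplet spacing
  NA_real_
}

#' Match multiplet observations against a signature library
#'
#' A library resonance is matched when some observation lies within
#' \code{delta_tol} ppm of its chemical shift, has a compatible splitting
#' pattern, and (when both sides define a coupling) agrees on J within
#' \code{j_tol} Hz. A metabolite is identified only when every one of its
#' resonances is matched; one observation may serve several metabolites
#' (shared sugar-region signals).
#'
#' @param observations data.frame from \code{\link{groupMultiplets}}.
#' @param library a \linkS4class{SignatureLibrary}; must be non-empty.
#' @param delta_tol chemical-shift tolerance in ppm.
#' @param j_tol coupling tolerance in Hz.
#' @return an \linkS4class{AssignmentReport}.
#' @export
matchLibrary <- function(observations, library, delta_tol = 0.03,
                         j_tol = 1.0) {
  stopifnot(is(library, "SignatureLibrary"))
  validObject(library)
  df <- resonances(library)
  matched <- logical(nrow(df))
  cent <- rep(NA_real_, nrow(df))
  obs_used <- rep(FALSE, NROW(observations))
  for (r in seq_len(nrow(df))) {
    best <- NA_real_
    for (oi in seq_len(NROW(observations))) {
      ob <- observations[oi, ]
      err <- abs(ob$centroid - df$center[r])
      if (err > delta_tol) next
      if (!patternCompatible(ob$pattern_guess, df$multiplicity[r],
                             df$j1[r], df$j2[r], j_tol)) next
      jl <- libraryJ(df$multiplicity[r], df$j1[r], df$j2[r])
      if (!is.na(jl) && !is.na(ob$j_estimate) &&
          abs(ob$j_estimate - jl) > j_tol) next
      obs_used[oi] <- TRUE
      if (is.na(best) || err < abs(best - df$center[r])) best <- ob$centroid
    }
    if (!is.na(best)) {
      matched[r] <- TRUE
      cent[r] <- best
    }
  }
  matches <- data.frame(metabolite = df$metabolite, center = df$center,
                        multiplicity = df$multiplicity,
                        matched = matched, centroid = cent,
                        delta_error = cent - df$center)
  identified <- vapply(unique(df$metabolite), function(m)
    all(matched[df$metabolite == m]), logical(1))
  unmatched <- observations[!obs_used, , drop = FALSE]
  regions <- if (NROW(observations) > 0)
    as.data.frame(table(region = classifyRegion(observations$centroid)),
                  stringsAsFactors = FALSE)
  else data.frame(region = character(), Freq = integer())
  names(regions) <- c("region", "n_observations")
  new("AssignmentReport", matches = matches,
      identified = names(identified)[identified],
      unmatched = unmatched, region_summary = regions)
}

#' Classify a chemical shift into the standard spectral regions
#'
#' A typical flower-extract proton spectrum divides into an aromatic
#' region (6.00 < delta <= 10.00 ppm), a sugar region
#' (3.50 < delta <= 6.00), and an organic/amino acid region
#' (0.00 <= delta <= 3.50); boundaries belong to the lower region.
#' Positions outside [0, 10] (other than exactly 0) are labelled
#' "outside".
#'
#' @param position chemical shift(s) in ppm (vectorized).
#' @return character vector of labels: "aromatic", "sugar",
#'   "organic_amino" or "outside".
#' @export
classifyRegion <- function(position) {
  out <- rep("outside", length(position))
  out[position > 6 & position <= 10] <- "aromatic"
  out[position > 3.5 & position <= 6] <- "sugar"
  out[position >= 0 & position <= 3.5] <- "organic_amino"
  out
}
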