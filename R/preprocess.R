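#' Calibrate a spectrum to a reference resonance
#'
#' Shifts the chemical-shift axis so that the apex of the reference signal
#' (TMS or TSP by convention) sits at \code{reference_ppm}. The apex is the
#' maximum intensity inside the search window; if no point in the window
#' rises above the noise floor (3 x the scaled median absolute deviation of
#' the window's intensities), the spectrum is returned unshifted and
#' \code{reference_found} is FALSE. Intensities are never changed.
#'
#' @param spectrum an \linkS4class{NMRSpectrum}.
#' @param reference_ppm target position of the reference peak (ppm).
#' @param window half-width of the search window (ppm).
#' @return list with elements \code{spectrum} (the calibrated
#'   \linkS4class{NMRSpectrum}) and \code{calibration} (a one-row
#'   data.frame with \code{shift_applied}, \code{reference_found},
#'   \code{reference_height}).
#' @export
calibrateSpectrum <- function(spectrum, reference_ppm = 0.0, window = 0.2) {
  stopifnot(is(spectrum, "NMRSpectrum"))
  p <- spectrum@ppm
  if (min(p) > reference_ppm - window || max(p) < reference_ppm + window)
    stop("spectrum axis does not cover the calibration window [",
         reference_ppm - window, ", ", reference_ppm + window, "] ppm")
  inwin <- which(p >= reference_ppm - window & p <= reference_ppm + window)
  wi <- spectrum@intensity[inwin]
  floor_ <- 3 * mad(wi)
  apex <- which.max(wi)
  found <- wi[apex] > floor_ && wi[apex] > 0
  if (!found)
    return(list(spectrum = spectrum,
                calibration = data.frame(shift_applied = 0,
                                         reference_found = FALSE,
                                         reference_height = NA_real_)))
  shift <- reference_ppm - p[inwin[apex]]
  out <- new("NMRSpectrum", ppm = p + shift, intensity = spectrum@intensity,
             meta = spectrum@meta)
  list(spectrum = out,
       calibration = data.frame(shift_applied = shift, reference_found = TRUE,
                                reference_height = wi[apex]))
}

## Whittaker smoother with asymmetric weights: minimizes
## sum w_i (y_i - z_i)^2 + lambda * sum (diff(z, 2))^2
asls_baseline <- function(y, lambda, p, max_iter = 10L) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2, n,
                          k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(max_iter)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (all(w_new == w)) break
    w <- w_new
  }
  z
}

#' Baseline-correct a spectrum by asymmetric least squares
#'
#' Estimates a slowly varying baseline with an asymmetrically weighted
#' Whittaker smoother (points above the running estimate are down-weighted
#' by \code{asymmetry}, so peaks do not pull the baseline up) and subtracts
#' it. The axis is never changed.
#'
#' @param spectrum an \linkS4class{NMRSpectrum}; intensities must be
#'   finite.
#' @param smoothness roughness penalty of the smoother (larger = stiffer
#'   baseline).
#' @param asymmetry weight given to points above the baseline estimate
#'   (fraction in (0, 1); small values hug the signal floor).
#' @return the corrected \linkS4class{NMRSpectrum}.
#' @export
baselineCorrect <- function(spectrum, smoothness = 1e7, asymmetry = 0.01) {
  stopifnot(is(spectrum, "NMRSpectrum"))
  y <- spectrum@intensity
  if (any(!is.finite(y))) stop("intensities must be finite")
  if (length(y) < 4 || all(y == 0)) return(spectrum)
  z <- asls_baseline(y, smoothness, asymmetry)
  new("NMRSpectrum", ppm = spectrum@ppm, intensity = y - z,
      meta = spectrum@meta)
}
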