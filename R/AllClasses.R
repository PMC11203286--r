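#' @import methods
#' @importFrom stats mad median rnorm rlnorm runif setNames cutree as.dist dist hclust
#' @importFrom utils head tail write.csv read.csv
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData
#' @importFrom S4Vectors metadata DataFrame
NULL

MULTIPLICITIES <- c("s", "d", "dd", "t", "m")

## number of J couplings each multiplicity code requires
J_COUNT <- c(s = 0L, d = 1L, dd = 2L, t = 1L, m = 0L)

#' NMRSpectrum: a one-dimensional proton NMR spectrum
#'
#' Holds a chemical-shift axis in ppm (stored strictly decreasing, the NMR
#' display convention), a matching intensity vector, and free-form sample
#' metadata (sample id, species and variant labels, extraction solvent,
#' spectrometer frequency).
#'
#' @slot ppm numeric, strictly monotone decreasing chemical-shift axis (ppm).
#' @slot intensity numeric, same length as \code{ppm}.
#' @slot meta list of metadata; \code{field_mhz} must be a positive number
#'   when present.
#' @exportClass NMRSpectrum
setClass("NMRSpectrum",
  representation(ppm = "numeric", intensity = "numeric", meta = "list"),
  prototype(ppm = numeric(), intensity = numeric(), meta = list()))

setValidity("NMRSpectrum", function(object) {
  if (length(object@ppm) != length(object@intensity))
    return("ppm and intensity must have the same length")
  if (length(object@ppm) >= 2 && any(diff(object@ppm) >= 0))
    return("ppm axis must be strictly monotone decreasing")
  fm <- object@meta$field_mhz
  if (!is.null(fm) && (!is.numeric(fm) || fm <= 0))
    return("field_mhz must be a positive number")
  TRUE
})

#' SignatureLibrary: a chemical-shift library of metabolite signatures
#'
#' One row per resonance. A metabolite signature is the set of rows sharing
#' a metabolite name; identification requires every resonance of a signature
#' to be matched. Multiplicity codes: s (singlet), d (doublet),
#' dd (doublet of doublets), t (triplet), m (unresolved multiplet).
#' d and t carry one coupling constant (\code{j1}), dd carries two
#' (\code{j1}, \code{j2}); s and m carry none.
#'
#' @slot resonances data.frame with columns \code{metabolite},
#'   \code{center} (ppm), \code{multiplicity}, \code{j1}, \code{j2} (Hz,
#'   NA where absent), \code{rel_intensity} (proton weight, > 0) and
#'   \code{assignment} (free text).
#' @exportClass SignatureLibrary
setClass("SignatureLibrary", representation(resonances = "data.frame"))

setValidity("SignatureLibrary", function(object) {
  df <- object@resonances
  need <- c("metabolite", "center", "multiplicity", "j1", "j2",
            "rel_intensity", "assignment")
  if (!all(need %in% names(df)))
    return(paste("resonances must have columns:", paste(need, collapse = ", ")))
  if (nrow(df) == 0) return("library must contain at least one resonance")
  if (!all(df$multiplicity %in% MULTIPLICITIES))
    return(paste("unknown multiplicity code(s):",
                 paste(setdiff(unique(df$multiplicity), MULTIPLICITIES),
                       collapse = ", ")))
  nj <- (!is.na(df$j1)) + (!is.na(df$j2))
  bad <- nj != J_COUNT[df$multiplicity]
  if (any(bad))
    return(paste0("resonance ", df$metabolite[bad][1], " at ",
                  df$center[bad][1], " ppm: multiplicity '",
                  df$multiplicity[bad][1], "' requires ",
                  J_COUNT[df$multiplicity[bad][1]], " J value(s), got ",
                  nj[bad][1]))
  if (any(df$center < -1 | df$center > 13))
    return("resonance centers must lie within [-1, 13] ppm")
  if (any(!is.finite(df$rel_intensity) | df$rel_intensity <= 0))
    return("rel_intensity must be finite and > 0")
  for (m in unique(df$metabolite)) {
    cen <- sort(df$center[df$metabolite == m])
    if (length(cen) > 1 && any(diff(cen) < 0.001))
      return(paste0("duplicate resonance centers (within 0.001 ppm) in ", m))
  }
  TRUE
})

#' SpectrumParams: acquisition-like parameters for spectral simulation
#'
#' @slot field_mhz spectrometer frequency in MHz (default 400).
#' @slot n_points axis length (default 32768, i.e. 32K).
#' @slot ppm_min,ppm_max axis range in ppm (defaults -0.5 and 12.5).
#' @slot linewidth_hz Lorentzian full width at half maximum in Hz.
#' @slot noise_sigma additive Gaussian noise scale, relative to the apex
#'   height of a unit-amount singlet.
#' @slot solvent_peaks data.frame with columns \code{ppm} and
#'   \code{amplitude}: residual solvent/reference signals added to every
#'   rendered spectrum.
#' @exportClass SpectrumParams
setClass("SpectrumParams",
  representation(field_mhz = "numeric", n_points = "integer",
                 ppm_min = "numeric", ppm_max = "numeric",
                 linewidth_hz = "numeric", noise_sigma = "numeric",
                 solvent_peaks = "data.frame"))

setValidity("SpectrumParams", function(object) {
  if (object@field_mhz <= 0) return("field_mhz must be > 0")
  if (object@n_points < 2L) return("n_points must be >= 2")
  if (object@ppm_min >= object@ppm_max) return("ppm_min must be < ppm_max")
  if (object@linewidth_hz <= 0) return("linewidth_hz must be > 0")
  if (object@noise_sigma < 0) return("noise_sigma must be >= 0")
  sp <- object@solvent_peaks
  if (nrow(sp) > 0 && !all(c("ppm", "amplitude") %in% names(sp)))
    return("solvent_peaks needs columns ppm and amplitude")
  TRUE
})

#' CohortDesign: sampling plan for the synthetic cohort generator
#'
#' @slot entries data.frame with columns \code{sample_id}, \code{species},
#'   \code{variant}, \code{extraction}; sample ids unique.
#' @slot profiles named list, species -> named numeric vector of mean
#'   metabolite concentrations (arbitrary units, >= 0).
#' @slot cv coefficient of variation of the within-species lognormal
#'   concentration jitter (>= 0).
#' @slot variant_edits data.frame of per-variant signature edits with
#'   columns \code{variant}, \code{action} (one of delete/scale/add),
#'   \code{metabolite}, \code{center}, \code{factor}, \code{multiplicity},
#'   \code{j1}, \code{j2}, \code{rel_intensity}, \code{assignment}.
#' @exportClass CohortDesign
setClass("CohortDesign",
  representation(entries = "data.frame", profiles = "list", cv = "numeric",
                 variant_edits = "data.frame"))

setValidity("CohortDesign", function(object) {
  e <- object@entries
  need <- c("sample_id", "species", "variant", "extraction")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(e$sample_id))
    return("sample_id values must be unique")
  if (object@cv < 0) return("cv must be >= 0")
  miss <- setdiff(unique(e$species), names(object@profiles))
  if (length(miss) > 0)
    return(paste("no concentration profile for species:",
                 paste(miss, collapse = ", ")))
  for (p in object@profiles)
    if (any(p < 0)) return("concentration profiles must be >= 0")
  ve <- object@variant_edits
  if (nrow(ve) > 0 && !all(ve$action %in% c("delete", "scale", "add")))
    return("variant_edits actions must be delete, scale or add")
  TRUE
})

#' BucketSpec: rectangular bucketing geometry with exclusion windows
#'
#' Defaults follow the standard fingerprinting setup: buckets of width
#' 0.01 ppm covering 1 to 12 ppm, with the residual water (4.75-5.06 ppm),
#' methanol (3.16-3.45 ppm) and reference (-0.05-0.05 ppm) windows excluded.
#' A bucket overlapping any exclusion window is dropped entirely.
#'
#' @slot range_low,range_high bucketing range in ppm.
#' @slot width bucket width in ppm; \code{(range_high - range_low)/width}
#'   must be an integer.
#' @slot exclusions data.frame with columns \code{low}, \code{high}.
#' @exportClass BucketSpec
setClass("BucketSpec",
  representation(range_low = "numeric", range_high = "numeric",
                 width = "numeric", exclusions = "data.frame"))

setValidity("BucketSpec", function(object) {
  if (object@range_low >= object@range_high)
    return("range_low must be < range_high")
  if (object@width <= 0) return("width must be > 0")
  n <- (object@range_high - object@range_low) / object@width
  if (abs(n - round(n)) > 1e-9)
    return("(range_high - range_low)/width must be an integer")
  ex <- object@exclusions
  if (nrow(ex) > 0) {
    if (!all(c("low", "high") %in% names(ex)))
      return("exclusions needs columns low and high")
    if (any(ex$low >= ex$high))
      return("each exclusion interval must have low < high")
  }
  TRUE
})

#' BucketTable: samples-by-buckets fingerprint matrix
#'
#' A \linkS4class{SummarizedExperiment} whose rows are retained buckets
#' (rowData columns \code{low}, \code{high}, \code{center}) and whose
#' columns are samples. The single assay \code{"buckets"} holds raw
#' positive-intensity integrals or, after normalization, integers 0-100.
#'
#' @exportClass BucketTable
setClass("BucketTable", contains = "SummarizedExperiment")

setValidity("BucketTable", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("low", "high") %in% names(rd)))
    return("rowData must have columns low and high")
  if (!"buckets" %in% SummarizedExperiment::assayNames(object))
    return("assay 'buckets' is required")
  v <- SummarizedExperiment::assay(object, "buckets")
  if (any(!is.finite(v))) return("bucket values must be finite")
  if (any(v < 0)) return("bucket values must be non-negative")
  if (isTRUE(S4Vectors::metadata(object)$normalized)) {
    if (any(v != round(v)) || any(v > 100))
      return("normalized bucket values must be integers in [0, 100]")
  }
  TRUE
})

#' AssignmentReport: result of matching observations against a library
#'
#' @slot matches data.frame, one row per library resonance, with the
#'   matching observation centroid and the chemical-shift error where a
#'   match was found.
#' @slot identified character vector of metabolites whose resonances were
#'   all matched.
#' @slot unmatched data.frame of multiplet observations that matched no
#'   library resonance.
#' @slot region_summary data.frame of observation counts per spectral
#'   region (aromatic / sugar / organic-amino / outside).
#' @exportClass AssignmentReport
setClass("AssignmentReport",
  representation(matches = "data.frame", identified = "character",
                 unmatched = "data.frame", region_summary = "data.frame"))
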