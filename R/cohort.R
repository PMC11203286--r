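#' Construct a CohortDesign
#'
#' @param entries data.frame with columns \code{sample_id}, \code{species},
#'   \code{variant}, \code{extraction}.
#' @param profiles named list: species -> named numeric vector of mean
#'   metabolite concentrations.
#' @param cv coefficient of variation of the within-species lognormal
#'   concentration jitter.
#' @param variant_edits data.frame of per-(species, variant) signature
#'   edits; see \linkS4class{CohortDesign}.
#' @return a \linkS4class{CohortDesign}.
#' @export
CohortDesign <- function(entries, profiles, cv = 0.05,
                         variant_edits = data.frame()) {
  e <- as.data.frame(entries)
  if (!"variant" %in% names(e)) e$variant <- ""
  if (!"extraction" %in% names(e)) e$extraction <- "methanol"
  new("CohortDesign", entries = e, profiles = profiles, cv = cv,
      variant_edits = as.data.frame(variant_edits))
}

#' Read a cohort configuration (design + spectrum parameters) from YAML
#'
#' The file holds the sample roster (sample ids, species, color variants,
#' extraction), the per-species mean concentration profiles, the
#' within-species cv, the per-variant signature edits, and the spectrum
#' simulation parameters.
#'
#' @param path path to a YAML (or JSON) configuration file.
#' @return list with elements \code{design} (a
#'   \linkS4class{CohortDesign}) and \code{params} (a
#'   \linkS4class{SpectrumParams}).
#' @export
readCohortConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  co <- cfg$cohort
  if (is.null(co)) stop("config has no 'cohort' section: ", path)
  entries <- do.call(rbind, lapply(co$samples, function(s)
    data.frame(sample_id = s$sample_id, species = s$species,
               variant = if (is.null(s$variant)) "" else s$variant,
               extraction = if (is.null(s$extraction)) "methanol"
                            else s$extraction)))
  profiles <- lapply(co$profiles, function(p) unlist(p))
  ve <- if (is.null(co$variant_edits)) data.frame() else
    do.call(rbind, lapply(co$variant_edits, function(ed)
      data.frame(species = ed$species, variant = ed$variant,
                 action = ed$action, metabolite = ed$metabolite,
                 center = if (is.null(ed$center)) NA_real_ else ed$center,
                 factor = if (is.null(ed$factor)) NA_real_ else ed$factor,
                 multiplicity = if (is.null(ed$multiplicity)) NA_character_
                                else ed$multiplicity,
                 j1 = if (is.null(ed$j1)) NA_real_ else ed$j1,
                 j2 = if (is.null(ed$j2)) NA_real_ else ed$j2,
                 rel_intensity = if (is.null(ed$rel_intensity)) NA_real_
                                 else ed$rel_intensity,
                 assignment = if (is.null(ed$assignment)) NA_character_
                              else ed$assignment)))
  design <- CohortDesign(entries, profiles,
                         cv = if (is.null(co$cv)) 0.05 else co$cv,
                         variant_edits = ve)
  params <- if (is.null(cfg$spectrum_params)) SpectrumParams() else {
    p <- cfg$spectrum_params
    sp <- if (is.null(p$solvent_peaks)) SpectrumParams()@solvent_peaks else
      do.call(rbind, lapply(p$solvent_peaks, function(s)
        data.frame(ppm = s$ppm, amplitude = s$amplitude)))
    SpectrumParams(
      field_mhz = if (is.null(p$field_mhz)) 400 else p$field_mhz,
      n_points = if (is.null(p$n_points)) 32768L else as.integer(p$n_points),
      ppm_min = if (is.null(p$ppm_min)) -0.5 else p$ppm_min,
      ppm_max = if (is.null(p$ppm_max)) 12.5 else p$ppm_max,
      linewidth_hz = if (is.null(p$linewidth_hz)) 1.5 else p$linewidth_hz,
      noise_sigma = if (is.null(p$noise_sigma)) 0.002 else p$noise_sigma,
      solvent_peaks = sp)
  }
  list(design = design, params = params)
}

#' The packaged synthetic cohort design
#'
#' A 33-sample, 23-species sampling plan emulating the structure of the
#' study cohort the package's analysis is built for: multi-sample species
#' with color variants (Rosa chinensis, Chrysanthemum x morifolium,
#' Calendula officinalis), a multi-variety species (Brassica oleracea),
#' and 19 further single-sample species. Species concentration profiles
#' and variant edits are stored in the packaged
#' \code{extdata/synthetic_cohort.yaml} fixture.
#'
#' @return a \linkS4class{CohortDesign}.
#' @export
defaultCohortDesign <- function() {
  readCohortConfig(system.file("extdata", "synthetic_cohort.yaml",
                               package = "floraNMR"))$design
}
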