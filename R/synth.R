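## footprint of an unresolved 'm' multiplet, in ppm: five equal lines span
## this width, so line spacing (0.002 ppm = 0.8 Hz at 400 MHz) stays below
## the default linewidth and the envelope renders as one broad hump
M_SPAN_PPM <- 0.008
M_LINES <- 5L

#' Construct SpectrumParams
#'
#' Defaults emulate a 400 MHz acquisition digitized to 32K points over
#' -0.5 to 12.5 ppm with a 1.5 Hz Lorentzian linewidth, weak additive
#' Gaussian noise, and residual reference/solvent signals (TMS at 0.00 ppm,
#' methanol at 3.31 ppm, water at 4.87 ppm) that fall inside the standard
#' exclusion windows of the bucketing step.
#'
#' @param field_mhz spectrometer frequency in MHz.
#' @param n_points number of axis points.
#' @param ppm_min,ppm_max axis range in ppm.
#' @param linewidth_hz Lorentzian full width at half maximum in Hz.
#' @param noise_sigma additive Gaussian noise standard deviation, relative
#'   to the apex height of a unit-amount singlet.
#' @param solvent_peaks data.frame with columns \code{ppm},
#'   \code{amplitude}.
#' @return a \linkS4class{SpectrumParams}.
#' @export
SpectrumParams <- function(field_mhz = 400, n_points = 32768L,
                           ppm_min = -0.5, ppm_max = 12.5,
                           linewidth_hz = 1.5, noise_sigma = 0.002,
                           solvent_peaks = data.frame(
                             ppm = c(0.0, 3.31, 4.87),
                             amplitude = c(1.0, 2.0, 4.0))) {
  new("SpectrumParams", field_mhz = field_mhz,
      n_points = as.integer(n_points), ppm_min = ppm_min, ppm_max = ppm_max,
      linewidth_hz = linewidth_hz, noise_sigma = noise_sigma,
      solvent_peaks = as.data.frame(solvent_peaks))
}

#' @rdname SpectrumParams
#' @export
defaultSpectrumParams <- function() SpectrumParams()

#' Multiplet splitting pattern from multiplicity and J-couplings
#'
#' Returns the line offsets (ppm, symmetric about 0) and fractional weights
#' (summing to 1) of a first-order multiplet at a given spectrometer
#' frequency: a doublet splits into two half-weight lines separated by
#' J/field ppm; a triplet into three lines spaced J/field with weights
#' 1/4, 1/2, 1/4; a doublet of doublets into four quarter-weight lines at
#' (+/-J1 +/- J2)/(2 field); a singlet is one unit line; an unresolved
#' multiplet ('m', no J reported) is rendered as five equal lines spanning
#' 0.008 ppm so that, at the default linewidth, it presents as a single
#' broad envelope.
#'
#' @param multiplicity one of "s", "d", "dd", "t", "m".
#' @param j_values numeric vector of coupling constants in Hz (length 1 for
#'   d and t, 2 for dd, 0 for s and m).
#' @param field_mhz spectrometer frequency in MHz.
#' @return data.frame with columns \code{offset} (ppm) and \code{weight}.
#' @export
multipletPattern <- function(multiplicity, j_values = numeric(), field_mhz = 400) {
  j_values <- j_values[!is.na(j_values)]
  need <- J_COUNT[multiplicity]
  if (is.na(need))
    stop("unknown multiplicity code: ", multiplicity)
  if (length(j_values) != need)
    stop("multiplicity '", multiplicity, "' requires ", need,
         " J value(s), got ", length(j_values))
  out <- switch(multiplicity,
    s = data.frame(offset = 0, weight = 1),
    d = {
      h <- j_values[1] / (2 * field_mhz)
      data.frame(offset = c(-h, h), weight = c(0.5, 0.5))
    },
    t = {
      s <- j_values[1] / field_mhz
      data.frame(offset = c(-s, 0, s), weight = c(0.25, 0.5, 0.25))
    },
    dd = {
      o <- c(-j_values[1] - j_values[2], -abs(j_values[1] - j_values[2]),
             abs(j_values[1] - j_values[2]), j_values[1] + j_values[2]) /
        (2 * field_mhz)
      data.frame(offset = o, weight = rep(0.25, 4))
    },
    m = data.frame(offset = seq(-M_SPAN_PPM / 2, M_SPAN_PPM / 2,
                                length.out = M_LINES),
                   weight = rep(1 / M_LINES, M_LINES)))
  out[order(out$offset), , drop = FALSE]
}

#' Render a synthetic 1H-NMR spectrum from a signature library
#'
#' Sums, over every resonance of every requested metabolite and every line
#' of its multiplet pattern, a unit-height Lorentzian of the configured
#' linewidth scaled by amount x rel_intensity x line weight; adds the
#' residual solvent/reference Lorentzians and i.i.d. Gaussian noise. The
#' output is a pure function of (library, concentrations, params, seed).
#'
#' @param library a \linkS4class{SignatureLibrary}.
#' @param concentrations named numeric vector, metabolite -> amount
#'   (arbitrary units); every name must exist in the library.
#' @param params a \linkS4class{SpectrumParams}.
#' @param seed integer seed for the additive noise.
#' @param meta metadata list stored on the spectrum.
#' @return an \linkS4class{NMRSpectrum} (axis stored decreasing).
#' @export
renderSpectrum <- function(library, concentrations, params = SpectrumParams(),
                           seed = 0L, meta = list()) {
  stopifnot(is(library, "SignatureLibrary"), is(params, "SpectrumParams"))
  validObject(library)
  validObject(params)
  df <- resonances(library)
  unknown <- setdiff(names(concentrations), df$metabolite)
  if (length(unknown) > 0)
    stop("metabolite(s) not in library: ", paste(unknown, collapse = ", "))
  axis <- seq(params@ppm_max, params@ppm_min, length.out = params@n_points)
  y <- numeric(params@n_points)
  fwhm_ppm <- params@linewidth_hz / params@field_mhz
  for (met in names(concentrations)) {
    amount <- concentrations[[met]]
    if (amount == 0) next
    for (r in which(df$metabolite == met)) {
      pat <- multipletPattern(df$multiplicity[r],
                              c(df$j1[r], df$j2[r]), params@field_mhz)
      for (l in seq_len(nrow(pat)))
        y <- y + amount * df$rel_intensity[r] * pat$weight[l] *
          lorentzian(axis, df$center[r] + pat$offset[l], fwhm_ppm)
    }
  }
  sp <- params@solvent_peaks
  for (s in seq_len(nrow(sp)))
    y <- y + sp$amplitude[s] * lorentzian(axis, sp$ppm[s], fwhm_ppm)
  if (params@noise_sigma > 0) {
    set.seed(as.integer(seed %% 2147483647))
    y <- y + rnorm(params@n_points, 0, params@noise_sigma)
  }
  meta$field_mhz <- params@field_mhz
  NMRSpectrum(axis, y, meta)
}

## lognormal jitter with mean preserved and coefficient of variation cv;
## zero means stay exactly zero, cv = 0 returns the means unchanged
jitterConcentrations <- function(means, cv, seed) {
  if (cv == 0) return(means)
  sdlog <- sqrt(log1p(cv^2))
  set.seed(as.integer(seed))
  out <- means
  pos <- means > 0
  out[pos] <- rlnorm(sum(pos), log(means[pos]) - sdlog^2 / 2, sdlog)
  out
}

## apply the per-variant presence/absence and scaling edits to a library;
## returns the edited resonance table plus amounts for metabolites the
## edits introduce
applyVariantEdits <- function(library, edits) {
  df <- resonances(library)
  extra <- numeric()
  if (NROW(edits) > 0)
    for (col in c("center", "factor", "multiplicity", "j1", "j2",
                  "rel_intensity", "assignment"))
      if (!col %in% names(edits)) edits[[col]] <- NA
  for (i in seq_len(NROW(edits))) {
    e <- edits[i, ]
    hit <- df$metabolite == e$metabolite
    if (!is.na(e$center)) hit <- hit & abs(df$center - e$center) <= 0.005
    if (e$action == "delete") {
      df <- df[!hit, , drop = FALSE]
    } else if (e$action == "scale") {
      df$rel_intensity[hit] <- df$rel_intensity[hit] * e$factor
    } else if (e$action == "add") {
      df <- rbind(df, res_row(e$metabolite, e$center, e$multiplicity,
                              e$j1, e$j2,
                              ifelse(is.na(e$rel_intensity), 1,
                                     e$rel_intensity),
                              if (is.na(e$assignment)) "" else e$assignment))
      extra[e$metabolite] <- e$factor
    }
  }
  list(library = SignatureLibrary(df), extra = extra)
}

#' Generate a synthetic multi-species flower cohort
#'
#' One spectrum per design entry. Within-species concentrations are drawn
#' lognormally around the species profile with the design's coefficient of
#' variation; color-variant edits (resonance deletions, scalings and
#' additions) are applied to the library before rendering. Per-sample seeds
#' are derived from the master seed and the sample id with
#' \code{\link{subSeed}}, so every sample is individually reproducible.
#'
#' @param design a \linkS4class{CohortDesign}.
#' @param library a \linkS4class{SignatureLibrary}.
#' @param params a \linkS4class{SpectrumParams}.
#' @param seed integer master seed.
#' @return list of \linkS4class{NMRSpectrum}, one per design entry.
#' @export
generateCohort <- function(design, library = flowerSignatureLibrary(),
                           params = SpectrumParams(), seed = 0L) {
  stopifnot(is(design, "CohortDesign"))
  validObject(design)
  allmet <- unique(resonances(library)$metabolite)
  for (sp in names(design@profiles)) {
    miss <- setdiff(names(design@profiles[[sp]]), allmet)
    if (length(miss) > 0)
      stop("profile for ", sp, " names metabolite(s) not in library: ",
           paste(miss, collapse = ", "))
  }
  e <- design@entries
  out <- vector("list", nrow(e))
  for (i in seq_len(nrow(e))) {
    sid <- e$sample_id[i]
    ss <- subSeed(seed, sid)
    prof <- design@profiles[[e$species[i]]]
    amounts <- jitterConcentrations(prof, design@cv, ss)
    ve <- design@variant_edits
    if (NROW(ve) > 0)
      ve <- ve[ve$species == e$species[i] & ve$variant == e$variant[i], ,
               drop = FALSE]
    ed <- applyVariantEdits(library, ve)
    ## an edit may delete a metabolite's only resonance; drop its amount
    amounts <- amounts[names(amounts) %in%
                         unique(resonances(ed$library)$metabolite)]
    amounts <- c(amounts, ed$extra)
    out[[i]] <- renderSpectrum(
      ed$library, amounts, params, seed = (ss + 1L) %% 2147483647L,
      meta = list(sample_id = sid, species = e$species[i],
                  variant = e$variant[i], extraction = e$extraction[i]))
  }
  names(out) <- e$sample_id
  out
}
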