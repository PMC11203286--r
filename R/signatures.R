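#' Construct an NMRSpectrum
#'
#' @param ppm chemical-shift axis in ppm (either order; stored decreasing).
#' @param intensity intensity vector, same length.
#' @param meta list of metadata (sample_id, species, variant, extraction,
#'   field_mhz, ...).
#' @return an \linkS4class{NMRSpectrum}.
#' @export
NMRSpectrum <- function(ppm, intensity, meta = list()) {
  d <- asDecreasing(as.numeric(ppm), as.numeric(intensity))
  new("NMRSpectrum", ppm = d$ppm, intensity = d$intensity, meta = meta)
}

#' Construct a SignatureLibrary from a resonance table
#'
#' @param resonances data.frame with columns \code{metabolite},
#'   \code{center}, \code{multiplicity}, \code{j1}, \code{j2},
#'   \code{rel_intensity}, \code{assignment}.
#' @return a \linkS4class{SignatureLibrary}.
#' @export
SignatureLibrary <- function(resonances) {
  df <- as.data.frame(resonances)
  if (!"j1" %in% names(df)) df$j1 <- NA_real_
  if (!"j2" %in% names(df)) df$j2 <- NA_real_
  if (!"rel_intensity" %in% names(df)) df$rel_intensity <- 1
  if (!"assignment" %in% names(df)) df$assignment <- ""
  rownames(df) <- NULL
  new("SignatureLibrary", resonances = df)
}

## one resonance row; NA J values trimmed by multiplicity in validity
res_row <- function(metabolite, center, multiplicity, j1 = NA_real_,
                    j2 = NA_real_, rel_intensity = 1, assignment = "") {
  data.frame(metabolite = metabolite, center = center,
             multiplicity = multiplicity, j1 = j1, j2 = j2,
             rel_intensity = rel_intensity, assignment = assignment,
             stringsAsFactors = FALSE)
}

#' The packaged flower-metabolite chemical-shift library
#'
#' Twenty metabolites commonly observed in 1H-NMR spectra of methanol
#' extracts of flowers, with chemical shifts (ppm), multiplicities and
#' scalar couplings (Hz). Relative intensities are proton counts for the
#' listed group. The broad overlapping sugar CH/CH2 envelope of glucose
#' and fructose (reported as a 3.49-3.89 ppm band) is represented by two
#' unresolved multiplets at the band edges.
#'
#' @return a \linkS4class{SignatureLibrary} with 20 metabolites.
#' @export
flowerSignatureLibrary <- function() {
  rows <- rbind(
    res_row("Kaempferol",          8.07, "d",  8.9, NA, 2, "aromatic 2',6'-CH"),
    res_row("Kaempferol",          6.96, "d",  3.4, NA, 1, "aromatic CH"),
    res_row("Kaempferol",          6.44, "dd", 2.0, 2.1, 1, "aromatic CH"),
    res_row("Sucrose",             5.41, "d",  3.8, NA, 1, "furanose CH"),
    res_row("alpha-glucose",       5.15, "d",  3.6, NA, 1, "alpha-anomeric CH"),
    res_row("beta-glucose",        4.53, "d",  7.8, NA, 1, "beta-anomeric CH"),
    res_row("Fructose",            4.22, "d",  7.8, NA, 1, "furanose CH"),
    res_row("Glucose and Fructose", 3.89, "m", NA, NA, 2, "CH, CH2 envelope"),
    res_row("Glucose and Fructose", 3.49, "m", NA, NA, 2, "CH, CH2 envelope"),
    res_row("Aspartate",           2.99, "dd", 3.4, 3.5, 2, "beta-CH2"),
    res_row("Citrate",             2.79, "dd", 5.6, 7.5, 4, "alpha-CH2"),
    res_row("Methionine",          2.77, "m",  NA, NA, 2, "CH2"),
    res_row("Malate",              2.73, "m",  NA, NA, 2, "alpha-CH2"),
    res_row("Succinic acid",       2.56, "s",  NA, NA, 4, "CH2"),
    res_row("Glutamate",           2.37, "m",  NA, NA, 2, "alpha-CH2"),
    res_row("Glutamate",           2.02, "m",  NA, NA, 2, "beta-CH2"),
    res_row("Glutamine",           2.32, "m",  NA, NA, 2, "CH2"),
    res_row("Acetic acid",         2.18, "s",  NA, NA, 3, "CH3"),
    res_row("Proline",             1.91, "m",  NA, NA, 2, "beta-CH2"),
    res_row("Lysine",              1.61, "m",  NA, NA, 2, "CH2"),
    res_row("Alanine",             1.49, "d",  7.2, NA, 3, "beta-CH3"),
    res_row("Isoleucine",          3.66, "m",  NA, NA, 1, "CH"),
    res_row("Isoleucine",          1.96, "m",  NA, NA, 1, "CH"),
    res_row("Isoleucine",          1.47, "m",  NA, NA, 1, "CH2"),
    res_row("Isoleucine",          1.26, "m",  NA, NA, 1, "CH2"),
    res_row("Isoleucine",          1.01, "d",  2.0, NA, 3, "CH3"),
    res_row("Isoleucine",          0.96, "t",  2.3, NA, 3, "CH3"),
    res_row("Leucine",             3.72, "m",  NA, NA, 1, "alpha-CH"),
    res_row("Leucine",             1.67, "m",  NA, NA, 3, "beta-CH2, CH"),
    res_row("Leucine",             0.95, "m",  NA, NA, 6, "2 x CH3"),
    res_row("Valine",              2.26, "m",  NA, NA, 1, "alpha-CH"),
    res_row("Valine",              1.06, "d",  7.0, NA, 3, "beta-CH3"),
    res_row("Valine",              0.91, "d",  3.6, NA, 3, "beta-CH3"))
  SignatureLibrary(rows)
}

#' Metabolite names in a library
#'
#' @param library a \linkS4class{SignatureLibrary}.
#' @return character vector of unique metabolite names, in library order.
#' @export
libraryMetabolites <- function(library) {
  unique(resonances(library)$metabolite)
}
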