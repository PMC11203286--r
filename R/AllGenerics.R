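#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes: \code{ppm} and
#' \code{intensity} return the axis and signal of an
#' \linkS4class{NMRSpectrum}; \code{spectrumMeta} its metadata list;
#' \code{resonances} the resonance table of a
#' \linkS4class{SignatureLibrary}; \code{bucketValues}, \code{bucketEdges},
#' \code{sampleIds} and \code{isNormalized} interrogate a
#' \linkS4class{BucketTable}; \code{identifiedMetabolites} extracts the
#' identified set from an \linkS4class{AssignmentReport}.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ppm", function(x) standardGeneric("ppm"))

#' @rdname accessors
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @rdname accessors
#' @export
setGeneric("spectrumMeta", function(x) standardGeneric("spectrumMeta"))

#' @rdname accessors
#' @export
setGeneric("resonances", function(x) standardGeneric("resonances"))

#' @rdname accessors
#' @export
setGeneric("bucketValues", function(x) standardGeneric("bucketValues"))

#' @rdname accessors
#' @export
setGeneric("bucketEdges", function(x) standardGeneric("bucketEdges"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname accessors
#' @export
setGeneric("identifiedMetabolites",
           function(x) standardGeneric("identifiedMetabolites"))

#' @rdname accessors
setMethod("ppm", "NMRSpectrum", function(x) x@ppm)

#' @rdname accessors
setMethod("intensity", "NMRSpectrum", function(x) x@intensity)

#' @rdname accessors
setMethod("spectrumMeta", "NMRSpectrum", function(x) x@meta)

#' @rdname accessors
setMethod("resonances", "SignatureLibrary", function(x) x@resonances)

#' @rdname accessors
setMethod("bucketValues", "BucketTable", function(x)
  t(SummarizedExperiment::assay(x, "buckets")))

#' @rdname accessors
setMethod("bucketEdges", "BucketTable", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  data.frame(low = rd$low, high = rd$high)
})

#' @rdname accessors
setMethod("sampleIds", "BucketTable", function(x) colnames(x))

#' @rdname accessors
setMethod("isNormalized", "BucketTable", function(x)
  isTRUE(S4Vectors::metadata(x)$normalized))

#' @rdname accessors
setMethod("identifiedMetabolites", "AssignmentReport",
          function(x) x@identified)

setMethod("show", "NMRSpectrum", function(object) {
  m <- object@meta
  cat("NMRSpectrum:", length(object@ppm), "points,",
      sprintf("%.3f to %.3f ppm", max(object@ppm), min(object@ppm)), "\n")
  if (!is.null(m$sample_id)) cat("  sample:", m$sample_id, "\n")
  if (!is.null(m$species))
    cat("  species:", m$species,
        if (!is.null(m$variant) && nzchar(m$variant))
          paste0("(", m$variant, ")") else "", "\n")
  if (!is.null(m$field_mhz)) cat("  field:", m$field_mhz, "MHz\n")
})

setMethod("show", "SignatureLibrary", function(object) {
  df <- object@resonances
  cat("SignatureLibrary:", length(unique(df$metabolite)), "metabolites,",
      nrow(df), "resonances,",
      sprintf("%.2f to %.2f ppm", min(df$center), max(df$center)), "\n")
})

setMethod("show", "CohortDesign", function(object) {
  e <- object@entries
  cat("CohortDesign:", nrow(e), "samples,",
      length(unique(e$species)), "species, cv =", object@cv, "\n")
})

setMethod("show", "BucketSpec", function(object) {
  cat(sprintf("BucketSpec: %.2f to %.2f ppm, width %.3g ppm, %d exclusion(s)\n",
              object@range_low, object@range_high, object@width,
              nrow(object@exclusions)))
})

setMethod("show", "AssignmentReport", function(object) {
  cat("AssignmentReport:", length(object@identified),
      "metabolites identified\n")
  if (length(object@identified) > 0)
    cat(" ", paste(object@identified, collapse = ", "), "\n")
  cat("  unmatched multiplets:", nrow(object@unmatched), "\n")
})
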