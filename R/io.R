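## metadata keys serialized with spectra; field_mhz is numeric
META_KEYS <- c("sample_id", "species", "variant", "extraction", "field_mhz")

#' Write a spectrum to disk
#'
#' Two formats: \code{"tsv"}, a diff-able two-column text format
#' (ppm, intensity) with '#'-prefixed metadata header lines, and
#' \code{"jcamp"}, JCAMP-DX with an (X++(Y..Y)) AFFN XYDATA block.
#' Output bytes are deterministic for fixed input.
#'
#' @param spectrum an \linkS4class{NMRSpectrum} with non-empty intensity.
#' @param path output file path.
#' @param format "tsv" or "jcamp".
#' @return \code{path}, invisibly.
#' @export
writeSpectrum <- function(spectrum, path, format = c("tsv", "jcamp")) {
  format <- match.arg(format)
  stopifnot(is(spectrum, "NMRSpectrum"))
  if (length(spectrum@intensity) == 0)
    stop("refusing to write a spectrum with empty intensity")
  m <- spectrum@meta
  if (format == "tsv") {
    hdr <- character()
    for (k in META_KEYS)
      if (!is.null(m[[k]]))
        hdr <- c(hdr, sprintf("# %s: %s", k, format(m[[k]], digits = 15)))
    body <- sprintf("%.10g\t%.10g", spectrum@ppm, spectrum@intensity)
    writeLines(c(hdr, body), path)
  } else {
    n <- length(spectrum@ppm)
    lines <- c(
      "##TITLE=floraNMR spectrum",
      "##JCAMP-DX=4.24",
      "##DATA TYPE=NMR SPECTRUM",
      "##XUNITS=PPM",
      "##YUNITS=ARBITRARY UNITS",
      sprintf("##.OBSERVE FREQUENCY=%s",
              format(if (is.null(m$field_mhz)) 400 else m$field_mhz,
                     digits = 15)),
      "##XFACTOR=1", "##YFACTOR=1",
      sprintf("##FIRSTX=%.10g", spectrum@ppm[1]),
      sprintf("##LASTX=%.10g", spectrum@ppm[n]),
      sprintf("##NPOINTS=%d", n))
    for (k in setdiff(META_KEYS, "field_mhz"))
      if (!is.null(m[[k]]))
        lines <- c(lines, sprintf("##$%s=%s", toupper(k), m[[k]]))
    lines <- c(lines, "##XYDATA=(X++(Y..Y))")
    chunks <- split(seq_len(n), ceiling(seq_len(n) / 6))
    for (ii in chunks)
      lines <- c(lines, paste(c(sprintf("%.10g", spectrum@ppm[ii[1]]),
                                sprintf("%.10g", spectrum@intensity[ii])),
                              collapse = " "))
    lines <- c(lines, "##END=")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a spectrum from disk
#'
#' Counterpart of \code{\link{writeSpectrum}}. The axis is normalized to
#' the decreasing storage convention regardless of file order. Malformed
#' numeric fields raise an error naming the line.
#'
#' @param path input file path.
#' @param format "tsv" or "jcamp".
#' @return an \linkS4class{NMRSpectrum}.
#' @export
readSpectrum <- function(path, format = c("tsv", "jcamp")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  meta <- list()
  if (format == "tsv") {
    is_hdr <- grepl("^#", lines)
    for (h in lines[is_hdr]) {
      mm <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
      if (length(mm) == 3) {
        key <- trimws(mm[2]); val <- trimws(mm[3])
        meta[[key]] <- if (key == "field_mhz") as.numeric(val) else val
      }
    }
    body_idx <- which(!is_hdr & nzchar(trimws(lines)))
    p <- numeric(length(body_idx)); y <- numeric(length(body_idx))
    for (i in seq_along(body_idx)) {
      parts <- strsplit(trimws(lines[body_idx[i]]), "\\s+")[[1]]
      v <- suppressWarnings(as.numeric(parts))
      if (length(v) != 2 || any(is.na(v)))
        stop("malformed spectrum line ", body_idx[i], " in ", path, ": '",
             lines[body_idx[i]], "'")
      p[i] <- v[1]; y[i] <- v[2]
    }
    return(NMRSpectrum(p, y, meta))
  }
  ## JCAMP-DX
  getLDR <- function(label) {
    hit <- grep(paste0("^##", gsub("([.$])", "\\\\\\1", label), "="), lines)
    if (length(hit) == 0) return(NULL)
    sub("^[^=]*=", "", lines[hit[1]])
  }
  npoints <- as.integer(getLDR("NPOINTS"))
  xfactor <- as.numeric(getLDR("XFACTOR"))
  yfactor <- as.numeric(getLDR("YFACTOR"))
  if (is.null(npoints) || is.na(npoints)) stop("JCAMP file lacks ##NPOINTS=")
  if (is.null(xfactor) || is.na(xfactor)) xfactor <- 1
  if (is.null(yfactor) || is.na(yfactor)) yfactor <- 1
  fm <- getLDR(".OBSERVE FREQUENCY")
  if (!is.null(fm)) meta$field_mhz <- as.numeric(fm)
  for (k in setdiff(META_KEYS, "field_mhz")) {
    v <- getLDR(paste0("$", toupper(k)))
    if (!is.null(v)) meta[[k]] <- v
  }
  start <- grep("^##XYDATA=", lines)
  if (length(start) == 0) stop("JCAMP file lacks an ##XYDATA= block")
  end <- grep("^##END", lines)
  end <- end[end > start[1]][1]
  block <- lines[(start[1] + 1):(end - 1)]
  x1 <- rep(NA_real_, length(block))
  ys <- vector("list", length(block))
  for (i in seq_along(block)) {
    toks <- strsplit(trimws(block[i]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(toks))
    if (any(is.na(v)))
      stop("malformed XYDATA line ", start[1] + i, " in ", path)
    x1[i] <- v[1]
    ys[[i]] <- v[-1]
  }
  y <- unlist(ys) * yfactor
  if (length(y) != npoints)
    stop("JCAMP XYDATA holds ", length(y), " points, ##NPOINTS= says ",
         npoints)
  firstx <- as.numeric(getLDR("FIRSTX")) * xfactor
  lastx <- as.numeric(getLDR("LASTX")) * xfactor
  p <- seq(firstx, lastx, length.out = npoints)
  NMRSpectrum(p, y, meta)
}

## deterministic 32-bit hash of a configuration, for run stamping
configHash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  sprintf("%08x", stringHash(as.character(s)))
}

#' Read a pipeline configuration from YAML
#'
#' The file references a cohort configuration (or a directory of spectrum
#' files), and sets the bucketing geometry, the number of clusters to cut,
#' assignment tolerances, the master seed, and preprocessing switches.
#'
#' @param path YAML file path.
#' @return a named list (class \code{floraNMRConfig}).
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$.dir <- dirname(normalizePath(path))
  if (is.null(cfg$seed)) cfg$seed <- 0L
  if (cfg$seed < 0) stop("seed must be a non-negative integer")
  structure(cfg, class = "floraNMRConfig")
}

#' Run the full fingerprinting pipeline
#'
#' Stages, in order: simulate (or ingest) spectra, calibrate and
#' baseline-correct, bucket with solvent exclusion, normalize, cluster
#' (Euclidean/Ward), cut and score species recovery, and assign
#' metabolites per sample against the signature library. All outputs go
#' to \code{out_dir}; a manifest records the configuration hash and seed,
#' and the log records every analysis parameter used. Identical
#' configurations produce byte-identical outputs.
#'
#' @param config a list from \code{\link{readPipelineConfig}}, or a path
#'   to a YAML pipeline configuration.
#' @param out_dir output directory (created if needed); defaults to the
#'   configuration's \code{output_dir} or a temporary directory.
#' @return invisibly, a list with the bucket table, the dendrogram, the
#'   cluster assignment, the species-recovery score and the per-sample
#'   assignment reports, plus the output file paths.
#' @export
runPipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  if (is.null(out_dir))
    out_dir <- if (!is.null(config$output_dir))
      file.path(config$.dir, config$output_dir) else tempfile("floraNMR_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  logcon <- file(logf, "w")
  on.exit(close(logcon), add = TRUE)
  say <- function(...) writeLines(paste0(...), logcon)
  hash <- configHash(unclass(config)[setdiff(names(config), ".dir")])
  seed <- as.integer(config$seed)
  say("floraNMR pipeline run; config_hash=", hash, " seed=", seed)

  stage <- "simulate/ingest"
  res <- tryCatch({
    library <- flowerSignatureLibrary()
    if (!is.null(config$cohort_config)) {
      cc <- readCohortConfig(file.path(config$.dir, config$cohort_config))
      spectra <- generateCohort(cc$design, library, cc$params, seed = seed)
      truth <- setNames(cc$design@entries$species,
                        cc$design@entries$sample_id)
      say("generated ", length(spectra), " spectra (",
          length(unique(truth)), " species), cv=", cc$design@cv,
          ", noise_sigma=", cc$params@noise_sigma)
    } else if (!is.null(config$spectra)) {
      paths <- file.path(config$.dir, unlist(config$spectra))
      fmt <- if (is.null(config$spectrum_format)) "tsv"
             else config$spectrum_format
      spectra <- lapply(paths, readSpectrum, format = fmt)
      truth <- NULL
      say("ingested ", length(spectra), " spectra")
    } else stop("config must provide cohort_config or spectra")

    stage <- "preprocess"
    do_cal <- !identical(config$preprocess$calibrate, FALSE)
    do_bl <- !identical(config$preprocess$baseline, FALSE)
    spectra <- lapply(spectra, function(s) {
      if (do_cal) s <- calibrateSpectrum(s)$spectrum
      if (do_bl) s <- baselineCorrect(s)
      s
    })
    say("preprocess: calibrate=", do_cal, " baseline=", do_bl)

    stage <- "bucket"
    bs <- config$bucket
    spec <- BucketSpec(
      range_low = if (is.null(bs$range_low)) 1 else bs$range_low,
      range_high = if (is.null(bs$range_high)) 12 else bs$range_high,
      width = if (is.null(bs$width)) 0.01 else bs$width,
      exclusions = if (is.null(bs$exclusions))
        BucketSpec()@exclusions else
        do.call(rbind, lapply(bs$exclusions, function(e)
          data.frame(low = e$low, high = e$high))))
    say("bucket: range ", spec@range_low, "-", spec@range_high,
        " ppm, width ", spec@width, ", exclusions ",
        paste(sprintf("%g:%g", spec@exclusions$low, spec@exclusions$high),
              collapse = " "))
    table <- buildBucketTable(spectra, spec, normalize = TRUE)
    say("normalization: per-spectrum below-mean -> 0, above-mean -> 1..100")
    bucket_csv <- file.path(out_dir, "buckets.csv")
    df <- data.frame(sample_id = sampleIds(table),
                     bucketValues(table), check.names = FALSE)
    write.csv(df, bucket_csv, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(config_hash = hash, seed = seed,
           bucket_spec = list(range_low = spec@range_low,
                              range_high = spec@range_high,
                              width = spec@width,
                              exclusions = spec@exclusions),
           normalized = TRUE),
      file.path(out_dir, "buckets_spec.json"), auto_unbox = TRUE,
      digits = NA)

    stage <- "cluster"
    d <- euclideanDistances(table)
    dm <- as.matrix(d)
    write.csv(data.frame(sample_id = rownames(dm), dm, check.names = FALSE),
              file.path(out_dir, "distance.csv"), row.names = FALSE,
              quote = FALSE)
    dend <- wardLinkage(d)
    nwk <- file.path(out_dir, "dendrogram.nwk")
    dendrogramNewick(dend, nwk)
    k <- if (!is.null(config$cluster$k)) config$cluster$k
         else if (!is.null(truth)) length(unique(truth))
         else stop("cluster k not given and no species labels available")
    assignment <- cutDendrogram(dend, k)
    say("cluster: metric=euclidean linkage=ward.D2 k=", k)
    recovery <- if (!is.null(truth)) speciesRecovery(assignment, truth)
                else NULL
    if (!is.null(recovery))
      say("species recovery: ", recovery$recovered, "/",
          length(recovery$per_species), " pure (purity ",
          format(recovery$purity, digits = 4), ")")

    stage <- "assign"
    dtol <- if (is.null(config$assign$delta_tol)) 0.03
            else config$assign$delta_tol
    jtol <- if (is.null(config$assign$j_tol)) 1.0 else config$assign$j_tol
    say("assign: delta_tol=", dtol, " ppm, j_tol=", jtol, " Hz")
    reports <- lapply(spectra, function(s) {
      obs <- groupMultiplets(pickPeaks(s),
                             field_mhz = spectrumMeta(s)$field_mhz)
      matchLibrary(obs, library, delta_tol = dtol, j_tol = jtol)
    })
    rep_json <- file.path(out_dir, "assignments.json")
    jsonlite::write_json(
      list(config_hash = hash, seed = seed,
           samples = lapply(seq_along(reports), function(i) list(
             sample_id = spectrumMeta(spectra[[i]])$sample_id,
             identified = identifiedMetabolites(reports[[i]]),
             cluster = unname(assignment[i])))),
      rep_json, auto_unbox = TRUE, digits = NA)

    jsonlite::write_json(
      list(config_hash = hash, seed = seed,
           outputs = c("buckets.csv", "buckets_spec.json", "distance.csv",
                       "dendrogram.nwk", "assignments.json", "run.log")),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
    list(table = table, dendrogram = dend, assignment = assignment,
         recovery = recovery, reports = reports, out_dir = out_dir)
  }, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
  invisible(res)
}
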