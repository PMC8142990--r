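# TIFF input/output. Reading goes through tiff::readTIFF (which handles
# 8/16-bit integer and 32-bit float grayscale). Integer export goes through
# tiff::writeTIFF. 32-bit float export uses a minimal writer below, because
# the installed tiff package only writes unsigned-integer sample formats
# scaled from [0, 1], which cannot represent phase maps losslessly.

# ---- minimal multi-page float32 TIFF writer -------------------------------

# Writes an uncompressed little-endian grayscale float32 TIFF, one IFD per
# frame, single strip per frame. `description` (a string) is attached to the
# first IFD's ImageDescription tag.
writeFloatTiff <- function(frames, path, description = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(length(frames) >= 1L, all(vapply(frames, is.matrix, logical(1))))
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  descRaw <- NULL
  descCount <- 0L
  if (!is.null(description)) {
    descRaw <- c(charToRaw(enc2utf8(description)), as.raw(0L))
    descCount <- length(descRaw)            # includes the terminating NUL
    if (descCount %% 2L) descRaw <- c(descRaw, as.raw(0L))  # even padding
  }

  # Layout: 8-byte header, then per frame [pixel strip][IFD], description
  # block (if any) after the first frame's IFD.
  nFr <- length(frames)
  stripLen <- vapply(frames, function(f) 4L * length(f), integer(1))
  nEntries <- function(i) if (i == 1L && !is.null(descRaw)) 11L else 10L
  ifdLen <- function(i) 2L + 12L * nEntries(i) + 4L
  offsets <- vector("list", nFr)
  pos <- 8L
  for (i in seq_len(nFr)) {
    strip <- pos
    ifd <- strip + stripLen[i]
    descOff <- 0L
    after <- ifd + ifdLen(i)
    if (i == 1L && !is.null(descRaw)) {
      descOff <- after
      after <- after + length(descRaw)
    }
    offsets[[i]] <- list(strip = strip, ifd = ifd, desc = descOff)
    pos <- after
  }

  writeBin(charToRaw("II"), con)
  w2(42L)
  w4(offsets[[1L]]$ifd)

  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count); w4(value)
  }
  for (i in seq_len(nFr)) {
    f <- frames[[i]]
    writeBin(as.numeric(t(f)), con, size = 4, endian = "little")  # row-major
    w2(nEntries(i))
    entry(256L, 4L, 1L, ncol(f))                     # ImageWidth
    entry(257L, 4L, 1L, nrow(f))                     # ImageLength
    entry(258L, 3L, 1L, 32L)                         # BitsPerSample
    entry(259L, 3L, 1L, 1L)                          # Compression: none
    entry(262L, 3L, 1L, 1L)                          # Photometric: BlackIsZero
    if (i == 1L && !is.null(descRaw))
      entry(270L, 2L, descCount, offsets[[i]]$desc)  # ImageDescription
    entry(273L, 4L, 1L, offsets[[i]]$strip)          # StripOffsets
    entry(277L, 3L, 1L, 1L)                          # SamplesPerPixel
    entry(278L, 4L, 1L, nrow(f))                     # RowsPerStrip
    entry(279L, 4L, 1L, stripLen[i])                 # StripByteCounts
    entry(339L, 3L, 1L, 3L)                          # SampleFormat: IEEE float
    w4(if (i < nFr) offsets[[i + 1L]]$ifd else 0L)   # next IFD
    if (i == 1L && !is.null(descRaw)) writeBin(descRaw, con)
  }
  invisible(path)
}

# ---- stacks ---------------------------------------------------------------

#' Read an interferogram stack from TIFF
#'
#' Accepts a multi-page TIFF path, a character vector of single-page files,
#' or a glob pattern; multiple files are ordered lexicographically. Integer
#' data are converted to floating intensities without rescaling unless
#' \code{scaling} is given. If a JSON sidecar \code{<path>.json} written by
#' \code{\link{writeInterferogramStack}} is present, the recorded shifts and
#' generation parameters are restored.
#'
#' @param path TIFF file(s) or glob pattern
#' @param scaling counts per stored unit (default 1 = no rescaling)
#' @return an \linkS4class{InterferogramStack}
#' @export
readInterferogramStack <- function(path, scaling = 1) {
  files <- if (length(path) == 1L && !file.exists(path)) sort(Sys.glob(path))
           else path
  if (!length(files))
    stop(sprintf("no files match '%s'", path))
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  frames <- list()
  for (f in files) {
    pages <- tryCatch(
      # as.is=TRUE keeps integer counts unscaled but is rejected for float
      # images; those are already stored in physical counts.
      tryCatch(tiff::readTIFF(f, all = TRUE, as.is = TRUE),
               error = function(e) {
                 if (grepl("as.is", conditionMessage(e), fixed = TRUE))
                   tiff::readTIFF(f, all = TRUE)
                 else stop(e)
               }),
      error = function(e)
        stop(sprintf("cannot parse '%s' as TIFF: %s",
                     f, conditionMessage(e)), call. = FALSE))
    frames <- c(frames, lapply(pages, function(p) {
      if (length(dim(p)) == 3L)
        stop(sprintf("'%s' is not grayscale (found %d channels)", f, dim(p)[3L]))
      m <- as.matrix(p) * scaling
      storage.mode(m) <- "double"
      m
    }))
  }
  if (!length(frames)) stop("zero pages read")
  shapes <- vapply(frames, function(f) paste(dim(f), collapse = "x"), character(1))
  if (length(unique(shapes)) > 1L)
    stop("mixed frame shapes: ", paste(unique(shapes), collapse = ", "))
  shifts <- NULL; A <- NA_real_; B <- NA_real_; ns <- 0; seed <- NA_integer_
  sidecar <- paste0(files[1L], ".json")
  if (length(files) == 1L && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    shifts <- meta$shifts_rad
    A <- meta$background_A %||% NA_real_
    B <- meta$modulation_B %||% NA_real_
    ns <- meta$noise_sigma %||% 0
    seed <- meta$seed %||% NA_integer_
  }
  InterferogramStack(frames, shiftsRad = shifts, backgroundA = A,
                     modulationB = B, noiseSigma = ns,
                     seed = as.integer(seed))
}

#' Write an interferogram stack to a multi-page TIFF
#'
#' 16-bit unsigned output clips to [0, 65535] and rounds; 32-bit float
#' output is lossless. A JSON sidecar \code{<path>.json} records shifts,
#' generation parameters and seed so a stack directory is self-describing.
#'
#' @param stack an \linkS4class{InterferogramStack}
#' @param path output file
#' @param dtype "uint16" (default) or "float32"
#' @return the path, invisibly
#' @export
writeInterferogramStack <- function(stack, path, dtype = c("uint16", "float32")) {
  dtype <- match.arg(dtype)
  fr <- stackFrames(stack)
  if (dtype == "uint16") {
    scaled <- lapply(fr, function(f) pmin(pmax(round(f), 0), 65535) / 65535)
    tiff::writeTIFF(scaled, path, bits.per.sample = 16L, compression = "none")
  } else {
    writeFloatTiff(fr, path)
  }
  scalarOrNA <- function(x) if (is.numeric(x) && length(x) == 1L) x else NA_real_
  meta <- list(frames = length(fr), dtype = dtype,
               shifts_rad = frameShifts(stack),
               background_A = scalarOrNA(stack@backgroundA),
               modulation_B = scalarOrNA(stack@modulationB),
               noise_sigma = stack@noiseSigma,
               seed = stack@seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

# ---- phase maps -----------------------------------------------------------

opticsToList <- function(cfg) {
  list(wavelength_nm = wavelengthNm(cfg), delta_n = deltaN(cfg),
       pass_factor = passFactor(cfg), pixel_size_nm = pixelSizeNm(cfg),
       psf_fwhm_nm = psfFwhmNm(cfg))
}

opticsFromList <- function(x) {
  OpticalConfig(wavelengthNm = x$wavelength_nm, deltaN = x$delta_n,
                passFactor = x$pass_factor, pixelSizeNm = x$pixel_size_nm,
                psfFwhmNm = x$psf_fwhm_nm %||% 0)
}

#' Write a phase map as 32-bit float TIFF
#'
#' The optical configuration is serialized as JSON into the TIFF
#' ImageDescription tag, so the file alone suffices to reconstruct the
#' \linkS4class{PhaseMap}. Round trip is exact.
#'
#' @param phase a \linkS4class{PhaseMap}
#' @param path output file
#' @return the path, invisibly
#' @export
writePhaseTiff <- function(phase, path) {
  desc <- jsonlite::toJSON(list(units = "radians",
                                optics = opticsToList(optics(phase))),
                           auto_unbox = TRUE, digits = NA)
  writeFloatTiff(phaseValues(phase), path, description = as.character(desc))
  invisible(path)
}

#' Read a phase map written by \code{\link{writePhaseTiff}}
#'
#' If the metadata tag is missing the phase still loads, with default optics
#' and a warning.
#'
#' @param path a 32-bit float TIFF of phase in radians
#' @return a \linkS4class{PhaseMap}
#' @export
readPhaseTiff <- function(path) {
  img <- tryCatch(tiff::readTIFF(path, info = TRUE),
                  error = function(e)
                    stop(sprintf("cannot parse '%s' as TIFF: %s",
                                 path, conditionMessage(e)), call. = FALSE))
  desc <- attr(img, "description")
  cfg <- NULL
  if (!is.null(desc)) {
    cfg <- tryCatch({
      meta <- jsonlite::fromJSON(desc)
      opticsFromList(as.list(meta$optics))
    }, error = function(e) NULL)
  }
  if (is.null(cfg)) {
    warning("no optics metadata found in '", path,
            "'; using default optical configuration", call. = FALSE)
    cfg <- OpticalConfig()
  }
  v <- as.matrix(img)
  storage.mode(v) <- "double"
  attributes(v) <- list(dim = dim(v))
  new("PhaseMap", values = v, optics = cfg)
}

# ---- run artifacts --------------------------------------------------------

#' Write all artifacts of an end-to-end run
#'
#' Produces, under \code{outDir}: stack.tif (+ sidecar), phase_raw.tif,
#' phase.tif, height.tif (all float32), truth.csv, particles.csv,
#' distribution.csv, summary.json and manifest.json. Coordinates in the CSV
#' files are 0-based pixel-centered (x = column, y = row), stated in each
#' header comment.
#'
#' @param result list returned by \code{\link{runEndToEnd}}
#' @param config the \linkS4class{ExperimentConfig} that produced it
#' @param outDir output directory (created if needed)
#' @return outDir, invisibly
#' @export
writeRunArtifacts <- function(result, config, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outDir, ...)
  writeInterferogramStack(result$stack, p("stack.tif"), dtype = "float32")
  writePhaseTiff(result$rawPhase, p("phase_raw.tif"))
  writePhaseTiff(result$phase, p("phase.tif"))
  writeFloatTiff(result$height, p("height.tif"),
                 description = "{\"units\":\"nm\"}")

  writeCsvWithHeader <- function(df, path, comment) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", comment), con)
    utils::write.csv(df, con, row.names = FALSE)
  }
  writeCsvWithHeader(
    cbind(particle_id = seq_len(nrow(particles(result$scene))),
          particles(result$scene)),
    p("truth.csv"),
    "ground truth; coordinates 0-based pixel-centered, x = column, y = row")
  writeCsvWithHeader(
    result$particleTable, p("particles.csv"),
    "detections; coordinates 0-based pixel-centered, x = column, y = row")
  d <- result$distribution
  edges <- binEdges(d)
  distDf <- if (length(edges) >= 2L) {
    data.frame(bin_left_nm = edges[-length(edges)],
               bin_right_nm = edges[-1L],
               count = binCounts(d), weight = d@binWeights)
  } else {
    data.frame(bin_left_nm = numeric(0), bin_right_nm = numeric(0),
               count = numeric(0), weight = numeric(0))
  }
  writeCsvWithHeader(distDf, p("distribution.csv"), "size histogram, nm bins")

  rep <- result$report
  jsonlite::write_json(
    list(summary = sizeSummary(d),
         recovery = list(n_true = rep@nTrue, n_detected = rep@nDetected,
                         n_matched = rep@nMatched,
                         false_positives = rep@falsePositives,
                         count_error = rep@countError,
                         diameter_bias_nm = rep@diameterBiasNm,
                         diameter_rmse_nm = rep@diameterRmseNm,
                         shift_rmse_rad = rep@shiftRmseRad,
                         converged = rep@converged)),
    p("summary.json"), auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(
    list(package = "qpmsizer",
         version = as.character(utils::packageVersion("qpmsizer")),
         seed = config@seed,
         config = configToList(config),
         config_hash = digestConfig(config)),
    p("manifest.json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(outDir)
}

# ---- experiment config serialization --------------------------------------

configToList <- function(config) {
  list(optics = opticsToList(config@optics),
       scene = config@scene,
       acquisition = config@acquisition,
       retrieval = config@retrieval,
       sizing = config@sizing,
       seed = config@seed)
}

configFromList <- function(x) {
  opt <- if (!is.null(x$optics)) opticsFromList(x$optics) else OpticalConfig()
  ExperimentConfig(optics = opt,
                   scene = x$scene %||% list(),
                   acquisition = x$acquisition %||% list(),
                   retrieval = x$retrieval %||% list(),
                   sizing = x$sizing %||% list(),
                   seed = x$seed %||% 1L)
}

# Stable content hash of the serialized config (no external digest
# dependency: sum of a byte-rolling polynomial over the canonical JSON).
digestConfig <- function(config) {
  s <- as.character(jsonlite::toJSON(configToList(config), auto_unbox = TRUE,
                                     digits = NA))
  bytes <- as.integer(charToRaw(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Read an experiment configuration from YAML or JSON
#'
#' @param path .yaml/.yml or .json file; the structure mirrors the
#'   arguments of \code{\link{ExperimentConfig}}, with optics given as
#'   wavelength_nm, delta_n, pass_factor, pixel_size_nm, psf_fwhm_nm
#' @return an \linkS4class{ExperimentConfig}
#' @export
readExperimentConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("config must be .yaml, .yml or .json"))
  configFromList(x)
}

#' Write an experiment configuration to YAML or JSON
#'
#' @param config an \linkS4class{ExperimentConfig}
#' @param path .yaml/.yml or .json output file
#' @return the path, invisibly
#' @export
writeExperimentConfig <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  x <- configToList(config)
  switch(ext,
    yaml = , yml = yaml::write_yaml(x, path),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"),
    stop("config must be .yaml, .yml or .json"))
  invisible(path)
}
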