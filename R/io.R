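#' Read a grayscale image
#'
#' Reads a PNG, TIFF or JPEG file into a single-channel float matrix scaled
#' to \[0, 255\]. Multi-channel inputs are converted to luminance
#' (0.299 R + 0.587 G + 0.114 B) with a warning; 16-bit inputs are rescaled
#' onto the 8-bit range (the decoders return intensities in \[0, 1\]).
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg` file.
#' @return Numeric matrix with values in \[0, 255\].
#' @export
readGrayImage <- function(path) {
  if (!file.exists(path))
    stop("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    stop("unsupported image format '", ext,
         "' (supported: png, tif/tiff, jpg/jpeg): ", path))
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc >= 3L) {
      warning("color image converted to luminance: ", path)
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]                      # gray + alpha
    }
  }
  arr * 255
}

#' Write a grayscale image
#'
#' Clips to \[0, 255\], rounds to 8-bit and writes a single-channel PNG or
#' TIFF (or JPEG at default quality).
#'
#' @param img Numeric matrix with finite values.
#' @param path Output path; the extension selects the encoder.
#' @return Invisibly, `path`.
#' @export
writeGrayImage <- function(img, path) {
  checkImage(img)
  v <- round(pmin(pmax(img, 0), 255)) / 255
  ext <- tolower(tools::file_ext(path))
  ok <- switch(ext,
    png = png::writePNG(v, path),
    tif = , tiff = tiff::writeTIFF(v, path, bits.per.sample = 8L),
    jpg = , jpeg = jpeg::writeJPEG(v, path),
    stop("unsupported image format '", ext, "': ", path))
  invisible(path)
}

configToList <- function(config) {
  n <- config$nsct
  list(nsct = list(levels = n@levels, dirExponents = n@dirExponents,
                   pyramidFilter = n@pyramidFilter,
                   directionalFilter = n@directionalFilter),
       loggabor = unclass(config$loggabor),
       pc = unclass(config$pc),
       windowM = config$windowM, windowN = config$windowN,
       pcTieTolerance = config$pcTieTolerance,
       ruleSet = config$ruleSet,
       energyBoundary = config$energyBoundary)
}

listToConfig <- function(x) {
  fusionConfig(
    nsct = nsctConfig(x$nsct$levels, x$nsct$dirExponents,
                      x$nsct$pyramidFilter, x$nsct$directionalFilter),
    loggabor = do.call(logGaborParams, x$loggabor),
    pc = do.call(pcParams, x$pc),
    windowM = x$windowM, windowN = x$windowN,
    pcTieTolerance = x$pcTieTolerance,
    ruleSet = x$ruleSet, energyBoundary = x$energyBoundary)
}

#' Write a fusion configuration to a YAML file
#'
#' Serialization is lossless: numbers are written with 17 significant
#' digits, so `readRunConfig(writeRunConfig(cfg, f))` reproduces `cfg`
#' bit-exactly.
#'
#' @param config A [fusionConfig()] list.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(configToList(config), path, precision = 17L)
  invisible(path)
}

#' Read a fusion configuration from a YAML file
#'
#' @param path Path written by [writeRunConfig()] (or hand-edited with the
#'   same keys; missing sub-keys fall back to package defaults).
#' @return A [fusionConfig()] list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  listToConfig(yaml::read_yaml(path))
}
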