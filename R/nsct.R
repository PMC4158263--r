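#' Create an NSCT configuration
#'
#' @param levels Number of pyramid levels (default 3).
#' @param dirExponents Integer vector, one entry per level, coarse to fine;
#'   level `k` is split into `2^dirExponents[k]` directional subbands.
#'   Default `c(2, 3, 4)`: the finest scale gets the most directions.
#' @param pyramidFilter Pyramid filter pair name (`"9-7"` or `"burt"`).
#' @param directionalFilter Directional bank realization (`"fan"`).
#' @return An [NSCTConfig-class] object.
#' @examples
#' nsctConfig(levels = 3, dirExponents = c(2, 3, 4))
#' @export
nsctConfig <- function(levels = 3L, dirExponents = c(2L, 3L, 4L),
                       pyramidFilter = "9-7", directionalFilter = "fan") {
  pyramidPrototype(pyramidFilter)            # fail early on unknown names
  if (!identical(directionalFilter, "fan"))
    stop("unknown directional filter name: '", directionalFilter, "'")
  new("NSCTConfig", levels = as.integer(levels),
      dirExponents = as.integer(dirExponents),
      pyramidFilter = pyramidFilter, directionalFilter = directionalFilter)
}

#' Nonsubsampled contourlet decomposition
#'
#' Decomposes an image into one low-frequency subimage and
#' `sum(2^dirExponents)` directional high-frequency subimages, all with the
#' dimensions of the input. The pyramid stage is a two-channel undecimated
#' filter bank whose filters are upsampled a-trous (zeros inserted) by
#' `2^j` at cascade step `j`; signals are never resampled. The directional
#' stage splits each bandpass band with smooth fan windows. All filtering is
#' circular (periodic boundaries), so the transform is linear and exactly
#' shift covariant, and `nsctReconstruct()` inverts it to floating-point
#' precision.
#'
#' @param img Numeric matrix (single-channel image).
#' @param config An [NSCTConfig-class]; default `nsctConfig()`.
#' @return An [NSCTDecomposition-class].
#' @examples
#' img <- matrix(runif(64 * 64, 0, 255), 64, 64)
#' dec <- nsctDecompose(img)
#' max(abs(nsctReconstruct(dec) - img))  # ~1e-13
#' @export
nsctDecompose <- function(img, config = nsctConfig()) {
  checkImage(img, minDim = 8L)
  validObject(config)
  dm <- dim(img)
  if (any(dm < 2L^config@levels))
    stop("image must be at least 2^levels (", 2L^config@levels,
         ") pixels in each dimension")
  X <- fft2(img)
  high <- vector("list", config@levels)
  ## peel the finest band first: cascade step j = 0 ... levels-1 maps to
  ## decomposition level k = levels ... 1 (level 1 is the coarsest)
  for (j in 0:(config@levels - 1L)) {
    k <- config@levels - j
    masks <- pyramidMasks(dm, config@pyramidFilter, j)
    Band <- masks$HP * X
    X <- masks$H0 * X
    wins <- designDirectionalWindows(dm, config@dirExponents[k],
                                     config@directionalFilter)
    high[[k]] <- lapply(wins, function(w) ifft2Re(w * Band))
  }
  new("NSCTDecomposition", low = ifft2Re(X), high = high,
      config = config, imgDim = as.integer(dm))
}

#' @describeIn NSCTDecomposition Inverse NSCT of a decomposition.
#' @export
setMethod("nsctReconstruct", "NSCTDecomposition", function(x) {
  validObject(x)
  cfg <- x@config
  dm <- x@imgDim
  X <- fft2(x@low)
  ## invert the cascade from the coarsest level outward; directional
  ## synthesis is the sum of the channels (identity synthesis windows)
  for (k in seq_len(cfg@levels)) {
    j <- cfg@levels - k
    masks <- pyramidMasks(dm, cfg@pyramidFilter, j)
    Band <- fft2(Reduce(`+`, x@high[[k]]))
    X <- masks$G0 * X + Band
  }
  ifft2Re(X)
})

#' @describeIn NSCTDecomposition Number of subbands per level plus low band.
#' @export
setMethod("show", "NSCTDecomposition", function(object) {
  cfg <- object@config
  cat("NSCTDecomposition of a", paste(object@imgDim, collapse = " x "),
      "image\n")
  cat("  pyramid: ", cfg@levels, " levels, '", cfg@pyramidFilter,
      "' filters\n", sep = "")
  cat("  directions (coarse to fine): ",
      paste(2L^cfg@dirExponents, collapse = ", "),
      " ('", cfg@directionalFilter, "' bank)\n", sep = "")
  cat("  subbands: 1 low +", sum(2L^cfg@dirExponents), "high, all",
      paste(object@imgDim, collapse = " x "), "\n")
})

#' @describeIn NSCTDecomposition Low-frequency subimage.
#' @export
setMethod("lowBand", "NSCTDecomposition", function(x) x@low)

#' @describeIn NSCTDecomposition High-frequency subimages.
#' @export
setMethod("highBands", "NSCTDecomposition", function(x, level) {
  if (missing(level)) return(x@high)
  if (level < 1L || level > x@config@levels)
    stop("level must be in 1..", x@config@levels)
  x@high[[level]]
})

#' @describeIn NSCTDecomposition Dimensions of the decomposed image.
#' @param x An `NSCTDecomposition`.
#' @export
setMethod("dim", "NSCTDecomposition", function(x) x@imgDim)
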