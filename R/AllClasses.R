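#' @import methods
NULL

#' NSCT decomposition settings
#'
#' Configuration of the nonsubsampled contourlet transform: number of pyramid
#' levels, directional-split exponents per level, and the filter realizations
#' used for the pyramid and directional stages.
#'
#' @slot levels Number of pyramid levels (theta).
#' @slot dirExponents Integer vector of length `levels`, ordered coarse to
#'   fine; level `k` is split into `2^dirExponents[k]` directional subbands.
#' @slot pyramidFilter Name of the pyramid filter pair (`"9-7"` or `"burt"`).
#' @slot directionalFilter Name of the directional-bank realization
#'   (`"fan"`, smooth raised-cosine frequency fan windows).
#' @seealso [nsctConfig()], [nsctDecompose()]
#' @exportClass NSCTConfig
setClass("NSCTConfig",
  representation(levels = "integer",
                 dirExponents = "integer",
                 pyramidFilter = "character",
                 directionalFilter = "character"))

setValidity("NSCTConfig", function(object) {
  if (length(object@levels) != 1L || object@levels < 1L)
    return("levels must be a single positive integer")
  if (length(object@dirExponents) != object@levels)
    return("dirExponents must have one entry per level")
  if (any(object@dirExponents < 0L))
    return("dirExponents must be non-negative")
  if (length(object@pyramidFilter) != 1L ||
      length(object@directionalFilter) != 1L)
    return("filter names must be single strings")
  TRUE
})

#' Nonsubsampled contourlet decomposition of an image
#'
#' Holds one low-frequency subimage and, for each pyramid level, a list of
#' directional high-frequency subimages. Every subband has the dimensions of
#' the decomposed image (the transform is undecimated), so the object is
#' fully described by its subbands plus the [NSCTConfig-class] used.
#'
#' @slot low Low-frequency subimage (matrix, input-sized).
#' @slot high List of length `levels(config)`; element `k` (coarse to fine)
#'   is a list of `2^dirExponents[k]` directional subband matrices.
#' @slot config The [NSCTConfig-class] used for the decomposition.
#' @slot imgDim Dimensions of the original image.
#' @seealso [nsctDecompose()], [nsctReconstruct()], [lowBand()], [highBands()]
#' @exportClass NSCTDecomposition
setClass("NSCTDecomposition",
  representation(low = "matrix",
                 high = "list",
                 config = "NSCTConfig",
                 imgDim = "integer"))

setValidity("NSCTDecomposition", function(object) {
  dm <- object@imgDim
  if (length(dm) != 2L) return("imgDim must have length 2")
  if (!identical(dim(object@low), dm))
    return("low subband does not match the image dimensions")
  cfg <- object@config
  if (length(object@high) != cfg@levels)
    return("one high-frequency level list per pyramid level is required")
  for (k in seq_along(object@high)) {
    bands <- object@high[[k]]
    if (length(bands) != 2L^cfg@dirExponents[k])
      return(sprintf("level %d must hold %d directional subbands", k,
                     2L^cfg@dirExponents[k]))
    for (b in bands)
      if (!identical(dim(b), dm))
        return("all subbands must match the image dimensions")
  }
  TRUE
})

#' Log-Gabor filter bank sampled on an FFT grid
#'
#' A set of `U x V` frequency-domain Log-Gabor kernels (scales times
#' orientations) sampled on the FFT lattice of a fixed image shape. Kernels
#' are real, non-negative, one-sided in angle (so filtered outputs are
#' complex quadrature pairs) and have zero response at DC.
#'
#' @slot params Parameter list from [logGaborParams()].
#' @slot kernels List of length `U * V` of frequency-domain kernel matrices,
#'   scale-major order (scale 1 orientations first).
#' @slot imgDim Image dimensions the bank is sampled for.
#' @seealso [logGaborBank()], [logGaborResponse()], [logGaborEnergy()]
#' @exportClass LogGaborBank
setClass("LogGaborBank",
  representation(params = "list",
                 kernels = "list",
                 imgDim = "integer"))

setValidity("LogGaborBank", function(object) {
  p <- object@params
  if (length(object@kernels) != p$numScales * p$numOrientations)
    return("kernel count must equal numScales * numOrientations")
  for (k in object@kernels) {
    if (!identical(dim(k), object@imgDim))
      return("all kernels must match imgDim")
    if (any(k < 0)) return("kernels must be non-negative")
    if (k[1, 1] != 0) return("kernels must vanish at the DC bin")
  }
  TRUE
})

#' Result of fusing a registered image pair
#'
#' The fused image together with per-subband selection (provenance) maps:
#' at every coefficient, the fusion rules either copy source A, copy source
#' B, or (low band, tie case / averaging rule) mix the two. Selection maps
#' are coded 1 = A, 2 = B, 0 = mixed.
#'
#' @slot fused Fused image (matrix, float, nominal range 0-255).
#' @slot selectionLow Selection map of the low-frequency band.
#' @slot selectionHigh List (levels) of lists (directions) of selection maps.
#' @slot config The fusion configuration list from [fusionConfig()].
#' @seealso [fuseImages()], [fusedImage()], [selectionMaps()]
#' @exportClass FusionResult
setClass("FusionResult",
  representation(fused = "matrix",
                 selectionLow = "matrix",
                 selectionHigh = "list",
                 config = "list"))

#' Objective evaluation of a fused image
#'
#' The six-metric report for a fused image F against its sources A and B:
#' standard deviation, edge-based similarity Q^AB/F, mutual information,
#' cross entropy, spatial frequency, and (when a reference is supplied)
#' PSNR in dB. `psnr` is `NA` when no reference was given and `Inf` when
#' the fused image equals the reference.
#'
#' @slot std Standard deviation of F.
#' @slot qabf Edge-based similarity in \[0, 1\].
#' @slot mi Mutual information MI_AF + MI_BF in bits.
#' @slot crossEntropy Mean histogram cross entropy of (A, F) and (B, F).
#' @slot spatialFrequency RMS row/column first-difference measure.
#' @slot psnr Peak signal-to-noise ratio versus the reference, dB.
#' @seealso [evaluateAll()]
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(std = "numeric",
                 qabf = "numeric",
                 mi = "numeric",
                 crossEntropy = "numeric",
                 spatialFrequency = "numeric",
                 psnr = "numeric"))
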