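#' @describeIn NSCTDecomposition The low-frequency subimage.
#' @param x An object.
#' @export
setGeneric("lowBand", function(x) standardGeneric("lowBand"))

#' @describeIn NSCTDecomposition Directional high-frequency subimages of one
#'   level (a list of matrices), or the full per-level list when `level` is
#'   missing.
#' @param level Pyramid level, 1 (coarsest) to `levels`.
#' @export
setGeneric("highBands", function(x, level) standardGeneric("highBands"))

#' @describeIn NSCTDecomposition Inverse transform; returns the image matrix.
#' @export
setGeneric("nsctReconstruct", function(x) standardGeneric("nsctReconstruct"))

#' @describeIn FusionResult The fused image matrix.
#' @export
setGeneric("fusedImage", function(x) standardGeneric("fusedImage"))

#' @describeIn FusionResult Selection maps: `list(low = matrix,
#'   high = list-of-lists)`, coded 1 = source A, 2 = source B, 0 = mixed.
#' @export
setGeneric("selectionMaps", function(x) standardGeneric("selectionMaps"))
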