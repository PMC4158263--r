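#' Fusion configuration
#'
#' Bundles every tunable of the fusion pipeline: the NSCT settings, the
#' Log-Gabor bank for high-frequency activity, the phase-congruency
#' parameters for the low band, the local-energy window, the tie tolerance
#' of the low-band rule, and the rule set.
#'
#' @param nsct An [NSCTConfig-class] (default `nsctConfig()`).
#' @param loggabor A [logGaborParams()] list.
#' @param pc A [pcParams()] list.
#' @param windowM,windowN Local-energy window half-sizes (default 1:
#'   a 3 x 3 window).
#' @param pcTieTolerance Non-negative tolerance under which the two phase-
#'   congruency values count as equal and the low coefficients are averaged
#'   (default 1e-9; exact equality is measure-zero in floats).
#' @param ruleSet `"proposed"` (phase congruency + local Log-Gabor energy)
#'   or `"average_maximum"` (average the low band, pick the larger-absolute
#'   high coefficient).
#' @param energyBoundary Border policy of the local-energy window
#'   (`"periodic"` or `"reflect"`).
#' @return A validated configuration list of class `fusionConfig`.
#' @export
fusionConfig <- function(nsct = nsctConfig(), loggabor = logGaborParams(),
                         pc = pcParams(), windowM = 1L, windowN = 1L,
                         pcTieTolerance = 1e-9,
                         ruleSet = c("proposed", "average_maximum"),
                         energyBoundary = c("periodic", "reflect")) {
  ruleSet <- match.arg(ruleSet)
  energyBoundary <- match.arg(energyBoundary)
  validObject(nsct)
  if (pcTieTolerance < 0) stop("pcTieTolerance must be non-negative")
  if (windowM < 0 || windowN < 0) stop("window half-sizes must be >= 0")
  structure(list(nsct = nsct, loggabor = loggabor, pc = pc,
                 windowM = as.integer(windowM), windowN = as.integer(windowN),
                 pcTieTolerance = pcTieTolerance, ruleSet = ruleSet,
                 energyBoundary = energyBoundary),
            class = "fusionConfig")
}

#' Low-frequency fusion rule
#'
#' Per-pixel selection of the low-frequency coefficient by phase
#' congruency: take the coefficient of the source with the larger PC value;
#' where the two PC values agree within `tol`, average the coefficients.
#'
#' @param LA,LB Low-frequency subimages of sources A and B.
#' @param PCA,PCB Phase-congruency maps of `LA` and `LB`.
#' @param tol Tie tolerance (non-negative).
#' @return List with `fused` (matrix) and `selection` (matrix coded
#'   1 = A, 2 = B, 0 = averaged).
#' @export
fuseLow <- function(LA, LB, PCA, PCB, tol = 1e-9) {
  checkSameShape(LA, LB, PCA, PCB)
  if (tol < 0) stop("tol must be non-negative")
  tie <- abs(PCA - PCB) <= tol
  useA <- PCA > PCB & !tie
  fused <- 0.5 * (LA + LB)
  fused[useA] <- LA[useA]
  useB <- !useA & !tie
  fused[useB] <- LB[useB]
  selection <- matrix(0, nrow(LA), ncol(LA))
  selection[useA] <- 1
  selection[useB] <- 2
  list(fused = fused, selection = selection)
}

#' High-frequency fusion rule
#'
#' Per-pixel selection of the high-frequency coefficient by local
#' Log-Gabor energy: the coefficient of source A is taken where
#' `LEA >= LEB`, otherwise the coefficient of source B. Coefficients are
#' copied, never mixed.
#'
#' @param HA,HB High-frequency subbands of sources A and B.
#' @param LEA,LEB Local energy maps of `HA` and `HB`.
#' @return List with `fused` and `selection` (1 = A, 2 = B).
#' @export
fuseHigh <- function(HA, HB, LEA, LEB) {
  checkSameShape(HA, HB, LEA, LEB)
  useA <- LEA >= LEB
  fused <- HB
  fused[useA] <- HA[useA]
  selection <- matrix(2, nrow(HA), ncol(HA))
  selection[useA] <- 1
  list(fused = fused, selection = selection)
}

#' Fuse a registered pair of images in the NSCT domain
#'
#' The three-step pipeline: (1) decompose both sources with the NSCT;
#' (2) fuse the low-frequency subimages by phase congruency ([fuseLow()])
#' and every high-frequency subband by local Log-Gabor energy
#' ([fuseHigh()]); (3) invert the NSCT on the fused subbands. With
#' `ruleSet = "average_maximum"` the widely used baseline is applied
#' instead: the low band is the average of the sources and each high
#' coefficient is the one with the larger absolute value.
#'
#' The sources must be registered; no alignment is performed.
#'
#' @param A,B Numeric matrices of identical dimensions (nominal intensity
#'   range 0-255).
#' @param config A [fusionConfig()] list.
#' @return A [FusionResult-class].
#' @examples
#' ph <- makePhantomPair(size = c(64, 64), seed = 1)
#' res <- fuseImages(ph$A, ph$B)
#' dim(fusedImage(res))
#' @export
fuseImages <- function(A, B, config = fusionConfig()) {
  checkImage(A, what = "A"); checkImage(B, what = "B")
  checkSameShape(A, B)
  decA <- nsctDecompose(A, config$nsct)
  decB <- nsctDecompose(B, config$nsct)
  nlev <- config$nsct@levels
  selHigh <- vector("list", nlev)
  highF <- vector("list", nlev)
  if (config$ruleSet == "proposed") {
    pcA <- phaseCongruency(lowBand(decA), config$pc)
    pcB <- phaseCongruency(lowBand(decB), config$pc)
    lowRes <- fuseLow(lowBand(decA), lowBand(decB), pcA, pcB,
                      config$pcTieTolerance)
    bank <- logGaborBank(dim(A), config$loggabor)
    for (k in seq_len(nlev)) {
      nd <- length(highBands(decA, k))
      highF[[k]] <- vector("list", nd)
      selHigh[[k]] <- vector("list", nd)
      for (d in seq_len(nd)) {
        HA <- highBands(decA, k)[[d]]
        HB <- highBands(decB, k)[[d]]
        LEA <- localEnergy(logGaborEnergy(logGaborResponse(HA, bank)),
                           config$windowM, config$windowN,
                           config$energyBoundary)
        LEB <- localEnergy(logGaborEnergy(logGaborResponse(HB, bank)),
                           config$windowM, config$windowN,
                           config$energyBoundary)
        r <- fuseHigh(HA, HB, LEA, LEB)
        highF[[k]][[d]] <- r$fused
        selHigh[[k]][[d]] <- r$selection
      }
    }
  } else {
    lowRes <- list(fused = 0.5 * (lowBand(decA) + lowBand(decB)),
                   selection = matrix(0, nrow(A), ncol(A)))
    for (k in seq_len(nlev)) {
      nd <- length(highBands(decA, k))
      highF[[k]] <- vector("list", nd)
      selHigh[[k]] <- vector("list", nd)
      for (d in seq_len(nd)) {
        HA <- highBands(decA, k)[[d]]
        HB <- highBands(decB, k)[[d]]
        useA <- abs(HA) >= abs(HB)
        fused <- HB
        fused[useA] <- HA[useA]
        sel <- matrix(2, nrow(A), ncol(A))
        sel[useA] <- 1
        highF[[k]][[d]] <- fused
        selHigh[[k]][[d]] <- sel
      }
    }
  }
  decF <- new("NSCTDecomposition", low = lowRes$fused, high = highF,
              config = config$nsct, imgDim = as.integer(dim(A)))
  new("FusionResult", fused = nsctReconstruct(decF),
      selectionLow = lowRes$selection, selectionHigh = selHigh,
      config = unclass(config))
}

#' @describeIn FusionResult The fused image matrix.
#' @export
setMethod("fusedImage", "FusionResult", function(x) x@fused)

#' @describeIn FusionResult Per-subband selection maps.
#' @export
setMethod("selectionMaps", "FusionResult",
          function(x) list(low = x@selectionLow, high = x@selectionHigh))

#' @describeIn FusionResult Summary of the fusion run.
#' @param object A `FusionResult`.
#' @export
setMethod("show", "FusionResult", function(object) {
  cat("FusionResult:", paste(dim(object@fused), collapse = " x "),
      "fused image, rule set '", object@config$ruleSet, "'\n", sep = " ")
  sel <- object@selectionLow
  cat(sprintf("  low band: %.1f%% from A, %.1f%% from B, %.1f%% averaged\n",
              100 * mean(sel == 1), 100 * mean(sel == 2),
              100 * mean(sel == 0)))
})
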