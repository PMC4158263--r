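#' Phase-congruency parameters
#'
#' Settings for the phase-congruency measure: a bank of Log-Gabor quadrature
#' filters (scales times orientations) plus the noise-floor and weighting
#' constants of the local-energy model.
#'
#' @param numScales Wavelet scales per orientation (default 4).
#' @param numOrientations Number of filter orientations (default 6).
#' @param finestWavelength Wavelength of the finest-scale filter in pixels
#'   (default 3; centre frequency 1/3 cycles/pixel).
#' @param scaleMultiplier Wavelength ratio between successive scales
#'   (default 2.1).
#' @param sigmaRatio Radial bandwidth ratio of the filters (default 0.55).
#' @param noiseThresholdK Multiplier k for the noise floor `T`, estimated
#'   from the finest-scale amplitude distribution (default 2.0).
#' @param epsilon Small constant stabilising the normalisation
#'   (default 1e-4).
#' @param cutoff,gain Constants of the sigmoid frequency-spread weight
#'   `W = 1 / (1 + exp(gain * (cutoff - spread)))` (defaults 0.5 and 10).
#' @return A validated parameter list of class `pcParams`.
#' @export
pcParams <- function(numScales = 4L, numOrientations = 6L,
                     finestWavelength = 3, scaleMultiplier = 2.1,
                     sigmaRatio = 0.55, noiseThresholdK = 2,
                     epsilon = 1e-4, cutoff = 0.5, gain = 10) {
  if (numScales < 1L || numOrientations < 1L)
    stop("numScales and numOrientations must be positive")
  if (finestWavelength < 2) stop("finestWavelength must be at least 2 px")
  if (scaleMultiplier <= 1) stop("scaleMultiplier must exceed 1")
  if (epsilon <= 0) stop("epsilon must be positive")
  structure(list(numScales = as.integer(numScales),
                 numOrientations = as.integer(numOrientations),
                 finestWavelength = finestWavelength,
                 scaleMultiplier = scaleMultiplier,
                 sigmaRatio = sigmaRatio,
                 noiseThresholdK = noiseThresholdK,
                 epsilon = epsilon, cutoff = cutoff, gain = gain),
            class = "pcParams")
}

#' Phase congruency map
#'
#' Computes the phase-congruency measure
#' `PC = sum_theta sum_n W [A_n (cos(phi_n - phibar) - |sin(phi_n -
#' phibar)|) - T]_+ / (sum_theta sum_n A_n + eps)` on a per-pixel basis,
#' where `A_n` and `phi_n` are the amplitude and phase of the response to a
#' Log-Gabor quadrature filter at scale `n`, `phibar` is the amplitude-
#' weighted mean phase over scales, `W` is a sigmoid weight on the spread of
#' filter responses across scales, `T` is a noise floor and `[.]_+` clamps
#' negatives to zero. High values mark pixels where Fourier components are
#' maximally in phase (edges, lines); the measure is invariant to affine
#' intensity rescaling of the input, which is what makes it a robust
#' selector for multimodal low-frequency coefficients.
#'
#' Numerators and denominators are accumulated over orientations before the
#' final division, giving one scalar map. The noise floor `T` is estimated
#' per orientation from the median finest-scale amplitude under a Rayleigh
#' noise-response model, scaled by `noiseThresholdK`.
#'
#' @param img Numeric matrix, at least 8 x 8, finite values.
#' @param params A [pcParams()] list.
#' @return Matrix of the same shape with values in \[0, 1\].
#' @examples
#' step <- cbind(matrix(0, 32, 16), matrix(255, 32, 16))
#' pc <- phaseCongruency(step)
#' range(pc)  # within [0, 1]; large near column 16/17
#' @export
phaseCongruency <- function(img, params = pcParams()) {
  checkImage(img, minDim = 8L)
  p <- params
  dm <- dim(img)
  X <- fft2(img)
  numer <- matrix(0, dm[1], dm[2])
  denom <- matrix(0, dm[1], dm[2])
  tiny <- .Machine$double.eps * 100
  for (v in seq_len(p$numOrientations)) {
    theta0 <- (v - 1) * pi / p$numOrientations
    sumE <- sumO <- sumA <- matrix(0, dm[1], dm[2])
    maxA <- matrix(0, dm[1], dm[2])
    resp <- vector("list", p$numScales)
    for (n in seq_len(p$numScales)) {
      f0 <- 1 / (p$finestWavelength * p$scaleMultiplier^(n - 1))
      k <- logGaborKernel(dm, f0, theta0, p$sigmaRatio,
                          sigmaTheta = pi / p$numOrientations / 1.2)
      G <- ifft2(X * k)
      resp[[n]] <- G
      A <- Mod(G)
      sumE <- sumE + Re(G)
      sumO <- sumO + Im(G)
      sumA <- sumA + A
      maxA <- pmax(maxA, A)
    }
    ## amplitude-weighted mean phase direction over scales
    XE <- sqrt(sumE^2 + sumO^2) + tiny
    mE <- sumE / XE
    mO <- sumO / XE
    energy <- matrix(0, dm[1], dm[2])
    for (n in seq_len(p$numScales)) {
      e <- Re(resp[[n]]); o <- Im(resp[[n]])
      energy <- energy + (e * mE + o * mO - abs(e * mO - o * mE))
    }
    ## Rayleigh-model noise floor from the finest-scale amplitude median
    tau <- stats::median(Mod(resp[[1]])) / sqrt(log(4))
    totalTau <- tau * (1 - (1 / p$scaleMultiplier)^p$numScales) /
      (1 - 1 / p$scaleMultiplier)
    noiseT <- totalTau * sqrt(pi / 2) +
      p$noiseThresholdK * totalTau * sqrt((4 - pi) / 2)
    energy <- pmax(energy - noiseT, 0)
    ## sigmoid weighting by the spread of response across scales
    spread <- (sumA / (maxA + tiny)) / p$numScales
    W <- 1 / (1 + exp(p$gain * (p$cutoff - spread)))
    numer <- numer + W * energy
    denom <- denom + sumA
  }
  pc <- numer / (denom + p$epsilon)
  pmin(pmax(pc, 0), 1)
}
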